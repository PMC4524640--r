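#' Blocked five-fold cross-validation plan
#'
#' Splits the usable bins (in time order) into `k` contiguous, equal-length
#' (within one bin) blocks; each block is a held-out test fold.
#'
#' @param n number of usable bins.
#' @param k number of folds (default 5).
#' @return integer vector of fold assignments, length `n`.
#' @export
fold_plan <- function(n, k = 5L) {
  if (n < k) stop("fewer bins than folds")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Blocked cross-validated seizure forecasting
#'
#' Runs the full forecasting pipeline with five-fold blocked
#' cross-validation: the labeled bins are split into five contiguous
#' equal-length time blocks; for each block the classifier is trained on the
#' labeled (preictal/interictal) bins of the other four and applied to every
#' monitored bin of the held-out block. Out-of-fold decision calls are
#' assembled in time order, the warning engine is run once on the assembled
#' sequence, and all metrics are computed against the Poisson chance
#' predictor.
#'
#' Leakage guard: preictal bins whose seizure onset falls inside the test
#' block are dropped from the training set even when the fold boundary
#' bisects the preictal window.
#'
#' @param fm a [feature_matrix()] over the monitored bins.
#' @param catalog full [seizure_catalog()].
#' @param gaps [gap_list()] or `NULL`.
#' @param timeline `c(start, end)` (s).
#' @param lab_config [labeling_config()].
#' @param clf_config [classifier_config()].
#' @param k number of folds (default 5).
#' @param window_len warning window (min), default the preictal length.
#' @param target_tiw threshold-tuning target (default 0.30).
#' @param tune if `TRUE`, grid-search the cost per fold on a training
#'   excerpt; default `FALSE` (use `clf_config$cost`).
#' @return an `evaluation_result` (see [evaluate_warnings()]) with the
#'   assembled `calls` attached.
#' @export
crossval_forecast <- function(fm, catalog, gaps, timeline,
                              lab_config = labeling_config(),
                              clf_config = classifier_config(), k = 5L,
                              window_len = lab_config$preictal_len,
                              target_tiw = 0.30, tune = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- label_bins(timeline, catalog, gaps, lab_config)
  lab <- labels$label[match(fm$time, labels$time)]
  if (anyNA(lab)) stop("feature bins not aligned with the labeling grid")
  o <- order(fm$time)
  x <- fm$values[o, , drop = FALSE]
  t <- fm$time[o]
  lab <- lab[o]
  folds <- fold_plan(length(t), k)

  lead <- identify_lead_seizures(catalog, lab_config, gaps,
                                 rec_start = timeline[1L])
  # map each preictal bin to the lead seizure owning it
  pre_owner <- rep(NA_integer_, length(t))
  if (nrow(lead)) {
    w0 <- lead$onset - (lab_config$preictal_offset +
                          lab_config$preictal_len) * 60
    w1 <- lead$onset - lab_config$preictal_offset * 60
    for (s in seq_len(nrow(lead)))
      pre_owner[t >= w0[s] & t < w1[s]] <- s
    onset_fold <- vapply(lead$onset, function(on) {
      i <- findInterval(on, t)
      if (i < 1L) 1L else folds[i]
    }, integer(1L))
  }

  calls <- data.frame(time = t, decision = NA_real_, call = NA)
  for (f in seq_len(k)) {
    test <- folds == f
    trainable <- !test & lab %in% c("preictal", "interictal")
    if (nrow(lead)) {
      orphan <- !is.na(pre_owner) & onset_fold[pmax(pre_owner, 1L)] == f
      trainable <- trainable & !orphan
    }
    if (!any(lab[trainable] == "preictal"))
      warning("fold ", f, " has no preictal training bins")
    cost <- clf_config$cost
    if (tune) {
      cost <- tryCatch(
        tune_hyperparameters(x[trainable, , drop = FALSE], lab[trainable],
                             clf_config),
        error = function(e) clf_config$cost)
    }
    model <- train_classifier(x[trainable, , drop = FALSE],
                              droplevels(lab[trainable]),
                              classifier_config(cost = cost,
                                                tolerance = clf_config$tolerance))
    pred <- classify_bins(model, x[test, , drop = FALSE])
    calls$decision[test] <- pred$decision
    calls$call[test] <- pred$call
  }
  res <- evaluate_warnings(calls[, c("time", "call")], catalog, gaps,
                           timeline, lab_config, window_len, target_tiw)
  res$calls <- calls
  res
}
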