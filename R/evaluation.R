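#' Lead-seizure sensitivity
#'
#' Fraction of lead-seizure onsets that fall inside a warning interval.
#'
#' @param warnings a [aggregate_warnings()] result (or two-column matrix).
#' @param lead_seizures a [seizure_catalog()] of lead seizures.
#' @return fraction in \[0, 1\] (`NaN` when there are no lead seizures).
#' @export
compute_sensitivity <- function(warnings, lead_seizures) {
  if (nrow(lead_seizures) == 0L) return(NaN)
  mean(points_in_intervals(lead_seizures$onset, as.matrix(warnings)))
}

#' Time in warning (TIW)
#'
#' Proportion of monitored time spent in a warning state: the union of
#' warnings intersected with the monitored intervals, divided by total
#' monitored time. The complement of the study's specificity.
#'
#' @param warnings warning intervals.
#' @param monitored two-column matrix of monitored-time intervals (s), as
#'   from [monitored_intervals()].
#' @return fraction in \[0, 1\].
#' @export
compute_tiw <- function(warnings, monitored) {
  monitored <- interval_merge(monitored)
  tot <- sum(monitored[, 2L] - monitored[, 1L])
  if (tot <= 0) stop("no monitored time")
  interval_intersect_len(as.matrix(warnings), monitored) / tot
}

#' False positives per day
#'
#' Merged warnings containing no seizure onset, per monitored day.
#'
#' @param warnings warning intervals.
#' @param catalog full [seizure_catalog()] (all seizures, not only lead).
#' @param monitored monitored-time intervals (s).
#' @return rate (warnings/day).
#' @export
compute_fp_per_day <- function(warnings, catalog, monitored) {
  monitored <- interval_merge(monitored)
  days <- sum(monitored[, 2L] - monitored[, 1L]) / 86400
  if (days <= 0) stop("no monitored time")
  w <- interval_merge(as.matrix(warnings))
  if (nrow(w) == 0L) return(0)
  fp <- sum(vapply(seq_len(nrow(w)), function(k) {
    !any(catalog$onset >= w[k, 1L] & catalog$onset < w[k, 2L])
  }, logical(1L)))
  fp / days
}

#' Days without warning (DWW)
#'
#' Number of complete 24-hour periods, anchored at the recording start, that
#' intersect no warning.
#'
#' @param warnings warning intervals.
#' @param timeline numeric `c(start, end)` (s).
#' @return integer day count.
#' @export
compute_dww <- function(warnings, timeline) {
  ndays <- floor((timeline[2L] - timeline[1L]) / 86400)
  if (ndays < 1L) return(0L)
  w <- interval_merge(as.matrix(warnings))
  starts <- timeline[1L] + 86400 * (seq_len(ndays) - 1L)
  sum(vapply(starts, function(s) {
    interval_intersect_len(cbind(s, s + 86400), w) == 0
  }, logical(1L)))
}

#' Time-matched Poisson chance-predictor p-value
#'
#' Null model: a chance forecaster issues warnings of length `warning_len`
#' at Poisson-distributed times, with the rate chosen so that its asymptotic
#' time in warning matches the algorithm's (`P = 1 - exp(-lambda * W) =
#' tiw`). Each of the `n` lead seizures is then hit independently with
#' probability `P = tiw`, and the p-value is the binomial upper-tail
#' probability of `k` or more hits.
#'
#' @param n number of lead seizures.
#' @param k number of hits (lead seizures inside a warning).
#' @param tiw matched time-in-warning fraction.
#' @param warning_len warning length (min); determines the matched rate
#'   `lambda = -log(1 - tiw)/warning_len` but cancels from the hit
#'   probability.
#' @return upper-tail probability of >= k hits (`p = 1` at `k = 0`; the
#'   degenerate `tiw = 0` with `k > 0` returns 0).
#' @export
poisson_p_value <- function(n, k, tiw, warning_len = 90) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (tiw < 0 || tiw > 1) stop("tiw must lie in [0, 1]")
  if (k == 0L) return(1)
  stats::pbinom(k - 1, n, tiw, lower.tail = FALSE)
}

#' ROC over the warning threshold sweep
#'
#' Re-aggregates warnings at every integer threshold of the moving window
#' and reports the (TIW, sensitivity) operating point per threshold, plus
#' the trapezoidal area under the curve with endpoints (0,0) and (1,1)
#' appended.
#'
#' @param calls bin classification calls (`time`, `call`) in time order.
#' @param lead_seizures [seizure_catalog()] of lead seizures.
#' @param monitored monitored-time intervals.
#' @param window_len moving-window length (min).
#' @param gaps optional [gap_list()].
#' @param thresholds integer thresholds to sweep; default `1:window_len`.
#' @return a `roc_curve` data.frame (`threshold`, `tiw`, `sensitivity`) with
#'   attribute `auc`.
#' @export
roc_curve <- function(calls, lead_seizures, monitored, window_len = 90,
                      gaps = NULL, thresholds = seq_len(window_len)) {
  rows <- lapply(thresholds, function(th) {
    w <- aggregate_warnings(calls, warning_config(window_len, th), gaps)
    data.frame(threshold = th, tiw = compute_tiw(w, monitored),
               sensitivity = compute_sensitivity(w, lead_seizures))
  })
  out <- do.call(rbind, rows)
  pts <- out[order(out$tiw, out$sensitivity), ]
  x <- c(0, pts$tiw, 1); y <- c(0, pts$sensitivity, 1)
  y[is.nan(y)] <- 0
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Tune the warning threshold to a target time in warning
#'
#' Chooses the operating point with the largest TIW not exceeding the
#' target (TIW is non-increasing in the threshold, so this is the smallest
#' admissible threshold and maximizes sensitivity under the TIW cap). If no
#' threshold attains the target, the point with the smallest TIW is returned
#' with a message.
#'
#' @param roc a [roc_curve()] result.
#' @param target target TIW fraction (default 0.30).
#' @return the chosen threshold (integer).
#' @export
tune_threshold_to_tiw <- function(roc, target = 0.30) {
  ok <- roc$tiw <= target
  if (!any(ok)) {
    message("no threshold attains TIW <= ", target,
            "; using the minimum-TIW threshold")
    return(roc$threshold[which.min(roc$tiw)])
  }
  cand <- roc[ok, ]
  cand$threshold[which.max(cand$tiw)]
}

#' Assemble an evaluation result
#'
#' Computes all forecasting metrics for a fixed set of bin calls at a tuned
#' operating point: threshold tuned to the target TIW, sensitivity, TIW,
#' FP/day, DWW, ROC/AUC and the Poisson chance-predictor p-value.
#'
#' @param calls bin calls (`time`, `call`).
#' @param catalog full [seizure_catalog()].
#' @param gaps [gap_list()] or `NULL`.
#' @param timeline `c(start, end)` (s).
#' @param lab_config [labeling_config()].
#' @param window_len warning window (min); defaults to the labeling
#'   config's preictal length.
#' @param target_tiw target time in warning for threshold tuning.
#' @return an `evaluation_result` list with fields `lead_sensitivity`,
#'   `tiw`, `fp_per_day`, `dww`, `auc`, `p_value`, `n_lead`, `n_hit`,
#'   `threshold`, `roc`, `warnings`.
#' @export
evaluate_warnings <- function(calls, catalog, gaps, timeline,
                              lab_config = labeling_config(),
                              window_len = lab_config$preictal_len,
                              target_tiw = 0.30) {
  lead <- identify_lead_seizures(catalog, lab_config, gaps,
                                 rec_start = timeline[1L])
  monitored <- monitored_intervals(timeline, gaps, lab_config)
  roc <- roc_curve(calls, lead, monitored, window_len, gaps)
  th <- tune_threshold_to_tiw(roc, target_tiw)
  w <- aggregate_warnings(calls, warning_config(window_len, th), gaps)
  sens <- compute_sensitivity(w, lead)
  tiw <- compute_tiw(w, monitored)
  n_lead <- nrow(lead)
  n_hit <- if (n_lead) round(sens * n_lead) else 0L
  res <- list(lead_sensitivity = sens, tiw = tiw,
              fp_per_day = compute_fp_per_day(w, catalog, monitored),
              dww = compute_dww(w, timeline),
              auc = attr(roc, "auc"),
              p_value = if (n_lead) poisson_p_value(n_lead, n_hit, tiw,
                                                    window_len) else NA_real_,
              n_lead = n_lead, n_hit = n_hit, threshold = th, roc = roc,
              warnings = w)
  class(res) <- "evaluation_result"
  res
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Seizure-forecasting evaluation\n")
  cat(sprintf("  lead seizures: %d, hits: %d (sensitivity %.3f)\n",
              x$n_lead, x$n_hit, x$lead_sensitivity))
  cat(sprintf("  TIW %.3f | FP/day %.2f | DWW %d | AUC %.3f\n",
              x$tiw, x$fp_per_day, x$dww, x$auc))
  cat(sprintf("  Poisson chance-predictor p = %.4g (threshold %d)\n",
              x$p_value, x$threshold))
  invisible(x)
}
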