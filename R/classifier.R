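#' Classifier configuration
#'
#' Soft-margin linear support-vector classification (C-SVC) of one-minute
#' feature bins, with class weights inversely proportional to the class
#' sample counts to counter the heavy preictal/interictal imbalance.
#'
#' @param cost soft-margin cost C (> 0), default 1.
#' @param grid candidate costs for [tune_hyperparameters()].
#' @param tuning_excerpt fraction of the training data (first contiguous
#'   block, in time order) used for the tuning grid search; default 0.1.
#' @param gamma accepted and ignored: the kernel is linear, for which gamma
#'   is inert; a note is logged if a value is supplied.
#' @param tolerance termination tolerance of the SVM optimizer (default
#'   0.01). Bin decisions feed a 90-minute warning aggregation, so margin
#'   precision beyond this does not change the forecaster's output.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(cost = 1, grid = 10^seq(-2, 2),
                              tuning_excerpt = 0.1, gamma = NULL,
                              tolerance = 0.01) {
  if (cost <= 0) stop("cost must be positive")
  if (!length(grid)) stop("cost grid must be non-empty")
  if (!is.null(gamma))
    message("gamma is inert for a linear kernel; ignored")
  structure(list(kernel = "linear", cost = cost, grid = sort(grid),
                 tuning_excerpt = tuning_excerpt, tolerance = tolerance),
            class = "classifier_config")
}

feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}

check_two_class <- function(labels) {
  labels <- factor(labels, levels = c("interictal", "preictal"))
  n <- table(labels)
  if (n[["preictal"]] == 0L)
    stop("no preictal training bins: check the labeling stage ",
         "(lead seizures / preictal windows)")
  if (n[["interictal"]] == 0L)
    stop("no interictal training bins: check the labeling stage")
  labels
}

balanced_accuracy <- function(truth, pred) {
  lv <- levels(truth)
  mean(vapply(lv, function(l) {
    idx <- truth == l
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == l)
  }, numeric(1L)), na.rm = TRUE)
}

#' Grid-search the SVM cost on a training excerpt
#'
#' Takes the first contiguous `tuning_excerpt` fraction of the training rows
#' (time order, to avoid leaking later data), splits it in half in time,
#' trains on the first half at each candidate cost and scores bin-level
#' balanced accuracy on the second half. Ties resolve to the smallest cost.
#'
#' @param features [feature_matrix()] or numeric matrix (rows in time order).
#' @param labels factor/character of "preictal"/"interictal" per row.
#' @param config a [classifier_config()].
#' @return the chosen cost (scalar).
#' @export
tune_hyperparameters <- function(features, labels, config = classifier_config()) {
  x <- feature_values(features)
  labels <- check_two_class(labels)
  n_ex <- max(4L, floor(nrow(x) * config$tuning_excerpt))
  n_ex <- min(n_ex, nrow(x))
  half <- n_ex %/% 2L
  tr <- seq_len(half); va <- (half + 1L):n_ex
  if (length(unique(labels[tr])) < 2L || length(unique(labels[va])) < 2L)
    stop("tuning excerpt does not contain both classes in both halves")
  acc <- vapply(config$grid, function(C) {
    mod <- try(train_classifier(x[tr, , drop = FALSE], labels[tr],
                                classifier_config(cost = C,
                                                  tolerance = config$tolerance)),
               silent = TRUE)
    if (inherits(mod, "try-error")) return(-Inf)
    pred <- classify_bins(mod, x[va, , drop = FALSE])
    balanced_accuracy(labels[va],
                      ifelse(pred$call, "preictal", "interictal"))
  }, numeric(1L))
  if (all(!is.finite(acc)))
    stop("no grid candidate could be trained on the tuning excerpt ",
         "(degenerate features?)")
  config$grid[which.max(acc)]  # which.max takes the first (smallest) on ties
}

#' Train the class-weighted linear SVM
#'
#' Features are z-scored per column with training-set statistics
#' (zero-variance columns pass through unscaled), then a linear-kernel C-SVC
#' is fit with class weights proportional to (total rows)/(class rows). The
#' fitted hyperplane is stored explicitly as a weight vector and bias on the
#' raw feature scale, oriented so that a positive decision value means
#' preictal.
#'
#' @inheritParams tune_hyperparameters
#' @return a `trained_model` list: `w` (weights, one per feature column),
#'   `b` (bias), `center`, `scale`, `columns` (column names), `config`,
#'   `n_train` (per-class counts).
#' @export
train_classifier <- function(features, labels, config = classifier_config()) {
  x <- feature_values(features)
  labels <- check_two_class(labels)
  if (nrow(x) != length(labels)) stop("row/label length mismatch")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (all(scl == 0))
    stop("all feature columns are constant: degenerate training data")
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  n <- table(labels)
  wts <- as.numeric(sum(n)) / as.numeric(n)
  names(wts) <- names(n)
  fit <- e1071::svm(xs, labels, type = "C-classification", kernel = "linear",
                    cost = config$cost, class.weights = wts, scale = FALSE,
                    tolerance = config$tolerance, cachesize = 200)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the hyperplane: positive decision value = preictal
  d <- drop(xs %*% w) + b
  pred <- predict(fit, xs)
  agree <- mean((d > 0) == (pred == "preictal"))
  if (agree < 0.5) { w <- -w; b <- -b }
  structure(list(w = w, b = b, center = ctr, scale = scl,
                 columns = colnames(x), config = config,
                 n_train = as.list(n)), class = "trained_model")
}

#' Classify one-minute bins
#'
#' Applies the stored hyperplane: decision value
#' `d = sum(w * (x - center)/scale) + b`; `call` is `d > 0` (preictal).
#'
#' @param model a [train_classifier()] result.
#' @param features [feature_matrix()] or matrix with the model's columns.
#' @return data.frame with `time` (if available), `decision`, `call`
#'   (logical, TRUE = preictal).
#' @export
classify_bins <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  x <- feature_values(features)
  if (ncol(x) != length(model$w))
    stop("feature column count (", ncol(x), ") does not match model (",
         length(model$w), ")")
  if (!is.null(colnames(x)) && !is.null(model$columns) &&
      !identical(colnames(x), model$columns))
    stop("feature columns do not match the model's training columns")
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  d <- drop(xs %*% model$w) + model$b
  out <- data.frame(decision = d, call = d > 0)
  if (inherits(features, "feature_matrix"))
    out <- cbind(data.frame(time = features$time), out)
  out
}
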