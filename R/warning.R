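#' Warning-engine configuration
#'
#' @param window_len moving-window / warning length in minutes (equal to the
#'   preictal window length by convention; default 90).
#' @param threshold integer count of preictal bins within the trailing
#'   window required to trigger a warning (`1 <= threshold <= window_len`).
#' @return a `warning_config` list.
#' @export
warning_config <- function(window_len = 90, threshold = 45) {
  if (threshold < 1 || threshold > window_len)
    stop("threshold must lie in [1, window_len]")
  structure(list(window_len = window_len, threshold = threshold),
            class = "warning_config")
}

#' Aggregate bin classifications into seizure warnings
#'
#' The number of preictal calls among the trailing `window_len` minutes is
#' evaluated at every bin (causal window: only past bins can trigger). When
#' the count reaches the threshold, a warning of duration `window_len`
#' minutes starts at that bin; the warning is re-armed (extended) while the
#' condition persists, and overlapping or abutting warnings are merged. Raw
#' warnings crossing into a recording gap are truncated at the gap start.
#'
#' @param calls data.frame with `time` (bin start, s, ascending) and `call`
#'   (logical, TRUE = preictal), as returned by [classify_bins()].
#' @param config a [warning_config()].
#' @param gaps optional [gap_list()] used to truncate warnings.
#' @return a `warning_sequence` data.frame of merged `(start, end)`
#'   intervals (s).
#' @export
aggregate_warnings <- function(calls, config, gaps = NULL) {
  stopifnot(inherits(config, "warning_config"))
  if (config$threshold > config$window_len)
    stop("threshold must not exceed window_len")
  t <- calls$time
  if (is.unsorted(t)) stop("bin calls must be time-ordered")
  W <- config$window_len * 60
  out <- matrix(numeric(0), ncol = 2L)
  if (length(t)) {
    cs <- c(0, cumsum(as.numeric(calls$call)))
    lo <- findInterval(t - W, t)        # last index with time <= t_i - W
    cnt <- cs[seq_along(t) + 1L] - cs[lo + 1L]
    trig <- which(cnt >= config$threshold)
    if (length(trig)) {
      starts <- t[trig]
      ends <- starts + W
      if (!is.null(gaps) && nrow(gaps)) {
        for (k in seq_along(starts)) {
          nxt <- gaps$start[gaps$start >= starts[k]]
          if (length(nxt)) ends[k] <- min(ends[k], min(nxt))
        }
      }
      out <- interval_merge(cbind(starts, ends))
    }
  }
  out <- as.data.frame(out)
  names(out) <- c("start", "end")
  class(out) <- c("warning_sequence", "data.frame")
  out
}
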