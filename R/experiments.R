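#' Preictal-window length sweep
#'
#' Repeats the cross-validated forecasting run over a grid of preictal
#' window lengths: bins are relabeled with `preictal_len = L`, the warning
#' window is set to `L`, the threshold is tuned to the target TIW, and
#' sensitivity at that operating point is reported. Performance is expected
#' to peak when the analysis window matches the true physiological
#' signature length. Grid points with `L + preictal_offset >=
#' lead_min_sep` are skipped with a message.
#'
#' @param fm a [feature_matrix()].
#' @param catalog,gaps,timeline recording annotations (see
#'   [crossval_forecast()]).
#' @param lab_config base [labeling_config()].
#' @param clf_config [classifier_config()].
#' @param grid preictal window lengths (min); default 10-240 by 10.
#' @param target_tiw sweep operating point (default 0.30).
#' @param ... passed to [crossval_forecast()].
#' @return a `sweep_result` data.frame: one row per grid point with
#'   `param`, `sensitivity`, `tiw`, `p_value`.
#' @export
run_preictal_sweep <- function(fm, catalog, gaps, timeline,
                               lab_config = labeling_config(),
                               clf_config = classifier_config(),
                               grid = seq(10, 240, by = 10),
                               target_tiw = 0.30, ...) {
  rows <- lapply(grid, function(L) {
    if (L + lab_config$preictal_offset >= lab_config$lead_min_sep * 60) {
      message("preictal window ", L, " min reaches the lead-seizure ",
              "separation; skipped")
      return(NULL)
    }
    cfg <- lab_config
    cfg$preictal_len <- L
    res <- crossval_forecast(fm, catalog, gaps, timeline, cfg, clf_config,
                             window_len = L, target_tiw = target_tiw, ...)
    data.frame(param = L, sensitivity = res$lead_sensitivity, tiw = res$tiw,
               p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Frequency-band sweep
#'
#' Restricts the feature columns by frequency band and repeats the
#' cross-validated run at the target TIW. Three variants: `"single"` (one
#' band at a time), `"leave_one_out"` (all bands but one), and
#' `"cumulative"` (increasing prefix of bands, low to high frequency; the
#' full prefix equals the basic all-band run).
#'
#' @inheritParams run_preictal_sweep
#' @param kind `"single"`, `"leave_one_out"` or `"cumulative"`.
#' @param bands integer band indices in the sweep; default all bands in
#'   `fm`.
#' @return a `sweep_result` data.frame with `param` = band index (the held
#'   band for `"single"`, the omitted band for `"leave_one_out"`, the
#'   largest included band for `"cumulative"`).
#' @export
run_band_sweep <- function(fm, catalog, gaps, timeline,
                           lab_config = labeling_config(),
                           clf_config = classifier_config(),
                           kind = c("single", "leave_one_out", "cumulative"),
                           bands = sort(unique(fm$columns$band)),
                           target_tiw = 0.30, ...) {
  kind <- match.arg(kind)
  universe <- sort(unique(fm$columns$band))
  rows <- lapply(bands, function(b) {
    keep <- switch(kind,
                   single = b,
                   leave_one_out = setdiff(universe, b),
                   cumulative = universe[universe <= b])
    sub <- subset_features(fm, bands = keep)
    res <- crossval_forecast(sub, catalog, gaps, timeline, lab_config,
                             clf_config, target_tiw = target_tiw, ...)
    data.frame(param = b, sensitivity = res$lead_sensitivity, tiw = res$tiw,
               p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Bilateral electrode-pair experiment
#'
#' Restricts the correlation features to location-matched cross-hemisphere
#' contact pairs, one anatomical location label at a time (all frequency
#' bands retained), and repeats the cross-validated run. The feature matrix
#' must contain columns for the bilateral pairs of the montage (e.g. built
#' by [correlation_features()] or [generate_feature_level()] with
#' `pairs = bilateral_pairs(m)`).
#'
#' @inheritParams run_preictal_sweep
#' @param m a [montage()] providing the bilateral pair map.
#' @return a `sweep_result` data.frame with `param` = location label,
#'   ordered by decreasing sensitivity.
#' @export
run_bilateral_pair_experiment <- function(fm, catalog, gaps, timeline,
                                          lab_config = labeling_config(),
                                          clf_config = classifier_config(),
                                          m = default_montage(),
                                          target_tiw = 0.30, ...) {
  bp <- bilateral_pairs(m)
  locs <- unique(bp$location)
  rows <- lapply(locs, function(loc) {
    sub <- subset_features(fm, pairs = bp[bp$location == loc, ])
    res <- crossval_forecast(sub, catalog, gaps, timeline, lab_config,
                             clf_config, target_tiw = target_tiw, ...)
    data.frame(param = loc, sensitivity = res$lead_sensitivity,
               tiw = res$tiw, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$sensitivity, out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
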