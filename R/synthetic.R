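#' Simulation configuration for synthetic iEEG
#'
#' Describes a synthetic chronic recording: a homogeneous-Poisson seizure
#' process thinned by a refractory interval, Poisson-start recording gaps,
#' and a preictal signature — a band-limited common component added to
#' designated contact pairs during a window ending `signature_offset`
#' minutes before each seizure onset, raising both their pairwise
#' correlation and band power in `signature_band`.
#'
#' @param duration_hours recording span (h).
#' @param sampling_rate Hz (default 400).
#' @param n_channels channel count (default 16: four 4-contact strips).
#' @param seizure_rate pre-thinning seizure rate (events/day, default 2).
#' @param refractory minimum inter-seizure onset interval (min, default 240).
#' @param signature_band length-2 numeric, Hz (default the 29.5-43.5 Hz
#'   filter-bank band).
#' @param signature_pairs data.frame (`i`, `j`) of contact pairs carrying the
#'   preictal change; default the two upper adjacent pairs of strip 1.
#' @param signature_len preictal signature duration (min, default 90).
#' @param signature_offset signature end before onset (min, default 5),
#'   matching the labeling convention.
#' @param signature_strength effect size: fractional increase in pairwise
#'   correlation / band power (0 = null; default 0.3, a moderate but
#'   detectable change).
#' @param gap_rate gap starts per day (default 0.5).
#' @param gap_len_range gap length range (min), uniform; default 5-120 min so
#'   some gaps exceed the one-hour qualifying threshold.
#' @param baseline_cor baseline inter-channel correlation within a strip
#'   (default 0.2): real adjacent contacts are neither independent nor
#'   duplicated.
#' @param bin_ar lag-1 autocorrelation of feature-level bin noise (default
#'   0 = independent bins). Real synchrony features drift slowly from
#'   minute to minute; positive values shrink the effective sample count
#'   per preictal window, which matters for experiments that vary the
#'   training-window length. Feature-level generator only.
#' @param seed integer seed governing all stochastic draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_hours = 72, sampling_rate = 400,
                       n_channels = 16, seizure_rate = 2, refractory = 240,
                       signature_band = c(29.5, 43.5),
                       signature_pairs = data.frame(i = c(1L, 2L),
                                                    j = c(2L, 3L)),
                       signature_len = 90, signature_offset = 5,
                       signature_strength = 0.3, gap_rate = 0.5,
                       gap_len_range = c(5, 120), baseline_cor = 0.2,
                       bin_ar = 0, seed = 1L) {
  cfg <- list(duration_hours = duration_hours, sampling_rate = sampling_rate,
              n_channels = n_channels, seizure_rate = seizure_rate,
              refractory = refractory, signature_band = signature_band,
              signature_pairs = signature_pairs,
              signature_len = signature_len,
              signature_offset = signature_offset,
              signature_strength = signature_strength, gap_rate = gap_rate,
              gap_len_range = gap_len_range, baseline_cor = baseline_cor,
              bin_ar = bin_ar, seed = as.integer(seed))
  if (refractory < 0) stop("refractory must be >= 0")
  if (signature_strength < 0) stop("signature_strength must be >= 0")
  if (signature_band[1L] < 0 || signature_band[2L] >= sampling_rate / 2)
    stop("signature_band must lie within [0, sampling_rate/2)")
  if (duration_hours * 60 < refractory)
    stop("duration too short to hold one refractory interval")
  if (signature_len + signature_offset >= refractory)
    stop("signature_len + signature_offset must be shorter than refractory ",
         "(preictal labels would overlap seizures)")
  if (bin_ar < 0 || bin_ar >= 1) stop("bin_ar must lie in [0, 1)")
  if (any(signature_pairs$i > n_channels | signature_pairs$j > n_channels))
    stop("signature_pairs outside montage")
  class(cfg) <- "sim_config"
  cfg
}

# Homogeneous Poisson onsets (rate per day) over [0, dur_s), thinned so
# consecutive kept onsets are >= refractory_s apart.
draw_seizure_onsets <- function(rate_per_day, dur_s, refractory_s) {
  lambda <- rate_per_day / 86400
  if (lambda <= 0) return(numeric(0))
  t <- 0; kept <- numeric(0); last <- -Inf
  repeat {
    t <- t + stats::rexp(1L, lambda)
    if (t >= dur_s) break
    if (t - last >= refractory_s) { kept <- c(kept, t); last <- t }
  }
  kept
}

# Poisson-start gaps with uniform lengths; candidates that would swallow a
# seizure onset or its preictal signature window are rejected.
draw_gaps <- function(cfg, dur_s, onsets) {
  lambda <- cfg$gap_rate / 86400
  if (lambda <= 0) return(gap_list())
  protect <- if (length(onsets)) {
    cbind(onsets - (cfg$signature_len + cfg$signature_offset) * 60,
          onsets + 120)
  } else matrix(numeric(0), ncol = 2L)
  starts <- numeric(0); ends <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1L, lambda)
    if (t >= dur_s) break
    len <- stats::runif(1L, cfg$gap_len_range[1L], cfg$gap_len_range[2L]) * 60
    e <- min(t + len, dur_s)
    if (length(starts) && t < ends[length(ends)]) next
    if (nrow(protect) &&
        interval_intersect_len(cbind(t, e), protect) > 0) next
    starts <- c(starts, t); ends <- c(ends, e)
  }
  gap_list(starts, ends)
}

#' Generate a synthetic raw-signal recording
#'
#' Background channels are band-limited Gaussian noise sharing a per-strip
#' common component (baseline correlation `baseline_cor`). During each
#' seizure's preictal signature window an additional common component,
#' band-limited to `signature_band` and scaled by `signature_strength`, is
#' added to both contacts of every signature pair. Gaps are excised, so the
#' result is a list of contiguous segments. Deterministic given
#' `config$seed`.
#'
#' Raw-signal synthesis holds `fs * duration * n_channels` doubles in
#' memory plus one filtering pass per band; it is intended for hours-scale
#' validation runs, typically at reduced sampling rate. Use
#' [generate_feature_level()] for days-scale pipeline studies.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_dataset` list: `segments` (list of
#'   [recording_segment()]), `seizures` ([seizure_catalog()]), `gaps`
#'   ([gap_list()]), `truth` (the config).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fs <- config$sampling_rate
  dur_s <- config$duration_hours * 3600
  onsets <- draw_seizure_onsets(config$seizure_rate, dur_s,
                                config$refractory * 60)
  gaps <- draw_gaps(config, dur_s, onsets)
  seiz <- seizure_catalog(onsets, pmin(onsets + 60, dur_s))

  n <- as.integer(round(dur_s * fs))
  nstrip <- ceiling(config$n_channels / 4)
  # smooth broadband background: order-2 lowpass at 0.8 Nyquist
  bg <- signal::butter(2, 0.8)
  rho <- config$baseline_cor
  x <- matrix(0, n, config$n_channels)
  shared <- lapply(seq_len(nstrip), function(s)
    as.numeric(signal::filter(bg, stats::rnorm(n))))
  for (ch in seq_len(config$n_channels)) {
    s <- (ch - 1L) %/% 4L + 1L
    e <- as.numeric(signal::filter(bg, stats::rnorm(n)))
    x[, ch] <- sqrt(1 - rho) * e + sqrt(rho) * shared[[s]]
  }

  if (config$signature_strength > 0 && length(onsets)) {
    sig_spec <- filter_bank_spec(matrix(config$signature_band, 1L, 2L),
                                 taps = min(2001L, as.integer(2 * fs) %/%
                                              2L * 2L + 1L))
    sig_bank <- design_filter_bank(sig_spec, fs)
    chans <- unique(c(config$signature_pairs$i, config$signature_pairs$j))
    for (on in onsets) {
      w1 <- on - config$signature_offset * 60
      w0 <- max(0, w1 - config$signature_len * 60)
      if (w1 <= w0) next
      i0 <- as.integer(round(w0 * fs)) + 1L
      i1 <- min(n, as.integer(round(w1 * fs)))
      z <- fir_apply(sig_bank$coef[[1L]], stats::rnorm(i1 - i0 + 1L))
      sdz <- stats::sd(z)
      if (sdz == 0) next
      for (ch in chans) {
        scale <- config$signature_strength * stats::sd(x[i0:i1, ch]) / sdz
        x[i0:i1, ch] <- x[i0:i1, ch] + scale * z
      }
    }
  }

  keep <- interval_setdiff(cbind(0, dur_s), as.matrix(gaps))
  segments <- lapply(seq_len(nrow(keep)), function(k) {
    i0 <- as.integer(floor(keep[k, 1L] * fs)) + 1L
    i1 <- as.integer(floor(keep[k, 2L] * fs))
    recording_segment(x[i0:i1, , drop = FALSE], fs, start = (i0 - 1L) / fs)
  })
  structure(list(segments = segments, seizures = seiz, gaps = gaps,
                 truth = config), class = "synthetic_dataset")
}

#' Generate a synthetic feature-level dataset
#'
#' Fast path that emits a one-minute [feature_matrix()] directly, bypassing
#' raw-signal synthesis. Each correlation column (pair x band) draws iid
#' Gaussian bin values around a column-specific baseline mean; in bins
#' falling inside a seizure's preictal signature window, columns belonging
#' to `signature_pairs` in the band containing `signature_band` have their
#' mean increased by the fraction `signature_strength`. All other columns
#' are exchangeable between classes. Bins overlapping gaps are dropped.
#'
#' @param config a [sim_config()].
#' @param band_edges filter-bank edges used to index columns; default
#'   [default_band_edges()].
#' @param m a [montage()]; default [default_montage()].
#' @param pairs contact pairs for the feature columns; default adjacent
#'   within-strip pairs.
#' @return a `synthetic_dataset` list with `features` (a
#'   [feature_matrix()]), `seizures`, `gaps`, `truth`.
#' @export
generate_feature_level <- function(config, band_edges = default_band_edges(),
                                   m = default_montage(),
                                   pairs = adjacent_pairs(m)) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  dur_s <- config$duration_hours * 3600
  onsets <- draw_seizure_onsets(config$seizure_rate, dur_s,
                                config$refractory * 60)
  gaps <- draw_gaps(config, dur_s, onsets)
  seiz <- seizure_catalog(onsets, pmin(onsets + 60, dur_s))

  nb <- nrow(band_edges); np <- nrow(pairs)
  cols <- data.frame(kind = "cor",
                     i = rep(pairs$i, each = nb), j = rep(pairs$j, each = nb),
                     band = rep(seq_len(nb), times = np),
                     low = rep(band_edges[, 1L], times = np),
                     high = rep(band_edges[, 2L], times = np))
  nbin <- floor(dur_s / 60)
  t <- 60 * (seq_len(nbin) - 1L)
  # per-column baseline: summed per-second correlations over a minute
  mu <- stats::runif(nrow(cols), 15, 35)
  sd_col <- stats::runif(nrow(cols), 1.5, 4)
  if (config$bin_ar > 0) {
    # stationary AR(1) bin noise with unit marginal variance (50-bin burn-in)
    rho <- config$bin_ar
    vals <- vapply(seq_len(nrow(cols)), function(cc) {
      e <- stats::rnorm(nbin + 50L, sd = sqrt(1 - rho^2))
      as.numeric(stats::filter(e, rho, method = "recursive"))[-seq_len(50L)]
    }, numeric(nbin))
  } else {
    vals <- matrix(stats::rnorm(nbin * nrow(cols)), nbin, nrow(cols))
  }
  vals <- sweep(vals, 2L, sd_col, "*")
  vals <- sweep(vals, 2L, mu, "+")

  sig_band <- which(band_edges[, 1L] < config$signature_band[2L] &
                    band_edges[, 2L] > config$signature_band[1L])
  key <- paste(cols$i, cols$j)
  sig_cols <- which(cols$band %in% sig_band &
                    key %in% paste(config$signature_pairs$i,
                                   config$signature_pairs$j))
  if (config$signature_strength > 0 && length(onsets) && length(sig_cols)) {
    for (on in onsets) {
      w1 <- on - config$signature_offset * 60
      w0 <- w1 - config$signature_len * 60
      rows <- which(t >= w0 & t < w1)
      if (!length(rows)) next
      vals[rows, sig_cols] <- vals[rows, sig_cols] +
        rep(config$signature_strength * mu[sig_cols], each = length(rows))
    }
  }

  if (nrow(gaps)) {
    drop <- points_in_intervals(t, cbind(gaps$start - 60 + 1e-9, gaps$end))
    vals <- vals[!drop, , drop = FALSE]
    t <- t[!drop]
  }
  fm <- feature_matrix(vals, t, cols)
  structure(list(features = fm, seizures = seiz, gaps = gaps,
                 truth = config), class = "synthetic_dataset")
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
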