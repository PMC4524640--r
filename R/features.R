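#' Contiguous multichannel recording segment
#'
#' @param data numeric matrix, samples x channels.
#' @param fs sampling rate (Hz).
#' @param start absolute start time of the first sample (s).
#' @return a `recording_segment`.
#' @export
recording_segment <- function(data, fs, start = 0) {
  data <- as.matrix(data)
  stopifnot(fs > 0, is.numeric(data))
  structure(list(data = data, fs = fs, start = start),
            class = "recording_segment")
}

#' Feature matrix container
#'
#' One row per one-minute bin; columns carry per-column metadata (feature
#' kind, contact pair or channel, frequency band).
#'
#' @param values numeric matrix, bins x features.
#' @param time bin start times (s), one per row.
#' @param columns data.frame of per-column metadata with at least columns
#'   `kind` ("cor" or "pow"), `i`, `j` (contacts; `j` NA for power), `band`
#'   (band index), `low`, `high` (band edges Hz).
#' @param bin_len bin length (s), default 60.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, time, columns, bin_len = 60) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(time), ncol(values) == nrow(columns))
  colnames(values) <- feature_colnames(columns)
  structure(list(values = values, time = as.numeric(time), columns = columns,
                 bin_len = bin_len), class = "feature_matrix")
}

feature_colnames <- function(columns) {
  ifelse(columns$kind == "cor",
         sprintf("cor_c%02d_c%02d_b%02d", columns$i, columns$j, columns$band),
         sprintf("pow_c%02d_b%02d", columns$i, columns$band))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "one-minute bins x",
      ncol(x$values), "features\n")
  cat("  kinds:", paste(unique(x$columns$kind), collapse = ", "),
      "| bands:", length(unique(x$columns$band)), "\n")
  invisible(x)
}

#' Subset feature columns by band and/or pair
#'
#' @param fm a [feature_matrix()].
#' @param bands integer band indices to keep (`NULL` = all).
#' @param pairs data.frame with columns `i`, `j`: contact pairs to keep
#'   (`NULL` = all).
#' @return a [feature_matrix()] with the selected columns.
#' @export
subset_features <- function(fm, bands = NULL, pairs = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- rep(TRUE, nrow(fm$columns))
  if (!is.null(bands)) keep <- keep & fm$columns$band %in% bands
  if (!is.null(pairs)) {
    key <- paste(fm$columns$i, fm$columns$j)
    keep <- keep & key %in% c(paste(pairs$i, pairs$j), paste(pairs$j, pairs$i))
  }
  if (!any(keep)) stop("no feature columns left after subsetting")
  feature_matrix(fm$values[, keep, drop = FALSE], fm$time,
                 fm$columns[keep, , drop = FALSE], fm$bin_len)
}

# Column-wise Pearson correlation of two (samples x blocks) matrices.
# Zero-variance blocks yield 0 (correlation undefined) with a warning flag.
block_correlations <- function(xi, xj) {
  n <- nrow(xi)
  xi <- sweep(xi, 2L, colMeans(xi))
  xj <- sweep(xj, 2L, colMeans(xj))
  si <- sqrt(colSums(xi^2)); sj <- sqrt(colSums(xj^2))
  bad <- si == 0 | sj == 0
  r <- numeric(ncol(xi))
  ok <- !bad
  r[ok] <- colSums(xi[, ok, drop = FALSE] * xj[, ok, drop = FALSE]) /
    (si[ok] * sj[ok])
  attr(r, "n_degenerate") <- sum(bad)
  r
}

#' Band-limited adjacent-pair correlation features
#'
#' For every one-minute bin, adjacent within-strip contact pair and filter
#' bank band: the signals are band-filtered, the Pearson correlation
#' coefficient is computed on consecutive sub-blocks of `block_len` seconds,
#' and the per-block coefficients are summed over the minute. With the
#' default montage (12 adjacent pairs) and 11-band bank this yields 132
#' feature columns. Bins are aligned to each segment start; partial trailing
#' bins are dropped.
#'
#' @param segments a [recording_segment()] or list of them (shared montage
#'   and sampling rate).
#' @param m a [montage()].
#' @param bank a [design_filter_bank()] result (designed at the segments'
#'   sampling rate).
#' @param pairs data.frame of contact pairs (`i`, `j`); default the adjacent
#'   within-strip pairs of `m`.
#' @param bin_len bin length (s), default 60.
#' @param block_len correlation sub-block length (s), default 1; must divide
#'   `bin_len`.
#' @return a [feature_matrix()] of summed correlations (dimensionless; each
#'   value bounded by the number of sub-blocks per bin).
#' @export
correlation_features <- function(segments, m = default_montage(), bank,
                                 pairs = adjacent_pairs(m), bin_len = 60,
                                 block_len = 1) {
  if (inherits(segments, "recording_segment")) segments <- list(segments)
  stopifnot(inherits(bank, "filter_bank"))
  if (bin_len %% block_len != 0) stop("bin_len must be divisible by block_len")
  fs <- segments[[1L]]$fs
  if (abs(fs - bank$fs) > 1e-9) stop("filter bank designed at different fs")
  bpm <- bin_len %/% block_len           # blocks per bin
  spb <- as.integer(round(block_len * fs))  # samples per block
  nb <- length(bank$coef)
  np <- nrow(pairs)
  cols <- data.frame(kind = "cor",
                     i = rep(pairs$i, each = nb), j = rep(pairs$j, each = nb),
                     band = rep(seq_len(nb), times = np),
                     low = rep(bank$band_edges[, 1L], times = np),
                     high = rep(bank$band_edges[, 2L], times = np))
  vals <- NULL; times <- numeric(0); n_deg <- 0L
  chans <- sort(unique(c(pairs$i, pairs$j)))
  for (seg in segments) {
    if (abs(seg$fs - fs) > 1e-9) stop("segments have mismatched sampling rates")
    n <- nrow(seg$data)
    nblocks <- n %/% spb
    nbins <- nblocks %/% bpm
    if (nbins == 0L) next
    segvals <- matrix(0, nbins, nb * np)
    for (b in seq_len(nb)) {
      filt <- list()
      for (ch in chans)
        filt[[as.character(ch)]] <- fir_apply(bank$coef[[b]], seg$data[, ch])
      for (p in seq_len(np)) {
        xi <- matrix(filt[[as.character(pairs$i[p])]][seq_len(nbins * bpm * spb)],
                     nrow = spb)
        xj <- matrix(filt[[as.character(pairs$j[p])]][seq_len(nbins * bpm * spb)],
                     nrow = spb)
        r <- block_correlations(xi, xj)
        n_deg <- n_deg + attr(r, "n_degenerate")
        segvals[, (p - 1L) * nb + b] <-
          colSums(matrix(r, nrow = bpm))
      }
    }
    vals <- rbind(vals, segvals)
    times <- c(times, seg$start + bin_len * (seq_len(nbins) - 1L))
  }
  if (n_deg > 0L)
    warning(n_deg, " zero-variance block(s): correlation undefined, set to 0")
  if (is.null(vals)) vals <- matrix(numeric(0), 0L, nb * np)
  feature_matrix(vals, times, cols, bin_len)
}

#' Power-in-band features
#'
#' Mean power (signal-units squared) of each channel's band-filtered signal
#' per one-minute bin, for each band of `pib_bands`. With 16 channels and
#' the default 5-band list this yields 80 columns.
#'
#' @inheritParams correlation_features
#' @param channels integer channel indices; default all montage contacts.
#' @param pib_bands k x 2 matrix of band edges (Hz).
#' @param fs sampling rate; default taken from the segments.
#' @return a [feature_matrix()] of mean band powers.
#' @export
pib_features <- function(segments, m = default_montage(),
                         pib_bands = default_pib_bands(),
                         channels = m$contact, bin_len = 60, fs = NULL) {
  if (inherits(segments, "recording_segment")) segments <- list(segments)
  if (is.null(fs)) fs <- segments[[1L]]$fs
  # the PIB band list is non-contiguous: design each band independently
  banks <- lapply(seq_len(nrow(pib_bands)), function(k) {
    design_filter_bank(filter_bank_spec(pib_bands[k, , drop = FALSE]), fs)
  })
  nb <- nrow(pib_bands); nc <- length(channels)
  cols <- data.frame(kind = "pow",
                     i = rep(channels, each = nb), j = NA_integer_,
                     band = rep(seq_len(nb), times = nc),
                     low = rep(pib_bands[, 1L], times = nc),
                     high = rep(pib_bands[, 2L], times = nc))
  spb <- as.integer(round(bin_len * fs))
  vals <- NULL; times <- numeric(0)
  for (seg in segments) {
    n <- nrow(seg$data)
    nbins <- n %/% spb
    if (nbins == 0L) next
    segvals <- matrix(0, nbins, nb * nc)
    for (ci in seq_len(nc)) {
      x <- seg$data[, channels[ci]]
      for (b in seq_len(nb)) {
        y <- fir_apply(banks[[b]]$coef[[1L]], x)
        pw <- colMeans(matrix(y[seq_len(nbins * spb)]^2, nrow = spb))
        segvals[, (ci - 1L) * nb + b] <- pw
      }
    }
    vals <- rbind(vals, segvals)
    times <- c(times, seg$start + bin_len * (seq_len(nbins) - 1L))
  }
  if (is.null(vals)) vals <- matrix(numeric(0), 0L, nb * nc)
  feature_matrix(vals, times, cols, bin_len)
}
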