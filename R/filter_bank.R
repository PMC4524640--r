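#' Default 11-band filter-bank edges
#'
#' Eleven contiguous, non-overlapping bandpass edges (Hz) spanning
#' 0.61-184.1 Hz, chosen to sample the recordable range of a 400 Hz device
#' more finely than the conventional EEG bands. Frequencies above 184.1 Hz
#' are avoided (sampling artifact near Nyquist).
#'
#' @return 11 x 2 matrix with columns `low`, `high`.
#' @export
default_band_edges <- function() {
  e <- c(0.61, 3.8, 9.7, 18.2, 29.5, 43.5, 60.2, 79.5, 101.6, 126.4, 153.9,
         184.1)
  cbind(low = e[-length(e)], high = e[-1L])
}

#' Default power-in-band edges
#'
#' The five conventional spectral bands used for the univariate
#' power-in-band comparison features (Hz). The list has no 4-8 Hz band;
#' it is reproduced verbatim from the comparison protocol and is
#' configurable.
#'
#' @return 5 x 2 matrix with columns `low`, `high`.
#' @export
default_pib_bands <- function() {
  cbind(low = c(0.1, 8, 12, 30, 70), high = c(4, 12, 30, 70, 180))
}

#' Filter-bank specification
#'
#' @param band_edges k x 2 matrix of (low, high) Hz. Bands must be
#'   contiguous (high of band k = low of band k+1) and non-overlapping.
#' @param taps FIR filter length (odd); `NULL` sizes the filter to the
#'   sampling rate at design time (about 8 s of impulse response).
#' @param window window descriptor; only `"bartletthann"` is supported.
#' @return a `filter_bank_spec` list.
#' @export
filter_bank_spec <- function(band_edges = default_band_edges(), taps = NULL,
                             window = "bartletthann") {
  band_edges <- as.matrix(band_edges)
  if (ncol(band_edges) != 2L) stop("band_edges must have two columns")
  if (any(band_edges[, 2L] <= band_edges[, 1L]))
    stop("band high edge must exceed low edge")
  if (nrow(band_edges) > 1L) {
    if (any(abs(band_edges[-1L, 1L] - band_edges[-nrow(band_edges), 2L]) >
            1e-9))
      stop("bands must be contiguous and non-overlapping")
  }
  if (!identical(window, "bartletthann"))
    stop("only the Bartlett-Hanning window is supported")
  if (!is.null(taps) && (taps %% 2L != 1L || taps < 3L))
    stop("taps must be an odd integer >= 3")
  structure(list(band_edges = band_edges, taps = taps, window = window),
            class = "filter_bank_spec")
}

# Bartlett-Hanning window of length n
bartlett_hanning <- function(n) {
  x <- (seq_len(n) - 1L) / (n - 1L) - 0.5
  0.62 - 0.48 * abs(x) + 0.38 * cos(2 * pi * x)
}

#' Design a bandpass FIR filter bank
#'
#' Linear-phase bandpass filters (windowed-sinc design with a
#' Bartlett-Hanning window), one per band of the specification.
#'
#' @param spec a [filter_bank_spec()].
#' @param fs sampling rate (Hz).
#' @return a `filter_bank` list with elements `coef` (list of coefficient
#'   vectors), `band_edges`, `fs`, `taps`.
#' @export
design_filter_bank <- function(spec = filter_bank_spec(), fs) {
  stopifnot(inherits(spec, "filter_bank_spec"), fs > 0)
  if (any(spec$band_edges >= fs / 2))
    stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  taps <- spec$taps
  if (is.null(taps)) taps <- as.integer(8 * fs) %/% 2L * 2L + 1L
  w <- bartlett_hanning(taps)
  coef <- lapply(seq_len(nrow(spec$band_edges)), function(k) {
    signal::fir1(taps - 1L, spec$band_edges[k, ] / (fs / 2), type = "pass",
                 window = w)
  })
  structure(list(coef = coef, band_edges = spec$band_edges, fs = fs,
                 taps = taps), class = "filter_bank")
}

# FFT-based FIR filtering with group-delay compensation so output is aligned
# with input (linear-phase filter assumed; length preserved, tail zero-padded).
fir_apply <- function(b, x) {
  n <- length(x)
  y <- signal::fftfilt(b, c(x, numeric(length(b))))
  d <- (length(b) - 1L) %/% 2L
  y[(d + 1L):(d + n)]
}

#' Apply a filter bank to a signal
#'
#' @param bank a [design_filter_bank()] result.
#' @param x numeric signal vector sampled at `bank$fs`.
#' @return matrix (length(x) x n_bands) of band-filtered signals.
#' @export
apply_filter_bank <- function(bank, x) {
  stopifnot(inherits(bank, "filter_bank"))
  vapply(bank$coef, function(b) fir_apply(b, x), numeric(length(x)))
}
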