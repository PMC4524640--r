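# Independent brute-force oracles used across the suite. These deliberately
# use different mechanisms from the package implementations.

# Lead-seizure oracle: walk backwards from each onset over 1-second steps'
# worth of event history, accumulating recorded seizure-free time until a
# blocker (previous seizure offset, qualifying gap end, recording start).
oracle_lead <- function(catalog, gaps, cfg, rec_start = 0) {
  need <- cfg$lead_min_sep * 3600
  qthr <- cfg$gap_event_threshold * 3600
  sapply(seq_len(nrow(catalog)), function(k) {
    t1 <- catalog$onset[k]
    stops <- rec_start
    if (k > 1L) stops <- c(stops, catalog$offset[seq_len(k - 1L)])
    if (nrow(gaps)) {
      qe <- gaps$end[(gaps$end - gaps$start) > qthr]
      stops <- c(stops, qe[qe <= t1])
    }
    t0 <- max(stops)
    if (t0 >= t1) return(FALSE)
    # subtract gap seconds by direct summation
    gap_s <- 0
    if (nrow(gaps)) {
      for (g in seq_len(nrow(gaps))) {
        lo <- max(t0, gaps$start[g]); hi <- min(t1, gaps$end[g])
        if (hi > lo) gap_s <- gap_s + (hi - lo)
      }
    }
    (t1 - t0 - gap_s) >= need
  })
}

# Warning-engine oracle: slide the window one bin at a time, mark covered
# bins in a boolean array, recover merged intervals with rle().
oracle_warnings <- function(call, t, window_len, threshold) {
  n <- length(call)
  W <- window_len
  covered <- logical(n + W)
  for (i in seq_len(n)) {
    cnt <- sum(call[max(1L, i - W + 1L):i])
    if (cnt >= threshold) covered[i:(i + W - 1L)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (!length(idx)) return(matrix(numeric(0), ncol = 2L))
  cbind(t[1L] + 60 * (starts[idx] - 1L), t[1L] + 60 * ends[idx])
}

# Rank-based AUC of decision values for a binary truth vector
rank_auc <- function(decision, truth) {
  pos <- decision[truth]; neg <- decision[!truth]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Reduced-scale labeling convention for synthetic runs (hours-scale records:
# no implant burn-in, 2 h interictal exclusion radius)
synth_lab_config <- function(preictal_len = 90) {
  labeling_config(preictal_len = preictal_len, preictal_offset = 5,
                  lead_min_sep = 4, interictal_excl = 2,
                  post_implant_excl = 0, gap_event_threshold = 1)
}

# A small raw-signal simulation at reduced sampling rate, with band edges
# scaled below the 32 Hz Nyquist
small_raw_config <- function(strength = 1, seed = 7, duration_hours = 1.5) {
  sim_config(duration_hours = duration_hours, sampling_rate = 64,
             n_channels = 16, seizure_rate = 72, refractory = 25,
             signature_band = c(9.7, 18.2), signature_len = 10,
             signature_offset = 2, signature_strength = strength,
             gap_rate = 0, seed = seed)
}

small_edges <- function() cbind(c(0.61, 3.8, 9.7, 18.2),
                                c(3.8, 9.7, 18.2, 29.5))

small_raw_lab_config <- function() {
  labeling_config(preictal_len = 10, preictal_offset = 2, lead_min_sep = 0.3,
                  interictal_excl = 0.05, post_implant_excl = 0)
}
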