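#' Seizure catalog
#'
#' An ordered list of seizure events on the recording clock (seconds).
#'
#' @param onset numeric vector of seizure onset times (s).
#' @param offset numeric vector of seizure offset times (s); defaults to one
#'   minute after onset.
#' @return a `seizure_catalog` data.frame with columns `onset`, `offset`.
#' @export
seizure_catalog <- function(onset = numeric(0), offset = onset + 60) {
  if (length(onset) != length(offset)) stop("onset/offset length mismatch")
  if (any(offset < onset)) stop("seizure offset before onset")
  if (is.unsorted(onset, strictly = TRUE) && length(onset) > 1L)
    stop("seizure onsets must be strictly increasing")
  out <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset))
  class(out) <- c("seizure_catalog", "data.frame")
  out
}

#' Recording-gap list
#'
#' Ordered, non-overlapping intervals of missing data (seconds).
#'
#' @param start,end numeric vectors of gap boundaries (s).
#' @return a `gap_list` data.frame with columns `start`, `end`.
#' @export
gap_list <- function(start = numeric(0), end = numeric(0)) {
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end < start)) stop("gap end before start")
  o <- order(start)
  start <- as.numeric(start[o]); end <- as.numeric(end[o])
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("gaps must be non-overlapping")
  out <- data.frame(start = start, end = end)
  class(out) <- c("gap_list", "data.frame")
  out
}

#' Epoch-labeling configuration
#'
#' Parameters of the preictal/interictal labeling rules. A seizure is a
#' *lead* seizure when it is preceded by at least `lead_min_sep` hours of
#' recorded seizure-free data; recording gaps longer than
#' `gap_event_threshold` hours are treated as potential (unobserved) seizure
#' events and reset that clock. Preictal training windows cover
#' `preictal_len` minutes ending `preictal_offset` minutes before onset of
#' each lead seizure. Interictal data must be at least `interictal_excl`
#' hours from any seizure or qualifying gap boundary (applied on both sides),
#' and the first `post_implant_excl` days after implantation are excluded
#' outright for post-surgical non-stationarity.
#'
#' @param preictal_len preictal window length, minutes (default 90).
#' @param preictal_offset pre-seizure offset, minutes (default 5).
#' @param lead_min_sep minimum seizure-free recorded time before a lead
#'   seizure, hours (default 4).
#' @param interictal_excl exclusion radius around seizures/qualifying gaps
#'   for the interictal class, hours (default 168 = one week).
#' @param post_implant_excl post-implant burn-in, days (default 70).
#' @param gap_event_threshold gap length above which a gap counts as a
#'   potential seizure event, hours (default 1).
#' @return a `labeling_config` list.
#' @export
labeling_config <- function(preictal_len = 90, preictal_offset = 5,
                            lead_min_sep = 4, interictal_excl = 168,
                            post_implant_excl = 70,
                            gap_event_threshold = 1) {
  cfg <- list(preictal_len = preictal_len, preictal_offset = preictal_offset,
              lead_min_sep = lead_min_sep, interictal_excl = interictal_excl,
              post_implant_excl = post_implant_excl,
              gap_event_threshold = gap_event_threshold)
  if (any(unlist(cfg) < 0)) stop("labeling parameters must be non-negative")
  if ((preictal_len + preictal_offset) >= lead_min_sep * 60)
    stop("preictal_len + preictal_offset must be shorter than lead_min_sep")
  class(cfg) <- "labeling_config"
  cfg
}

qualifying_gaps <- function(gaps, config) {
  if (is.null(gaps) || nrow(gaps) == 0L) return(gaps[0, , drop = FALSE])
  gaps[(gaps$end - gaps$start) > config$gap_event_threshold * 3600, ,
       drop = FALSE]
}

#' Identify lead seizures
#'
#' A seizure is lead when the recorded (non-gap) time between its onset and
#' the latest preceding "event boundary" — recording start, previous seizure
#' offset, or the end of a gap longer than the qualifying threshold — is at
#' least `lead_min_sep` hours.
#'
#' @param catalog a [seizure_catalog()].
#' @param config a [labeling_config()].
#' @param gaps a [gap_list()] or `NULL`.
#' @param rec_start recording start time (s); data before it does not count.
#' @return the subset of `catalog` rows that are lead seizures.
#' @export
identify_lead_seizures <- function(catalog, config = labeling_config(),
                                   gaps = NULL, rec_start = 0) {
  stopifnot(inherits(catalog, "seizure_catalog"))
  if (nrow(catalog) == 0L) return(catalog)
  if (is.unsorted(catalog$onset, strictly = TRUE) && nrow(catalog) > 1L)
    stop("seizure catalog must be ordered by onset")
  if (is.null(gaps)) gaps <- gap_list()
  qg <- qualifying_gaps(gaps, config)
  need <- config$lead_min_sep * 3600
  lead <- logical(nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    t1 <- catalog$onset[k]
    blockers <- rec_start
    if (k > 1L) blockers <- c(blockers, catalog$offset[k - 1L])
    if (nrow(qg) > 0L) blockers <- c(blockers, qg$end[qg$end <= t1])
    t0 <- max(blockers)
    if (t0 >= t1) next
    recorded <- (t1 - t0) -
      interval_intersect_len(cbind(t0, t1), as.matrix(gaps))
    lead[k] <- recorded >= need
  }
  out <- catalog[lead, , drop = FALSE]
  class(out) <- class(catalog)
  out
}

#' Label one-minute bins as preictal / interictal / excluded
#'
#' Applies the epoch-labeling rules over a recording timeline. Bins are
#' half-open one-minute intervals aligned to the timeline start. Precedence:
#' bins without data (gaps), ictal bins and the post-implant burn-in are
#' excluded unconditionally; preictal windows of lead seizures are labeled
#' preictal; bins within the interictal exclusion radius of any seizure or
#' qualifying gap boundary (and not preictal) are excluded; everything else
#' is interictal.
#'
#' @param timeline numeric length-2 vector `c(start, end)` in seconds.
#' @param catalog a [seizure_catalog()].
#' @param gaps a [gap_list()] or `NULL`.
#' @param config a [labeling_config()].
#' @return a `bin_labels` data.frame with columns `time` (bin start, s) and
#'   `label` (factor preictal/interictal/excluded).
#' @export
label_bins <- function(timeline, catalog, gaps = NULL,
                       config = labeling_config()) {
  stopifnot(length(timeline) == 2L, timeline[2L] > timeline[1L])
  if (is.null(gaps)) gaps <- gap_list()
  n <- floor((timeline[2L] - timeline[1L]) / 60)
  t <- timeline[1L] + 60 * (seq_len(n) - 1L)
  lab <- rep("interictal", n)

  excl_soft <- matrix(numeric(0), ncol = 2L)
  r <- config$interictal_excl * 3600
  if (nrow(catalog) > 0L)
    excl_soft <- rbind(excl_soft,
                       cbind(catalog$onset - r, catalog$offset + r))
  qg <- qualifying_gaps(gaps, config)
  if (nrow(qg) > 0L)
    excl_soft <- rbind(excl_soft, cbind(qg$start - r, qg$end + r))
  if (nrow(excl_soft) > 0L)
    lab[points_in_intervals(t, excl_soft)] <- "excluded"

  lead <- identify_lead_seizures(catalog, config, gaps,
                                 rec_start = timeline[1L])
  if (nrow(lead) > 0L) {
    w0 <- lead$onset - (config$preictal_offset + config$preictal_len) * 60
    w1 <- lead$onset - config$preictal_offset * 60
    pre_windows <- cbind(w0, w1)
    # overlapping preictal windows cannot arise from lead seizures
    # (lead_min_sep > preictal span is enforced by labeling_config)
    lab[points_in_intervals(t, pre_windows)] <- "preictal"
  }

  hard <- matrix(numeric(0), ncol = 2L)
  if (config$post_implant_excl > 0)
    hard <- rbind(hard, cbind(timeline[1L],
                              timeline[1L] + config$post_implant_excl * 86400))
  if (nrow(catalog) > 0L)
    hard <- rbind(hard, cbind(catalog$onset, catalog$offset))
  if (nrow(gaps) > 0L) {
    # a bin overlapping a gap has incomplete data: widen to bin resolution
    hard <- rbind(hard, cbind(gaps$start - 60 + 1e-9, gaps$end))
  }
  if (nrow(hard) > 0L)
    lab[points_in_intervals(t, hard)] <- "excluded"

  out <- data.frame(time = t,
                    label = factor(lab, levels = c("preictal", "interictal",
                                                   "excluded")))
  class(out) <- c("bin_labels", "data.frame")
  out
}

#' Monitored-time intervals
#'
#' Recorded time available for forecasting: the timeline minus gaps and minus
#' the post-implant burn-in.
#'
#' @inheritParams label_bins
#' @return two-column matrix of (start, end) intervals in seconds.
#' @export
monitored_intervals <- function(timeline, gaps = NULL,
                                config = labeling_config()) {
  if (is.null(gaps)) gaps <- gap_list()
  base <- cbind(timeline[1L] + config$post_implant_excl * 86400, timeline[2L])
  if (base[1L] >= base[2L]) return(matrix(numeric(0), ncol = 2L))
  interval_setdiff(base, as.matrix(gaps))
}

#' Cohort summary statistics
#'
#' Arithmetic means and sample (n-1 denominator) standard deviations of
#' numeric columns over a subset of subjects.
#'
#' @param table data.frame of per-subject rows.
#' @param subset row selector (logical or integer); default all rows.
#' @param columns character vector of columns to summarize; default all
#'   numeric columns.
#' @return data.frame with columns `column`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(table, subset = NULL, columns = NULL) {
  rows <- if (is.null(subset)) table else table[subset, , drop = FALSE]
  if (nrow(rows) < 2L)
    stop("cohort summary needs at least 2 rows (sd undefined otherwise)")
  if (is.null(columns))
    columns <- names(rows)[vapply(rows, is.numeric, logical(1L))]
  data.frame(column = columns,
             mean = vapply(columns, function(cl) mean(rows[[cl]]), numeric(1L)),
             sd = vapply(columns, function(cl) stats::sd(rows[[cl]]),
                         numeric(1L)),
             n = nrow(rows), row.names = NULL)
}

#' Canine cohort recording summary
#'
#' Per-dog recording durations and seizure counts for the eight implanted
#' dogs of the reference chronic-recording study; dogs with fewer than five
#' lead seizures are flagged as excluded from analysis.
#'
#' @return data.frame with one row per dog.
#' @export
canine_cohort <- function() {
  d <- data.frame(
    dog = 1:8,
    name = c("Buck", "Tanner", "Drools", "Foster", "Gus", "Joseph", "Ripley",
             "Sakic"),
    recording_days = c(476, 398, 452, 393, 338, 287, 294, 290),
    gapfree_days = c(342, 255, 213, 298, 29, 168, 80, 126),
    annotated_seizures = c(47, 2, 104, 29, 0, 144, 22, 0),
    lead_seizures = c(40, 2, 18, 27, 0, 86, 8, 0),
    stringsAsFactors = FALSE)
  d$analyzed <- d$lead_seizures >= 5
  d
}
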