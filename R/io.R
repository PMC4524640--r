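# On-disk formats: EDF for signals, CSV for annotations/labels/ROC/sweeps,
# JSON for models and evaluation results, flat YAML for run configs.
# Timestamps are epoch/recording seconds; all intervals half-open.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

#' Write a recording segment as EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one data record
#' holding the whole segment, per-channel physical scaling computed from the
#' data range. The exact sampling rate and absolute segment start time are
#' carried in the header's recording-identification field so the round trip
#' preserves timestamps exactly and sample values to 16-bit quantization.
#'
#' @param segment a [recording_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(segment, path) {
  stopifnot(inherits(segment, "recording_segment"))
  x <- segment$data
  n <- nrow(x); nc <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  rec_id <- sprintf("fs=%.10g start=%.10g", segment$fs, segment$start)
  hdr <- paste0(pad_field("0", 8L), pad_field("X", 80L),
                pad_field(rec_id, 80L), "01.01.00", "00.00.00",
                pad_field(256L + 256L * nc, 8L), pad_field("", 44L),
                pad_field(1L, 8L),
                pad_field(formatC(n / segment$fs, digits = 6, format = "g"),
                          8L),
                pad_field(nc, 4L))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- apply(x, 2L, min); pmax_ <- apply(x, 2L, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  sig_hdr <- function(field, width)
    paste(vapply(field, pad_field, character(1L), width = width),
          collapse = "")
  writeChar(paste0(
    sig_hdr(sprintf("ch%02d", seq_len(nc)), 16L),
    sig_hdr(rep("", nc), 80L), sig_hdr(rep("uV", nc), 8L),
    sig_hdr(formatC(pmin_, digits = 7, format = "g"), 8L),
    sig_hdr(formatC(pmax_, digits = 7, format = "g"), 8L),
    sig_hdr(rep(-32768L, nc), 8L), sig_hdr(rep(32767L, nc), 8L),
    sig_hdr(rep("", nc), 80L), sig_hdr(rep(n, nc), 8L),
    sig_hdr(rep("", nc), 32L)), con, eos = NULL)
  for (ch in seq_len(nc)) {
    dig <- as.integer(round((x[, ch] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                              65535 - 32768))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a [recording_segment()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr) < 256L) stop("truncated EDF header: ", path)
  rec_id <- substr(hdr, 89L, 168L)
  m <- regmatches(rec_id, regexec("fs=([0-9.eE+-]+) start=([0-9.eE+-]+)",
                                  rec_id))[[1L]]
  if (length(m) != 3L) stop("EDF header lacks fs/start metadata: ", path)
  fs <- as.numeric(m[2L]); start <- as.numeric(m[3L])
  nc <- as.integer(substr(hdr, 253L, 256L))
  sh <- readChar(con, 256L * nc, useBytes = TRUE)
  if (nchar(sh) < 256L * nc) stop("truncated EDF signal header: ", path)
  fld <- function(off, width, k)
    substr(sh, off * nc + (k - 1L) * width + 1L, off * nc + k * width)
  pmin_ <- numeric(nc); pmax_ <- numeric(nc); ns <- integer(nc)
  for (k in seq_len(nc)) {
    pmin_[k] <- as.numeric(fld(104L, 8L, k))
    pmax_[k] <- as.numeric(fld(112L, 8L, k))
    ns[k] <- as.integer(fld(216L, 8L, k))
  }
  if (length(unique(ns)) != 1L)
    stop("per-channel sample counts differ (sampling-rate mismatch): ", path)
  n <- ns[1L]
  x <- matrix(0, n, nc)
  for (ch in seq_len(nc)) {
    dig <- readBin(con, "integer", n = n, size = 2L, endian = "little",
                   signed = TRUE)
    if (length(dig) < n) stop("truncated EDF data: ", path)
    x[, ch] <- (dig + 32768) / 65535 * (pmax_[ch] - pmin_[ch]) + pmin_[ch]
  }
  recording_segment(x, fs, start)
}

#' Write/read recording segments (one EDF file per segment)
#'
#' @param segments list of [recording_segment()].
#' @param dir output directory (created if needed).
#' @return `write_signals`: character vector of file paths;
#'   `read_signals`: list of segments ordered by start time.
#' @export
write_signals <- function(segments, dir) {
  if (inherits(segments, "recording_segment")) segments <- list(segments)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("segment%03d.edf", seq_along(segments)))
  for (k in seq_along(segments)) write_edf(segments[[k]], paths[k])
  invisible(paths)
}

#' @rdname write_signals
#' @param paths EDF file paths (or a directory containing `.edf` files).
#' @export
read_signals <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.edf$", full.names = TRUE)
  segs <- lapply(paths, read_edf)
  segs[order(vapply(segs, function(s) s$start, numeric(1L)))]
}

#' Annotation CSV round trip
#'
#' Seizures: one row per event (`onset`, `offset`, epoch seconds). Gaps: one
#' row per gap (`start`, `end`).
#'
#' @param catalog a [seizure_catalog()]; `gaps` a [gap_list()].
#' @param path CSV path.
#' @return the written path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @export
write_seizures <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seizures
#' @export
read_seizures <- function(path) {
  d <- utils::read.csv(path)
  seizure_catalog(d$onset, d$offset)
}

#' @rdname write_seizures
#' @param gaps a [gap_list()].
#' @export
write_gaps <- function(gaps, path) {
  utils::write.csv(as.data.frame(gaps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seizures
#' @export
read_gaps <- function(path) {
  d <- utils::read.csv(path)
  gap_list(d$start, d$end)
}

#' Feature-matrix CSV round trip
#'
#' Values go to `<path>` (first column `time`, then one column per feature);
#' column metadata (pair/channel, band edges) goes to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV path.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(data.frame(time = fm$time, fm$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  jsonlite::write_json(list(columns = fm$columns, bin_len = fm$bin_len),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  feature_matrix(as.matrix(d[, -1L, drop = FALSE]), d$time,
                 as.data.frame(meta$columns), meta$bin_len)
}

#' Trained-model JSON round trip
#'
#' @param model a [train_classifier()] result.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  obj <- list(w = model$w, b = model$b, center = model$center,
              scale = model$scale, columns = model$columns,
              cost = model$config$cost, n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = o$w, b = o$b, center = o$center, scale = o$scale,
                 columns = o$columns,
                 config = classifier_config(cost = o$cost),
                 n_train = o$n_train), class = "trained_model")
}

#' Serialize an evaluation result as JSON
#'
#' @param result an `evaluation_result` (see [evaluate_warnings()]).
#' @param path JSON path.
#' @export
write_result <- function(result, path) {
  obj <- result[c("lead_sensitivity", "tiw", "fp_per_day", "dww", "auc",
                  "p_value", "n_lead", "n_hit", "threshold")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flat key-value run configuration (YAML)
#'
#' Recognized keys mirror the constructor arguments of [sim_config()],
#' [labeling_config()] and [classifier_config()]; unknown keys fail.
#'
#' @param path YAML file.
#' @return list with elements `sim`, `labeling`, `classifier`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- list(sim = names(formals(sim_config)),
                labeling = names(formals(labeling_config)),
                classifier = names(formals(classifier_config)))
  extra <- setdiff(names(y), c(unlist(known), "seed"))
  if (length(extra)) stop("unknown config keys: ",
                          paste(extra, collapse = ", "))
  pick <- function(keys) y[intersect(names(y), keys)]
  sim <- do.call(sim_config, pick(known$sim))
  lab <- do.call(labeling_config, pick(known$labeling))
  clf <- do.call(classifier_config, pick(known$classifier))
  list(sim = sim, labeling = lab, classifier = clf,
       seed = if (!is.null(y$seed)) y$seed else sim$seed)
}
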