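# Interval arithmetic on two-column (start, end) matrices, half-open [start, end).
# All times are seconds on the recording clock.

#' Merge overlapping or abutting intervals
#'
#' @param x two-column numeric matrix or data.frame of (start, end).
#' @return matrix with non-overlapping, ordered rows.
#' @keywords internal
interval_merge <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(matrix(numeric(0), ncol = 2L,
                                   dimnames = list(NULL, c("start", "end"))))
  x <- x[x[, 2L] > x[, 1L], , drop = FALSE]
  if (nrow(x) == 0L) return(matrix(numeric(0), ncol = 2L,
                                   dimnames = list(NULL, c("start", "end"))))
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  out <- matrix(x[1L, ], ncol = 2L)
  for (i in seq_len(nrow(x))[-1L]) {
    j <- nrow(out)
    if (x[i, 1L] <= out[j, 2L]) {
      out[j, 2L] <- max(out[j, 2L], x[i, 2L])
    } else {
      out <- rbind(out, x[i, ])
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Total length of the intersection of two interval sets
#' @keywords internal
interval_intersect_len <- function(a, b) {
  a <- interval_merge(a); b <- interval_merge(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

#' Set difference a \ b for interval sets
#' @keywords internal
interval_setdiff <- function(a, b) {
  a <- interval_merge(a); b <- interval_merge(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(a))) {
    segs <- matrix(a[i, ], ncol = 2L)
    for (j in seq_len(nrow(b))) {
      nxt <- matrix(numeric(0), ncol = 2L)
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1L]; e <- segs[k, 2L]
        bs <- b[j, 1L]; be <- b[j, 2L]
        if (be <= s || bs >= e) { nxt <- rbind(nxt, c(s, e)); next }
        if (bs > s) nxt <- rbind(nxt, c(s, bs))
        if (be < e) nxt <- rbind(nxt, c(be, e))
      }
      segs <- nxt
      if (nrow(segs) == 0L) break
    }
    out <- rbind(out, segs)
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Which points fall inside any interval of a set
#' @keywords internal
points_in_intervals <- function(p, x) {
  x <- interval_merge(x)
  if (nrow(x) == 0L) return(rep(FALSE, length(p)))
  vapply(p, function(t) any(t >= x[, 1L] & t < x[, 2L]), logical(1L))
}
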