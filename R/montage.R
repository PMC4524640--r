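#' Electrode montage
#'
#' A montage maps electrode contacts to strips, hemispheres and anatomical
#' location labels. The reference implant is a bilateral array of sixteen
#' contacts arranged as four 4-contact subdural strips, two per hemisphere
#' (one inferior, one superior).
#'
#' @param contact integer contact indices.
#' @param strip integer strip id per contact.
#' @param pos integer position within strip (1 = anterior).
#' @param hemisphere `"left"` or `"right"` per contact.
#' @param location anatomical label per contact (e.g. `"Ant-inf"`,
#'   `"Center-sup"`, `"Post-inf"`); used to form location-matched bilateral
#'   pairs.
#' @return a `montage` data.frame, one row per contact.
#' @seealso [default_montage()], [adjacent_pairs()], [bilateral_pairs()]
#' @export
montage <- function(contact, strip, pos, hemisphere, location) {
  m <- data.frame(contact = as.integer(contact), strip = as.integer(strip),
                  pos = as.integer(pos), hemisphere = hemisphere,
                  location = location, stringsAsFactors = FALSE)
  if (anyDuplicated(m$contact)) stop("duplicate contact indices in montage")
  if (!all(m$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  tab <- table(m$strip)
  if (any(tab != 4L))
    stop("each strip must carry exactly 4 contacts")
  class(m) <- c("montage", "data.frame")
  m
}

#' Default 16-contact bilateral montage
#'
#' Four 4-contact strips: strips 1 (left inferior), 2 (left superior),
#' 3 (right inferior), 4 (right superior); positions run anterior to
#' posterior. Location labels mark anterior, central and posterior sites on
#' the inferior/superior strips so that each label has a mirror-image partner
#' on the opposite hemisphere. The anatomical contact-to-label map of a real
#' implant is approximate; this default is a documented convention and any
#' alternative can be supplied through [montage()].
#'
#' @return a `montage` with 16 contacts.
#' @export
default_montage <- function() {
  inf_lab <- c("Ant-inf", "Center-inf", "Center-inf", "Post-inf")
  sup_lab <- c("Ant-sup", "Center-sup", "Center-sup", "Post-sup")
  montage(contact = 1:16,
          strip = rep(1:4, each = 4L),
          pos = rep(1:4, times = 4L),
          hemisphere = rep(c("left", "left", "right", "right"), each = 4L),
          location = c(inf_lab, sup_lab, inf_lab, sup_lab))
}

#' Physically adjacent within-strip contact pairs
#'
#' Each 4-contact strip yields 3 adjacent pairs, so the default montage gives
#' 12 pairs.
#'
#' @param m a [montage()].
#' @return data.frame with columns `i`, `j` (contact indices), `strip`.
#' @export
adjacent_pairs <- function(m = default_montage()) {
  stopifnot(inherits(m, "montage"))
  out <- do.call(rbind, lapply(split(m, m$strip), function(s) {
    s <- s[order(s$pos), ]
    data.frame(i = s$contact[-nrow(s)], j = s$contact[-1L],
               strip = s$strip[1L])
  }))
  rownames(out) <- NULL
  out
}

#' Location-matched cross-hemisphere contact pairs
#'
#' Pairs each left-hemisphere contact with the right-hemisphere contact that
#' shares its location label and within-strip position (mirror-image site).
#'
#' @param m a [montage()].
#' @return data.frame with columns `i` (left contact), `j` (right contact),
#'   `location`.
#' @export
bilateral_pairs <- function(m = default_montage()) {
  stopifnot(inherits(m, "montage"))
  left <- m[m$hemisphere == "left", ]
  right <- m[m$hemisphere == "right", ]
  out <- do.call(rbind, lapply(seq_len(nrow(left)), function(k) {
    cand <- right[right$location == left$location[k] &
                  right$pos == left$pos[k], ]
    if (nrow(cand) == 0L) return(NULL)
    data.frame(i = left$contact[k], j = cand$contact[1L],
               location = left$location[k], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
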