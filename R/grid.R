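#' The canonical 24-2 test-point grid
#'
#' Returns the 54 test locations of the Humphrey 24-2 pattern in right-eye
#' orientation (temporal eccentricity positive, superior positive), ordered
#' row-major from the superior-temporal corner: rows from y = +21 down to
#' y = -21 degrees, and within each row from temporal (largest x) to nasal.
#' The two locations overlying the physiologic blind spot sit at
#' (x, y) = (15, 3) and (15, -3).
#'
#' @param drop_blind_spot if `TRUE`, return only the 52 non-blind-spot
#'   locations.
#' @return a data.frame with columns `index`, `x_deg`, `y_deg`,
#'   `is_blind_spot`.
#' @export
vf_locations <- function(drop_blind_spot = FALSE) {
  rows <- list(
    c(y = 21, xmax = 9), c(y = 15, xmax = 15), c(y = 9, xmax = 21),
    c(y = 3, xmax = 21), c(y = -3, xmax = 21), c(y = -9, xmax = 21),
    c(y = -15, xmax = 15), c(y = -21, xmax = 9)
  )
  pts <- do.call(rbind, lapply(rows, function(r) {
    x <- seq(r[["xmax"]], -r[["xmax"]], by = -6)
    # the central rows extend one extra step nasally (to -27 degrees)
    if (abs(r[["y"]]) == 3) x <- c(x, -27)
    data.frame(x_deg = x, y_deg = r[["y"]])
  }))
  pts$index <- seq_len(nrow(pts))
  pts$is_blind_spot <- pts$x_deg == 15 & abs(pts$y_deg) == 3
  pts <- pts[, c("index", "x_deg", "y_deg", "is_blind_spot")]
  if (drop_blind_spot) pts <- pts[!pts$is_blind_spot, ]
  pts
}

#' Permutation mapping each grid index to its left-right mirror image
#'
#' Used to fold left-eye (OS) fields into the canonical right-eye orientation:
#' location (x, y) maps to (-x, y).  The two nasal-extension points at
#' (-27, +/-3) have no temporal counterpart on the 24-2 lattice and map to
#' themselves.  Applying the permutation twice is the identity.
#'
#' @return integer vector of length 54.
#' @export
mirror_index_map <- function() {
  loc <- vf_locations()
  vapply(seq_len(nrow(loc)), function(i) {
    j <- which(loc$x_deg == -loc$x_deg[i] & loc$y_deg == loc$y_deg[i])
    if (length(j) == 1L) j else i
  }, integer(1))
}

#' Mirror a TD vector about the vertical midline
#'
#' @param td numeric vector of 54 total-deviation values in canonical order.
#' @return the mirrored vector.
#' @export
mirror_td <- function(td) {
  stopifnot(length(td) == 54L)
  td[mirror_index_map()]
}

#' Surrogate global indices
#'
#' Simplified stand-ins for the perimeter's global indices, used for synthetic
#' and replicate-averaged fields: MD is the unweighted mean and PSD the sample
#' standard deviation of the 52 non-blind-spot TD values.  The instrument's
#' own MD is variance-weighted toward central points; these surrogates are
#' deliberately simpler and documented as approximations.
#'
#' @param td numeric vector of 54 TD values in dB.
#' @return mean deviation (dB) for `surrogate_md`; pattern standard deviation
#'   (dB) for `surrogate_psd`.
#' @export
surrogate_md <- function(td) {
  mean(td[!vf_locations()$is_blind_spot])
}

#' @rdname surrogate_md
#' @export
surrogate_psd <- function(td) {
  sd(td[!vf_locations()$is_blind_spot])
}
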