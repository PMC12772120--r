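#' Compartment geometry of a columnar ciliated-epithelium template
#'
#' Builds the five boolean pixel masks of an idealized patch of motile
#' ciliated columnar epithelium, apical side up: the ciliary axoneme band
#' (CL) rendered as thin vertical strips, the transition zone (TZ) as a
#' 2-3 px horizontal line beneath it, the rootlet band (RL) as short strips
#' beneath the TZ, and the cell body split into cytoplasm (CYTO) and
#' elliptical nuclei (NUC).
#'
#' The three ciliary masks (CL, TZ, RL) are pairwise disjoint, as are
#' cytoplasm and nucleus; all five masks are non-empty for any image at
#' least 64 px on a side.
#'
#' @param shape integer length-2, image dimensions (rows, cols); >= 64 each.
#' @return Object of class `compartment_geometry`: a named list of five
#'   logical matrices (`CL`, `TZ`, `RL`, `CYTO`, `NUC`) plus attribute
#'   `shape`.
#' @examples
#' geom <- compartment_geometry(c(96, 96))
#' sapply(geom, sum)
#' @export
compartment_geometry <- function(shape = c(96L, 96L)) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L))
    stop("image shape must be at least 64x64 pixels")
  nr <- shape[1]; nc <- shape[2]

  blank <- function() matrix(FALSE, nr, nc)
  rows <- function(a, b) max(1L, round(a * nr)):min(nr, round(b * nr))
  xm <- 3:(nc - 2)                        # lateral margin
  strips <- xm[(xm %% 4L) %in% c(0L, 1L)] # 2-px strips every 4 px

  cl <- blank(); cl[rows(0.04, 0.20), strips] <- TRUE
  tz <- blank(); tz[rows(0.24, 0.26), xm] <- TRUE
  rl <- blank(); rl[rows(0.30, 0.40), strips] <- TRUE

  body <- blank(); body[rows(0.45, 0.97), xm] <- TRUE
  nuc <- blank()
  cy <- round(0.72 * nr)
  ry <- max(4L, round(0.09 * nr)); rx <- max(5L, round(0.08 * nc))
  for (cx in round(c(0.2, 0.5, 0.8) * nc)) {
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    nuc <- nuc | (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1)
  }
  nuc <- nuc & body
  cyto <- body & !nuc

  out <- list(CL = cl, TZ = tz, RL = rl, CYTO = cyto, NUC = nuc)
  stopifnot(all(vapply(out, any, logical(1))))
  structure(out, shape = shape, class = "compartment_geometry")
}
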