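#' Median expression per protein, tissue and compartment
#'
#' Collapses per-core measurements to one value per (protein, tissue,
#' compartment): the median over QC-passing cores of the per-core mean
#' candidate intensity in that compartment's ROI. Even core counts use the
#' arithmetic mean of the two central values. A (protein, tissue) pair with
#' no passing cores yields `NA` with a `missing` flag rather than a silent
#' zero.
#'
#' @param measurements data.frame from [process_study()] (passing cores
#'   only; rows from failed cores must already be absent).
#' @param qc optional QC data.frame; if supplied, rows of `measurements`
#'   belonging to failed cores are dropped defensively.
#' @return data.frame: protein, tissue, compartment, median, n_cores,
#'   missing. Contains one row per protein x tissue x compartment present
#'   in the study design implied by the data.
#' @export
aggregate_median <- function(measurements, qc = NULL) {
  if (!is.null(qc)) {
    bad <- qc[!qc$passed, c("protein", "tissue", "patient", "core")]
    if (nrow(bad)) {
      key <- function(d) paste(d$protein, d$tissue, d$patient, d$core,
                               sep = "\r")
      measurements <- measurements[!key(measurements) %in% key(bad), ]
    }
  }
  if (nrow(measurements) == 0L) stop("no passing measurements")
  # the grid covers every (protein, tissue) seen in the study, including
  # pairs whose cores were all excluded, so those surface as missing
  tissues <- unique(c(measurements$tissue, qc$tissue))
  proteins <- unique(c(measurements$protein, qc$protein))
  grid <- expand.grid(
    compartment = compartment_labels(),
    tissue = tissues, protein = proteins,
    stringsAsFactors = FALSE)[, c("protein", "tissue", "compartment")]
  agg <- stats::aggregate(mean ~ protein + tissue + compartment,
                          data = measurements, FUN = stats::median)
  names(agg)[names(agg) == "mean"] <- "median"
  cnt <- stats::aggregate(mean ~ protein + tissue + compartment,
                          data = measurements, FUN = length)
  names(cnt)[names(cnt) == "mean"] <- "n_cores"
  out <- merge(merge(grid, agg, all.x = TRUE), cnt, all.x = TRUE)
  out$n_cores[is.na(out$n_cores)] <- 0L
  out$missing <- is.na(out$median)
  out[order(out$protein, out$tissue, out$compartment), ]
}

#' Min-max normalize one protein's profile
#'
#' Rescales a protein's expression values to `[0, 1]` over its full
#' compartment-by-tissue profile: `x' = (x - min) / (max - min)`. A
#' constant profile maps to all zeros; missing entries stay missing and are
#' excluded from the min/max.
#'
#' @param x numeric vector (one protein's profile; may contain `NA`).
#' @return Numeric vector of the same length in `[0, 1]` (or `NA`).
#' @examples
#' minmax_normalize(c(2, 4, 10))  # 0 0.25 1
#' @export
minmax_normalize <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) stop("all entries missing")
  lo <- min(obs); hi <- max(obs)
  if (hi == lo) return(ifelse(is.na(x), NA_real_, 0))
  (x - lo) / (hi - lo)
}

#' Build the normalized expression-profile matrix
#'
#' Assembles the median table into a proteins x (compartment, tissue)
#' matrix, min-max scaled per protein (row). Columns follow the fixed
#' order compartments (CL, TZ, RL, CYTO, NUC) crossed with tissues; labels
#' are `<compartment>_<tissue code>` (e.g. `CL_FT`).
#'
#' @param medians data.frame from [aggregate_median()].
#' @param tissues tissue order for columns; defaults to the five-tissue
#'   panel in `tissue_codes()` order, restricted to tissues present.
#' @return Numeric matrix with proteins as rownames, values in `[0, 1]`
#'   (missing cells `NA`).
#' @export
build_matrix <- function(medians, tissues = NULL) {
  if (is.null(tissues)) {
    tissues <- intersect(names(tissue_codes()), unique(medians$tissue))
    extra <- setdiff(unique(medians$tissue), tissues)
    tissues <- c(tissues, extra)
  }
  codes <- tissue_codes()
  code <- function(t) ifelse(t %in% names(codes), codes[t], t)
  # column order: compartment-major (CL over all tissues, then TZ, ...)
  cols <- as.vector(outer(code(tissues), compartment_labels(),
                          function(t, c) paste(c, t, sep = "_")))
  proteins <- unique(medians$protein)
  if (anyDuplicated(paste(medians$protein, medians$tissue,
                          medians$compartment)))
    stop("duplicate (protein, tissue, compartment) rows")
  m <- matrix(NA_real_, length(proteins), length(cols),
              dimnames = list(proteins, cols))
  lab <- paste(medians$compartment, code(medians$tissue), sep = "_")
  m[cbind(match(medians$protein, proteins), match(lab, cols))] <-
    medians$median
  norm <- t(apply(m, 1L, minmax_normalize))
  dimnames(norm) <- dimnames(m)
  norm
}
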