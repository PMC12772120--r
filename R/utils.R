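# Internal numeric helpers shared across modules.

# round half away from zero (inputs here are nonnegative intensities);
# base round() is round-half-even, which is wrong for the 8-bit rescale.
round_half_up <- function(x) floor(x + 0.5)

# clip to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fixed compartment order
#'
#' The five subcellular compartments of a motile ciliated cell, ordered
#' apical to basal tie-break order used throughout: ciliary axoneme (CL),
#' transition zone (TZ), rootlet (RL), cytoplasm (CYTO), nucleus (NUC).
#'
#' @return Character vector of the five compartment labels.
#' @export
compartment_labels <- function() c("CL", "TZ", "RL", "CYTO", "NUC")

#' Default tissue panel
#'
#' The five tissue types harbouring motile ciliated epithelium used in the
#' study design: fallopian tube, bronchus, endometrium, cervix, nasopharynx.
#' Codes are used as column-label suffixes in the expression matrix.
#'
#' @return Named character vector mapping tissue name to short code.
#' @export
tissue_codes <- function() {
  c(fallopian_tube = "FT", bronchus = "B", endometrium = "E",
    cervix = "C", nasopharynx = "N")
}

# the eight channel roles of a raw stack, in page order
stack_roles <- function() {
  c("CL", "TZ", "RL", "CYTO", "NUC", "CANDIDATE", "DAPI", "AF")
}
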