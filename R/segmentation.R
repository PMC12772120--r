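#' Convert an intensity image to 8-bit
#'
#' Linear min-max rescale of the observed intensity range to `[0, 255]`
#' with round-half-up, the deterministic batch analogue of the usual
#' display-range conversion. A constant image maps to all zeros. An image
#' that is already 8-bit (`bit_depth = 8`) is returned unchanged.
#'
#' @param image numeric/integer matrix of nonnegative intensities.
#' @param bit_depth bit depth of the input (8 or 16).
#' @return Integer matrix with values in `[0, 255]`.
#' @examples
#' convert_to_8bit(matrix(c(0, 32768, 65535), 1), 16)  # 0 128 255
#' @export
convert_to_8bit <- function(image, bit_depth = 16L) {
  if (length(image) == 0L) stop("empty image")
  if (any(image < 0)) stop("negative intensities")
  if (bit_depth == 8L) {
    storage.mode(image) <- "integer"
    return(image)
  }
  lo <- min(image); hi <- max(image)
  out <- if (hi == lo) {
    matrix(0L, nrow(image), ncol(image))
  } else {
    matrix(as.integer(round_half_up((image - lo) / (hi - lo) * 255)),
           nrow(image), ncol(image))
  }
  out
}

#' Drop non-analytic channels from a stack
#'
#' DAPI and autofluorescence pages are used only for acquisition and
#' orientation; the quantitative pipeline works on the five panel-marker
#' channels plus the candidate channel.
#'
#' @param stack a `cilia_stack`.
#' @return The stack with six channels (`CL, TZ, RL, CYTO, NUC, CANDIDATE`)
#'   and an updated manifest.
#' @export
discard_channels <- function(stack) {
  keep <- c(compartment_labels(), "CANDIDATE")
  missing <- setdiff(stack_roles(), names(stack$manifest))
  if (length(missing))
    stop("manifest is missing channel role(s): ",
         paste(missing, collapse = ", "))
  stack$channels <- stack$channels[keep]
  stack$manifest <- stats::setNames(seq_along(keep), keep)
  stack
}

#' Three-level multi-Otsu thresholds of an 8-bit histogram
#'
#' Finds the threshold pair `(t1, t2)` partitioning intensities into three
#' classes `{x < t1}`, `{t1 <= x < t2}`, `{x >= t2}` that maximizes the
#' between-class variance
#' \deqn{\sigma^2_B = \sum_c \omega_c (\mu_c - \mu)^2}
#' over all pairs for which every class has positive mass. Ties are broken
#' by the lexicographically smallest `(t1, t2)`. The brightest class
#' `{x >= t2}` is the segmentation mask downstream.
#'
#' @param histogram integer vector of 256 counts (bins 0..255).
#' @return List of class `threshold_pair`: `t1`, `t2`, `sigma_b` (the
#'   maximal between-class variance).
#' @seealso [segment_marker()]
#' @export
multi_otsu_thresholds <- function(histogram) {
  if (length(histogram) != 256L) stop("histogram must have 256 bins")
  total <- sum(histogram)
  if (total == 0) stop("empty histogram")
  if (sum(histogram > 0) < 3L)
    stop("segmentation failed: fewer than 3 distinct intensity values",
         call. = FALSE)

  p <- histogram / total
  lev <- 0:255
  cp <- cumsum(p)            # P(X <= l)
  cm <- cumsum(p * lev)      # E[X 1{X <= l}]
  mu <- cm[256]

  # class statistics for classes [0, t1-1], [t1, t2-1], [t2, 255];
  # grid over all admissible (t1, t2), 1 <= t1 < t2 <= 255
  t1 <- rep(1:254, times = 254:1)
  t2 <- unlist(lapply(1:254, function(a) (a + 1):255))
  w1 <- cp[t1]; m1 <- cm[t1]
  w2 <- cp[t2] - cp[t1]; m2 <- cm[t2] - cm[t1]
  w3 <- 1 - cp[t2]; m3 <- mu - cm[t2]
  ok <- w1 > 0 & w2 > 0 & w3 > 0
  # sigma_b = sum_c m_c^2 / w_c - mu^2  (w_c mu_c^2 with mu_c = m_c / w_c)
  sb <- rep(-Inf, length(t1))
  sb[ok] <- m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok] + m3[ok]^2 / w3[ok] - mu^2
  best <- which.max(sb)  # grid is in lexicographic (t1, t2) order
  structure(list(t1 = t1[best], t2 = t2[best], sigma_b = sb[best]),
            class = "threshold_pair")
}

#' Segment one marker channel into its brightest-class ROI
#'
#' Applies three-level multi-Otsu thresholding to the channel's 256-bin
#' histogram and keeps only the brightest class (`intensity >= t2`) as the
#' compartment's region of interest. No connected-component filtering is
#' applied. Segmentation fails (an error of class `cilia_seg_failure`) when
#' the image carries fewer than three distinct intensity values or the
#' brightest-class mask is empty.
#'
#' @param image 8-bit integer matrix (one converted marker channel).
#' @param compartment compartment label attached to the ROI.
#' @return List of class `compartment_roi`: `compartment`, `mask` (logical
#'   matrix), `area`, `thresholds` (the `threshold_pair`).
#' @export
segment_marker <- function(image, compartment = "ROI") {
  h <- tabulate(as.vector(image) + 1L, nbins = 256L)
  thr <- tryCatch(multi_otsu_thresholds(h), error = function(e) {
    stop(structure(class = c("cilia_seg_failure", "error", "condition"),
                   list(message = conditionMessage(e), call = NULL)))
  })
  mask <- image >= thr$t2
  if (!any(mask))
    stop(structure(class = c("cilia_seg_failure", "error", "condition"),
                   list(message = "segmentation failed: empty brightest-class mask",
                        call = NULL)))
  structure(list(compartment = compartment, mask = mask,
                 area = sum(mask), thresholds = thr),
            class = "compartment_roi")
}

#' Candidate-channel statistics within one ROI
#'
#' @param candidate 8-bit integer matrix (the converted candidate channel).
#' @param roi a `compartment_roi`.
#' @param protein,core_id identifiers carried into the output row.
#' @return One-row data.frame: protein, tissue, patient, core, compartment,
#'   mean, max, min, area.
#' @export
extract_roi_stats <- function(candidate, roi, protein, core_id) {
  if (!identical(dim(candidate), dim(roi$mask)))
    stop("candidate image and ROI mask dimensions differ")
  v <- candidate[roi$mask]
  if (length(v) == 0L) stop("empty ROI mask")
  data.frame(protein = protein, tissue = core_id$tissue,
             patient = core_id$patient, core = core_id$core,
             compartment = roi$compartment,
             mean = mean(v), max = max(v), min = min(v),
             area = roi$area, stringsAsFactors = FALSE)
}

#' Process one core stack end to end
#'
#' 8-bit conversion of every channel, discarding of DAPI/autofluorescence,
#' multi-Otsu segmentation of each of the five marker channels, and
#' extraction of candidate-channel statistics in each marker ROI. If
#' segmentation fails for any marker the whole stack is excluded and a
#' failed QC verdict is returned instead of measurements.
#'
#' @param stack a `cilia_stack`.
#' @param keep_rois logical; also return the five ROIs (for diagnostics).
#' @return List with `measurements` (5-row data.frame, or NULL on failure),
#'   `qc` (one-row data.frame: tissue, patient, core, protein, passed,
#'   reason), and optionally `rois`.
#' @export
process_core <- function(stack, keep_rois = FALSE) {
  stack$channels <- lapply(stack$channels, convert_to_8bit,
                           bit_depth = stack$bit_depth)
  stack$bit_depth <- 8L
  stack <- discard_channels(stack)

  qc <- data.frame(tissue = stack$core_id$tissue,
                   patient = stack$core_id$patient,
                   core = stack$core_id$core, protein = stack$protein,
                   passed = TRUE, reason = "", stringsAsFactors = FALSE)
  rois <- list()
  for (cmp in compartment_labels()) {
    r <- tryCatch(segment_marker(stack$channels[[cmp]], cmp),
                  cilia_seg_failure = function(e) e)
    if (inherits(r, "cilia_seg_failure")) {
      qc$passed <- FALSE
      qc$reason <- sprintf("marker %s: %s", cmp, conditionMessage(r))
      return(list(measurements = NULL, qc = qc))
    }
    rois[[cmp]] <- r
  }
  meas <- do.call(rbind, lapply(rois, function(r)
    extract_roi_stats(stack$channels$CANDIDATE, r, stack$protein,
                      stack$core_id)))
  rownames(meas) <- NULL
  out <- list(measurements = meas, qc = qc)
  if (keep_rois) out$rois <- rois
  out
}

#' Process a collection of stacks
#'
#' @param stacks list of `cilia_stack` objects.
#' @param verbose log one line per excluded core to stderr.
#' @return List with `measurements` (data.frame over all passing cores) and
#'   `qc` (one row per stack).
#' @export
process_study <- function(stacks, verbose = FALSE) {
  res <- lapply(stacks, process_core)
  qc <- do.call(rbind, lapply(res, `[[`, "qc"))
  rownames(qc) <- NULL
  if (verbose) {
    for (i in which(!qc$passed))
      message(sprintf("excluded core %s/%s/%s [%s]: %s", qc$tissue[i],
                      qc$patient[i], qc$core[i], qc$protein[i], qc$reason[i]))
  }
  meas <- do.call(rbind, lapply(res, `[[`, "measurements"))
  if (!is.null(meas)) rownames(meas) <- NULL
  list(measurements = meas, qc = qc)
}
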