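#' Ground-truth localization profile for a synthetic candidate protein
#'
#' A candidate protein's true subcellular distribution is a weight vector
#' over the five compartments (CL, TZ, RL, CYTO, NUC) summing to 1. A
#' per-tissue override map emulates tissue-variable proteins whose
#' localization differs between, say, respiratory and reproductive
#' epithelium.
#'
#' @param protein character protein identifier.
#' @param weights numeric length 5, nonnegative, summing to 1 (tolerance
#'   1e-9), in compartment order `compartment_labels()`.
#' @param tissue_overrides optional named list mapping a tissue name to an
#'   alternative 5-weight vector.
#' @return Object of class `ground_truth_profile` with fields `protein`,
#'   `weights` (named), `tissue_overrides`, `dominant` (label of the
#'   largest weight; ties broken by fixed compartment order).
#' @examples
#' ground_truth_profile("P1", c(0.7, 0.1, 0.1, 0.05, 0.05))
#' @export
ground_truth_profile <- function(protein, weights, tissue_overrides = NULL) {
  check_w <- function(w) {
    if (length(w) != 5L || any(w < 0))
      stop("weights must be 5 nonnegative values")
    if (abs(sum(w) - 1) > 1e-9)
      stop("weights must sum to 1 (got ", sum(w), ")")
    stats::setNames(as.numeric(w), compartment_labels())
  }
  weights <- check_w(weights)
  if (!is.null(tissue_overrides))
    tissue_overrides <- lapply(tissue_overrides, check_w)
  structure(
    list(protein = as.character(protein), weights = weights,
         tissue_overrides = tissue_overrides,
         dominant = compartment_labels()[which.max(weights)]),
    class = "ground_truth_profile")
}

# weights effective in one tissue
profile_weights <- function(profile, tissue) {
  ov <- profile$tissue_overrides
  if (!is.null(ov) && tissue %in% names(ov)) ov[[tissue]] else profile$weights
}

#' Acquisition-noise model for the synthetic generator
#'
#' All levels are expressed on the 8-bit display scale (0-255); generated
#' stacks are stored at 16 bits (value x 257) so the 8-bit conversion stage
#' downstream is exercised non-trivially.
#'
#' @param background baseline intensity, in `[0, 255]`.
#' @param amplitude full marker/candidate signal above background;
#'   `background + amplitude` must not exceed 255.
#' @param sigma standard deviation of additive Gaussian read noise.
#' @param shot_noise logical; if `TRUE`, pixel values are Poisson-resampled
#'   around their expected level before read noise.
#' @param af_amplitude mean level of the autofluorescence channel.
#' @param seed integer seed; identical seed and arguments give bit-identical
#'   stacks.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(background = 20, amplitude = 180, sigma = 8,
                        shot_noise = FALSE, af_amplitude = 10, seed = 1L) {
  if (background < 0 || background > 255) stop("background outside [0,255]")
  if (amplitude < 0 || background + amplitude > 255)
    stop("background + amplitude must lie in [0,255]")
  if (sigma < 0) stop("sigma must be nonnegative")
  structure(list(background = background, amplitude = amplitude,
                 sigma = sigma, shot_noise = isTRUE(shot_noise),
                 af_amplitude = af_amplitude, seed = as.integer(seed)),
            class = "noise_model")
}

#' Study design for a synthetic tissue-microarray experiment
#'
#' The default design mirrors a TMA with five ciliated-epithelium tissues,
#' duplicate 1 mm cores from three individuals per tissue (six cores per
#' tissue), and one slide (hence one stack per core) per candidate protein.
#'
#' @param tissues character vector of tissue names.
#' @param patients_per_tissue number of individuals sampled per tissue.
#' @param cores_per_patient number of replicate cores per individual.
#' @param profiles list of [ground_truth_profile()] objects, one per
#'   candidate protein.
#' @param shape image dimensions in pixels (rows, cols), >= 64 each.
#' @return Object of class `study_design`.
#' @export
study_design <- function(tissues = names(tissue_codes()),
                         patients_per_tissue = 3L, cores_per_patient = 2L,
                         profiles = list(), shape = c(96L, 96L)) {
  if (patients_per_tissue < 1L || cores_per_patient < 1L)
    stop("patients and cores per patient must be >= 1")
  structure(list(tissues = tissues,
                 patients_per_tissue = as.integer(patients_per_tissue),
                 cores_per_patient = as.integer(cores_per_patient),
                 profiles = profiles, shape = as.integer(shape)),
            class = "study_design")
}

#' Regularly spaced candidate profiles for simulations
#'
#' Convenience constructor: `n` candidate proteins whose dominant
#' compartment cycles through the five compartments, each with the stated
#' dominant weight and the remainder spread evenly over the other four.
#'
#' @param n number of proteins.
#' @param dominant_weight weight of the dominant compartment (> 0.2 so the
#'   dominant compartment is unique).
#' @return List of [ground_truth_profile()] objects named `protein_001`, ...
#' @export
make_profiles <- function(n, dominant_weight = 0.6) {
  if (dominant_weight <= 0.2 || dominant_weight > 1)
    stop("dominant_weight must be in (0.2, 1]")
  labs <- compartment_labels()
  lapply(seq_len(n), function(i) {
    w <- rep((1 - dominant_weight) / 4, 5)
    w[((i - 1L) %% 5L) + 1L] <- dominant_weight
    ground_truth_profile(sprintf("protein_%03d", i), w)
  })
}

# 3x3 binary dilation, used to draw the intermediate rim around marker masks
dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | out[, -nc]
  out[, -nc] <- out[, -nc] | out[, -1]
  out
}

# render one 8-bit-scale channel to a 16-bit integer matrix with noise
render_channel <- function(value8, noise) {
  if (noise$shot_noise) {
    v <- stats::rpois(length(value8), lambda = pmax(value8, 0))
    value8 <- matrix(v, nrow(value8), ncol(value8))
  }
  if (noise$sigma > 0)
    value8 <- value8 + matrix(stats::rnorm(length(value8), 0, noise$sigma),
                              nrow(value8), ncol(value8))
  matrix(as.integer(round_half_up(clip(value8, 0, 255) * 257)),
         nrow(value8), ncol(value8))
}

#' Generate one synthetic TMA-core image stack
#'
#' Renders the eight channels of one core for one candidate protein: the
#' five panel-marker channels (bright on their compartment geometry, with a
#' half-amplitude rim one pixel wide so each noiseless marker image carries
#' exactly three intensity levels), the candidate channel (expected value
#' `background + amplitude * weight(compartment)` on each compartment mask,
#' `background` elsewhere), DAPI (bright on nuclei), and autofluorescence.
#'
#' @param design a [study_design()].
#' @param tissue tissue name; must be one of `design$tissues`.
#' @param patient,core identifiers (integers or short strings).
#' @param profile a [ground_truth_profile()].
#' @param noise a [noise_model()]; its `seed` makes the stack reproducible.
#' @return Object of class `cilia_stack`: named list `channels` (eight
#'   16-bit integer matrices in `stack_roles()` order), `manifest` (role ->
#'   page index), `core_id`, `protein`, `bit_depth`, `geometry`.
#' @examples
#' d <- study_design(profiles = make_profiles(1))
#' s <- generate_core(d, "bronchus", 1, 1, d$profiles[[1]],
#'                    noise_model(sigma = 0))
#' names(s$channels)
#' @export
generate_core <- function(design, tissue, patient, core, profile, noise) {
  if (!tissue %in% design$tissues)
    stop("unknown tissue label: ", tissue)
  stopifnot(inherits(profile, "ground_truth_profile"),
            inherits(noise, "noise_model"))
  geom <- compartment_geometry(design$shape)
  w <- profile_weights(profile, tissue)
  b <- noise$background; a <- noise$amplitude

  set.seed(noise$seed)
  base <- matrix(b, design$shape[1], design$shape[2])
  chans <- vector("list", 8L)
  names(chans) <- stack_roles()
  for (cmp in compartment_labels()) {
    v <- base
    rim <- dilate3(geom[[cmp]]) & !geom[[cmp]]
    v[rim] <- b + 0.5 * a
    v[geom[[cmp]]] <- b + a
    chans[[cmp]] <- render_channel(v, noise)
  }
  v <- base
  for (cmp in compartment_labels()) v[geom[[cmp]]] <- b + a * w[[cmp]]
  chans[["CANDIDATE"]] <- render_channel(v, noise)
  v <- base
  v[dilate3(geom$NUC) & !geom$NUC] <- b + 0.5 * a
  v[geom$NUC] <- b + a
  chans[["DAPI"]] <- render_channel(v, noise)
  chans[["AF"]] <- render_channel(
    matrix(noise$af_amplitude, design$shape[1], design$shape[2]), noise)

  structure(list(
    channels = chans,
    manifest = stats::setNames(seq_along(chans), names(chans)),
    core_id = list(tissue = tissue, patient = as.character(patient),
                   core = as.character(core)),
    protein = profile$protein, bit_depth = 16L, geometry = geom),
    class = "cilia_stack")
}

#' @export
print.cilia_stack <- function(x, ...) {
  cat(sprintf("<cilia_stack> %s | %s patient %s core %s | %dx%d, %d-bit, %d channels\n",
              x$protein, x$core_id$tissue, x$core_id$patient, x$core_id$core,
              nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              x$bit_depth, length(x$channels)))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One stack per (protein, tissue, patient, core). A configurable fraction
#' of stacks is "failed" by replacing one marker channel with a constant
#' image (degenerate histogram), the deterministic trigger for the
#' downstream segmentation-failure exclusion rule.
#'
#' @param design a [study_design()] with a non-empty profile list.
#' @param seed integer master seed; per-stack seeds are derived from it.
#' @param failed_fraction fraction of stacks to corrupt, in `[0, 1)`.
#' @param noise a [noise_model()] template (its `seed` field is overridden
#'   per stack).
#' @return List with `stacks` (list of `cilia_stack`), `truth` (data.frame
#'   protein/tissue/compartment/weight), `cores` (data.frame
#'   protein/tissue/patient/core/failed), and `design`.
#' @examples
#' st <- generate_study(study_design(profiles = make_profiles(2)), seed = 7)
#' length(st$stacks)  # 5 tissues x 3 patients x 2 cores x 2 proteins
#' @export
generate_study <- function(design, seed, failed_fraction = 0,
                           noise = noise_model()) {
  if (length(design$profiles) == 0L) stop("candidate protein list is empty")
  if (failed_fraction < 0 || failed_fraction >= 1)
    stop("failed_fraction must be in [0, 1)")
  seed <- as.integer(seed)

  grid <- expand.grid(core = seq_len(design$cores_per_patient),
                      patient = seq_len(design$patients_per_tissue),
                      tissue = design$tissues,
                      prot = seq_along(design$profiles),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  set.seed(seed)
  n_fail <- round(failed_fraction * n)
  failed_idx <- if (n_fail > 0) sort(sample.int(n, n_fail)) else integer(0)
  # which marker channel to corrupt, per failed stack
  fail_marker <- sample(compartment_labels(), n, replace = TRUE)

  stacks <- vector("list", n)
  cores <- data.frame(protein = character(n), tissue = character(n),
                      patient = character(n), core = character(n),
                      failed = logical(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- grid[i, ]
    pr <- design$profiles[[g$prot]]
    nm <- noise
    nm$seed <- (seed %% 100000L) * 20011L + i   # < 2^31 for any seed
    s <- generate_core(design, g$tissue, g$patient, g$core, pr, nm)
    if (i %in% failed_idx) {
      s$channels[[fail_marker[i]]][] <-
        as.integer(round_half_up(noise$background * 257))
    }
    stacks[[i]] <- s
    cores[i, ] <- list(pr$protein, g$tissue, as.character(g$patient),
                       as.character(g$core), i %in% failed_idx)
  }

  truth <- do.call(rbind, lapply(design$profiles, function(p) {
    do.call(rbind, lapply(design$tissues, function(tis) {
      data.frame(protein = p$protein, tissue = tis,
                 compartment = compartment_labels(),
                 weight = unname(profile_weights(p, tis)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(truth) <- NULL

  list(stacks = stacks, truth = truth, cores = cores, design = design)
}
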