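#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end workflow. The
#' configuration round-trips losslessly through JSON.
#'
#' @param n_proteins candidate proteins to simulate (ignored when
#'   `input_dir` is given).
#' @param k row clusters for the dendrogram cut.
#' @param p_cutoff raw enrichment p-value cutoff.
#' @param ntpm_threshold transcript-expression cutoff of the selection
#'   funnel (inclusive).
#' @param linkage hclust linkage method.
#' @param seed master seed for simulation.
#' @param failed_fraction fraction of simulated stacks corrupted to
#'   exercise QC exclusion.
#' @param shape simulated image dimensions.
#' @param sigma additive Gaussian noise level of the simulation.
#' @param input_dir optional directory of TIFF/JSON stacks to analyse
#'   instead of simulating.
#' @param output_dir optional directory for result files.
#' @param annotation optional annotation table or TSV/GMT path.
#' @param fe optional FE-score table (data.frame or TSV path with columns
#'   protein, pe, fe).
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(n_proteins = 20L, k = 7L, p_cutoff = 0.05,
                            ntpm_threshold = 0.1, linkage = "complete",
                            seed = 1L, failed_fraction = 0,
                            shape = c(96L, 96L), sigma = 8,
                            input_dir = NULL, output_dir = NULL,
                            annotation = NULL, fe = NULL) {
  stopifnot(k >= 1L, p_cutoff > 0, p_cutoff <= 1, ntpm_threshold >= 0,
            failed_fraction >= 0, failed_fraction < 1, sigma >= 0)
  structure(list(n_proteins = as.integer(n_proteins), k = as.integer(k),
                 p_cutoff = p_cutoff, ntpm_threshold = ntpm_threshold,
                 linkage = linkage, seed = as.integer(seed),
                 failed_fraction = failed_fraction,
                 shape = as.integer(shape), sigma = sigma,
                 input_dir = input_dir, output_dir = output_dir,
                 annotation = annotation, fe = fe),
            class = "pipeline_config")
}

#' Run the localization-profiling pipeline
#'
#' End-to-end workflow: obtain image stacks (simulate a seeded synthetic
#' study, or read an input directory), segment each core against the
#' five-marker panel, aggregate medians, build the normalized expression
#' matrix, cluster rows and columns, cut row clusters, and — when an
#' annotation or FE table is supplied — run per-cluster GO
#' over-representation and the FE-score summary. Identical configuration
#' and seed give identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `cilia_run` with components `measurements`,
#'   `qc`, `medians`, `matrix`, `row_dendrogram`, `col_dendrogram`,
#'   `assignment`, `enrichment`, `fe_summary`, `truth` (simulation only),
#'   `config`.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(n_proteins = 10, k = 5, seed = 42))
#' summary(run)
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL; cores <- NULL
  if (is.null(config$input_dir)) {
    design <- study_design(profiles = make_profiles(config$n_proteins),
                           shape = config$shape)
    study <- generate_study(design, seed = config$seed,
                            failed_fraction = config$failed_fraction,
                            noise = noise_model(sigma = config$sigma))
    stacks <- study$stacks; truth <- study$truth; cores <- study$cores
  } else {
    tifs <- list.files(config$input_dir, pattern = "\\.tiff?$",
                       full.names = TRUE)
    if (length(tifs) == 0L) stop("no TIFF stacks in ", config$input_dir)
    stacks <- lapply(tifs, read_stack)
  }

  seg <- process_study(stacks)
  medians <- aggregate_median(seg$measurements, seg$qc)
  mat <- build_matrix(medians[!medians$missing, ])

  row_hc <- cluster_items(mat, "rows", method = config$linkage)
  col_hc <- cluster_items(mat, "columns", method = config$linkage)
  k <- min(config$k, length(row_hc$order))
  assignment <- cut_clusters(row_hc, k = k)

  enr <- NULL
  ann <- config$annotation
  if (!is.null(ann)) {
    if (is.character(ann)) ann <- read_annotation(ann)
    enr <- do.call(rbind, lapply(sort(unique(assignment)), function(cl) {
      genes <- intersect(names(assignment)[assignment == cl],
                         unique(ann$gene))
      if (length(genes) == 0L) return(NULL)
      r <- enrich_cluster(genes, ann, p_cutoff = config$p_cutoff)
      if (nrow(r)) cbind(cluster = cl, r) else NULL
    }))
  }
  fe_sum <- NULL
  fe <- config$fe
  if (!is.null(fe)) {
    if (is.character(fe)) fe <- utils::read.delim(fe)
    fe_sum <- fe_distribution(fe, assignment)
  }

  run <- structure(list(measurements = seg$measurements, qc = seg$qc,
                        medians = medians, matrix = mat,
                        row_dendrogram = row_hc, col_dendrogram = col_hc,
                        assignment = assignment, enrichment = enr,
                        fe_summary = fe_sum, truth = truth, cores = cores,
                        config = config),
                   class = "cilia_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' Write the artifact bundle of a pipeline run
#'
#' Measurements, QC verdicts, median table, normalized matrix, cluster
#' assignment, Newick dendrograms, enrichment table, heatmap, and a JSON
#' run manifest recording every parameter needed to reproduce the run.
#'
#' @param run a `cilia_run`. @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(run$measurements, file.path(dir, "measurements.csv"))
  write_table_csv(run$qc, file.path(dir, "qc.csv"))
  write_table_csv(run$medians, file.path(dir, "medians.csv"))
  write_matrix_csv(run$matrix, file.path(dir, "matrix.csv"))
  write_table_csv(data.frame(protein = names(run$assignment),
                             cluster = unname(run$assignment)),
                  file.path(dir, "clusters.csv"))
  write_dendrogram(run$row_dendrogram, file.path(dir, "rows.nwk"))
  write_dendrogram(run$col_dendrogram, file.path(dir, "columns.nwk"))
  if (!is.null(run$enrichment))
    write_table_csv(run$enrichment, file.path(dir, "enrichment.csv"))
  render_heatmap(run$matrix, run$assignment,
                 file.path(dir, "heatmap.png"))
  cfg <- run$config
  cfg$annotation <- NULL; cfg$fe <- NULL
  jsonlite::write_json(
    list(package = "ciliamap",
         version = as.character(utils::packageVersion("ciliamap")),
         parameters = unclass(cfg)),
    path = file.path(dir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.cilia_run <- function(x, ...) {
  cat("Subcellular localization profiling run\n")
  cat(sprintf("  cores processed : %d (%d passed QC, %d excluded)\n",
              nrow(x$qc), sum(x$qc$passed), sum(!x$qc$passed)))
  cat(sprintf("  proteins        : %d\n", nrow(x$matrix)))
  cat(sprintf("  expression matrix: %d x %d (min-max scaled medians)\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  row clusters (k=%d): sizes %s\n",
              length(unique(x$assignment)),
              paste(cluster_sizes(x$assignment), collapse = ", ")))
  if (!is.null(x$enrichment))
    cat(sprintf("  enriched GO terms: %d below p < %g\n",
                nrow(x$enrichment), x$config$p_cutoff))
  invisible(x)
}

#' @export
summary.cilia_run <- function(object, ...) {
  dom <- apply(object$matrix, 1L, function(r)
    sub("_.*", "", colnames(object$matrix)[which.max(r)]))
  s <- list(n_cores = nrow(object$qc), n_passed = sum(object$qc$passed),
            n_proteins = nrow(object$matrix),
            cluster_sizes = cluster_sizes(object$assignment),
            dominant_compartment = table(dom))
  class(s) <- "summary.cilia_run"
  s
}

#' @export
print.summary.cilia_run <- function(x, ...) {
  cat(sprintf("Cores: %d (%d passed QC)\nProteins profiled: %d\n",
              x$n_cores, x$n_passed, x$n_proteins))
  cat("Cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("Apparent dominant compartment (argmax of normalized profile):\n")
  print(x$dominant_compartment)
  invisible(x)
}

#' @export
plot.cilia_run <- function(x, file = tempfile(fileext = ".png"), ...) {
  render_heatmap(x$matrix, x$assignment, file, ...)
  invisible(file)
}
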