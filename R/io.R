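# Multi-page TIFF + JSON-manifest stack IO and CSV table writers.

#' Write a stack as multi-page TIFF with a JSON channel manifest
#'
#' One page per channel, 16-bit; the sidecar `<stem>.json` maps page index
#' to channel role and records the core identity.
#'
#' @param stack a `cilia_stack`.
#' @param dir output directory (created if needed).
#' @return Path of the TIFF file, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- paste(stack$protein, stack$core_id$tissue, stack$core_id$patient,
                stack$core_id$core, sep = "__")
  tif <- file.path(dir, paste0(stem, ".tiff"))
  pages <- lapply(stack$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  jsonlite::write_json(
    list(roles = as.list(stack$manifest), protein = stack$protein,
         tissue = stack$core_id$tissue, patient = stack$core_id$patient,
         core = stack$core_id$core, bit_depth = stack$bit_depth),
    path = file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE)
  invisible(tif)
}

#' Read a stack written by [write_stack()]
#'
#' @param tif path to the multi-page TIFF; the manifest is expected at the
#'   same path with extension `.json`.
#' @return A `cilia_stack` (without ground-truth geometry).
#' @export
read_stack <- function(tif) {
  man_path <- sub("\\.tiff?$", ".json", tif)
  if (!file.exists(man_path)) stop("missing manifest: ", man_path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  roles <- man$roles
  if (length(roles) != length(pages))
    stop(sprintf("manifest lists %d roles but TIFF has %d pages",
                 length(roles), length(pages)))
  ord <- order(unlist(roles))
  chans <- stats::setNames(pages[unlist(roles)[ord]], names(roles)[ord])
  chans <- lapply(chans, function(m) {
    storage.mode(m) <- "integer"; m
  })
  structure(list(channels = chans,
                 manifest = stats::setNames(seq_along(chans), names(chans)),
                 core_id = list(tissue = man$tissue, patient = man$patient,
                                core = man$core),
                 protein = man$protein,
                 bit_depth = as.integer(man$bit_depth)),
            class = "cilia_stack")
}

# numeric CSV precision defaults to 6 significant digits for stable diffs
fmt_num <- function(d, digits) {
  if (is.na(digits)) return(d)
  for (j in seq_along(d))
    if (is.double(d[[j]])) d[[j]] <- signif(d[[j]], digits)
  d
}

#' Write a data.frame to CSV
#'
#' Doubles are rounded to `digits` significant digits (default 6) for
#' stable diffs; pass `digits = NA` to keep full precision (used for
#' ground-truth tables that must round-trip exactly).
#'
#' @param d data.frame. @param file path. @param digits significant digits.
#' @return `file`, invisibly.
#' @export
write_table_csv <- function(d, file, digits = 6) {
  utils::write.csv(fmt_num(d, digits), file, row.names = FALSE)
  invisible(file)
}

#' Write / read the expression matrix as CSV
#'
#' Proteins as rows (first column `protein`), `compartment_tissue` column
#' headers; values round-trip to at least 1e-9.
#'
#' @param m matrix from [build_matrix()]. @param file path.
#' @return `file` / the matrix.
#' @export
write_matrix_csv <- function(m, file) {
  d <- data.frame(protein = rownames(m), m, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read a gene annotation table (TSV or GMT)
#'
#' TSV needs columns gene/term/name/category; GMT lines are
#' `term<TAB>name|category<TAB>gene...`.
#'
#' @param file path; format inferred from the extension.
#' @return data.frame with columns gene, term, name, category.
#' @export
read_annotation <- function(file) {
  if (grepl("\\.gmt$", file, ignore.case = TRUE)) {
    lines <- readLines(file)
    rows <- lapply(strsplit(lines, "\t"), function(f) {
      if (length(f) < 3L) stop("malformed GMT line")
      meta <- strsplit(f[2], "|", fixed = TRUE)[[1]]
      data.frame(gene = f[-(1:2)], term = f[1], name = meta[1],
                 category = if (length(meta) > 1) meta[2] else NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    utils::read.delim(file, stringsAsFactors = FALSE)
  }
}
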