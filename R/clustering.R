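#' Hierarchical clustering of the expression matrix
#'
#' Agglomerative clustering with Euclidean distance and complete linkage —
#' the defaults of the standard heatmap packages — applied to rows
#' (proteins) or columns (compartment-tissue profiles). Rows containing
#' missing values are dropped with a warning (no imputation is performed).
#'
#' @param matrix numeric expression matrix ([build_matrix()] output).
#' @param axis `"rows"` or `"columns"`.
#' @param method linkage method passed to [stats::hclust()].
#' @return An `hclust` object (attribute `axis` records the axis).
#' @export
cluster_items <- function(matrix, axis = c("rows", "columns"),
                          method = "complete") {
  axis <- match.arg(axis)
  x <- if (axis == "columns") t(matrix) else matrix
  drop <- apply(x, 1L, anyNA)
  if (any(drop)) {
    warning(sum(drop), " item(s) with missing values dropped from ",
            axis, " clustering: ",
            paste(utils::head(rownames(x)[drop], 5L), collapse = ", "))
    x <- x[!drop, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 complete items to cluster")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = method)
  attr(hc, "axis") <- axis
  hc
}

#' Cut a dendrogram into k clusters
#'
#' Fixed-k cut of the row dendrogram; cluster ids are renumbered by
#' dendrogram leaf order (the leftmost leaf's cluster is 1) so labels are
#' deterministic and match a plotted heatmap top to bottom.
#'
#' @param dendrogram an `hclust` object from [cluster_items()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param h optional height; if given, overrides `k` (height cut).
#' @return Named integer vector item -> cluster id in `1..k`.
#' @export
cut_clusters <- function(dendrogram, k = 7L, h = NULL) {
  n <- length(dendrogram$order)
  if (is.null(h)) {
    if (k < 1L || k > n) stop("k must be between 1 and the item count")
    cl <- stats::cutree(dendrogram, k = k)
  } else {
    cl <- stats::cutree(dendrogram, h = h)
  }
  # renumber in dendrogram order
  first <- cl[dendrogram$order]
  map <- stats::setNames(seq_along(unique(first)), unique(first))
  out <- map[as.character(cl)]
  names(out) <- names(cl)
  storage.mode(out) <- "integer"
  out
}

#' Sizes of a cluster assignment
#'
#' @param assignment named vector from [cut_clusters()].
#' @return Integer vector of cluster sizes, ordered by cluster id.
#' @export
cluster_sizes <- function(assignment) {
  as.integer(table(factor(assignment, levels = sort(unique(assignment)))))
}

#' Render the clustered expression heatmap
#'
#' Presentational twin of the localization heatmap: proteins x
#' compartment-tissue matrix with row/column dendrograms (Euclidean,
#' complete linkage) and a row-cluster annotation bar.
#'
#' @param matrix expression matrix (complete rows only are drawn).
#' @param assignment optional named cluster vector for the annotation bar.
#' @param file output path (`.png` or `.pdf`).
#' @param ... further arguments to [pheatmap::pheatmap()].
#' @return `file`, invisibly.
#' @export
render_heatmap <- function(matrix, assignment = NULL, file, ...) {
  keep <- !apply(matrix, 1L, anyNA)
  m <- matrix[keep, , drop = FALSE]
  ann <- NA
  if (!is.null(assignment)) {
    ann <- data.frame(cluster = factor(assignment[rownames(m)]),
                      row.names = rownames(m))
  }
  pheatmap::pheatmap(m,
                     clustering_distance_rows = "euclidean",
                     clustering_distance_cols = "euclidean",
                     clustering_method = "complete",
                     annotation_row = ann, filename = file,
                     silent = TRUE, ...)
  invisible(file)
}

#' Export a dendrogram as Newick text
#'
#' @param dendrogram an `hclust` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dendrogram <- function(dendrogram, file) {
  ape::write.tree(ape::as.phylo(dendrogram), file = file)
  invisible(file)
}
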