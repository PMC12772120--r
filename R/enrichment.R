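#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value: the probability of drawing at least `k`
#' annotated genes when `n` genes are drawn without replacement from a
#' universe of `N` genes of which `K` carry the annotation,
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
#'   \binom{N}{n},}
#' summed stably in log space.
#'
#' @param k observed annotated genes in the drawn set.
#' @param n drawn set size (cluster genes with any annotation).
#' @param K annotated genes in the universe.
#' @param N universe size.
#' @return The upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(4, 4, 5, 10)  # 5 / choose(10, 4)
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0) stop("negative parameter")
  if (n > N || K > N) stop("n and K must not exceed N")
  if (k > min(n, K)) stop("k must not exceed min(n, K)")
  if (k == 0) return(1)
  i <- k:min(n, K)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  p <- exp(m) * sum(exp(lp - m))
  min(p, 1)
}

#' GO over-representation for one protein cluster
#'
#' Tests every annotation term with at least one cluster gene against the
#' hypergeometric null and keeps terms below the p-value cutoff. The
#' universe defaults to all annotated genes in the annotation table
#' (self-contained; no live database access). The rich factor of a term is
#' `k / K`: the fraction of the term's genes found in the cluster.
#'
#' @param cluster_genes character vector of gene/protein ids in one cluster.
#' @param annotation data.frame with columns `gene`, `term`, `name`,
#'   `category` (category in biological_process / molecular_function /
#'   cellular_component); duplicate (gene, term) pairs are an error.
#' @param universe character vector; defaults to all genes in `annotation`.
#' @param p_cutoff retain terms with `p < p_cutoff` (default 0.05, raw).
#' @param adjust apply Benjamini-Hochberg adjustment before filtering
#'   (off by default; the cutoff is then applied to the adjusted value).
#' @return data.frame: term, name, category, k, n, K, N, p, rich_factor,
#'   sorted by p.
#' @export
enrich_cluster <- function(cluster_genes, annotation, universe = NULL,
                           p_cutoff = 0.05, adjust = FALSE) {
  if (length(cluster_genes) == 0L) stop("empty cluster")
  req <- c("gene", "term", "name", "category")
  if (!all(req %in% names(annotation)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  if (nrow(annotation) == 0L) stop("empty annotation")
  if (anyDuplicated(annotation[, c("gene", "term")]))
    stop("duplicate (gene, term) pairs in annotation")
  if (is.null(universe)) universe <- unique(annotation$gene)
  if (!all(cluster_genes %in% universe))
    stop("cluster contains genes outside the universe")
  ann <- annotation[annotation$gene %in% universe, ]

  N <- length(universe)
  in_cluster <- unique(cluster_genes)
  annotated_cluster <- intersect(in_cluster, unique(ann$gene))
  n <- length(annotated_cluster)
  if (n == 0L)
    return(data.frame(term = character(), name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      rich_factor = numeric()))

  hit <- ann[ann$gene %in% annotated_cluster, ]
  terms <- unique(hit$term)
  rows <- lapply(terms, function(tm) {
    sub <- ann[ann$term == tm, ]
    k <- sum(sub$gene %in% annotated_cluster)
    K <- nrow(sub)
    data.frame(term = tm, name = sub$name[1], category = sub$category[1],
               k = k, n = n, K = K, N = N,
               p = hypergeom_upper_tail(k, n, K, N),
               rich_factor = k / K, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  keep <- if (adjust) out$p_adjust < p_cutoff else out$p < p_cutoff
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top terms per category per cluster
#'
#' Selects up to three terms per GO category, ranked by the number of
#' associated cluster proteins `k` (descending), with ties broken by
#' smaller p then lexical term id.
#'
#' @param results data.frame from [enrich_cluster()] (already filtered at
#'   the p cutoff), optionally with a `cluster` column.
#' @param n_top terms kept per category (per cluster if present).
#' @return The selected subset, ordered cluster/category/rank.
#' @export
top_terms <- function(results, n_top = 3L) {
  if (nrow(results) == 0L) return(results)
  grp <- interaction(
    if ("cluster" %in% names(results)) results$cluster else 0,
    results$category, drop = TRUE)
  picked <- lapply(split(results, grp), function(d) {
    d <- d[order(-d$k, d$p, d$term), , drop = FALSE]
    utils::head(d, n_top)
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Functional-evidence score distribution
#'
#' Summarizes HUPO Human Proteome Project Function Evidence (FE) grades —
#' FE1 (at least one function known) through FE5 (function unknown) —
#' over all proteins and per localization cluster. Reports the headline
#' split between FE1 and FE2-5.
#'
#' @param fe data.frame with columns `protein` and `fe` (integer 1-5);
#'   a `pe` column is carried along if present.
#' @param assignment optional named cluster vector ([cut_clusters()]); if
#'   given, a per-cluster FE x cluster contingency is included and proteins
#'   without an FE record are listed (never silently dropped).
#' @return List: `counts` (per FE score), `percent` (rounded to integer
#'   percent), `fe1_percent`, `fe2to5_percent`, `by_cluster` (matrix or
#'   NULL), `missing` (proteins lacking FE records).
#' @export
fe_distribution <- function(fe, assignment = NULL) {
  if (!all(c("protein", "fe") %in% names(fe)))
    stop("fe table must have columns protein, fe")
  if (!all(fe$fe %in% 1:5)) stop("FE scores must be integers 1..5")
  counts <- stats::setNames(
    as.integer(table(factor(fe$fe, levels = 1:5))), paste0("FE", 1:5))
  total <- sum(counts)
  pct <- round(100 * counts / total)
  out <- list(counts = counts, percent = pct,
              fe1_percent = unname(round(100 * counts[1] / total)),
              fe2to5_percent = unname(round(100 * sum(counts[2:5]) / total)),
              by_cluster = NULL, missing = character(0))
  if (!is.null(assignment)) {
    out$missing <- setdiff(names(assignment), fe$protein)
    idx <- match(names(assignment), fe$protein)
    ok <- !is.na(idx)
    out$by_cluster <- table(fe = factor(fe$fe[idx[ok]], levels = 1:5),
                            cluster = assignment[ok])
  }
  out
}

#' Candidate-selection funnel
#'
#' Computational filters of the candidate-selection procedure: transcript
#' expression in ciliated cells (nTPM at or above the threshold, inclusive)
#' and antibody reliability class membership, with an optional
#' differential-expression flag. Manual curation is outside this package's
#' scope; the funnel stops at the computational stages.
#'
#' @param genes data.frame with columns `gene`, `ntpm`, `reliability`, and
#'   optionally `differential` (logical).
#' @param criteria list with `ntpm_threshold` (default 0.1) and
#'   `reliability_classes` (default Enhanced, Supported, Approved).
#' @return List: `selected` (character vector of surviving genes) and
#'   `funnel` (named integer vector of survivors per stage).
#' @export
select_candidates <- function(genes,
                              criteria = list(
                                ntpm_threshold = 0.1,
                                reliability_classes =
                                  c("Enhanced", "Supported", "Approved"))) {
  req <- c("gene", "ntpm", "reliability")
  if (!all(req %in% names(genes)))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  funnel <- c(input = nrow(genes))
  g <- genes[genes$ntpm >= criteria$ntpm_threshold, ]
  funnel["expressed"] <- nrow(g)
  g <- g[g$reliability %in% criteria$reliability_classes, ]
  funnel["reliable_antibody"] <- nrow(g)
  if ("differential" %in% names(genes)) {
    g <- g[g$differential, ]
    funnel["differential"] <- nrow(g)
  }
  list(selected = g$gene, funnel = funnel)
}
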