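# Hypergeometric over-representation, rich factors, FE summaries and the
# candidate-selection funnel.

test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10), 5 / choose(10, 4),
               tolerance = 1e-12)
  set.seed(14)
  for (i in 1:200) {
    N <- sample(2:30, 1)
    n <- sample(0:N, 1); K <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(k, n, K, N), hyper_oracle(k, n, K, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "exceed")
  expect_error(hypergeom_upper_tail(1, 4, 11, 10), "exceed")
})

test_that("p is non-increasing in k at fixed (n, K, N)", {
  for (prm in list(c(8, 10, 40), c(5, 5, 12), c(20, 30, 100))) {
    p <- vapply(0:min(prm[1], prm[2]), hypergeom_upper_tail,
                numeric(1), n = prm[1], K = prm[2], N = prm[3])
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("cluster enrichment filters at p < 0.05 and reports rich factors", {
  universe <- sprintf("g%02d", 1:40)
  cluster <- universe[1:8]
  ann <- toy_annotation(cluster, universe)
  res <- enrich_cluster(cluster, ann, p_cutoff = 0.05)
  # the term annotating the whole universe has p = 1 and is filtered out
  expect_false("GO:ALL" %in% res$term)
  # the constructed perfect term is the most significant of its category
  bp <- res[res$category == "biological_process", ]
  expect_equal(bp$term[which.min(bp$p)], "GO:PERFECT")
  perfect <- res[res$term == "GO:PERFECT", ]
  expect_equal(perfect$k, 8L)
  expect_equal(perfect$rich_factor, 1)   # RF = 1 iff cluster holds all term genes
  expect_true(all(res$rich_factor > 0 & res$rich_factor <= 1))
  expect_true(all(res$p < 0.05))

  expect_equal(unique(res$N), 40L)
  expect_error(enrich_cluster(character(0), ann), "empty")
  expect_error(enrich_cluster("zz", ann), "outside the universe")
  expect_error(enrich_cluster(cluster, ann[0, ]), "empty annotation")
  expect_error(enrich_cluster(cluster, rbind(ann, ann[1, ])), "duplicate")
})

test_that("rich factor follows its definition k / K", {
  universe <- sprintf("g%02d", 1:30)
  ann <- data.frame(gene = universe[1:12], term = "GO:T", name = "t",
                    category = "cellular_component")
  res <- enrich_cluster(universe[1:3], ann, universe = universe,
                        p_cutoff = 1.01)
  expect_equal(res$k, 3L); expect_equal(res$K, 12L)
  expect_equal(res$rich_factor, 0.25)
})

test_that("top_terms ranks by k, then smaller p, then term id", {
  res <- data.frame(
    term = c("GO:A", "GO:B", "GO:C", "GO:D", "GO:E"),
    name = letters[1:5], category = "biological_process",
    k = c(9L, 7L, 7L, 2L, 1L), n = 10L, K = c(20L, 30L, 10L, 5L, 2L),
    N = 100L, p = c(1e-6, 1e-3, 1e-4, 0.01, 0.04),
    rich_factor = 0.5, stringsAsFactors = FALSE)
  top <- top_terms(res)
  expect_equal(nrow(top), 3L)
  expect_setequal(top$term, c("GO:A", "GO:B", "GO:C"))
  expect_equal(top$term[2], "GO:C")   # k tie broken by smaller p
  expect_equal(nrow(top_terms(res[4:5, ])), 2L)
  # ties in k and p fall back to lexical term id
  res$p <- 0.01; res$k <- 5L
  expect_equal(top_terms(res)$term, c("GO:A", "GO:B", "GO:C"))
})

test_that("FE-score distribution reproduces the reference split", {
  fe <- utils::read.delim(system.file("extdata", "fe_scores_synthetic.tsv",
                                      package = "ciliamap"))
  expect_equal(nrow(fe), 187L)
  d <- fe_distribution(fe)
  expect_equal(d$fe1_percent, 27)
  expect_equal(d$fe2to5_percent, 73)
  expect_equal(sum(d$counts), 187)

  all5 <- data.frame(protein = c("a", "b"), fe = c(5L, 5L))
  expect_equal(unname(fe_distribution(all5)$percent), c(0, 0, 0, 0, 100))

  cl <- stats::setNames(rep(1:2, length.out = 10), fe$protein[1:10])
  d2 <- fe_distribution(fe, cl)
  expect_equal(unname(colSums(d2$by_cluster)), c(5, 5))
  # per-cluster percentages sum to 100 up to rounding
  pct <- round(100 * prop.table(d2$by_cluster, margin = 2))
  expect_true(all(abs(colSums(pct) - 100) <= 2))
  cl2 <- c(cl, phantom_protein = 1L)
  expect_equal(fe_distribution(fe, cl2)$missing, "phantom_protein")
})

test_that("selection funnel applies inclusive nTPM and reliability filters", {
  g <- data.frame(
    gene = paste0("g", 1:6),
    ntpm = c(0.1, 0.05, 2, 0, 5, 1),
    reliability = c("Enhanced", "Supported", "Uncertain", "Approved",
                    "Approved", "Supported"))
  sel <- select_candidates(g)
  expect_setequal(sel$selected, c("g1", "g5", "g6"))   # 2 fail nTPM, 1 reliability
  expect_true("g1" %in% sel$selected)                  # threshold is inclusive
  expect_false("g3" %in% sel$selected)                 # Uncertain excluded
  expect_true(all(diff(sel$funnel) <= 0))              # funnel non-increasing

  g$differential <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  sel2 <- select_candidates(g)
  expect_setequal(sel2$selected, c("g1", "g6"))
  expect_equal(unname(sel2$funnel), c(6, 4, 3, 2))
  expect_error(select_candidates(g[, 1:2]), "columns")
})
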