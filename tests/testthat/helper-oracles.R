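# Independent brute-force oracles and small fixture builders.

# Exhaustive three-class Otsu search: enumerates every admissible
# (t1, t2) pair and evaluates the defining between-class variance
# sum_c w_c (mu_c - mu)^2 directly, tracking the lexicographically
# smallest maximizer.
otsu_oracle <- function(h) {
  lev <- 0:255
  tot <- sum(h)
  W <- cumsum(h); M <- cumsum(h * lev)
  mu <- M[256] / tot
  best_sb <- -Inf; best <- c(NA_integer_, NA_integer_)
  for (a in 1:254) {
    w1 <- W[a]
    if (w1 == 0) next
    m1 <- M[a] / w1
    for (b in (a + 1):255) {
      w2 <- W[b] - W[a]; w3 <- tot - W[b]
      if (w2 == 0 || w3 == 0) next
      m2 <- (M[b] - M[a]) / w2
      m3 <- (M[256] - M[b]) / w3
      sb <- (w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2 + w3 * (m3 - mu)^2) / tot
      if (sb > best_sb) { best_sb <- sb; best <- c(a, b) }
    }
  }
  list(t1 = best[1], t2 = best[2], sigma_b = best_sb)
}

# random sparse 256-bin histogram with at least 3 populated bins
random_histogram <- function() {
  h <- integer(256)
  nz <- sample.int(256, sample(3:60, 1))
  h[nz] <- stats::rpois(length(nz), 50) + 1L
  h
}

# Hypergeometric upper tail by direct pmf summation with exact binomials.
hyper_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# n profiles drawn from three localization archetypes (CL / CYTO / NUC
# dominant); returns list(profiles, archetype labels)
archetype_profiles <- function(n_per = 4L, dominant_weight = 0.7) {
  doms <- c("CL", "CYTO", "NUC")
  labs <- compartment_labels()
  profiles <- list(); arch <- character(0)
  i <- 0L
  for (d in doms) for (r in seq_len(n_per)) {
    i <- i + 1L
    w <- rep((1 - dominant_weight) / 4, 5)
    w[labs == d] <- dominant_weight
    profiles[[i]] <- ground_truth_profile(sprintf("arch_%s_%02d", d, r), w)
    arch[i] <- d
  }
  names(arch) <- vapply(profiles, function(p) p$protein, character(1))
  list(profiles = profiles, archetype = arch)
}

# tiny annotation table: term_perfect annotates exactly `cluster`,
# term_all annotates the whole universe, term_half an overlapping mix
toy_annotation <- function(cluster, universe) {
  rbind(
    data.frame(gene = cluster, term = "GO:PERFECT", name = "perfect match",
               category = "biological_process"),
    data.frame(gene = universe, term = "GO:ALL", name = "everything",
               category = "biological_process"),
    data.frame(gene = universe[seq(1, length(universe), by = 2)],
               term = "GO:HALF", name = "every other gene",
               category = "molecular_function"))
}

# ground-truth dominant compartment per protein, named by protein id
dominant_map <- function(profiles) {
  stats::setNames(vapply(profiles, function(p) p$dominant, character(1)),
                  vapply(profiles, function(p) p$protein, character(1)))
}

# argmax compartment of each row of a normalized matrix
argmax_compartment <- function(mat) {
  stats::setNames(
    sub("_.*", "", colnames(mat)[apply(mat, 1L, which.max)]),
    rownames(mat))
}
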