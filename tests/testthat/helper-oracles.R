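# Independent brute-force oracles and small fixture builders used across
# the test files. Each oracle is deliberately written in the most naive
# way possible, sharing no code with the implementation it checks.

# Per-base oracle for exon flattening: the set of covered bases, and the
# per-base "boundary signature" (which input exons cover each base).
oracle_base_map <- function(exons) {
  bases <- sort(unique(unlist(
    mapply(function(s, e) seq(s, e - 1), exons$start, exons$end,
           SIMPLIFY = FALSE))))
  sig <- vapply(bases, function(b) {
    paste(which(exons$start <= b & b < exons$end), collapse = ",")
  }, character(1))
  list(bases = bases, sig = sig)
}

# Naive median-of-ratios size factors.
oracle_size_factors <- function(Y) {
  gm <- apply(Y, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(gm) & gm > 0
  apply(Y, 2, function(col) stats::median(col[ok] / gm[ok]))
}

# Naive full running-sum enrichment score: walk every gene position.
oracle_es <- function(scores, member_idx, weight_exp = 1) {
  ord <- order(scores, decreasing = TRUE)
  is_hit <- seq_along(scores)[ord] %in% member_idx
  N <- length(scores)
  NH <- sum(is_hit)
  NR <- sum(abs(scores[ord][is_hit])^weight_exp)
  running <- 0
  best <- -Inf
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      running <- running +
        (if (NR > 0) abs(scores[ord][i])^weight_exp / NR else 1 / NH)
    } else {
      running <- running - 1 / (N - NH)
    }
    best <- max(best, running)
  }
  best
}

# Naive per-gene rank-based integration (Eq-by-eq transcription).
oracle_rank_integrate <- function(de, ds, alpha) {
  g_de <- rank(de, ties.method = "average")
  g_ds <- rank(ds, ties.method = "average")
  out <- numeric(length(de))
  for (g in seq_along(de)) {
    num <- alpha * g_de[g] * de[g] + (1 - alpha) * g_ds[g] * ds[g]
    den <- alpha * g_de[g] + (1 - alpha) * g_ds[g]
    out[g] <- num / den
  }
  out
}

# A tiny deterministic count_data fixture: 2 genes x {3,2} sub-exons x 4
# samples, two groups.
toy_count_data <- function() {
  X <- rbind(
    c(10, 12, 30, 28),   # gene_a subexon 1
    c(5, 6, 15, 14),     # gene_a subexon 2
    c(0, 1, 2, 1),       # gene_a subexon 3
    c(40, 38, 41, 39),   # gene_b subexon 1
    c(20, 22, 19, 21))   # gene_b subexon 2
  colnames(X) <- paste0("s", 1:4)
  count_data(X, gene_id = c(rep("gene_a", 3), rep("gene_b", 2)),
             subexon_index = c(1:3, 1:2),
             groups = c("case", "case", "control", "control"),
             size_factors = rep(1, 4))
}

# Random NB/multinomial count_data with no planted effects.
random_null_cd <- function(n_genes = 50, m = 3, seed = 1, phi = 0.1) {
  sim <- simulate_dataset(sim_config(
    n_genes = n_genes, m_a = m, m_b = m, phi = phi, seed = seed,
    subexons_per_gene = c(1, 5)))
  sim$counts
}

expect_scores_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unname(a), unname(b), tolerance = tol)
}
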