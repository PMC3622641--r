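test_that("splicing estimates are degenerate for single-sub-exon genes", {
  X <- matrix(c(10, 20, 30), nrow = 1)
  est <- estimate_splicing(X, Y = c(10, 20, 30))
  expect_equal(est$p_hat, 1)
  expect_equal(est$var_p, 0)
})

test_that("identical fraction vectors give zero empirical variance and zero score", {
  # fractions (0.5, 0.3, 0.2) in every sample of both groups
  base <- c(0.5, 0.3, 0.2)
  X <- outer(base, c(100, 200, 150, 250))
  est_a <- estimate_splicing(X[, 1:2], colSums(X[, 1:2]))
  est_b <- estimate_splicing(X[, 3:4], colSums(X[, 3:4]))
  expect_equal(est_a$p_hat, base)
  expect_equal(sum(est_a$p_hat), 1, tolerance = 1e-9)
  res <- ds_score(est_a, est_b)
  expect_equal(res$score, 0)
  expect_equal(res$flag, "ok")
})

test_that("DS score reproduces the defining average", {
  # two sub-exons with standardized squared differences 4 and 1
  est_a <- structure(list(p_hat = c(0.8, 0.2), var_p = c(0.005, 0.02),
                          gene = c(1L, 1L), undefined = c(FALSE, FALSE),
                          n_subexons = c(2L, 2L)), class = "group_splicing")
  est_b <- structure(list(p_hat = c(0.6, 0.4), var_p = c(0.005, 0.02),
                          gene = c(1L, 1L), undefined = c(FALSE, FALSE),
                          n_subexons = c(2L, 2L)), class = "group_splicing")
  res <- ds_score(est_a, est_b, eps = 0)
  expect_equal(res$score, mean(c(0.2^2 / 0.01, 0.2^2 / 0.04)))
  expect_equal(res$score, 2.5)
})

test_that("fractions sum to one within every gene and group", {
  cd <- random_null_cd(n_genes = 40, m = 3, seed = 13)
  for (g in levels(cd$groups)) {
    j <- cd$groups == g
    est <- splicegsea:::splicing_estimates(
      cd$X[, j, drop = FALSE], as.integer(cd$gene),
      cd$Y[, j, drop = FALSE], cd$size_factors[j])
    sums <- tapply(est$p_hat, est$gene, sum)
    ok <- !tapply(est$undefined, est$gene, any)
    expect_true(all(abs(sums[ok] - 1) < 1e-9))
  }
})

test_that("vectorized estimates equal the per-gene estimator", {
  cd <- random_null_cd(n_genes = 30, m = 4, seed = 17)
  j <- cd$groups == "A"
  est <- splicegsea:::splicing_estimates(
    cd$X[, j, drop = FALSE], as.integer(cd$gene),
    cd$Y[, j, drop = FALSE], cd$size_factors[j])
  for (g in sample(levels(cd$gene), 10)) {
    rows <- as.character(cd$gene) == g
    single <- estimate_splicing(cd$X[rows, j, drop = FALSE],
                                cd$Y[g, j], cd$size_factors[j])
    expect_equal(unname(est$p_hat[rows]), unname(single$p_hat),
                 tolerance = 1e-12)
    expect_equal(unname(est$var_p[rows]), unname(single$var_p),
                 tolerance = 1e-12)
  }
})

test_that("DS scores are non-negative, symmetric, and flag degenerate genes", {
  cd <- random_null_cd(n_genes = 60, m = 3, seed = 19)
  det <- compute_ds_scores(cd, details = TRUE)
  expect_true(all(det$score >= 0))
  expect_true(all(det$score[det$flag == "single-subexon"] == 0))
  swapped <- factor(ifelse(cd$groups == "A", "B", "A"), levels = c("B", "A"))
  expect_scores_equal(compute_ds_scores(cd, swapped),
                      compute_ds_scores(cd), tol = 1e-12)
})

test_that("all-zero totals in a group flag the gene DS-undefined", {
  X <- rbind(c(0, 0, 5, 7), c(0, 0, 3, 2))
  cd <- count_data(X, c("g1", "g1"), 1:2, c("a", "a", "b", "b"),
                   size_factors = rep(1, 4))
  det <- compute_ds_scores(cd, details = TRUE)
  expect_equal(det$flag, "DS-undefined")
  expect_equal(det$score, 0)
})

test_that("proportions are recovered within 3 SE at deep counts", {
  set.seed(23)
  base <- c(0.5, 0.3, 0.2)
  m <- 10
  Y <- rnbinom(m, mu = 5000, size = 20)
  X <- vapply(Y, function(y) rmultinom(1, y, base)[, 1], numeric(3))
  est <- estimate_splicing(X, Y)
  for (i in 1:3)
    expect_lt(abs(est$p_hat[i] - base[i]), 3 * sqrt(est$var_p[i]))
})

test_that("pure expression scaling leaves DS scores at their null level", {
  # multiply all sub-exon counts of half the genes by a per-sample
  # constant in group B: proportions unchanged, so mean DS of scaled
  # genes must not exceed the unscaled null mean significantly
  sim <- simulate_dataset(sim_config(n_genes = 500, m_a = 6, m_b = 6,
                                     phi = 0.05, seed = 31,
                                     subexons_per_gene = c(2, 6)))
  cd <- sim$counts
  scaled <- seq_len(250)
  rows <- as.integer(cd$gene) %in% scaled
  fold <- rep(1, ncol(cd$X))
  fold[cd$groups == "B"] <- 3
  X2 <- cd$X
  X2[rows, ] <- t(t(X2[rows, ]) * fold)  # deterministic scaling
  cd2 <- count_data(round(X2), as.character(cd$gene), cd$subexon_index,
                    cd$groups, size_factors = cd$size_factors)
  s <- compute_ds_scores(cd2)
  tt <- t.test(s[scaled], s[-scaled], alternative = "greater")
  expect_gt(tt$p.value, 0.01)
})
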