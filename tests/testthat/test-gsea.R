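test_that("enrichment score follows the running sum on worked examples", {
  scores <- c(a = 3, b = 2, c = 1)
  # single top gene: running sum (1, 0.5, 0)
  expect_equal(enrichment_score(scores, "a"), 1)
  # all hit mass before any miss: ES = 1
  scores2 <- c(g1 = 5, g2 = 4, g3 = 0, g4 = 0)
  expect_equal(enrichment_score(scores2, c("g1", "g2")), 1)
  # errors
  expect_error(enrichment_score(scores, "zz"), "no overlap")
  expect_error(enrichment_score(scores, c("a", "b", "c")), "every scored gene")
})

test_that("enrichment score equals the brute-force oracle on random instances", {
  set.seed(33)
  for (w in c(0, 1)) {
    for (rep in 1:100) {
      n <- sample(20:120, 1)
      scores <- setNames(rgamma(n, 0.8), paste0("g", seq_len(n)))
      scores[sample(n, floor(n / 5))] <- 0  # exercise zero-score ties
      idx <- sample(n, sample(2:(n - 2), 1))
      expect_equal(enrichment_score(scores, idx, weight_exp = w),
                   oracle_es(scores, idx, weight_exp = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("label permutations preserve group sizes and are reproducible", {
  groups <- factor(rep(c("A", "B"), each = 6))
  p1 <- permute_labels(groups, 50, seed = 42)
  p2 <- permute_labels(groups, 50, seed = 42)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(12L, 50L))
  expect_true(all(colSums(p1) == 6))
  # small design: all distinct assignments enumerated with a warning
  small <- factor(rep(c("A", "B"), each = 3))
  expect_warning(pe <- permute_labels(small, 100), "distinct")
  expect_equal(ncol(pe), choose(6, 3))
  expect_equal(anyDuplicated(t(pe)), 0L)
})

test_that("permutation scoring is deterministic given a seed", {
  cd <- random_null_cd(n_genes = 30, m = 4, seed = 3)
  perm <- permute_labels(cd$groups, 8, seed = 5)
  a <- score_permutations(cd, perm)
  b <- score_permutations(cd, perm)
  expect_identical(a, b)
})

test_that("empirical p-values use the add-one estimator", {
  obs <- c(s1 = 2)
  perm <- matrix(runif(999), 1)  # everything below 2
  res <- gsea_significance(obs, perm)
  expect_equal(res$p_emp, 1 / 1000)
  # observed at the permutation median
  perm2 <- matrix(seq(0.001, 2, length.out = 999), 1)
  res2 <- gsea_significance(c(s1 = stats::median(perm2)), perm2)
  expect_equal(res2$p_emp, 0.5, tolerance = 0.01)
})

test_that("NES and FDR match a hand-computed pooled ratio on a toy example", {
  obs <- c(s1 = 0.9, s2 = 0.5, s3 = 0.2)
  perm <- rbind(c(0.3, 0.45, 0.15), c(0.25, 0.5, 0.75), c(0.1, 0.2, 0.3))
  res <- gsea_significance(obs, perm)
  mean_pos <- rowMeans(perm)
  expect_equal(res$NES, obs / mean_pos, ignore_attr = TRUE)
  nes <- obs / mean_pos
  pooled <- as.numeric(perm / mean_pos)
  raw <- sapply(nes, function(v) mean(pooled >= v) / mean(nes >= v))
  raw <- pmin(raw, 1)
  o <- order(nes, decreasing = TRUE)
  raw[o] <- rev(cummin(rev(raw[o])))
  expect_equal(res$FDR, unname(raw))
  # FDR monotone non-increasing in NES
  expect_true(all(diff(res$FDR[order(res$NES, decreasing = TRUE)]) >= 0))
})

test_that("GMT files round-trip and agree with an independent parser", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("first", "second"))
  re <- read_gmt(path)
  expect_equal(re$alpha, sets$alpha)
  expect_equal(attr(re, "descriptions")[["beta"]], "second")
  ref <- fgsea::gmtPathways(path)
  expect_equal(lapply(re, sort), lapply(ref, sort), ignore_attr = TRUE)
  # malformed line
  writeLines(c("only_name\tdesc"), path)
  expect_error(read_gmt(path), "fewer than 3")
})

test_that("run_gsea books permutations correctly and skips out-of-bound sets", {
  cd <- random_null_cd(n_genes = 40, m = 3, seed = 44)
  sets <- list(small = levels(cd$gene)[1:2],
               fine = levels(cd$gene)[3:12],
               huge = levels(cd$gene))
  # more permutations than distinct assignments: enumerate all 20
  expect_warning(
    run <- run_gsea(cd, sets, alphas = c(0, 0.5, 1), n_perm = 100,
                    seed = 1, min_size = 5, max_size = 30),
    "distinct")
  expect_setequal(run$skipped_sets, c("small", "huge"))
  expect_equal(unique(run$results$set_name), "fine")
  expect_equal(run$n_perm, choose(6, 3))
  # duplicate alphas are deduplicated with a warning
  expect_warning(
    run2 <- run_gsea(cd, sets["fine"], alphas = c(0.5, 0.5), n_perm = 5,
                     seed = 1, min_size = 5), "duplicate")
  expect_equal(run2$alphas, 0.5)
})

test_that("saturation curve is cumulative, monotone, and validates weights", {
  cd <- random_null_cd(n_genes = 50, m = 3, seed = 55)
  sets <- lapply(1:6, function(i) sample(levels(cd$gene), 10))
  names(sets) <- paste0("set", 1:6)
  suppressWarnings(
    run <- run_gsea(cd, sets, alphas = c(0, 0.5, 1), n_perm = 15, seed = 2))
  scan <- weight_scan(run, fdr_cutoff = 0.9)
  sat <- saturation_analysis(scan, c(1, 0, 0.5))
  expect_equal(sat$n_weights, 1:3)
  expect_true(all(diff(sat$cumulative_sets) >= 0))
  # one weight: curve starts at that weight's own count
  expect_equal(sat$cumulative_sets[1],
               length(scan$significant[["linear|1"]]))
  expect_error(saturation_analysis(scan, c(1, 0.25)), "not part")
})
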