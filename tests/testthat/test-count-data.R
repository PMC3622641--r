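test_that("count_data derives gene totals and maps groups by first occurrence", {
  cd <- toy_count_data()
  expect_equal(dim(cd$Y), c(2L, 4L))
  # Y is exactly the within-gene sub-exon sum
  expect_equal(unname(cd$Y["gene_a", ]), unname(colSums(cd$X[1:3, ])))
  expect_equal(unname(cd$Y["gene_b", ]), unname(colSums(cd$X[4:5, ])))
  # "case" appears first, so it is the first level (internal group A)
  expect_equal(levels(cd$groups), c("case", "control"))
})

test_that("load_counts round-trips a written table and validates inputs", {
  cd <- toy_count_data()
  dir <- withr::local_tempdir()
  counts_path <- file.path(dir, "counts.tsv")
  ph_path <- file.path(dir, "pheno.tsv")
  write.table(data.frame(gene_id = as.character(cd$gene),
                         subexon_index = cd$subexon_index, cd$X,
                         check.names = FALSE),
              counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = cd$samples,
                         group = as.character(cd$groups)),
              ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
  re <- load_counts(counts_path, ph_path)
  expect_equal(re$X, cd$X)
  expect_equal(re$Y, cd$Y)
  expect_equal(as.character(re$groups), as.character(cd$groups))

  # phenotype missing one sample -> hard error
  write.table(data.frame(sample = cd$samples[-1],
                         group = as.character(cd$groups)[-1]),
              ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_counts(counts_path, ph_path), "missing from phenotype")
})

test_that("invalid count matrices are rejected", {
  X <- matrix(1:4, 2)
  expect_error(count_data(rbind(X, X), rep("g", 4), c(1, 2, 1, 2),
                          c("a", "b")), "duplicated")
  expect_error(count_data(-X, c("g", "g"), 1:2, c("a", "b")), "negative")
  expect_error(count_data(X + 0.5, c("g", "g"), 1:2, c("a", "b")),
               "non-integer")
  expect_error(count_data(X, c("g", "g"), 1:2, c("a", "a")), "two groups")
  expect_error(count_data(matrix(1:6, 2), c("g", "g"), 1:2,
                          c("a", "b", "c")), "two groups")
})

test_that("size factors follow median-of-ratios closed forms", {
  Y1 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  expect_equal(estimate_size_factors(Y1), c(1 / sqrt(2), sqrt(2)))
  Y2 <- matrix(rep(c(5, 9, 14), 3), ncol = 3)
  expect_equal(estimate_size_factors(Y2), c(1, 1, 1))
})

test_that("size factors agree with a brute-force median-of-ratios oracle", {
  set.seed(11)
  # odd gene count: the median is a data point, so the ratio-space and
  # log-space medians coincide exactly
  Y <- matrix(rnbinom(51 * 4, mu = 100, size = 5), 51, 4)
  Y[Y == 0] <- 1
  expect_equal(estimate_size_factors(Y), oracle_size_factors(Y),
               tolerance = 1e-12)
  # even gene count: agreement up to the even-n median interpolation
  expect_equal(estimate_size_factors(Y[-1, ]),
               oracle_size_factors(Y[-1, ]), tolerance = 1e-3)
})

test_that("all-zero-reference matrices error with a fallback suggestion", {
  Y <- matrix(c(0, 5, 5, 0, 3, 0), ncol = 3)  # every gene hits a zero
  expect_error(estimate_size_factors(Y), "poscounts")
  s <- estimate_size_factors(Y, method = "poscounts")
  expect_true(all(s > 0))
})

test_that("size-factor product is invariant under sample relabelling", {
  set.seed(3)
  Y <- matrix(rnbinom(40 * 5, mu = 80, size = 10) + 1, 40, 5)
  s <- estimate_size_factors(Y)
  perm <- sample(5)
  s2 <- estimate_size_factors(Y[, perm])
  expect_equal(prod(s2), prod(s), tolerance = 1e-12)
  expect_equal(s2, s[perm], tolerance = 1e-12)
})

test_that("filtering removes low genes but keeps all reads in gene totals", {
  cd <- toy_count_data()
  # identity at zero thresholds
  same <- filter_low_expression(cd, 0, 0)
  expect_equal(same$X, cd$X)
  expect_true(all(same$ds_use))

  # add an all-zero gene: removed at threshold 1
  X <- rbind(cd$X, gene_z = rep(0, 4))
  cd2 <- count_data(X, c(as.character(cd$gene), "gene_z"),
                    c(cd$subexon_index, 1), cd$groups,
                    size_factors = rep(1, 4))
  f <- filter_low_expression(cd2, min_gene_total = 1, min_subexon_total = 5)
  expect_false("gene_z" %in% levels(f$gene))
  # the sparse third sub-exon of gene_a (total 4) leaves DS only
  expect_equal(unname(f$ds_use), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # gene totals unchanged for surviving genes (Y conservation)
  expect_equal(f$Y, cd$Y)

  # surviving rows equal brute-force application of the two rules
  gene_tot <- tapply(rowSums(cd2$X), as.character(cd2$gene), sum)
  keep_brute <- gene_tot[as.character(cd2$gene)] >= 1
  expect_equal(nrow(f$X), sum(keep_brute))
  expect_error(filter_low_expression(cd2, min_gene_total = 1e9),
               "every gene")
})
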