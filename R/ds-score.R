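# Differential splicing: sub-exon read-count fractions per group, their
# variances, and the per-gene DS score.

# Vectorized group-level splicing estimates over many genes at once.
# X: sub-exon x sample counts for ONE group; gi: integer gene index per row
# (1..G); Y: G x sample gene totals for the same group; s: size factors.
# Samples with Y_j = 0 for a gene contribute nothing to that gene's
# estimates (their fractions are undefined).
splicing_estimates <- function(X, gi, Y, s) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  m <- ncol(X)
  if (m < 2L)
    stopf("each group needs at least 2 replicates for permutation-based analysis")
  pos <- Y > 0
  n_c <- rowSums(pos)                    # contributing samples per gene
  Tg <- rowSums(Y)
  Ti <- rowSums(X)
  undefined <- Tg[gi] == 0
  p <- ifelse(undefined, NA_real_, Ti / Tg[gi])

  # empirical between-sample variance of per-sample fractions f_ij
  Yg <- Y[gi, , drop = FALSE]
  f <- X / ifelse(Yg > 0, Yg, NA)
  nc_r <- n_c[gi]
  sum_f <- rowSums(f, na.rm = TRUE)
  sum_f2 <- rowSums(f * f, na.rm = TRUE)
  mean_f <- ifelse(nc_r > 0, sum_f / nc_r, NA_real_)
  var_f <- ifelse(nc_r > 1, pmax(0, (sum_f2 - nc_r * mean_f^2) / (nc_r - 1)), 0)
  v_emp <- ifelse(nc_r > 0, var_f / nc_r, NA_real_)

  # NB delta-method variance of the pooled fraction, totals treated as
  # fixed: Var(p) = Tg^-2 * sum_j (mu_ij + phi_i mu_ij^2), mu_ij = p * Y_j,
  # with a per-sub-exon moment dispersion from depth-normalized counts
  Xn <- sweep(X, 2, s, "/")
  # zero rows where Y == 0 contribute X = 0, so plain row sums are the
  # sums over contributing samples
  sum_xn <- rowSums(Xn)
  sum_xn2 <- rowSums(Xn * Xn)
  mu <- ifelse(nc_r > 0, sum_xn / nc_r, NA_real_)
  vv <- ifelse(nc_r > 1, pmax(0, (sum_xn2 - nc_r * mu^2) / (nc_r - 1)), 0)
  inv_s_bar <- as.numeric(pos %*% (1 / s))[gi] / nc_r
  phi <- ifelse(!is.na(mu) & mu > 0,
                pmax(0, (vv - mu * inv_s_bar) / mu^2), 0)
  sumY2 <- rowSums(Y * Y)
  v_mod <- p / Tg[gi] + phi * p^2 * sumY2[gi] / Tg[gi]^2
  var_p <- pmax(v_mod, v_emp)

  # degenerate single-sub-exon genes: the fraction is identically 1
  n_sub <- tabulate(gi, nbins = nrow(Y))
  single <- n_sub[gi] == 1L
  var_p[single & !undefined] <- 0

  structure(list(p_hat = p, var_p = var_p, gene = gi,
                 undefined = undefined, n_subexons = n_sub[gi]),
            class = "group_splicing")
}

#' Per-group sub-exon fraction estimates for one gene
#'
#' Estimates, within one sample group, the expected read-count fraction of
#' each sub-exon of a gene, \eqn{\hat p_i = \sum_j X_{ij} / \sum_j Y_j}
#' (the pooled fraction, a \eqn{Y_j}-weighted mean of the per-sample
#' fractions \eqn{f_{ij} = X_{ij}/Y_j}), together with a variance estimate
#' \eqn{\hat V(\hat p_i)}. The variance is the larger of (a) a delta-method
#' variance under the NB sub-exon count model \eqn{\sigma^2 = \mu +
#' \phi\mu^2} and (b) the empirical between-sample variance of the
#' \eqn{f_{ij}} divided by the number of contributing samples; taking the
#' maximum guards the score denominator against under-dispersion
#' artifacts. Samples with \eqn{Y_j = 0} are dropped from the estimates.
#'
#' @param X sub-exon x sample count matrix of one gene, samples of one
#'   group.
#' @param Y per-sample gene totals (length `ncol(X)`).
#' @param s per-sample size factors (default all 1).
#' @return object of class `group_splicing`: list with `p_hat`, `var_p`
#'   (per sub-exon), `undefined` (TRUE when every sample has \eqn{Y_j=0}),
#'   `n_subexons`.
#' @export
estimate_splicing <- function(X, Y, s = rep(1, length(Y))) {
  X <- as.matrix(X)
  stopifnot(length(Y) == ncol(X))
  splicing_estimates(X, rep(1L, nrow(X)), matrix(Y, nrow = 1), s)
}

#' Differential splicing score
#'
#' Average, over the sub-exons of a gene, of the squared difference in
#' group fraction estimates over the sum of their variances:
#' \deqn{S_{DS}(g) = \frac{1}{N^{(g)}} \sum_{i=1}^{N^{(g)}}
#'   \frac{(\hat p_{i,A} - \hat p_{i,B})^2}
#'        {\hat V(\hat p_{i,A}) + \hat V(\hat p_{i,B})}.}
#' Genes with a single (usable) sub-exon have no splicing signal and score
#' 0 with flag `"single-subexon"`; genes with no reads in one group are
#' flagged `"DS-undefined"` and score 0.
#'
#' @param est_a,est_b `group_splicing` estimates on the identical sub-exon
#'   index (same genes, same rows).
#' @param eps denominator stabilizer (default 1e-8).
#' @param n_genes number of genes covered by the gene index of the
#'   estimates (defaults to the largest index present).
#' @return data.frame with columns `gene` (integer index),
#'   `n_subexons_used`, `score`, `flag` (`ok`, `single-subexon`,
#'   `DS-undefined`).
#' @export
ds_score <- function(est_a, est_b, eps = 1e-8,
                     n_genes = max(est_a$gene, 0L)) {
  if (length(est_a$p_hat) != length(est_b$p_hat) ||
      !identical(est_a$gene, est_b$gene))
    stopf("group estimates are on different sub-exon indices")
  gi <- est_a$gene
  undef_row <- est_a$undefined | est_b$undefined
  term <- (est_a$p_hat - est_b$p_hat)^2 /
    (est_a$var_p + est_b$var_p + eps)
  term[undef_row] <- NA_real_

  n_used <- tabulate(gi, nbins = n_genes)
  undef_gene <- as.logical(tabulate(gi[undef_row], nbins = n_genes) > 0)
  sum_term <- rep(0, n_genes)
  ok_row <- !is.na(term)
  if (any(ok_row))
    sum_term[sort(unique(gi[ok_row]))] <-
      rowsum(term[ok_row], gi[ok_row], reorder = TRUE)[, 1]
  score <- ifelse(n_used > 0 & !undef_gene, sum_term / n_used, 0)
  score[n_used <= 1L] <- 0
  flag <- rep("ok", n_genes)
  flag[n_used <= 1L] <- "single-subexon"
  flag[undef_gene] <- "DS-undefined"
  score[undef_gene] <- 0
  data.frame(gene = seq_len(n_genes), n_subexons_used = n_used,
             score = score, flag = flag, stringsAsFactors = FALSE)
}

#' Compute per-gene DS scores for a dataset
#'
#' Splits the sub-exon counts of a [count_data] object by group, estimates
#' each group's sub-exon fractions, and averages the per-sub-exon
#' standardized squared differences into the per-gene DS score. Sub-exons
#' excluded by [filter_low_expression()] (`ds_use = FALSE`) enter neither
#' the numerator nor the \eqn{N^{(g)}} divisor; gene totals keep all
#' reads.
#'
#' @inheritParams compute_de_scores
#' @param details if `TRUE` return the full per-gene data.frame (scores
#'   and flags) instead of the score vector.
#' @return named numeric vector of DS scores (or data.frame when
#'   `details = TRUE`).
#' @export
compute_ds_scores <- function(cd, groups = cd$groups, eps = 1e-8,
                              details = FALSE) {
  use <- cd$ds_use
  X <- cd$X[use, , drop = FALSE]
  gi <- as.integer(cd$gene)[use]
  ga <- groups == levels(groups)[1]
  s <- cd$size_factors
  est_a <- splicing_estimates(X[, ga, drop = FALSE], gi,
                              cd$Y[, ga, drop = FALSE], s[ga])
  est_b <- splicing_estimates(X[, !ga, drop = FALSE], gi,
                              cd$Y[, !ga, drop = FALSE], s[!ga])
  res <- ds_score(est_a, est_b, eps, n_genes = nlevels(cd$gene))
  res$gene_id <- levels(cd$gene)
  if (details) return(res)
  stats::setNames(res$score, res$gene_id)
}
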