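#' Per-group negative-binomial expression estimates
#'
#' Fits the gene-level count model within one group of samples. Counts are
#' modelled as \eqn{Y_j \sim NB(\mu_j, \sigma_j^2)} with
#' \eqn{\mu_j = s_j q} and \eqn{\sigma^2 = \mu + \phi \mu^2}; each group is
#' estimated on its own samples only (no information sharing across
#' groups), which keeps the class-label permutation scheme honest.
#'
#' Estimators (per gene): \eqn{\hat q} is the mean of depth-normalized
#' counts \eqn{Y_j/s_j}; the dispersion \eqn{\hat\phi} is a method-of-
#' moments estimate on normalized counts, floored at 0; the variance of
#' \eqn{\hat q} is propagated from the NB variance,
#' \eqn{\hat V(\hat q) = m^{-2} \sum_j (\hat q/s_j + \hat\phi \hat q^2)}.
#'
#' @param Y gene x sample count matrix for the samples of one group
#'   (at least 2 columns).
#' @param s size factors of those samples.
#' @return object of class `group_expression`: list with per-gene numeric
#'   vectors `q_hat`, `var_q`, `phi_hat`.
#' @export
estimate_group <- function(Y, s) {
  Y <- as.matrix(Y)
  m <- ncol(Y)
  if (m < 2L)
    stopf("each group needs at least 2 replicates for permutation-based analysis")
  if (length(s) != m || any(s <= 0))
    stopf("size factors must be positive, one per group sample")
  Yn <- sweep(Y, 2, s, "/")
  q_hat <- rowMeans(Yn)
  v_hat <- row_vars(Yn)
  phi_hat <- ifelse(q_hat > 0,
                    pmax(0, (v_hat - q_hat * mean(1 / s)) / q_hat^2), 0)
  var_q <- (q_hat * sum(1 / s) + m * phi_hat * q_hat^2) / m^2
  structure(list(q_hat = q_hat, var_q = var_q, phi_hat = phi_hat),
            class = "group_expression")
}

#' Differential expression score
#'
#' Squared difference of the two groups' expression estimates over the sum
#' of their variance estimates:
#' \deqn{S_{DE}(g) = \frac{(\hat q_{g,A} - \hat q_{g,B})^2}
#'   {\hat V(q_{g,A}) + \hat V(q_{g,B})}.}
#' The score is non-negative and direction-free by construction (squaring
#' discards the sign, so up- and down-regulation contribute alike). Genes
#' with zero counts in both groups score 0.
#'
#' @param est_a,est_b `group_expression` estimates for the two groups, on
#'   the same gene index.
#' @param eps small constant added to the variance sum so that genes that
#'   are flat in both groups do not produce 0/0 (default 1e-8).
#' @return numeric vector of per-gene DE scores.
#' @export
de_score <- function(est_a, est_b, eps = 1e-8) {
  if (length(est_a$q_hat) != length(est_b$q_hat))
    stopf("group estimates are on different gene indices")
  s <- (est_a$q_hat - est_b$q_hat)^2 / (est_a$var_q + est_b$var_q + eps)
  s[est_a$q_hat == 0 & est_b$q_hat == 0] <- 0
  s
}

#' Compute per-gene DE scores for a dataset
#'
#' Convenience wrapper: splits the gene totals of a [count_data] object by
#' group label, estimates each group with [estimate_group()] (size factors
#' are dataset-wide and held fixed), and returns [de_score()].
#'
#' @param cd a [count_data] object.
#' @param groups group factor to use (defaults to `cd$groups`); passing a
#'   permuted labelling computes a permutation score.
#' @param eps see [de_score()].
#' @return named numeric vector of DE scores, one per gene.
#' @export
compute_de_scores <- function(cd, groups = cd$groups, eps = 1e-8) {
  ga <- groups == levels(groups)[1]
  est_a <- estimate_group(cd$Y[, ga, drop = FALSE], cd$size_factors[ga])
  est_b <- estimate_group(cd$Y[, !ga, drop = FALSE], cd$size_factors[!ga])
  stats::setNames(de_score(est_a, est_b, eps), rownames(cd$Y))
}
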