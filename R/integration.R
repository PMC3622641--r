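#' Bundle observed and permutation scores
#'
#' @param obs named numeric vector of observed per-gene scores (DE or DS).
#' @param perm gene x permutation matrix of the same statistic computed
#'   under permuted class labels.
#' @param kind `"DE"` or `"DS"`.
#' @return object of class `score_set`.
#' @export
score_set <- function(obs, perm, kind = c("DE", "DS")) {
  kind <- match.arg(kind)
  perm <- as.matrix(perm)
  if (length(obs) != nrow(perm))
    stopf("observed vector and permutation matrix disagree on gene count")
  if (ncol(perm) < 1L) stopf("permutation matrix has no columns")
  if (any(obs < 0) || any(perm < 0))
    stopf("%s scores must be non-negative", kind)
  structure(list(obs = obs, perm = perm, kind = kind), class = "score_set")
}

#' Normalize scores by the mean permutation score
#'
#' Divides each gene's observed score and every one of its permutation
#' scores by the gene's mean permutation score \eqn{\bar T^{(g)}}, putting
#' DE and DS scores on a common empirical-background scale before
#' integration. After normalization every gene's permutation-score mean is
#' exactly 1. Genes whose permutation mean is 0 carry no signal under any
#' labelling; their normalized scores are defined as 0 and the genes are
#' retained (flagged in attribute `"zero_background"`), so gene-set sizes
#' do not depend on the integration weight.
#'
#' @param ss a [score_set()].
#' @return normalized `score_set` with attribute `zero_background`
#'   (logical per gene).
#' @export
normalize_scores <- function(ss) {
  stopifnot(inherits(ss, "score_set"))
  tbar <- rowMeans(ss$perm)
  zero <- tbar == 0
  div <- ifelse(zero, 1, tbar)
  out <- ss
  out$obs <- ifelse(zero, 0, ss$obs / div)
  out$perm <- ss$perm / div
  out$perm[zero, ] <- 0
  attr(out, "zero_background") <- zero
  out
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stopf("alpha must be a single number in [0, 1], got %s",
          paste(alpha, collapse = ","))
  alpha
}

#' Linear integration of normalized DE and DS scores
#'
#' Per-gene weighted sum
#' \eqn{S(g) = \alpha S_{DE,norm}(g) + (1-\alpha) S_{DS,norm}(g)},
#' applied identically to the observed scores and to every permutation
#' column. The extremes are degenerate by construction: \eqn{\alpha = 1}
#' returns the normalized DE scores exactly and \eqn{\alpha = 0} the
#' normalized DS scores.
#'
#' @param de_norm,ds_norm normalized [score_set()]s (see
#'   [normalize_scores()]) on the same gene index.
#' @param alpha weight in `[0, 1]` balancing DE against DS.
#' @return object of class `integrated_scores`: list with `obs`, `perm`,
#'   `alpha`, `strategy`.
#' @export
integrate_linear <- function(de_norm, ds_norm, alpha) {
  check_alpha(alpha)
  check_pair(de_norm, ds_norm)
  if (alpha == 1) {
    obs <- de_norm$obs; perm <- de_norm$perm
  } else if (alpha == 0) {
    obs <- ds_norm$obs; perm <- ds_norm$perm
  } else {
    obs <- alpha * de_norm$obs + (1 - alpha) * ds_norm$obs
    perm <- alpha * de_norm$perm + (1 - alpha) * ds_norm$perm
  }
  structure(list(obs = obs, perm = perm, alpha = alpha,
                 strategy = "linear"), class = "integrated_scores")
}

rank_combine <- function(de, ds, g_de, g_ds, alpha) {
  w_de <- alpha * g_de
  w_ds <- (1 - alpha) * g_ds
  (w_de * de + w_ds * ds) / (w_de + w_ds)
}

#' Rank-based integration of normalized DE and DS scores
#'
#' Data-adapted weighting: DE and DS scores are ranked in ascending order
#' (mid-ranks on ties), and the integrated score is the rank-weighted
#' combination
#' \deqn{S(g) = \frac{\alpha\,\gamma_{DE}(g)\,S_{DE,norm}(g) +
#'   (1-\alpha)\,\gamma_{DS}(g)\,S_{DS,norm}(g)}
#'   {\alpha\,\gamma_{DE}(g) + (1-\alpha)\,\gamma_{DS}(g)},}
#' so the component that is higher-ranked for a gene automatically
#' contributes more, with \eqn{\alpha} as a global tuning knob on top.
#' Two variants differ in how permutation columns are ranked:
#' `"rank-glb"` (global) reuses the observed-data ranks for every
#' permutation column, while `"rank-sp"` (permutation-specific) recomputes
#' the ranks within each permutation column.
#'
#' @inheritParams integrate_linear
#' @param variant `"rank-sp"` or `"rank-glb"`.
#' @return an `integrated_scores` object.
#' @export
integrate_rank <- function(de_norm, ds_norm, alpha,
                           variant = c("rank-sp", "rank-glb")) {
  check_alpha(alpha)
  variant <- match.arg(variant)
  check_pair(de_norm, ds_norm)
  if (alpha == 1) {
    obs <- de_norm$obs; perm <- de_norm$perm
  } else if (alpha == 0) {
    obs <- ds_norm$obs; perm <- ds_norm$perm
  } else {
    g_de <- rank(de_norm$obs, ties.method = "average")
    g_ds <- rank(ds_norm$obs, ties.method = "average")
    obs <- rank_combine(de_norm$obs, ds_norm$obs, g_de, g_ds, alpha)
    P <- ncol(de_norm$perm)
    perm <- matrix(0, nrow(de_norm$perm), P)
    for (k in seq_len(P)) {
      if (variant == "rank-sp") {
        pg_de <- rank(de_norm$perm[, k], ties.method = "average")
        pg_ds <- rank(ds_norm$perm[, k], ties.method = "average")
      } else {
        pg_de <- g_de
        pg_ds <- g_ds
      }
      perm[, k] <- rank_combine(de_norm$perm[, k], ds_norm$perm[, k],
                                pg_de, pg_ds, alpha)
    }
  }
  structure(list(obs = obs, perm = perm, alpha = alpha,
                 strategy = variant), class = "integrated_scores")
}

check_pair <- function(de_norm, ds_norm) {
  stopifnot(inherits(de_norm, "score_set"), inherits(ds_norm, "score_set"))
  if (length(de_norm$obs) != length(ds_norm$obs) ||
      !identical(dim(de_norm$perm), dim(ds_norm$perm)))
    stopf("DE and DS score sets are on different gene/permutation indices")
  invisible(TRUE)
}

#' Integrate by strategy name
#'
#' Dispatches to [integrate_linear()] or [integrate_rank()].
#'
#' @inheritParams integrate_linear
#' @param strategy `"linear"`, `"rank-sp"` or `"rank-glb"`.
#' @return an `integrated_scores` object.
#' @export
integrate_scores <- function(de_norm, ds_norm, alpha,
                             strategy = c("linear", "rank-sp", "rank-glb")) {
  strategy <- match.arg(strategy)
  if (strategy == "linear") integrate_linear(de_norm, ds_norm, alpha)
  else integrate_rank(de_norm, ds_norm, alpha, strategy)
}
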