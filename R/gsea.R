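# Enrichment engine: weighted KS-like running-sum statistic over
# score-ranked genes, class-label-permutation null, empirical p / FDR.

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated (the MSigDB convention).
#'
#' @param path GMT file path (optionally gzipped).
#' @return named list of character vectors with a `"descriptions"`
#'   attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("gene set file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stopf("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stopf("duplicated gene set name: %s", names(sets)[anyDuplicated(names(sets))])
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[`, character(1), 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Enrichment score of one gene set
#'
#' Kolmogorov-Smirnov-like running-sum statistic: genes are sorted by
#' score in decreasing order; walking down the ranking, the running sum
#' increases by \eqn{|S(g)|^{w}/N_R} at member genes (where
#' \eqn{N_R = \sum_{members} |S|^{w}}) and decreases by \eqn{1/(N-N_H)} at
#' non-members. The enrichment score is the maximum of the running sum
#' (one-sided: gene scores are non-negative and direction-free, so only
#' top-of-ranking concentration is rewarded).
#'
#' With `weight_exp = 1` this is the weighted statistic; `weight_exp = 0`
#' gives the classic equal-increment form. If every member has score 0
#' (so \eqn{N_R = 0}), increments fall back to the equal weights
#' \eqn{1/N_H}.
#'
#' @param gene_scores named numeric vector of per-gene scores.
#' @param members character vector of member gene ids (intersected with
#'   the scored genes) or integer indices into `gene_scores`.
#' @param weight_exp exponent on the gene score in the hit increments
#'   (default 1).
#' @return the enrichment score (a single number).
#' @export
enrichment_score <- function(gene_scores, members, weight_exp = 1) {
  idx <- if (is.character(members)) {
    which(names(gene_scores) %in% members)
  } else {
    as.integer(members)
  }
  if (length(idx) == 0L) stopf("gene set has no overlap with scored genes")
  if (length(idx) == length(gene_scores))
    stopf("gene set covers every scored gene; ES is undefined")
  es_for_sets(gene_scores, list(idx), weight_exp)[1]
}

# Core ES computation shared by observed and permutation columns: sort the
# score vector once, then evaluate each set from its member positions only.
# The running sum attains its maximum at a member position, so it is
# enough to evaluate it there: just after the k-th member (at position
# p_k) the sum is cumsum(increments)[k] - (p_k - k)/(N - NH).
es_for_sets <- function(scores, sets_idx, weight_exp = 1) {
  N <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  pos_of <- integer(N)
  pos_of[ord] <- seq_len(N)
  sorted <- scores[ord]
  vapply(sets_idx, function(idx) {
    NH <- length(idx)
    pos <- sort.int(pos_of[idx])
    w <- abs(sorted[pos])^weight_exp
    NR <- sum(w)
    inc <- if (NR > 0) w / NR else rep(1 / NH, NH)
    max(cumsum(inc) - (pos - seq_len(NH)) / (N - NH))
  }, numeric(1))
}

#' Draw class-label permutations
#'
#' Produces `n_perm` relabellings of the samples that preserve the two
#' group sizes (the standard sample-permutation scheme), so every
#' permutation keeps at least two replicates per group whenever the
#' design does. When the design admits fewer distinct assignments than
#' requested, all distinct assignments are enumerated instead (with a
#' warning) and the permutation count shrinks accordingly.
#'
#' @param groups two-level factor of observed group labels.
#' @param n_perm number of permutations requested.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return logical matrix, samples x permutations; `TRUE` marks membership
#'   in the first group.
#' @export
permute_labels <- function(groups, n_perm, seed = NULL) {
  stopifnot(is.factor(groups), nlevels(groups) == 2L)
  M <- length(groups)
  m_a <- sum(groups == levels(groups)[1])
  total <- choose(M, m_a)
  if (total <= n_perm) {
    warnf("only %d distinct label assignments exist; using all of them",
          total)
    cols <- utils::combn(M, m_a)
    out <- matrix(FALSE, M, ncol(cols))
    for (k in seq_len(ncol(cols))) out[cols[, k], k] <- TRUE
    return(out)
  }
  with_seed(seed, {
    out <- matrix(FALSE, M, n_perm)
    for (k in seq_len(n_perm)) out[sample.int(M, m_a), k] <- TRUE
    out
  })
}

#' Compute DE and DS scores under permuted class labels
#'
#' Re-runs the full per-group estimation and scoring for every permuted
#' labelling. Size factors are sample properties independent of the group
#' labels and are held fixed across permutations. The resulting raw
#' permutation score matrices are computed once and reused by every
#' integration strategy and weight.
#'
#' @param cd a [count_data] object.
#' @param perm logical samples x permutations matrix from
#'   [permute_labels()].
#' @param eps denominator stabilizer passed to the score functions.
#' @return list with gene x permutation matrices `de` and `ds`.
#' @export
score_permutations <- function(cd, perm, eps = 1e-8) {
  P <- ncol(perm)
  G <- nlevels(cd$gene)
  de <- matrix(0, G, P, dimnames = list(levels(cd$gene), NULL))
  ds <- matrix(0, G, P, dimnames = list(levels(cd$gene), NULL))
  lv <- levels(cd$groups)
  for (k in seq_len(P)) {
    g <- factor(ifelse(perm[, k], lv[1], lv[2]), levels = lv)
    de[, k] <- compute_de_scores(cd, g, eps)
    ds[, k] <- compute_ds_scores(cd, g, eps)
  }
  list(de = de, ds = ds)
}

#' Empirical significance of enrichment scores
#'
#' Given observed per-set enrichment scores and their label-permutation
#' null, computes for each set: the empirical p-value with the add-one
#' estimator \eqn{p = (1 + \#\{ES_{perm} \ge ES_{obs}\})/(P+1)}; the
#' normalized enrichment score \eqn{NES = ES / \overline{ES}_{perm}^{+}}
#' (mean over the set's positive permutation ES values); and a one-tailed
#' permutation FDR, the ratio of the pooled-permutation tail fraction of
#' NES to the observed tail fraction, clipped to `[0, 1]` and made
#' monotone non-increasing in NES.
#'
#' @param obs_es named numeric vector of observed enrichment scores.
#' @param perm_es sets x permutations matrix of permutation enrichment
#'   scores (same set order).
#' @param sizes optional integer vector of effective set sizes for the
#'   report.
#' @return data.frame with columns `set_name`, `size`, `ES`, `NES`,
#'   `p_emp`, `FDR`, `flag`.
#' @export
gsea_significance <- function(obs_es, perm_es, sizes = NA_integer_) {
  perm_es <- as.matrix(perm_es)
  S <- length(obs_es)
  stopifnot(nrow(perm_es) == S)
  P <- ncol(perm_es)
  p_emp <- (1 + rowSums(perm_es >= obs_es)) / (P + 1)
  pos_mean <- apply(perm_es, 1, function(x) {
    if (any(x > 0)) mean(x[x > 0]) else NA_real_
  })
  nes <- obs_es / pos_mean
  perm_nes <- perm_es / pos_mean
  pooled <- as.numeric(perm_nes[is.finite(perm_nes)])
  fdr <- rep(NA_real_, S)
  ok <- is.finite(nes)
  if (any(ok) && length(pooled) > 0L) {
    num <- vapply(nes[ok], function(v) mean(pooled >= v), numeric(1))
    den <- vapply(nes[ok], function(v) mean(nes[ok] >= v), numeric(1))
    raw <- pmin(pmax(num / den, 0), 1)
    o <- order(nes[ok], decreasing = TRUE)
    raw[o] <- rev(cummin(rev(raw[o])))  # monotone in NES
    fdr[ok] <- raw
  }
  data.frame(
    set_name = names(obs_es) %||% paste0("set_", seq_len(S)),
    size = sizes, ES = unname(obs_es), NES = unname(nes),
    p_emp = unname(p_emp), FDR = unname(fdr),
    flag = ifelse(ok, "ok", "undefined-NES"),
    stringsAsFactors = FALSE, row.names = NULL)
}

prepare_sets <- function(gene_sets, genes, min_size, max_size) {
  idx <- lapply(gene_sets, function(m) which(genes %in% m))
  sizes <- lengths(idx)
  keep <- sizes >= max(min_size, 1L) & sizes <= min(max_size, length(genes) - 1L)
  skipped <- names(gene_sets)[!keep]
  if (length(skipped) > 0L)
    message(sprintf("skipping %d gene set(s) outside size bounds [%d, %d]",
                    length(skipped), min_size, max_size))
  list(idx = idx[keep], sizes = sizes[keep], skipped = skipped)
}

#' Run the integrated enrichment analysis
#'
#' End-to-end engine: draws class-label permutations, recomputes DE and DS
#' scores for the observed and every permuted labelling, normalizes both
#' score sets against their permutation means, integrates them at every
#' requested (strategy, weight) combination, and scores every gene set
#' with the running-sum statistic plus permutation significance. The label
#' shuffles and the raw DE/DS permutation scores are shared across all
#' strategies and weights.
#'
#' @param cd a [count_data] object (typically after
#'   [filter_low_expression()]).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param strategies character vector from `"linear"`, `"rank-sp"`,
#'   `"rank-glb"`.
#' @param alphas numeric vector of integration weights in `[0, 1]`;
#'   duplicates are dropped with a warning.
#' @param n_perm number of label permutations (default 1000).
#' @param weight_exp running-sum weighting exponent (default 1; 0 for the
#'   classic unweighted statistic).
#' @param seed optional integer seed for the permutation draw.
#' @param min_size,max_size effective gene-set size bounds (defaults 5 and
#'   1000); sets outside are skipped.
#' @param eps denominator stabilizer for the score functions.
#' @return object of class `gsea_run`: list with `results` (data.frame
#'   over strategy x alpha x set with ES/NES/p_emp/FDR), `de_norm`,
#'   `ds_norm` (normalized [score_set()]s), `genes`, `skipped_sets`,
#'   `perm` (the label matrix), and the call parameters.
#' @export
run_gsea <- function(cd, gene_sets, strategies = "linear",
                     alphas = seq(0, 1, by = 0.1), n_perm = 1000,
                     weight_exp = 1, seed = NULL, min_size = 5,
                     max_size = 1000, eps = 1e-8) {
  stopifnot(inherits(cd, "count_data"))
  strategies <- match.arg(strategies,
                          c("linear", "rank-sp", "rank-glb"),
                          several.ok = TRUE)
  if (length(alphas) == 0L) stopf("alpha grid is empty")
  if (anyDuplicated(alphas)) {
    warnf("duplicate alpha values in grid; deduplicating")
    alphas <- unique(alphas)
  }
  for (a in alphas) check_alpha(a)

  genes <- levels(cd$gene)
  sets <- prepare_sets(gene_sets, genes, min_size, max_size)
  if (length(sets$idx) == 0L) stopf("no gene set passes the size bounds")

  perm <- permute_labels(cd$groups, n_perm, seed)
  obs_de <- compute_de_scores(cd, eps = eps)
  obs_ds <- compute_ds_scores(cd, eps = eps)
  pm <- score_permutations(cd, perm, eps)
  de_norm <- normalize_scores(score_set(obs_de, pm$de, "DE"))
  ds_norm <- normalize_scores(score_set(obs_ds, pm$ds, "DS"))

  res <- list()
  for (st in strategies) {
    for (a in alphas) {
      ints <- integrate_scores(de_norm, ds_norm, a, st)
      obs_es <- stats::setNames(
        es_for_sets(ints$obs, sets$idx, weight_exp), names(sets$idx))
      perm_es <- vapply(seq_len(ncol(perm)), function(k) {
        es_for_sets(ints$perm[, k], sets$idx, weight_exp)
      }, numeric(length(sets$idx)))
      perm_es <- matrix(perm_es, nrow = length(sets$idx))
      sig <- gsea_significance(obs_es, perm_es, sets$sizes)
      sig$strategy <- st
      sig$alpha <- a
      res[[paste(st, a)]] <- sig
    }
  }
  structure(
    list(results = do.call(rbind, c(res, list(make.row.names = FALSE))),
         de_norm = de_norm, ds_norm = ds_norm, genes = genes,
         skipped_sets = sets$skipped, perm = perm,
         strategies = strategies, alphas = alphas, n_perm = ncol(perm),
         weight_exp = weight_exp, seed = seed),
    class = "gsea_run")
}

#' @export
print.gsea_run <- function(x, ...) {
  cat(sprintf(
    "gsea_run: %d genes, %d sets, %d permutations, strategies {%s}, %d weights\n",
    length(x$genes), length(unique(x$results$set_name)), x$n_perm,
    paste(x$strategies, collapse = ", "), length(x$alphas)))
  invisible(x)
}

#' Multi-weight significance scan
#'
#' Runs (or reuses) the enrichment analysis over a grid of integration
#' weights and tabulates, per (strategy, weight), the gene sets meeting an
#' FDR cutoff, together with their union and a membership table. Scanning
#' a spread of weights and keeping the union is the recommended practice:
#' DE-dominated and DS-dominated gene sets surface at different weights.
#'
#' @param run a [run_gsea()] result, or a [count_data] object (in which
#'   case the remaining arguments are forwarded to [run_gsea()]).
#' @param fdr_cutoff FDR threshold for calling a set significant
#'   (default 0.05).
#' @param ... forwarded to [run_gsea()] when `run` is a [count_data].
#' @return object of class `weight_scan`: list with `results` (full
#'   table), `significant` (named list, key `"strategy|alpha"`), `union`
#'   (per strategy), `membership` (data.frame set x key of logicals),
#'   `alphas`, `strategies`, `fdr_cutoff`.
#' @export
weight_scan <- function(run, fdr_cutoff = 0.05, ...) {
  if (inherits(run, "count_data")) run <- run_gsea(run, ...)
  stopifnot(inherits(run, "gsea_run"))
  res <- run$results
  keys <- unique(paste(res$strategy, res$alpha, sep = "|"))
  significant <- lapply(keys, function(k) {
    part <- strsplit(k, "|", fixed = TRUE)[[1]]
    sub <- res[res$strategy == part[1] & res$alpha == as.numeric(part[2]), ]
    sub$set_name[!is.na(sub$FDR) & sub$FDR <= fdr_cutoff]
  })
  names(significant) <- keys
  sets <- sort(unique(res$set_name))
  membership <- as.data.frame(
    lapply(significant, function(s) sets %in% s), optional = TRUE)
  names(membership) <- keys
  rownames(membership) <- sets
  union_by_strategy <- lapply(
    stats::setNames(run$strategies, run$strategies), function(st) {
      sort(unique(unlist(significant[startsWith(keys, paste0(st, "|"))])))
    })
  structure(list(results = res, significant = significant,
                 union = union_by_strategy, membership = membership,
                 alphas = run$alphas, strategies = run$strategies,
                 fdr_cutoff = fdr_cutoff),
            class = "weight_scan")
}

#' Saturation analysis of the weight grid
#'
#' Cumulative count of unique significant gene sets as integration weights
#' are added one at a time in a stated order (by default the DE-only and
#' DS-only extremes first, then midpoints). The curve is monotone
#' non-decreasing by construction; a plateau indicates that additional
#' weights stop contributing new gene sets and the grid is sufficient.
#'
#' @param scan a [weight_scan()] result.
#' @param weight_order numeric vector giving the order in which weights
#'   are accumulated; every entry must be present in the scan's grid.
#' @param strategy which integration strategy's scan column to follow.
#' @return data.frame with columns `n_weights`, `weight_added`,
#'   `cumulative_sets`.
#' @export
saturation_analysis <- function(scan,
                                weight_order = c(1, 0, 0.5, 0.1, 0.9, 0.3,
                                                 0.7, 0.2, 0.4, 0.6, 0.8),
                                strategy = scan$strategies[1]) {
  stopifnot(inherits(scan, "weight_scan"))
  strategy <- match.arg(strategy, scan$strategies)
  match_idx <- vapply(weight_order, function(w) {
    hit <- which(abs(scan$alphas - w) < 1e-9)
    if (length(hit) == 0L)
      stopf("weight %g is not part of the scanned grid", w)
    hit[1]
  }, integer(1))
  acc <- character(0)
  counts <- integer(length(weight_order))
  for (i in seq_along(weight_order)) {
    key <- paste(strategy, scan$alphas[match_idx[i]], sep = "|")
    acc <- union(acc, scan$significant[[key]])
    counts[i] <- length(acc)
  }
  data.frame(n_weights = seq_along(weight_order),
             weight_added = weight_order,
             cumulative_sets = counts)
}
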