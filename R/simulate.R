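# Synthetic sub-exon count datasets with the NB structure the method
# assumes: gene totals drawn NB(s_j * q, phi), sub-exon counts obtained by
# multinomial thinning of the totals with per-group Dirichlet proportions.
# DE effects fold-change the totals; DS effects shift proportion mass
# between two sub-exons, leaving totals untouched -- the two effect types
# are orthogonal by construction.

#' Simulation configuration
#'
#' Collects every knob of the count simulator with validated defaults.
#' Baseline expression is log-normal across genes; dispersion is constant
#' (or per-gene gamma when `phi_shape` is given); size factors are uniform
#' on `size_factor_range`; sub-exon proportions are Dirichlet with
#' concentration `dirichlet_conc`.
#'
#' @param n_genes number of genes.
#' @param subexons_per_gene integer range `c(lo, hi)` of sub-exons per
#'   gene.
#' @param m_a,m_b group sizes (each at least 2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene expected normalized expression `q`.
#' @param phi NB dispersion (constant; 0 gives Poisson counts).
#' @param phi_shape optional gamma shape; when given, per-gene dispersions
#'   are drawn from `Gamma(phi_shape, rate = phi_shape/phi)` (mean `phi`).
#' @param size_factor_range uniform range of per-sample size factors.
#' @param de_fraction fraction of genes with a planted expression effect.
#' @param de_fold fold change applied to group-B expression of DE genes
#'   (direction random per gene).
#' @param ds_fraction fraction of genes with a planted splicing effect
#'   (drawn from genes with at least 2 sub-exons, disjoint from the DE
#'   genes).
#' @param ds_shift proportion mass moved between two random sub-exons of
#'   each DS gene in group B.
#' @param dirichlet_conc Dirichlet concentration of the baseline sub-exon
#'   proportions.
#' @param genesets list describing the planted gene-set collection:
#'   `n_null`, `n_de`, `n_ds`, `n_mixed` set counts, `size_range`, and
#'   `purity` (fraction of a planted set's members drawn from the matching
#'   effect pool, remainder from background).
#' @param seed integer seed driving the whole simulation.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000, subexons_per_gene = c(2, 8),
                       m_a = 5, m_b = 5,
                       baseline_meanlog = log(150), baseline_sdlog = 1,
                       phi = 0.1, phi_shape = NULL,
                       size_factor_range = c(0.7, 1.4),
                       de_fraction = 0, de_fold = 4,
                       ds_fraction = 0, ds_shift = 0.3,
                       dirichlet_conc = 5,
                       genesets = list(n_null = 0, n_de = 0, n_ds = 0,
                                       n_mixed = 0, size_range = c(10, 30),
                                       purity = 0.8),
                       seed = 1) {
  cfg <- list(n_genes = n_genes, subexons_per_gene = subexons_per_gene,
              m_a = m_a, m_b = m_b, baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, phi = phi,
              phi_shape = phi_shape, size_factor_range = size_factor_range,
              de_fraction = de_fraction, de_fold = de_fold,
              ds_fraction = ds_fraction, ds_shift = ds_shift,
              dirichlet_conc = dirichlet_conc, genesets = genesets,
              seed = seed)
  if (n_genes < 1) stopf("n_genes must be positive")
  if (m_a < 2 || m_b < 2) stopf("group sizes must be at least 2")
  if (de_fraction < 0 || de_fraction > 1 || ds_fraction < 0 ||
      ds_fraction > 1)
    stopf("effect fractions must lie in [0, 1]")
  if (de_fraction + ds_fraction > 1)
    stopf("DE and DS gene pools are disjoint; fractions sum above 1")
  if (de_fold <= 0) stopf("de_fold must be positive")
  if (ds_shift < 0 || ds_shift > 1) stopf("ds_shift must lie in [0, 1]")
  if (phi < 0) stopf("phi must be non-negative")
  if (subexons_per_gene[1] < 1 ||
      subexons_per_gene[2] < subexons_per_gene[1])
    stopf("invalid subexons_per_gene range")
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a sub-exon count dataset with planted effects
#'
#' Generates a two-group dataset under the package's own model
#' assumptions (see [sim_config()]): per-gene NB totals with
#' \eqn{\sigma^2 = \mu + \phi\mu^2} and \eqn{\mu_{gj} = s_j q_{g,group}},
#' multinomially thinned onto sub-exons by per-group Dirichlet
#' proportions. DE genes have their group-B expectation fold-changed; DS
#' genes have proportion mass moved between two sub-exons in group B.
#' Planted gene sets draw their members preferentially from the matching
#' effect pool; null sets draw from unaffected genes.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_data]; size factors estimated
#'   from the simulated data), `truth` (per-gene data.frame with the
#'   planted effects and generating parameters), `gene_sets` (named list
#'   with a `set_type` attribute: null / de / ds / mixed), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    G <- cfg$n_genes
    M <- cfg$m_a + cfg$m_b
    gene_ids <- sprintf("gene_%04d", seq_len(G))
    n_sub <- sample(seq(cfg$subexons_per_gene[1], cfg$subexons_per_gene[2]),
                    G, replace = TRUE)
    q <- stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
    phi_g <- if (is.null(cfg$phi_shape)) rep(cfg$phi, G) else
      stats::rgamma(G, shape = cfg$phi_shape, rate = cfg$phi_shape / cfg$phi)
    s <- stats::runif(M, cfg$size_factor_range[1], cfg$size_factor_range[2])
    grp_a <- c(rep(TRUE, cfg$m_a), rep(FALSE, cfg$m_b))

    n_de <- round(cfg$de_fraction * G)
    n_ds <- round(cfg$ds_fraction * G)
    if (n_de + n_ds > G) stopf("more effect genes than genes")
    de_idx <- sample.int(G, n_de)
    ds_pool <- setdiff(which(n_sub >= 2), de_idx)
    if (n_ds > length(ds_pool))
      stopf("not enough multi-sub-exon genes for the requested DS fraction")
    ds_idx <- resample(ds_pool, n_ds)

    q_b <- q
    de_dir <- rep(0, G)
    if (n_de > 0) {
      de_dir[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
      q_b[de_idx] <- q[de_idx] * cfg$de_fold^de_dir[de_idx]
    }

    props_a <- lapply(n_sub, function(n)
      rdirichlet1(rep(cfg$dirichlet_conc, n)))
    props_b <- props_a
    shift_applied <- rep(0, G)
    for (g in ds_idx) {
      pr <- props_b[[g]]
      ij <- sample.int(length(pr), 2)
      delta <- min(cfg$ds_shift, pr[ij[1]])
      pr[ij[1]] <- pr[ij[1]] - delta
      pr[ij[2]] <- pr[ij[2]] + delta
      props_b[[g]] <- pr
      shift_applied[g] <- delta
    }

    R <- sum(n_sub)
    X <- matrix(0, R, M)
    row_gene <- rep.int(seq_len(G), n_sub)
    offs <- c(0L, cumsum(n_sub))
    for (g in seq_len(G)) {
      rows <- (offs[g] + 1L):offs[g + 1L]
      mu <- s * ifelse(grp_a, q[g], q_b[g])
      y <- rnb(M, mu, phi_g[g])
      for (j in seq_len(M)) {
        pr <- if (grp_a[j]) props_a[[g]] else props_b[[g]]
        X[rows, j] <- stats::rmultinom(1, y[j], pr)
      }
    }
    colnames(X) <- sprintf("sample_%02d", seq_len(M))

    truth <- data.frame(
      gene_id = gene_ids, n_subexons = n_sub,
      de = seq_len(G) %in% de_idx, ds = seq_len(G) %in% ds_idx,
      fold = ifelse(de_dir != 0, cfg$de_fold^de_dir, 1),
      shift = shift_applied, q_a = q, q_b = q_b, phi = phi_g,
      stringsAsFactors = FALSE)

    gene_sets <- plant_gene_sets(cfg$genesets, gene_ids,
                                 de_idx, ds_idx)

    cd <- count_data(X, gene_id = gene_ids[row_gene],
                     subexon_index = sequence(n_sub),
                     groups = ifelse(grp_a, "A", "B"))
    list(counts = cd, truth = truth, gene_sets = gene_sets,
         config = cfg)
  })
}

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, size) x[sample.int(length(x), size)]

plant_gene_sets <- function(spec, gene_ids, de_idx, ds_idx) {
  spec <- utils::modifyList(
    list(n_null = 0, n_de = 0, n_ds = 0, n_mixed = 0,
         size_range = c(10, 30), purity = 0.8), as.list(spec))
  G <- length(gene_ids)
  bg <- setdiff(seq_len(G), c(de_idx, ds_idx))
  draw <- function(pool, type, k) {
    size <- sample(seq(spec$size_range[1], spec$size_range[2]), 1)
    if (type == "null" || length(pool) == 0L) {
      members <- resample(bg, min(size, length(bg)))
    } else {
      n_eff <- min(round(spec$purity * size), length(pool))
      members <- c(resample(pool, n_eff),
                   resample(bg, min(size - n_eff, length(bg))))
    }
    gene_ids[members]
  }
  types <- c(rep("null", spec$n_null), rep("de", spec$n_de),
             rep("ds", spec$n_ds), rep("mixed", spec$n_mixed))
  if (length(types) == 0L) return(structure(list(), set_type = character(0)))
  sets <- vector("list", length(types))
  for (i in seq_along(types)) {
    pool <- switch(types[i], null = integer(0), de = de_idx, ds = ds_idx,
                   mixed = c(de_idx, ds_idx))
    sets[[i]] <- draw(pool, types[i], i)
  }
  names(sets) <- sprintf("%s_set_%03d", types,
                         stats::ave(seq_along(types), types, FUN = seq_along))
  attr(sets, "set_type") <- stats::setNames(types, names(sets))
  attr(sets, "descriptions") <- stats::setNames(
    sprintf("planted %s gene set", types), names(sets))
  sets
}

#' Empirical mean-variance summary of a simulated or real dataset
#'
#' Per-gene, per-group empirical mean and variance of depth-normalized
#' gene counts, plus a pooled regression check of the NB mean-variance
#' relation \eqn{\sigma^2 = \mu + \phi\mu^2}: the slope of
#' \eqn{(\hat v - \hat\mu)} on \eqn{\hat\mu^2} (through the origin)
#' recovers the dispersion. The regression is weighted by
#' \eqn{1/\hat\mu^4}: the sampling variance of \eqn{\hat v} grows with the
#' fourth power of the mean, and without these weights the handful of
#' most-expressed genes dominates the slope.
#'
#' @param cd a [count_data] object.
#' @return list with `per_gene` (data.frame: gene_id, group, mean, var)
#'   and `phi_fit` (the regression slope).
#' @export
empirical_moments <- function(cd) {
  stopifnot(inherits(cd, "count_data"))
  lv <- levels(cd$groups)
  per_group <- lapply(lv, function(g) {
    j <- cd$groups == g
    if (sum(j) < 2L) stopf("group '%s' has fewer than 2 samples", g)
    Yn <- sweep(cd$Y[, j, drop = FALSE], 2, cd$size_factors[j], "/")
    data.frame(gene_id = rownames(cd$Y), group = g,
               mean = rowMeans(Yn), var = row_vars(Yn),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per_gene <- do.call(rbind, per_group)
  fit_data <- per_gene[per_gene$mean > 0, ]
  phi_fit <- unname(stats::coef(stats::lm(
    I(var - mean) ~ 0 + I(mean^2), data = fit_data,
    weights = 1 / fit_data$mean^4))[1])
  list(per_gene = per_gene, phi_fit = phi_fit)
}

#' Write a simulated dataset to disk
#'
#' Writes the count TSV (`gene_id`, `subexon_index`, one column per
#' sample), phenotype TSV, per-gene truth TSV, and the planted gene sets
#' as GMT into a directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cd <- sim$counts
  counts <- data.frame(gene_id = as.character(cd$gene),
                       subexon_index = cd$subexon_index,
                       cd$X, check.names = FALSE)
  paths <- file.path(dir, c("counts.tsv", "phenotype.tsv", "truth.tsv",
                            "gene_sets.gmt"))
  utils::write.table(counts, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = cd$samples, group = as.character(cd$groups)),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(sim$gene_sets, paths[4])
  invisible(paths)
}
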