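#' Construct a sub-exon count dataset
#'
#' Bundles a sub-exon read-count matrix with its sample annotation into the
#' container used throughout the package. Gene-level totals
#' \eqn{Y_j^{(g)} = \sum_i X_{ij}^{(g)}} are derived by summing sub-exon
#' counts within each gene, and DESeq-style size factors are estimated from
#' the gene totals unless supplied.
#'
#' Group labels are mapped to the internal two-group design (A, B) by order
#' of first occurrence in `groups`.
#'
#' @param X integer matrix of sub-exon read counts, rows = sub-exons,
#'   columns = samples.
#' @param gene_id character vector, the gene of each row of `X`.
#' @param subexon_index integer vector, the sub-exon index of each row
#'   within its gene; `(gene_id, subexon_index)` pairs must be unique.
#' @param groups vector of length `ncol(X)` with exactly two distinct
#'   values assigning each sample to a group.
#' @param size_factors optional positive numeric vector of per-sample
#'   sequencing-depth factors; estimated by [estimate_size_factors()] when
#'   `NULL`.
#' @return object of class `count_data`: a list with elements `X`, `gene`
#'   (factor, one level per gene in order of first appearance),
#'   `subexon_index`, `samples`, `groups` (factor with the two original
#'   labels as levels), `Y` (gene x sample total matrix), `size_factors`,
#'   and `ds_use` (logical per row; which sub-exons enter the splicing
#'   analysis, see [filter_low_expression()]).
#' @export
count_data <- function(X, gene_id, subexon_index, groups,
                       size_factors = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("sample_", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (any(X < 0)) stopf("count matrix contains negative values")
  if (any(X != round(X))) stopf("count matrix contains non-integer values")
  if (length(gene_id) != nrow(X) || length(subexon_index) != nrow(X))
    stopf("gene_id/subexon_index length must match nrow(X)")
  key <- paste(gene_id, subexon_index)
  if (anyDuplicated(key))
    stopf("duplicated (gene_id, subexon_index) row: %s",
          key[anyDuplicated(key)])
  if (length(groups) != ncol(X))
    stopf("groups must have one entry per sample column")
  glev <- unique(as.character(groups))
  if (length(glev) != 2L)
    stopf("exactly two groups required, found %d (%s)",
          length(glev), paste(glev, collapse = ", "))
  groups <- factor(as.character(groups), levels = glev)
  if (any(table(groups) < 1L)) stopf("both groups must be non-empty")

  gene <- factor(gene_id, levels = unique(gene_id))
  Y <- rowsum(X, gene, reorder = FALSE)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(Y)
  if (length(size_factors) != ncol(X) || any(size_factors <= 0))
    stopf("size_factors must be positive, one per sample")
  structure(
    list(X = X, gene = gene, subexon_index = as.integer(subexon_index),
         samples = colnames(X), groups = groups, Y = Y,
         size_factors = size_factors, ds_use = rep(TRUE, nrow(X))),
    class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf(paste0(
    "count_data: %d genes, %d sub-exons, %d samples (%s: %d, %s: %d)\n"),
    nlevels(x$gene), nrow(x$X), ncol(x$X),
    levels(x$groups)[1], sum(x$groups == levels(x$groups)[1]),
    levels(x$groups)[2], sum(x$groups == levels(x$groups)[2])))
  invisible(x)
}

#' Load sub-exon counts and a phenotype file
#'
#' Reads a sub-exon count table (columns `gene_id`, `subexon_index`, then
#' one column per sample) and a two-column phenotype table (`sample`,
#' `group`) and validates them into a [count_data] object. Both readers are
#' gzip-transparent. Sample order is taken from the count table.
#'
#' @param counts_path path to the count TSV (optionally gzipped).
#' @param phenotype_path path to the phenotype TSV (optionally gzipped).
#' @return a [count_data] object.
#' @export
load_counts <- function(counts_path, phenotype_path) {
  if (!file.exists(counts_path)) stopf("count file not found: %s", counts_path)
  if (!file.exists(phenotype_path))
    stopf("phenotype file not found: %s", phenotype_path)
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "subexon_index") %in% names(tab)))
    stopf("count table must have gene_id and subexon_index columns")
  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("sample", "group") %in% names(ph)))
    stopf("phenotype table must have sample and group columns")
  samples <- setdiff(names(tab), c("gene_id", "subexon_index"))
  missing_ph <- setdiff(samples, ph$sample)
  if (length(missing_ph) > 0L)
    stopf("sample(s) missing from phenotype file: %s",
          paste(missing_ph, collapse = ", "))
  extra_ph <- setdiff(ph$sample, samples)
  if (length(extra_ph) > 0L)
    stopf("phenotype sample(s) missing from count table: %s",
          paste(extra_ph, collapse = ", "))
  grp <- ph$group[match(samples, ph$sample)]
  X <- as.matrix(tab[, samples, drop = FALSE])
  count_data(X, tab$gene_id, tab$subexon_index, grp)
}

#' Estimate DESeq-style size factors from gene-level totals
#'
#' Median-of-ratios estimator: each sample's factor is the median, over
#' genes with a positive geometric mean, of the ratio of the sample's count
#' to the per-gene geometric mean across samples. Delegates to
#' `DESeq2::estimateSizeFactorsForMatrix()`.
#'
#' @param Y gene x sample matrix of gene-level counts.
#' @param method `"ratio"` (default; requires at least one gene with
#'   positive counts in every sample) or `"poscounts"` (pseudo-reference
#'   geometric mean over positive counts only, for sparse data).
#' @return positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(Y, method = c("ratio", "poscounts")) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (method == "ratio") {
    if (!any(rowSums(Y > 0) == ncol(Y)))
      stopf(paste("no gene has positive counts in all samples;",
                  "re-run with method = \"poscounts\""))
    s <- DESeq2::estimateSizeFactorsForMatrix(Y)
  } else {
    # geometric mean over positive counts only, zero-heavy rows dropped
    log_gm <- apply(Y, 1, function(row) {
      pos <- row > 0
      if (!any(pos)) -Inf else sum(log(row[pos])) / length(row)
    })
    keep <- is.finite(log_gm)
    if (!any(keep)) stopf("count matrix is all zero")
    s <- DESeq2::estimateSizeFactorsForMatrix(Y[keep, , drop = FALSE],
                                              geoMeans = exp(log_gm[keep]))
  }
  unname(s)
}

#' Remove low-count genes and flag low-count sub-exons
#'
#' Genes whose total read count over all samples falls below
#' `min_gene_total` are removed entirely. Sub-exons whose total falls below
#' `min_subexon_total` are excluded from the differential-splicing
#' computation only (`ds_use = FALSE`): the gene totals `Y` keep all reads,
#' so the differential-expression analysis is unaffected.
#'
#' @param cd a [count_data] object.
#' @param min_gene_total minimum summed gene count (default 10).
#' @param min_subexon_total minimum summed sub-exon count (default 5).
#' @return filtered [count_data] with attribute `"filter_log"` describing
#'   the removals.
#' @export
filter_low_expression <- function(cd, min_gene_total = 10,
                                  min_subexon_total = 5) {
  stopifnot(inherits(cd, "count_data"),
            min_gene_total >= 0, min_subexon_total >= 0)
  gene_tot <- rowSums(cd$Y)
  keep_gene <- names(gene_tot)[gene_tot >= min_gene_total]
  if (length(keep_gene) == 0L)
    stopf("filtering removed every gene (min_gene_total = %g)",
          min_gene_total)
  keep_row <- cd$gene %in% keep_gene
  X <- cd$X[keep_row, , drop = FALSE]
  gene <- factor(as.character(cd$gene[keep_row]), levels = keep_gene)
  out <- cd
  out$X <- X
  out$gene <- gene
  out$subexon_index <- cd$subexon_index[keep_row]
  out$Y <- cd$Y[keep_gene, , drop = FALSE]
  out$ds_use <- rowSums(X) >= min_subexon_total
  attr(out, "filter_log") <- sprintf(
    "removed %d/%d genes below %g total reads; excluded %d/%d sub-exons below %g total reads from DS",
    nlevels(cd$gene) - length(keep_gene), nlevels(cd$gene), min_gene_total,
    sum(!out$ds_use), nrow(X), min_subexon_total)
  out
}
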