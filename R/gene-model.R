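#' Flatten the exons of one gene into disjoint sub-exons
#'
#' Splits the union of a gene's annotated exons (over all of its isoforms)
#' at every distinct exon start and end, producing non-overlapping,
#' contiguous exon fragments ("sub-exons"). Any alternative 3'/5' splice
#' site, skipped exon or alternative first/last exon therefore starts a new
#' fragment, so differential usage of any part of the gene is visible at
#' the fragment level.
#'
#' Coordinates are 0-based half-open throughout this function: an exon
#' `(100, 200)` covers bases 100..199.
#'
#' @param exons data.frame with columns `start`, `end` (0-based half-open,
#'   `start < end`) and optionally `gene_id`, `chrom`, `strand` (each must
#'   be constant within the gene).
#' @return data.frame with columns `gene_id`, `subexon_index`, `chrom`,
#'   `start`, `end`, `strand`; fragments are pairwise disjoint, sorted by
#'   `start`, and their base union equals the base union of the input exons.
#' @examples
#' flatten_gene(data.frame(start = c(100, 150), end = c(200, 250)))
#' @export
flatten_gene <- function(exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) stopf("flatten_gene: empty exon list")
  gene_id <- if ("gene_id" %in% names(exons)) unique(exons$gene_id) else "gene"
  if (length(gene_id) != 1L)
    stopf("flatten_gene: records from multiple genes: %s",
          paste(gene_id, collapse = ", "))
  chrom <- if ("chrom" %in% names(exons)) unique(as.character(exons$chrom)) else "."
  strand <- if ("strand" %in% names(exons)) unique(as.character(exons$strand)) else "."
  if (length(chrom) != 1L)
    stopf("gene '%s' has exons on multiple chromosomes (%s)",
          gene_id, paste(chrom, collapse = ", "))
  if (length(strand) != 1L)
    stopf("gene '%s' has exons on both strands", gene_id)
  if (any(exons$start >= exons$end))
    stopf("gene '%s' has an exon with start >= end", gene_id)

  # disjoin() places a boundary at every distinct start/end over the union
  ir <- IRanges::IRanges(start = exons$start + 1L, end = exons$end)
  d <- IRanges::disjoin(ir)
  data.frame(
    gene_id = gene_id,
    subexon_index = seq_along(d),
    chrom = chrom,
    start = IRanges::start(d) - 1L,
    end = IRanges::end(d),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Flatten a transcript annotation into per-gene sub-exon models
#'
#' Reads exon features from a GTF/GFF file (1-based closed coordinates, the
#' standard dialect) and builds the disjoint sub-exon model of every gene
#' via [flatten_gene()]. Internally and in all outputs coordinates are
#' 0-based half-open.
#'
#' @param gtf_path path to a GTF/GFF file with `exon` features carrying
#'   `gene_id` attributes.
#' @param multi_chrom what to do with a gene annotated on several
#'   chromosomes (or both strands): `"error"` (default) or `"split"` into
#'   one model per `gene_id:chrom:strand`.
#' @return data.frame of sub-exons over all genes (columns as in
#'   [flatten_gene()]), ordered by gene then start.
#' @export
flatten_annotation <- function(gtf_path, multi_chrom = c("error", "split")) {
  multi_chrom <- match.arg(multi_chrom)
  if (!file.exists(gtf_path)) stopf("annotation file not found: %s", gtf_path)
  raw <- readLines(gtf_path, n = 1000L, warn = FALSE)
  if (length(raw) < 1000L &&
      !any(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))) {
    warnf("annotation '%s' contains no features", gtf_path)
    return(empty_subexon_table())
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (length(gr) == 0L) {
    warnf("annotation '%s' contains no features", gtf_path)
    return(empty_subexon_table())
  }
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta))
    stopf("annotation '%s' has no gene_id attribute", gtf_path)
  is_exon <- !is.na(meta$type) & tolower(as.character(meta$type)) == "exon"
  no_exon <- setdiff(unique(meta$gene_id), unique(meta$gene_id[is_exon]))
  if (length(no_exon) > 0L)
    warnf("skipping %d gene(s) with no exon features: %s",
          length(no_exon), paste(utils::head(no_exon, 5), collapse = ", "))
  gr <- gr[is_exon]
  if (length(gr) == 0L) {
    warnf("annotation '%s' contains no exon features", gtf_path)
    return(empty_subexon_table())
  }
  ex <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (multi_chrom == "split") {
    multi <- tapply(paste(ex$chrom, ex$strand), ex$gene_id,
                    function(x) length(unique(x)) > 1L)
    key <- paste(ex$gene_id, ex$chrom, ex$strand, sep = ":")
    ex$gene_id <- ifelse(multi[ex$gene_id], key, ex$gene_id)
  }
  pieces <- lapply(split(ex, ex$gene_id), flatten_gene)
  out <- do.call(rbind, pieces[order(names(pieces))])
  rownames(out) <- NULL
  out
}

empty_subexon_table <- function() {
  data.frame(gene_id = character(), subexon_index = integer(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Write a sub-exon definition table
#'
#' @param subexons data.frame from [flatten_annotation()] or
#'   [flatten_gene()].
#' @param path output TSV path. A header comment records the coordinate
#'   convention (0-based half-open).
#' @return `path`, invisibly.
#' @export
write_subexons <- function(subexons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sub-exon definition; coordinates are 0-based half-open", con)
  utils::write.table(subexons, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
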