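# SNP-to-gene interval assignment and the candidate-gene report.
#
# A SNP belongs to a gene if its position falls within the annotated gene
# span (UTRs + coding + introns) extended by a symmetric flank covering the
# upstream/downstream regions.  Sub-features are not distinguished: span
# plus flank membership is equivalent to the union of upstream / UTR /
# coding / intronic / downstream assignment.

#' Read a gene annotation interval file
#'
#' Two dialects: `"bed"` (0-based half-open: chrom, start, end, name
#' \[, score, strand\]; converted to 1-based inclusive on read) and `"tsv1"`
#' (1-based inclusive with header: gene_id, chrom, start_bp, end_bp,
#' strand).
#'
#' @param path input file.
#' @param dialect `"tsv1"` or `"bed"`.
#' @return A data frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start_bp`, `end_bp`, `strand`, sorted by chromosome and
#'   start.
#' @export
read_annotation <- function(path, dialect = c("tsv1", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "tsv1" && length(lines)) lines <- lines[-1L]  # header
  if (!length(lines)) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    class(ann) <- c("gene_annotation", "data.frame")
    return(ann)
  }
  f <- strsplit(trimws(lines), "[ \t]+")
  line_no <- seq_along(lines) + if (dialect == "tsv1") 1L else 0L
  if (dialect == "bed") {
    if (any(lengths(f) < 4L))
      stop(sprintf("BED line %d has fewer than 4 fields",
                   line_no[which(lengths(f) < 4L)[1]]))
    ann <- data.frame(
      gene_id = vapply(f, `[`, "", 4L),
      chrom = vapply(f, `[`, "", 1L),
      start_bp = as.integer(vapply(f, `[`, "", 2L)) + 1L,
      end_bp = as.integer(vapply(f, `[`, "", 3L)),
      strand = vapply(f, function(x) if (length(x) >= 6L) x[6L] else "+", ""),
      stringsAsFactors = FALSE)
  } else {
    if (any(lengths(f) < 5L))
      stop(sprintf("tsv1 line %d has fewer than 5 fields",
                   line_no[which(lengths(f) < 5L)[1]]))
    ann <- data.frame(
      gene_id = vapply(f, `[`, "", 1L),
      chrom = vapply(f, `[`, "", 2L),
      start_bp = as.integer(vapply(f, `[`, "", 3L)),
      end_bp = as.integer(vapply(f, `[`, "", 4L)),
      strand = vapply(f, `[`, "", 5L),
      stringsAsFactors = FALSE)
  }
  bad <- which(ann$start_bp > ann$end_bp)
  if (length(bad))
    stop(sprintf("annotation line %d: start %d > end %d after conversion",
                 line_no[bad[1]], ann$start_bp[bad[1]], ann$end_bp[bad[1]]))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         ann$gene_id[anyDuplicated(ann$gene_id)])
  o <- marker_order(ann$chrom, ann$start_bp)
  ann <- ann[o, , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a gene annotation in the tsv1 dialect
#'
#' @param annotation a `gene_annotation` data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_tsv1 <- function(annotation, path) {
  df <- as.data.frame(annotation)[, c("gene_id", "chrom", "start_bp",
                                      "end_bp", "strand")]
  write_tsv(df, path)
}

#' Assign SNPs to flanked gene spans
#'
#' A SNP is assigned to every gene whose flanked span
#' `[start - flank_bp, end + flank_bp]` on the same chromosome contains its
#' position; multi-gene assignment is allowed.  Interval overlap is resolved
#' per chromosome with `IRanges::findOverlaps()`.
#'
#' @param markers the `markers` data frame of a [genotype_dataset()] (or any
#'   data frame with `marker_id`, `chrom`, `pos_bp`); unmapped markers are
#'   never assigned.
#' @param annotation a `gene_annotation` from [read_annotation()].
#' @param flank_bp symmetric flank in bp covering upstream/downstream
#'   regions (default 5000); must be non-negative.
#' @return A named list mapping every `marker_id` to a character vector of
#'   gene ids (empty vector = intergenic).
#' @export
assign_snps_to_genes <- function(markers, annotation, flank_bp = 5000) {
  if (length(flank_bp) != 1L || is.na(flank_bp) || flank_bp < 0)
    stop("flank_bp must be a single non-negative number")
  res <- stats::setNames(
    rep(list(character(0)), nrow(markers)), markers$marker_id)
  mapped <- which(!is_unmapped_marker(markers$chrom, markers$pos_bp))
  for (ch in unique(markers$chrom[mapped])) {
    mi <- mapped[markers$chrom[mapped] == ch]
    gi <- which(annotation$chrom == ch)
    if (!length(gi)) next
    q <- IRanges::IRanges(start = markers$pos_bp[mi], width = 1L)
    s <- IRanges::IRanges(
      start = pmax(annotation$start_bp[gi] - flank_bp, 1L),
      end = annotation$end_bp[gi] + flank_bp)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    hits <- split(annotation$gene_id[gi][S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    for (k in names(hits))
      res[[mi[as.integer(k)]]] <- sort(unname(hits[[k]]))
  }
  res
}

#' Candidate genes hit by outlier SNPs
#'
#' One record per gene containing at least one flagged SNP.
#' `max_contiguous_run` is the longest run of flagged SNPs assigned to the
#' gene that are consecutive in genome map order among all markers (no
#' intervening marker of any kind).  Genes are sorted by `n_outlier_snps`
#' descending, then `gene_id` ascending.  Flagged SNPs assigned to no gene
#' are returned separately as the intergenic overflow, so per-gene and
#' intergenic counts together conserve the total flag count.
#'
#' @param scan a `scan_result` from [select_outliers()].
#' @param assignment output of [assign_snps_to_genes()] over the same
#'   markers.
#' @param markers the markers data frame the scan was computed on (map
#'   order).
#' @return A list of class `candidate_gene_report` with `genes` (data frame:
#'   `gene_id`, `n_outlier_snps`, `max_contiguous_run`, `outlier_snp_ids`
#'   comma-joined) and `intergenic_snp_ids` (character vector).
#' @export
candidate_gene_report <- function(scan, assignment, markers) {
  stopifnot(inherits(scan, "scan_result"))
  if (!identical(as.character(scan$marker_id),
                 as.character(markers$marker_id)))
    stop("scan and markers cover different marker sets")
  flagged <- which(scan$outlier_flags)
  empty <- data.frame(gene_id = character(), n_outlier_snps = integer(),
                      max_contiguous_run = integer(),
                      outlier_snp_ids = character(),
                      stringsAsFactors = FALSE)
  if (!length(flagged)) {
    out <- list(genes = empty, intergenic_snp_ids = character(0))
    class(out) <- "candidate_gene_report"
    return(out)
  }
  genes_of <- assignment[markers$marker_id[flagged]]
  intergenic <- markers$marker_id[flagged[lengths(genes_of) == 0L]]
  pairs <- data.frame(
    gene_id = unlist(genes_of, use.names = FALSE),
    idx = rep(flagged, lengths(genes_of)),
    stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    out <- list(genes = empty, intergenic_snp_ids = intergenic)
    class(out) <- "candidate_gene_report"
    return(out)
  }
  per_gene <- lapply(split(pairs$idx, pairs$gene_id), function(idx) {
    idx <- sort(idx)
    runs <- rle(cumsum(c(1L, diff(idx) != 1L)))$lengths
    list(n = length(idx), run = max(runs),
         ids = paste(markers$marker_id[idx], collapse = ","))
  })
  genes <- data.frame(
    gene_id = names(per_gene),
    n_outlier_snps = vapply(per_gene, function(x) x$n, integer(1)),
    max_contiguous_run = vapply(per_gene, function(x) x$run, integer(1)),
    outlier_snp_ids = vapply(per_gene, function(x) x$ids, character(1)),
    stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n_outlier_snps, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  out <- list(genes = genes, intergenic_snp_ids = intergenic)
  class(out) <- "candidate_gene_report"
  out
}

#' @export
print.candidate_gene_report <- function(x, ...) {
  cat(sprintf("candidate_gene_report: %d genes, %d intergenic outlier SNPs\n",
              nrow(x$genes), length(x$intergenic_snp_ids)))
  print(utils::head(x$genes, 10))
  invisible(x)
}
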