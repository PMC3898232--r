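test_that("annotation dialects parse with the right coordinate conventions", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "g.bed")
  writeLines(c("1\t999\t2000\tgeneA", "2\t0\t100\tgeneB\t0\t-"), bed)
  ann <- read_annotation(bed, "bed")
  expect_equal(ann$start_bp[ann$gene_id == "geneA"], 1000L)
  expect_equal(ann$end_bp[ann$gene_id == "geneA"], 2000L)
  expect_equal(ann$strand, c("+", "-"))

  empty <- file.path(dir, "empty.bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_annotation(empty, "bed")), 0L)

  # round trip through the tsv1 writer
  tsv <- file.path(dir, "g.tsv")
  write_annotation_tsv1(ann, tsv)
  back <- read_annotation(tsv, "tsv1")
  expect_equal(as.data.frame(back), as.data.frame(ann))

  bad <- file.path(dir, "bad.bed")
  writeLines("1\t2000\t1000\tgeneC", bad)
  expect_error(read_annotation(bad, "bed"), "line 1.*start")
})

test_that("SNP-to-gene assignment respects flanks, chromosomes and monotonicity", {
  ann <- structure(data.frame(
    gene_id = c("gA", "gB"), chrom = c("1", "2"),
    start_bp = c(1000000L, 1000L), end_bp = c(2000000L, 2000L),
    strand = "+", stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame"))
  markers <- data.frame(
    chrom = c("1", "1", "1", "2", "0"),
    marker_id = c("in", "near", "far", "otherchrom", "unmapped"),
    pos_bp = c(1500000L, 996000L, 994999L, 1500000L, 0L),
    stringsAsFactors = FALSE)

  a <- assign_snps_to_genes(markers, ann, flank_bp = 5000)
  expect_equal(a[["in"]], "gA")
  expect_equal(a[["near"]], "gA")       # 4,000 bp upstream, within flank
  expect_equal(a[["far"]], character(0))  # 5,001 bp upstream
  expect_equal(a[["otherchrom"]], character(0))
  expect_equal(a[["unmapped"]], character(0))

  # a SNP inside the gene is assigned at any flank, including zero
  expect_equal(assign_snps_to_genes(markers, ann, flank_bp = 0)[["in"]], "gA")
  expect_error(assign_snps_to_genes(markers, ann, flank_bp = -1),
               "non-negative")

  # growing the flank never removes an assignment
  prev <- a
  for (fl in c(10000, 100000, 1000000)) {
    cur <- assign_snps_to_genes(markers, ann, flank_bp = fl)
    for (m in names(prev))
      expect_true(all(prev[[m]] %in% cur[[m]]))
    prev <- cur
  }
})

test_that("contiguous-outlier runs count map-consecutive flagged SNPs per gene", {
  markers <- data.frame(chrom = "1",
                        marker_id = sprintf("s%02d", 1:10),
                        pos_bp = (1:10) * 1000L,
                        stringsAsFactors = FALSE)
  scan <- structure(list(
    outlier_flags = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                      TRUE, FALSE),
    marker_id = markers$marker_id,
    n_outliers = 7L, n_defined = 10L, selection_quantile = 0.99,
    thresholds = c("0.99" = 0.5)), class = "scan_result")
  assignment <- c(
    stats::setNames(rep(list("gRUN"), 5), markers$marker_id[1:5]),
    stats::setNames(rep(list("gGAP"), 4), markers$marker_id[6:9]),
    stats::setNames(list(character(0)), markers$marker_id[10]))

  rep_out <- candidate_gene_report(scan, assignment, markers)
  g <- rep_out$genes
  # five flagged SNPs at consecutive map positions -> one run of 5
  expect_equal(g$max_contiguous_run[g$gene_id == "gRUN"], 5L)
  expect_equal(g$n_outlier_snps[g$gene_id == "gRUN"], 5L)
  # two flagged SNPs separated by an unflagged one -> runs of 1
  expect_equal(g$max_contiguous_run[g$gene_id == "gGAP"], 1L)
  expect_equal(g$n_outlier_snps[g$gene_id == "gGAP"], 2L)
  # sorted by outlier count descending
  expect_equal(g$gene_id, c("gRUN", "gGAP"))
  expect_equal(rep_out$intergenic_snp_ids, character(0))

  none <- scan
  none$outlier_flags <- rep(FALSE, 10)
  none$n_outliers <- 0L
  expect_equal(nrow(candidate_gene_report(none, assignment, markers)$genes), 0L)
})

test_that("flagged SNP counts conserve across gene reports and intergenic overflow", {
  cfg <- sim_config(n_loci = 3000, n_selected = 60, seed = 71)
  sim <- simulate_dataset(cfg)
  tab <- fst_scan(sim$dataset)
  scan <- select_outliers(tab, scan_config())
  ann <- make_annotation_fixture(sim$dataset$markers, fraction = 0.5,
                                 seed = 72)
  assignment <- assign_snps_to_genes(sim$dataset$markers, ann,
                                     flank_bp = 5000)
  rep_out <- candidate_gene_report(scan, assignment, sim$dataset$markers)

  per_gene <- unique(unlist(strsplit(rep_out$genes$outlier_snp_ids, ",")))
  expect_equal(length(per_gene) + length(rep_out$intergenic_snp_ids),
               scan$n_outliers)
  expect_true(all(rep_out$genes$max_contiguous_run <=
                    rep_out$genes$n_outlier_snps))
  expect_true(all(rep_out$genes$n_outlier_snps >= 1L))
})

test_that("annotation fixture hits the requested marker coverage", {
  cfg <- sim_config(n_loci = 20000, seed = 81)
  sim <- simulate_dataset(cfg)
  mk <- sim$dataset$markers
  for (fr in c(0, 0.6, 1)) {
    ann <- make_annotation_fixture(mk, fraction = fr, seed = 82)
    a <- assign_snps_to_genes(mk, ann, flank_bp = 0)
    cov <- mean(lengths(a) > 0)
    if (fr == 0) expect_equal(cov, 0)
    else if (fr == 1) expect_equal(cov, 1)
    else expect_lt(abs(cov - fr), 0.02)
  }
})
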