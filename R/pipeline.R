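# End-to-end orchestration: input (read or simulate) -> QC -> ALLPOP scan ->
# merged-group scans -> outliers -> gene report -> PCA -> distance
# correlation, with a deterministic run manifest.  Stages run in fixed
# order; any stage failure aborts with a stage-named error.

#' Default pipeline configuration
#'
#' A fully simulated run at the study scale: nine breeds at the default
#' sample sizes, 45,652 markers of which 500 unmapped, 300 low-MAF and 200
#' low-call-rate are planted (leaving 44,652 after QC) plus 100
#' fixed-difference selected loci; ALLPOP scan plus the two merged-group
#' contrasts (Chinese indigenous + developed vs European commercial, and a
#' Northern vs Southern pool restricted to LW vs LC + WZS + BM); 97.5% and
#' 99% thresholds with candidate calling at 99%; a tiled annotation fixture
#' with a 5 kb flank; 10 principal components.
#'
#' @param seed integer seed driving the simulation and all subsampling.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_loci = 45652, n_selected = 100,
                    n_unmapped = 500, n_low_maf = 300, n_low_callrate = 200),
    qc = list(maf_threshold = 0.05, call_rate_threshold = 0.90,
              drop_unmapped = TRUE),
    groupings = list(
      CHN_VS_EURO = list(TC = "CHN", BM = "CHN", LW = "CHN", WZS = "CHN",
                         NX = "CHN", LC = "CHN", YT = "CHN",
                         Landrace = "EURO", LargeWhite = "EURO"),
      NORTH_VS_SOUTH = list(LW = "North", LC = "South", WZS = "South",
                            BM = "South", TC = NA, NX = NA, YT = NA,
                            Landrace = NA, LargeWhite = NA)),
    scan = list(quantiles = c(0.975, 0.99), selection_quantile = 0.99),
    annotation = "fixture",
    annotation_fraction = 0.6,
    flank_bp = 5000,
    pcs = 10
  )
}

#' @keywords internal
#' @noRd
merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        length(override[[k]]) > 0L)
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full selection-scan pipeline
#'
#' @param config a nested list as produced by [default_pipeline_config()],
#'   or a path to a YAML file with the same structure.  Recognised fields:
#'   `seed`; either `simulate` (arguments to [sim_config()]) or
#'   `ped`/`map` input paths; `qc` ([qc_config()] arguments); `groupings`
#'   (named list of breed -> group maps, `NA`/null = breed excluded, an
#'   empty list disables the extra contrasts; the ALLPOP grouping is always
#'   run); `scan` ([scan_config()] arguments);
#'   `annotation` (path, `"fixture"`, or `"none"` to skip gene mapping) with
#'   `annotation_dialect`, `annotation_fraction`; `flank_bp`; `pcs`.
#' @param output_dir directory for all outputs (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.yaml`): configuration echo, package version, row counts,
#'   thresholds and outlier counts per grouping.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- merge_config(default_pipeline_config(), config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  seed <- as.integer(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("fstscan")),
                   seed = seed, config = config)

  # --- input ---------------------------------------------------------------
  sim_truth <- NULL
  dataset <- stage("input", {
    if (!is.null(config$ped) && !is.null(config$map)) {
      say("input: reading %s / %s", config$ped, config$map)
      read_ped_map(config$ped, config$map)
    } else {
      sim_args <- config$simulate
      sim_args$seed <- seed
      if (!is.null(sim_args$pop_sizes)) sim_args$pop_sizes <-
          unlist(sim_args$pop_sizes)
      sc <- do.call(sim_config, sim_args)
      say("input: simulating %d individuals x %d markers (seed %d)",
          sum(sc$pop_sizes), sc$n_loci, seed)
      sim <- simulate_dataset(sc)
      sim_truth <- sim$truth
      write_tsv(as.data.frame(sim$truth), file.path(output_dir, "sim_truth.tsv"))
      sim$dataset
    }
  })
  manifest$n_individuals <- n_individuals(dataset)
  manifest$n_markers_input <- n_markers(dataset)

  # --- qc ------------------------------------------------------------------
  qc <- stage("qc", {
    cfg <- do.call(qc_config, config$qc)
    out <- run_qc(dataset, cfg)
    say("qc: %d -> %d markers (unmapped %d, MAF %d, call rate %d)",
        out$report$n_input, out$report$n_output,
        out$report$n_removed_unmapped, out$report$n_removed_maf,
        out$report$n_removed_callrate)
    write_qc_report(out$report, file.path(output_dir, "qc_removed.tsv"),
                    file.path(output_dir, "qc_summary.txt"))
    out
  })
  dataset <- qc$dataset
  manifest$qc <- qc$report[c("n_input", "n_removed_unmapped", "n_removed_maf",
                             "n_removed_callrate", "n_output")]

  # --- annotation ----------------------------------------------------------
  annotation <- stage("annotation", {
    if (is.null(config$annotation) || identical(config$annotation, "none"))
      NULL
    else if (identical(config$annotation, "fixture")) {
      ann <- make_annotation_fixture(dataset$markers,
                                     fraction = config$annotation_fraction,
                                     seed = seed + 3L)
      write_annotation_tsv1(ann, file.path(output_dir, "annotation_synthetic.tsv"))
      say("annotation: tiled synthetic fixture, %d genes", nrow(ann))
      ann
    } else {
      dialect <- if (is.null(config$annotation_dialect)) "tsv1"
                 else config$annotation_dialect
      ann <- read_annotation(config$annotation, dialect)
      say("annotation: %s, %d genes", config$annotation, nrow(ann))
      ann
    }
  })
  assignment <- if (!is.null(annotation))
    stage("annotation", assign_snps_to_genes(dataset$markers, annotation,
                                             flank_bp = config$flank_bp))

  # --- scans per grouping --------------------------------------------------
  scan_cfg <- do.call(scan_config, config$scan)
  groupings <- c(list(ALLPOP = NULL), config$groupings)
  manifest$groupings <- list()
  breeds <- sort(unique(dataset$individuals$breed))
  for (gname in names(groupings)) {
    grp <- stage(gname, {
      if (gname == "ALLPOP") all_pop_grouping(dataset)
      else merge_grouping(breeds, groupings[[gname]], name = gname)
    })
    tab <- stage(gname, fst_scan(dataset, grp))
    scan <- stage(gname, select_outliers(tab, scan_cfg))
    s <- attr(tab, "summary")
    say("%s: %d defined loci, mean fst %.4f (sd %.4f), %d outliers",
        gname, s$n_defined, s$mean, s$sd, scan$n_outliers)
    write_fst_table(tab, file.path(output_dir, sprintf("fst_%s.tsv", gname)))
    write_tsv(data.frame(marker_id = scan$marker_id, fst = tab$fst,
                         outlier = scan$outlier_flags),
              file.path(output_dir, sprintf("scan_%s.tsv", gname)))
    track <- per_chromosome_track(tab, scan)
    write_tsv(track, file.path(output_dir, sprintf("track_%s.tsv", gname)))
    if (!is.null(assignment)) {
      gene_rep <- candidate_gene_report(scan, assignment, dataset$markers)
      write_tsv(gene_rep$genes,
                file.path(output_dir, sprintf("genes_%s.tsv", gname)))
      write_tsv(data.frame(marker_id = gene_rep$intergenic_snp_ids),
                file.path(output_dir, sprintf("intergenic_%s.tsv", gname)))
      say("%s: %d candidate genes, %d intergenic outlier SNPs",
          gname, nrow(gene_rep$genes), length(gene_rep$intergenic_snp_ids))
    }
    manifest$groupings[[gname]] <- list(
      n_defined = s$n_defined, mean_fst = s$mean, sd_fst = s$sd,
      thresholds = as.list(scan$thresholds), n_outliers = scan$n_outliers)
    if (gname == "ALLPOP") {
      dc <- stage("distance_correlation",
                  fst_distance_correlation(tab, scan_cfg, seed = seed + 4L))
      write_tsv(as.data.frame(dc),
                file.path(output_dir, "fst_distance_correlation.tsv"))
    }
  }

  # --- pca -----------------------------------------------------------------
  stage("pca", {
    res <- structure_pca(dataset, k = config$pcs)
    write_tsv(res$scores_df, file.path(output_dir, "pca_scores.tsv"))
    write_tsv(data.frame(component = paste0("PC", seq_len(res$k)),
                         variance_fraction = res$variance_fraction),
              file.path(output_dir, "pca_variance.tsv"))
    say("pca: %d components, PC1 %.2f%%, PC2 %.2f%%", res$k,
        100 * res$variance_fraction[1],
        100 * if (res$k > 1) res$variance_fraction[2] else NA)
    manifest$pca <- list(k = res$k,
                         variance_fraction = res$variance_fraction)
  })

  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  say("done")
  message(sprintf("outputs in %s", output_dir))
  invisible(manifest)
}
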