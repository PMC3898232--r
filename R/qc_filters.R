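# Sequential marker quality control: unmapped markers, minor allele
# frequency, call rate.  Individuals are never removed.

#' Quality-control configuration
#'
#' @param maf_threshold markers with pooled minor allele frequency strictly
#'   below this are removed (default 0.05; a marker at exactly the threshold
#'   is retained).
#' @param call_rate_threshold markers genotyped in strictly less than this
#'   fraction of individuals are removed (default 0.90; exact boundary
#'   retained).
#' @param drop_unmapped remove markers with chromosome `"0"`/empty or
#'   position 0 (default `TRUE`).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_threshold = 0.05, call_rate_threshold = 0.90,
                      drop_unmapped = TRUE) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 1,
            call_rate_threshold >= 0, call_rate_threshold <= 1,
            is.logical(drop_unmapped))
  structure(list(maf_threshold = maf_threshold,
                 call_rate_threshold = call_rate_threshold,
                 drop_unmapped = isTRUE(drop_unmapped)),
            class = "qc_config")
}

# Pooled MAF and call rate for every marker; MAF is NA where all calls are
# missing.
#' @keywords internal
#' @noRd
marker_qc_stats <- function(dataset) {
  nn <- unname(colSums(!is.na(dataset$calls)))
  d <- unname(colSums(dataset$calls, na.rm = TRUE))
  f <- ifelse(nn > 0, d / (2 * nn), NA_real_)
  list(maf = pmin(f, 1 - f),
       call_rate = nn / max(1L, n_individuals(dataset)),
       n_nonmissing = nn)
}

#' Pooled minor allele frequency of a marker
#'
#' Allele frequencies are pooled over all individuals regardless of breed:
#' `f` = dosage sum / (2 x non-missing individuals), MAF = `min(f, 1 - f)`.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker_index column index (or marker_id) of the marker; if `NULL`,
#'   a vector of MAFs for all markers is returned (NA where every call is
#'   missing).
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(dataset, marker_index = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  st <- marker_qc_stats(dataset)
  if (is.null(marker_index)) return(st$maf)
  if (is.character(marker_index))
    marker_index <- match(marker_index, dataset$markers$marker_id)
  m <- st$maf[marker_index]
  if (anyNA(m))
    stop("MAF undefined: all calls missing at marker ",
         dataset$markers$marker_id[marker_index[which(is.na(m))[1]]])
  m
}

#' Per-marker call rate
#'
#' @inheritParams compute_maf
#' @return Fraction of individuals with a non-missing call, per marker.
#' @export
compute_call_rate <- function(dataset, marker_index = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  cr <- marker_qc_stats(dataset)$call_rate
  if (is.null(marker_index)) cr else cr[marker_index]
}

#' Run sequential marker quality control
#'
#' Applies three filters in order, each counted on the survivors of the
#' previous step: (1) drop unmapped markers; (2) drop markers with pooled
#' MAF strictly below `maf_threshold`; (3) drop markers with call rate
#' strictly below `call_rate_threshold`.  Markers whose MAF is undefined
#' (every call missing) pass the MAF step and are caught by the call-rate
#' step.  Marker order is preserved among survivors.
#'
#' @param dataset a [genotype_dataset()]; must be non-empty.
#' @param config a [qc_config()].
#' @return A list with `dataset` (the filtered [genotype_dataset()]) and
#'   `report` (class `qc_report`): counts per step satisfying
#'   `n_output = n_input - n_removed_unmapped - n_removed_maf -
#'   n_removed_callrate`, per-input-marker `maf` and `call_rate`, and a
#'   `removed` data frame (marker_id, reason).
#' @export
run_qc <- function(dataset, config = qc_config()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "qc_config"))
  if (n_individuals(dataset) == 0L || n_markers(dataset) == 0L)
    stop("run_qc requires a non-empty dataset")
  st <- marker_qc_stats(dataset)
  n_input <- n_markers(dataset)
  keep <- rep(TRUE, n_input)
  reason <- rep(NA_character_, n_input)

  if (config$drop_unmapped) {
    rm1 <- keep & is_unmapped_marker(dataset$markers$chrom,
                                     dataset$markers$pos_bp)
    reason[rm1] <- "unmapped"
    keep <- keep & !rm1
  }
  n_removed_unmapped <- sum(reason == "unmapped", na.rm = TRUE)

  rm2 <- keep & !is.na(st$maf) & st$maf < config$maf_threshold
  reason[rm2] <- "low_maf"
  keep <- keep & !rm2

  rm3 <- keep & st$call_rate < config$call_rate_threshold
  reason[rm3] <- "low_callrate"
  keep <- keep & !rm3

  report <- structure(list(
    n_input = n_input,
    n_removed_unmapped = n_removed_unmapped,
    n_removed_maf = sum(rm2),
    n_removed_callrate = sum(rm3),
    n_output = sum(keep),
    maf = st$maf,
    call_rate = st$call_rate,
    removed = data.frame(
      marker_id = dataset$markers$marker_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE)
  ), class = "qc_report")
  list(dataset = subset_markers(dataset, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "marker QC: %d input\n  removed unmapped:  %d\n  removed MAF:       %d\n",
    "  removed call rate: %d\n  retained:          %d\n"),
    x$n_input, x$n_removed_unmapped, x$n_removed_maf,
    x$n_removed_callrate, x$n_output))
  invisible(x)
}

#' Write a QC report as TSV plus a summary text block
#'
#' @param report a `qc_report` from [run_qc()].
#' @param tsv_path path for the per-removed-marker TSV (marker_id, reason).
#' @param summary_path optional path for a plain-text count summary.
#' @return Invisibly, `tsv_path`.
#' @export
write_qc_report <- function(report, tsv_path, summary_path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  write_tsv(report$removed, tsv_path)
  if (!is.null(summary_path)) {
    con <- file(summary_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(tsv_path)
}
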