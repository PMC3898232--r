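#' Construct a genotype dataset
#'
#' Bundles a diploid allele-dosage call matrix with its individual and marker
#' metadata.  Calls count copies of `allele_a2` at each marker, so every
#' non-missing entry is 0, 1 or 2; missing calls are `NA`.  On construction
#' markers are sorted by chromosome and base-pair position with unmapped
#' markers (chromosome `"0"`/empty or position 0) placed last.
#'
#' @param calls integer matrix, individuals in rows and markers in columns;
#'   entries in `{0, 1, 2, NA}` counting copies of `allele_a2`.
#' @param individuals data frame with columns `individual_id` (unique) and
#'   `breed`.
#' @param markers data frame with columns `chrom`, `marker_id`, `pos_bp`,
#'   `allele_a1`, `allele_a2`.  Positions are 1-based; `pos_bp = 0` together
#'   with chromosome `"0"` (or empty) flags an unmapped marker.
#' @param sort_markers sort markers into genome order (default `TRUE`).
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `calls`, `individuals` and `markers`.
#' @export
genotype_dataset <- function(calls, individuals, markers, sort_markers = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "breed") %in% names(individuals)))
    stop("individuals must have columns individual_id and breed")
  req <- c("chrom", "marker_id", "pos_bp", "allele_a1", "allele_a2")
  if (!all(req %in% names(markers)))
    stop("markers must have columns ", paste(req, collapse = ", "))
  if (nrow(calls) != nrow(individuals))
    stop(sprintf("call matrix has %d rows but %d individuals are listed",
                 nrow(calls), nrow(individuals)))
  if (ncol(calls) != nrow(markers))
    stop(sprintf("call matrix has %d columns but %d markers are listed",
                 ncol(calls), nrow(markers)))
  if (anyDuplicated(individuals$individual_id))
    stop("individual_id values must be unique")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("calls must be 0, 1, 2 or NA")
  markers$chrom <- as.character(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)
  if (any(markers$pos_bp < 0L, na.rm = TRUE))
    stop("pos_bp must be non-negative")
  if (sort_markers && nrow(markers) > 1L) {
    o <- marker_order(markers$chrom, markers$pos_bp)
    markers <- markers[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  rownames(markers) <- NULL
  rownames(individuals) <- NULL
  rownames(calls) <- individuals$individual_id
  colnames(calls) <- markers$marker_id
  structure(list(calls = calls, individuals = individuals, markers = markers),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  br <- table(x$individuals$breed)
  cat("breeds:", paste(sprintf("%s (%d)", names(br), br), collapse = ", "), "\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
n_individuals <- function(dataset) nrow(dataset$calls)

#' @keywords internal
#' @noRd
n_markers <- function(dataset) ncol(dataset$calls)

#' @keywords internal
#' @noRd
subset_markers <- function(dataset, keep) {
  genotype_dataset(dataset$calls[, keep, drop = FALSE],
                   dataset$individuals,
                   dataset$markers[keep, , drop = FALSE],
                   sort_markers = FALSE)
}

#' Summarize a genotype dataset
#'
#' @param dataset a [genotype_dataset()].
#' @return A list with `n_individuals`, `n_markers`, `breed_counts` (named
#'   integer vector), `chrom_counts` (named integer vector, unmapped markers
#'   under `"unmapped"`), and `missing_fraction`.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  chrom <- dataset$markers$chrom
  chrom[is_unmapped_marker(chrom, dataset$markers$pos_bp)] <- "unmapped"
  nm <- n_individuals(dataset) * n_markers(dataset)
  out <- list(
    n_individuals = n_individuals(dataset),
    n_markers = n_markers(dataset),
    breed_counts = c(table(dataset$individuals$breed)),
    chrom_counts = c(table(chrom)),
    missing_fraction = if (nm > 0) sum(is.na(dataset$calls)) / nm else 0
  )
  class(out) <- "genotype_summary"
  out
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf("%d individuals, %d markers, %.4f missing\n",
              x$n_individuals, x$n_markers, x$missing_fraction))
  cat("breeds:\n"); print(x$breed_counts)
  cat("markers per chromosome:\n"); print(x$chrom_counts)
  invisible(x)
}
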