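# PLINK text PED/MAP input and output.
#
# PED: one individual per row — family ID (used as breed label), individual
# ID, four ignored pedigree/sex/phenotype columns, then two allele columns
# per marker; "0 0" is the missing genotype.  MAP: one marker per row —
# chromosome, marker ID, genetic distance (ignored), base-pair position.

ALLOWED_ALLELES <- c("A", "C", "G", "T", "1", "2", "3", "4")

#' Read PLINK-style PED/MAP files
#'
#' Parses whitespace-delimited PED/MAP text files into a
#' [genotype_dataset()].  For each marker the two observed allele characters
#' are ordered lexicographically and calls are coded as dosages of the
#' larger one (`allele_a2`), a deterministic convention that needs no
#' external reference allele; the Fst estimator is invariant to which allele
#' is counted.  A marker with only one allele observed in-sample carries
#' that allele as `allele_a2` and `"0"` as `allele_a1` (its dosages are all
#' 2), so re-reading the same files always yields the same coding.  The
#' breed label is taken from the PED family-ID column.  Half-called
#' genotypes are rejected rather than silently set missing.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_dataset()] with markers sorted into genome order.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines)) {
    mf <- strsplit(trimws(map_lines), "[ \t]+")
    nfld <- lengths(mf)
    if (any(nfld < 4L))
      stop(sprintf("MAP line %d has %d fields; expected 4 (chrom, id, cM, pos)",
                   which(nfld < 4L)[1], nfld[nfld < 4L][1]))
    markers <- data.frame(
      chrom = vapply(mf, `[`, "", 1L),
      marker_id = vapply(mf, `[`, "", 2L),
      pos_bp = as.integer(vapply(mf, `[`, "", 4L)),
      allele_a1 = NA_character_, allele_a2 = NA_character_,
      stringsAsFactors = FALSE)
    if (anyNA(markers$pos_bp))
      stop("MAP contains a non-integer base-pair position")
  } else {
    markers <- data.frame(chrom = character(), marker_id = character(),
                          pos_bp = integer(), allele_a1 = character(),
                          allele_a2 = character(), stringsAsFactors = FALSE)
  }
  n_mark <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_ind <- length(ped_lines)
  pf <- strsplit(trimws(ped_lines), "[ \t]+")
  nfld <- lengths(pf)
  expected <- 6L + 2L * n_mark
  if (n_ind && any(nfld != expected)) {
    i <- which(nfld != expected)[1]
    stop(sprintf(
      "PED row %d has %d allele columns but MAP lists %d markers (%d expected)",
      i, nfld[i] - 6L, n_mark, 2L * n_mark))
  }
  individuals <- data.frame(
    individual_id = vapply(pf, function(f) f[2L], character(1)),
    breed = vapply(pf, function(f) f[1L], character(1)),
    stringsAsFactors = FALSE)

  calls <- matrix(NA_integer_, n_ind, n_mark)
  if (n_ind && n_mark) {
    am <- do.call(rbind, lapply(pf, function(f) f[-(1:6)]))
    a1 <- am[, seq(1L, 2L * n_mark, by = 2L), drop = FALSE]
    a2 <- am[, seq(2L, 2L * n_mark, by = 2L), drop = FALSE]
    known <- c(ALLOWED_ALLELES, "0")
    bad <- matrix(!(a1 %in% known) | !(a2 %in% known), n_ind, n_mark)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("unknown allele character at PED row %d, marker %s",
                   w[1], markers$marker_id[w[2]]))
    }
    half <- (a1 == "0") != (a2 == "0")
    if (any(half)) {
      w <- which(half, arr.ind = TRUE)[1, ]
      stop(sprintf("half-missing genotype at PED row %d, marker %s",
                   w[1], markers$marker_id[w[2]]))
    }
    for (j in seq_len(n_mark)) {
      obs <- sort(unique(c(a1[, j], a2[, j])))
      obs <- obs[obs != "0"]
      if (length(obs) > 2L)
        stop(sprintf("marker %s has more than two alleles (%s)",
                     markers$marker_id[j], paste(obs, collapse = ",")))
      ref2 <- if (length(obs)) obs[length(obs)] else "0"
      ref1 <- if (length(obs) == 2L) obs[1L] else "0"
      markers$allele_a1[j] <- ref1
      markers$allele_a2[j] <- ref2
      d <- (a1[, j] == ref2) + (a2[, j] == ref2)
      d[a1[, j] == "0"] <- NA_integer_
      calls[, j] <- as.integer(d)
    }
  }
  genotype_dataset(calls, individuals, markers)
}

#' Write PLINK-style PED/MAP files
#'
#' Inverse of [read_ped_map()]: the written files parse back to a dataset
#' equal in individuals, markers and calls.  Missing calls are written as
#' `"0 0"`; the MAP genetic-distance column is written as 0.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  mk <- dataset$markers
  map_lines <- if (nrow(mk)) {
    paste(mk$chrom, mk$marker_id, 0L, mk$pos_bp, sep = "\t")
  } else character()
  writeLines(map_lines, map_path)

  n_ind <- n_individuals(dataset)
  n_mark <- n_markers(dataset)
  geno <- matrix("0 0", n_ind, n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- mk$allele_a1[j]; a2 <- mk$allele_a2[j]
    d <- dataset$calls[, j]
    if (any(!is.na(d) & d < 2L) && (is.na(a1) || a1 == "0"))
      stop(sprintf("marker %s: allele_a1 unknown but dosage < 2 present",
                   mk$marker_id[j]))
    codes <- c(paste(a1, a1), paste(a1, a2), paste(a2, a2))
    ok <- !is.na(d)
    geno[ok, j] <- codes[d[ok] + 1L]
  }
  if (n_ind == 0L) {
    writeLines(character(), ped_path)
    return(invisible(c(ped_path, map_path)))
  }
  lead <- cbind(dataset$individuals$breed, dataset$individuals$individual_id,
                rep("0", n_ind), rep("0", n_ind), rep("0", n_ind),
                rep("-9", n_ind))
  rows <- apply(cbind(lead, geno), 1L, paste, collapse = " ")
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}
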