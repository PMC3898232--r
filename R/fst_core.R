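# Per-locus multi-population Fst by the gamete-level nested ANOVA
# (Weir-Cockerham-type) estimator:
#
#   Fst = (MSP - MSI) / (MSP + (nc - 1) MSI + nc MSG)
#
# where MSP, MSI, MSG are the mean squares among populations, among
# individuals within populations and among gametes within individuals of a
# two-level nested ANOVA on per-gamete allele indicators, and
# nc = (S1 - S2/S1)/(n - 1) corrects for unequal population sizes (S1 total
# sample size, S2 sum of squared group sizes, n non-empty groups).  All
# sample quantities are recomputed per locus from non-missing calls.

#' Define a breed-to-population grouping
#'
#' @param name grouping label (e.g. `"ALLPOP"`, `"CHN_VS_EURO"`).
#' @param assignment named character vector or list mapping each breed label
#'   to a population (group) name; `NA`/`NULL` values exclude a breed from
#'   the contrast entirely.
#' @return An object of class `fst_grouping` with elements `name`,
#'   `assignment` (breed -> 1-based population index, `NA` = excluded),
#'   `pop_names` and `n_pops`.
#' @export
grouping <- function(name, assignment) {
  if (is.list(assignment))
    assignment <- vapply(assignment, function(x)
      if (is.null(x) || length(x) == 0L || is.na(x)) NA_character_
      else as.character(x), character(1))
  assignment <- unlist(assignment)
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be a named breed -> group map")
  pop_names <- sort(unique(assignment[!is.na(assignment)]))
  if (length(pop_names) < 2L)
    stop("a grouping needs at least 2 populations, got ",
         length(pop_names))
  idx <- match(assignment, pop_names)
  names(idx) <- names(assignment)
  structure(list(name = name, assignment = idx, pop_names = pop_names,
                 n_pops = length(pop_names)),
            class = "fst_grouping")
}

#' Grouping treating every breed as its own population
#'
#' @param dataset a [genotype_dataset()].
#' @param name grouping label, default `"ALLPOP"`.
#' @return An `fst_grouping`.
#' @export
all_pop_grouping <- function(dataset, name = "ALLPOP") {
  breeds <- sort(unique(dataset$individuals$breed))
  grouping(name, stats::setNames(breeds, breeds))
}

#' Merge breeds into pooled populations for a pairwise contrast
#'
#' Individuals of merged breeds are pooled and treated as one population by
#' the downstream estimator (e.g. Chinese indigenous vs European commercial,
#' or Northern vs Southern pools).
#'
#' @param breeds character vector of breed labels present in the dataset.
#' @param group_map named map breed -> group name (`NA` excludes a breed);
#'   every breed in `breeds` must appear.
#' @param name grouping label; defaults to the merged group names joined by
#'   `"_VS_"`.
#' @return An `fst_grouping` with one population per distinct group name.
#' @export
merge_grouping <- function(breeds, group_map, name = NULL) {
  if (is.list(group_map))
    group_map <- vapply(group_map, function(x)
      if (is.null(x) || length(x) == 0L || is.na(x)) NA_character_
      else as.character(x), character(1))
  missing_breeds <- setdiff(breeds, names(group_map))
  if (length(missing_breeds))
    stop("breeds not assigned to any group: ",
         paste(missing_breeds, collapse = ", "))
  assignment <- group_map[breeds]
  names(assignment) <- breeds
  grp <- sort(unique(assignment[!is.na(assignment)]))
  if (is.null(name)) name <- paste(grp, collapse = "_VS_")
  grouping(name, assignment)
}

#' @keywords internal
#' @noRd
pop_index_for <- function(dataset, grp) {
  stopifnot(inherits(grp, "fst_grouping"))
  breeds <- dataset$individuals$breed
  unknown <- setdiff(unique(breeds), names(grp$assignment))
  if (length(unknown))
    stop("grouping '", grp$name, "' does not assign breeds: ",
         paste(unknown, collapse = ", "))
  unname(grp$assignment[breeds])
}

#' Sample-size correction factor for unequal group sizes
#'
#' `nc = (S1 - S2/S1)/(n - 1)` over non-empty groups, with S1 the total
#' sample size, S2 the sum of squared group sizes, and n the number of
#' non-empty groups.  For n equal groups of size s, `nc = s`.
#'
#' @param sizes per-population counts of individuals with non-missing calls.
#' @return The scalar correction factor.
#' @export
compute_nc <- function(sizes) {
  sizes <- sizes[sizes > 0]
  n <- length(sizes)
  if (n < 2L)
    stop("insufficient populations: nc needs >= 2 non-empty groups")
  s1 <- sum(sizes)
  s2 <- sum(sizes^2)
  (s1 - s2 / s1) / (n - 1)
}

#' Per-population allele statistics at one locus
#'
#' Counts only individuals with a non-missing call; populations with no data
#' at the locus are dropped (the number of groups shrinks accordingly).
#'
#' @param dataset a [genotype_dataset()].
#' @param grp an `fst_grouping`.
#' @param marker_index column index or marker_id.
#' @return A list with per-population `sizes` (s_i), `p` (allele_a2
#'   frequency), `h` (observed heterozygote proportion), plus pooled `p_bar`
#'   (size-weighted mean frequency), `n` (non-empty groups), `S1`, `S2` and
#'   `marker_id`.
#' @export
pop_locus_stats <- function(dataset, grp, marker_index) {
  if (is.character(marker_index))
    marker_index <- match(marker_index, dataset$markers$marker_id)
  pidx <- pop_index_for(dataset, grp)
  d <- dataset$calls[, marker_index]
  ok <- !is.na(d) & !is.na(pidx)
  d <- d[ok]; g <- pidx[ok]
  sizes <- tabulate(g, nbins = grp$n_pops)
  nonempty <- which(sizes > 0L)
  if (length(nonempty) < 2L)
    stop("insufficient populations: locus has data in ",
         length(nonempty), " population(s)")
  dos <- vapply(nonempty, function(k) sum(d[g == k]), numeric(1))
  het <- vapply(nonempty, function(k) sum(d[g == k] == 1L), numeric(1))
  s <- sizes[nonempty]
  p <- dos / (2 * s)
  list(marker_id = dataset$markers$marker_id[marker_index],
       pop_names = grp$pop_names[nonempty],
       sizes = s, p = p, h = het / s,
       p_bar = sum(s * p) / sum(s),
       n = length(s), S1 = sum(s), S2 = sum(s^2))
}

#' Nested-ANOVA mean squares at one locus
#'
#' Sums of squares of the two-level nested ANOVA on per-gamete allele
#' indicators (populations / individuals within populations / gametes within
#' individuals):
#' `SSP = sum 2 s_i (p_i - p_bar)^2` (df `n - 1`),
#' `SSI = sum (2 s_i p_i (1 - p_i) - s_i h_i / 2)` (df `S1 - n`),
#' `SSG = sum s_i h_i / 2` (df `S1`).
#' Negative sums of squares below 1e-12 (floating-point noise) are clamped
#' to 0.  `MSI` is `NA` when its degrees of freedom are 0, i.e. every
#' population holds a single individual.
#'
#' @param stats output of [pop_locus_stats()].
#' @return A list with `MSP`, `MSI`, `MSG`.
#' @export
anova_mean_squares <- function(stats) {
  s <- stats$sizes; p <- stats$p; h <- stats$h
  ssp <- sum(2 * s * (p - stats$p_bar)^2)
  ssg <- sum(s * h) / 2
  ssi <- sum(2 * s * p * (1 - p)) - ssg
  clamp <- function(x) if (x < 0 && x > -1e-12) 0 else x
  ssp <- clamp(ssp); ssi <- clamp(ssi); ssg <- clamp(ssg)
  df_i <- stats$S1 - stats$n
  list(MSP = ssp / (stats$n - 1),
       MSI = if (df_i > 0) ssi / df_i else NA_real_,
       MSG = ssg / stats$S1)
}

#' Fst estimate at one locus
#'
#' Applies `Fst = (MSP - MSI)/(MSP + (nc - 1) MSI + nc MSG)`.  The estimate
#' is `NA` (undefined) when the denominator is 0 (locus monomorphic in the
#' analysed sample), when MSI has no degrees of freedom, or when fewer than
#' two populations have data.  Negative estimates are retained.
#'
#' @inheritParams pop_locus_stats
#' @return A list of class `fst_record` with `marker_id`, `MSP`, `MSI`,
#'   `MSG`, `n_c`, `fst` and `n_pops_used`.
#' @export
fst_locus <- function(dataset, grp, marker_index) {
  if (is.character(marker_index))
    marker_index <- match(marker_index, dataset$markers$marker_id)
  rec <- list(marker_id = dataset$markers$marker_id[marker_index],
              MSP = NA_real_, MSI = NA_real_, MSG = NA_real_,
              n_c = NA_real_, fst = NA_real_, n_pops_used = NA_integer_)
  class(rec) <- "fst_record"
  stats <- tryCatch(pop_locus_stats(dataset, grp, marker_index),
                    error = function(e) NULL)
  if (is.null(stats)) return(rec)
  ms <- anova_mean_squares(stats)
  nc <- compute_nc(stats$sizes)
  rec$MSP <- ms$MSP; rec$MSI <- ms$MSI; rec$MSG <- ms$MSG
  rec$n_c <- nc; rec$n_pops_used <- stats$n
  if (!is.na(ms$MSI)) {
    denom <- ms$MSP + (nc - 1) * ms$MSI + nc * ms$MSG
    if (denom > 0) rec$fst <- (ms$MSP - ms$MSI) / denom
  }
  rec
}

#' @export
print.fst_record <- function(x, ...) {
  cat(sprintf("fst_record %s: fst=%s (MSP=%.4g MSI=%.4g MSG=%.4g nc=%.4g, %s pops)\n",
              x$marker_id,
              ifelse(is.na(x$fst), "UNDEFINED", sprintf("%.4f", x$fst)),
              x$MSP, x$MSI, x$MSG, x$n_c, x$n_pops_used))
  invisible(x)
}

# Vectorised ANOVA over all loci from per-population count matrices
# S (non-missing individuals), D (dosage sums), H (heterozygote counts),
# each n_pops x n_loci.
#' @keywords internal
#' @noRd
fst_from_counts <- function(S, D, H) {
  L <- ncol(S)
  n <- colSums(S > 0L)
  S1 <- colSums(S)
  S2 <- colSums(S^2)
  ok <- n >= 2L
  nc <- ifelse(ok, (S1 - S2 / pmax(S1, 1)) / pmax(n - 1, 1), NA_real_)
  P <- D / (2 * S)
  P[S == 0] <- 0
  pbar <- ifelse(S1 > 0, colSums(D) / (2 * pmax(S1, 1)), 0)
  ssp <- colSums(2 * S * sweep(P, 2, pbar)^2)
  hsum <- colSums(H)
  ssg <- hsum / 2
  ssi <- colSums(2 * S * P * (1 - P)) - ssg
  ssp <- pmax(ssp, 0); ssi <- pmax(ssi, 0)
  df_i <- S1 - n
  msp <- ifelse(ok, ssp / (n - 1), NA_real_)
  msi <- ifelse(ok & df_i > 0, ssi / pmax(df_i, 1), NA_real_)
  msg <- ifelse(ok, ssg / pmax(S1, 1), NA_real_)
  denom <- msp + (nc - 1) * msi + nc * msg
  fst <- ifelse(ok & !is.na(msi) & !is.na(denom) & denom > 0,
                (msp - msi) / denom, NA_real_)
  data.frame(n_pops_used = as.integer(n), MSP = msp, MSI = msi, MSG = msg,
             n_c = nc, fst = fst)
}

#' Genome-wide per-SNP Fst scan
#'
#' Estimates Fst at every marker for a given breed-to-population grouping,
#' recomputing per-locus sample sizes (and hence nc) from non-missing calls.
#' The summary reports the arithmetic mean and standard deviation of defined
#' per-locus estimates, plus a multilocus ratio-of-sums estimate
#' (sum of numerator components over sum of denominator components), which
#' is reported for reference but not used for outlier thresholds.
#'
#' @param dataset a (typically QC-filtered) [genotype_dataset()].
#' @param grp an `fst_grouping`; defaults to [all_pop_grouping()].
#' @return A data frame of class `fst_table` with one row per marker in map
#'   order: `marker_id`, `chrom`, `pos_bp`, `n_pops_used`, `MSP`, `MSI`,
#'   `MSG`, `n_c`, `fst` (`NA` = undefined).  Attributes: `grouping`
#'   (name), `summary` (list with `n_defined`, `mean`, `sd`,
#'   `ratio_of_sums`).
#' @export
fst_scan <- function(dataset, grp = all_pop_grouping(dataset)) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  pidx <- pop_index_for(dataset, grp)
  keep <- !is.na(pidx)
  calls <- dataset$calls[keep, , drop = FALSE]
  g <- pidx[keep]
  nonmiss <- !is.na(calls)
  calls0 <- calls
  calls0[!nonmiss] <- 0L
  S <- rowsum(nonmiss + 0L, g)
  D <- rowsum(calls0, g)
  H <- rowsum((calls0 == 1L & nonmiss) + 0L, g)
  res <- fst_from_counts(S, D, H)

  tab <- cbind(data.frame(marker_id = dataset$markers$marker_id,
                          chrom = dataset$markers$chrom,
                          pos_bp = dataset$markers$pos_bp,
                          stringsAsFactors = FALSE),
               res)
  v <- tab$fst[!is.na(tab$fst)]
  num <- tab$MSP - tab$MSI
  den <- tab$MSP + (tab$n_c - 1) * tab$MSI + tab$n_c * tab$MSG
  def <- !is.na(tab$fst)
  summary <- list(
    n_defined = length(v),
    mean = if (length(v)) mean(v) else NA_real_,
    sd = if (length(v) > 1) stats::sd(v) else NA_real_,
    ratio_of_sums = if (any(def)) sum(num[def]) / sum(den[def]) else NA_real_)
  structure(tab, grouping = grp$name, summary = summary,
            class = c("fst_table", "data.frame"))
}

#' @export
print.fst_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("fst_table [%s]: %d markers, %d defined; mean=%.4f sd=%.4f (ratio-of-sums %.4f)\n",
              attr(x, "grouping"), nrow(x), s$n_defined, s$mean, s$sd,
              s$ratio_of_sums))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write an Fst table as TSV
#'
#' @param table an `fst_table` from [fst_scan()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fst_table <- function(table, path) {
  stopifnot(inherits(table, "fst_table"))
  write_tsv(as.data.frame(table), path)
}
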