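# Balding-Nichols multi-breed genotype simulator with planted selected loci
# and planted quality-control defects, the validation backbone for every
# analysis stage: under this model the nested-ANOVA Fst estimator is
# consistent for the per-population drift parameter F, giving a clean
# recovery target.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the analysis is built for: nine pig
#' breeds with sample sizes 35, 22, 23, 25, 24, 40, 18, 26, 22 (total 235)
#' — six Chinese indigenous breeds (TC, BM, LW, WZS, NX, LC), two European
#' commercial breeds (Landrace, LargeWhite) and one developed breed (YT) —
#' genotyped at tens of thousands of autosomal + X-chromosome SNPs.
#'
#' @param pop_sizes named integer vector: individuals per population (names
#'   are breed labels).
#' @param n_loci total simulated markers.
#' @param drift_F Balding-Nichols drift parameter(s) in (0, 1); scalar or
#'   one value per population.
#' @param ancestral_freq_range interval for uniform ancestral allele
#'   frequency draws.
#' @param n_selected number of planted divergent (selected) loci.
#' @param selected_mode `"fixed_difference"` (frequency 0.98 in the
#'   `group_split` populations, 0.02 elsewhere) or `"boosted_F"` (redraw
#'   with `boosted_F`).
#' @param boosted_F drift value used by `selected_mode = "boosted_F"`.
#' @param group_split breed labels of the populations that diverge at
#'   selected loci (default the European commercial pair).
#' @param n_unmapped,n_low_maf,n_low_callrate planted QC-defect counts;
#'   defect classes are mutually exclusive and never overlap selected loci,
#'   so QC removal counts are exactly predictable.
#' @param min_neutral_maf neutral mapped markers are nudged (by flipping the
#'   minimal number of homozygous calls to heterozygous) so their pooled
#'   empirical MAF is at least this value, guaranteeing they survive the MAF
#'   filter; set to 0 to disable.
#' @param ld_block_size loci per linkage block (1 = independent loci); loci
#'   within a block share their ancestral and population frequency draws
#'   plus a small per-locus jitter.
#' @param ld_jitter_sd standard deviation of the within-block frequency
#'   jitter.
#' @param chrom_labels chromosome labels over which mapped markers are laid
#'   out evenly (default 18 autosomes plus X).
#' @param chrom_length_bp length of each chromosome in bp.
#' @param seed integer seed; all draws flow from it (frequencies use `seed`,
#'   planted-outlier placement `seed + 1`, genotypes and defect injection
#'   `seed + 2`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pop_sizes = c(TC = 35, BM = 22, LW = 23, WZS = 25,
                                     NX = 24, LC = 40, Landrace = 18,
                                     LargeWhite = 26, YT = 22),
                       n_loci = 45652,
                       drift_F = 0.2,
                       ancestral_freq_range = c(0.05, 0.95),
                       n_selected = 0L,
                       selected_mode = c("fixed_difference", "boosted_F"),
                       boosted_F = 0.6,
                       group_split = c("Landrace", "LargeWhite"),
                       n_unmapped = 0L, n_low_maf = 0L, n_low_callrate = 0L,
                       min_neutral_maf = 0.05,
                       ld_block_size = 1L, ld_jitter_sd = 0.01,
                       chrom_labels = c(as.character(1:18), "X"),
                       chrom_length_bp = 1.4e8,
                       seed = 1L) {
  selected_mode <- match.arg(selected_mode)
  if (is.null(names(pop_sizes)))
    names(pop_sizes) <- paste0("POP", seq_along(pop_sizes))
  stopifnot(all(pop_sizes >= 1), n_loci >= 1,
            all(drift_F > 0 & drift_F < 1),
            length(drift_F) %in% c(1L, length(pop_sizes)),
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2],
            n_selected >= 0, n_unmapped >= 0, n_low_maf >= 0,
            n_low_callrate >= 0,
            n_selected + n_unmapped + n_low_maf + n_low_callrate <= n_loci,
            ld_block_size >= 1, chrom_length_bp > 0,
            min_neutral_maf >= 0, min_neutral_maf < 0.5)
  if (!all(group_split %in% names(pop_sizes))) {
    if (n_selected > 0)
      stop("group_split names not among pop_sizes names")
    group_split <- intersect(group_split, names(pop_sizes))
  }
  structure(list(pop_sizes = pop_sizes, n_loci = as.integer(n_loci),
                 drift_F = rep_len(drift_F, length(pop_sizes)),
                 ancestral_freq_range = ancestral_freq_range,
                 n_selected = as.integer(n_selected),
                 selected_mode = selected_mode, boosted_F = boosted_F,
                 group_split = group_split,
                 n_unmapped = as.integer(n_unmapped),
                 n_low_maf = as.integer(n_low_maf),
                 n_low_callrate = as.integer(n_low_callrate),
                 min_neutral_maf = min_neutral_maf,
                 ld_block_size = as.integer(ld_block_size),
                 ld_jitter_sd = ld_jitter_sd,
                 chrom_labels = as.character(chrom_labels),
                 chrom_length_bp = chrom_length_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw ancestral and per-population allele frequencies
#'
#' Ancestral frequencies are uniform on `ancestral_freq_range`; population
#' `i` draws its frequency from
#' `Beta(p (1 - F_i)/F_i, (1 - p)(1 - F_i)/F_i)` independently per locus
#' (per block when `ld_block_size > 1`, with one shared draw per block plus
#' per-locus jitter), so that `Var(p_i | p) = F_i p (1 - p)`.
#'
#' @param config a [sim_config()].
#' @return A list with `ancestral` (length `n_loci`), `pop_freq`
#'   (populations x loci matrix) and `is_selected` (all `FALSE`; see
#'   [plant_outliers()]).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$n_loci
    n_pops <- length(config$pop_sizes)
    bs <- config$ld_block_size
    n_draw <- if (bs > 1L) ceiling(L / bs) else L
    anc_d <- stats::runif(n_draw, config$ancestral_freq_range[1],
                          config$ancestral_freq_range[2])
    pf_d <- matrix(NA_real_, n_pops, n_draw)
    for (i in seq_len(n_pops)) {
      f <- config$drift_F[i]
      pf_d[i, ] <- stats::rbeta(n_draw, anc_d * (1 - f) / f,
                                (1 - anc_d) * (1 - f) / f)
    }
    if (bs > 1L) {
      idx <- rep(seq_len(n_draw), each = bs)[seq_len(L)]
      ancestral <- anc_d[idx]
      pop_freq <- pf_d[, idx, drop = FALSE]
      jit <- matrix(stats::rnorm(n_pops * L, 0, config$ld_jitter_sd),
                    n_pops, L)
      pop_freq <- pmin(pmax(pop_freq + jit, 1e-4), 1 - 1e-4)
    } else {
      ancestral <- anc_d
      pop_freq <- pf_d
    }
    rownames(pop_freq) <- names(config$pop_sizes)
    list(ancestral = ancestral, pop_freq = pop_freq,
         is_selected = rep(FALSE, L))
  })
}

#' Plant divergently selected loci
#'
#' Overwrites the population frequencies of `n_selected` randomly chosen
#' mapped loci.  In `"fixed_difference"` mode the `group_split` populations
#' are set to frequency 0.98 and all others to 0.02 (a near-fixed
#' difference, expected per-SNP Fst near 1 in large samples); in
#' `"boosted_F"` mode the frequencies are redrawn from the Balding-Nichols
#' model with `boosted_F`.  Loci that will be flagged unmapped (the last
#' `n_unmapped` loci) are never selected, so planted selected loci always
#' survive quality control.
#'
#' @param freqs output of [simulate_frequencies()].
#' @param config the same [sim_config()].
#' @return `freqs` with modified `pop_freq` and `is_selected` truth flags.
#' @export
plant_outliers <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_selected == 0L) return(freqs)
  with_seed(config$seed + 1L, {
    L <- config$n_loci
    eligible <- seq_len(L - config$n_unmapped)
    sel <- sort(sample(eligible, config$n_selected))
    split_pops <- names(config$pop_sizes) %in% config$group_split
    if (config$selected_mode == "fixed_difference") {
      freqs$pop_freq[split_pops, sel] <- 0.98
      freqs$pop_freq[!split_pops, sel] <- 0.02
    } else {
      f <- config$boosted_F
      p <- freqs$ancestral[sel]
      for (i in seq_len(nrow(freqs$pop_freq)))
        freqs$pop_freq[i, sel] <- stats::rbeta(length(sel),
                                               p * (1 - f) / f,
                                               (1 - p) * (1 - f) / f)
    }
    freqs$is_selected[sel] <- TRUE
    freqs
  })
}

# Marker layout: mapped loci split into contiguous per-chromosome blocks
# with evenly spaced positions; unmapped defect loci carry chrom "0"/pos 0
# and sit at the end, so the constructed dataset is already in genome order.
#' @keywords internal
#' @noRd
layout_markers <- function(config) {
  L <- config$n_loci
  n_mapped <- L - config$n_unmapped
  ids <- sprintf("SNP%06d", seq_len(L))
  chrom <- rep("0", L)
  pos <- rep(0L, L)
  if (n_mapped > 0L) {
    nch <- length(config$chrom_labels)
    per <- diff(floor(seq(0, n_mapped, length.out = nch + 1L)))
    chrom[seq_len(n_mapped)] <- rep(config$chrom_labels, per)
    pos[seq_len(n_mapped)] <- unlist(lapply(per, function(k) {
      if (k == 0L) return(integer(0))
      spacing <- floor(config$chrom_length_bp / (k + 1L))
      as.integer(spacing * seq_len(k))
    }), use.names = FALSE)
  }
  data.frame(chrom = chrom, marker_id = ids, pos_bp = pos,
             allele_a1 = "A", allele_a2 = "G", stringsAsFactors = FALSE)
}

#' Sample genotypes and inject planted QC defects
#'
#' Individual dosages are Binomial(2, population frequency) draws
#' (Hardy-Weinberg within populations).  QC defects are then injected on
#' mutually exclusive, non-selected loci: the last `n_unmapped` markers get
#' chromosome `"0"` and position 0; `n_low_maf` markers have their calls
#' overwritten so the pooled MAF is about 0.02 (always below 0.05);
#' `n_low_callrate` markers get just over 10% of calls masked missing.
#' Finally, neutral mapped markers whose empirical pooled MAF fell below
#' `min_neutral_maf` by sampling noise are nudged up by flipping homozygous
#' calls to heterozygous, so the QC truth table is exact.
#'
#' @param freqs output of [simulate_frequencies()] /[plant_outliers()].
#' @param config the same [sim_config()].
#' @return A list with `dataset` (a [genotype_dataset()]) and `truth` (class
#'   `sim_truth`): per-marker `is_selected`, `defect_class`
#'   (`none`/`unmapped`/`low_maf`/`low_callrate`), `ancestral_freq`, with
#'   the population frequency matrix as attribute `pop_freq`.
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    L <- config$n_loci
    sizes <- config$pop_sizes
    N <- sum(sizes)
    calls <- matrix(NA_integer_, N, L)
    row0 <- 0L
    for (i in seq_along(sizes)) {
      s <- sizes[[i]]
      calls[row0 + seq_len(s), ] <-
        matrix(stats::rbinom(s * L, 2L, rep(freqs$pop_freq[i, ], each = s)),
               s, L)
      row0 <- row0 + s
    }
    individuals <- data.frame(
      individual_id = unlist(lapply(seq_along(sizes), function(i)
        sprintf("%s_%02d", names(sizes)[i], seq_len(sizes[[i]])))),
      breed = rep(names(sizes), sizes),
      stringsAsFactors = FALSE)
    markers <- layout_markers(config)

    defect <- rep("none", L)
    if (config$n_unmapped > 0L)
      defect[seq(L - config$n_unmapped + 1L, L)] <- "unmapped"
    candidates <- which(defect == "none" & !freqs$is_selected)
    n_def <- config$n_low_maf + config$n_low_callrate
    if (n_def > length(candidates))
      stop("not enough neutral mapped loci to host planted QC defects")
    if (n_def > 0L) {
      picked <- sample(candidates, n_def)
      lm <- picked[seq_len(config$n_low_maf)]
      lc <- setdiff(picked, lm)
      defect[lm] <- "low_maf"
      defect[lc] <- "low_callrate"
      m_het <- floor(0.04 * N)                 # pooled freq <= 0.02 < 0.05
      for (j in lm) {
        calls[, j] <- 0L
        if (m_het > 0L) calls[sample(N, m_het), j] <- 1L
      }
      m_miss <- floor(0.10 * N) + 1L           # call rate strictly < 0.90
      for (j in lc) calls[sample(N, m_miss), j] <- NA_integer_
    }

    if (config$min_neutral_maf > 0) {
      fixable <- which(defect %in% c("none", "low_callrate") &
                       !freqs$is_selected)
      nn <- colSums(!is.na(calls[, fixable, drop = FALSE]))
      ds <- colSums(calls[, fixable, drop = FALSE], na.rm = TRUE)
      minor <- pmin(ds, 2L * nn - ds)
      target <- ceiling(config$min_neutral_maf * 2 * nn)
      for (k in which(minor < target)) {
        j <- fixable[k]
        need <- target[k] - minor[k]
        from <- if (ds[k] <= nn[k]) 0L else 2L  # flip the major homozygote
        cand <- which(!is.na(calls[, j]) & calls[, j] == from)
        flip <- cand[seq_len(min(need, length(cand)))]
        calls[flip, j] <- 1L
      }
    }

    dataset <- genotype_dataset(calls, individuals, markers,
                                sort_markers = FALSE)
    truth <- data.frame(marker_id = markers$marker_id,
                        is_selected = freqs$is_selected,
                        defect_class = defect,
                        ancestral_freq = freqs$ancestral,
                        stringsAsFactors = FALSE)
    attr(truth, "pop_freq") <- freqs$pop_freq
    class(truth) <- c("sim_truth", "data.frame")
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate a complete multi-breed genotype dataset
#'
#' Runs [simulate_frequencies()], [plant_outliers()] and
#' [simulate_genotypes()] in order.  Identical configurations (including
#' the seed) yield byte-identical datasets and truth tables.
#'
#' @param config a [sim_config()].
#' @return A list with `dataset`, `truth` and `frequencies`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  freqs <- simulate_frequencies(config)
  freqs <- plant_outliers(freqs, config)
  out <- simulate_genotypes(freqs, config)
  out$frequencies <- freqs
  out
}

#' Tile a synthetic gene annotation over simulated markers
#'
#' Walks mapped markers per chromosome in blocks of `markers_per_gene`
#' consecutive markers; each block becomes a gene (spanning its markers
#' with a 100 bp margin) with probability `fraction`, so about that
#' fraction of mapped markers falls inside gene spans.
#'
#' @param markers markers data frame of a [genotype_dataset()].
#' @param fraction target fraction of mapped markers inside genes.
#' @param markers_per_gene consecutive markers spanned by one gene.
#' @param seed seed for block inclusion draws.
#' @return A `gene_annotation` data frame.
#' @export
make_annotation_fixture <- function(markers, fraction = 0.6,
                                    markers_per_gene = 5L, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, markers_per_gene >= 1)
  mapped <- which(!is_unmapped_marker(markers$chrom, markers$pos_bp))
  rows <- list()
  gid <- 0L
  with_seed(seed, {
    for (ch in unique(markers$chrom[mapped])) {
      idx <- mapped[markers$chrom[mapped] == ch]
      idx <- idx[order(markers$pos_bp[idx])]
      starts <- seq(1L, length(idx), by = markers_per_gene)
      for (s in starts) {
        block <- idx[s:min(s + markers_per_gene - 1L, length(idx))]
        take <- if (fraction >= 1) TRUE
                else if (fraction <= 0) FALSE
                else stats::runif(1) < fraction
        if (!take) next
        gid <- gid + 1L
        rows[[gid]] <- data.frame(
          gene_id = sprintf("GENE%05d", gid), chrom = ch,
          start_bp = max(1L, min(markers$pos_bp[block]) - 100L),
          end_bp = max(markers$pos_bp[block]) + 100L,
          strand = if (gid %% 2L) "+" else "-",
          stringsAsFactors = FALSE)
      }
    }
  })
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(),
               strand = character(), stringsAsFactors = FALSE)
  o <- marker_order(ann$chrom, ann$start_bp)
  ann <- ann[o, , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
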