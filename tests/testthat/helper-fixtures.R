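# Shared fixtures: tiny dataset builders and the independent
# gamete-expansion nested-ANOVA oracle used to validate the Fst estimator.

toy_dataset <- function(calls, breeds, chrom = NULL, pos = NULL,
                        sort_markers = TRUE) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  genotype_dataset(
    calls,
    data.frame(individual_id = sprintf("ind%03d", seq_len(nrow(calls))),
               breed = breeds, stringsAsFactors = FALSE),
    data.frame(chrom = chrom, marker_id = sprintf("m%03d", seq_len(L)),
               pos_bp = pos, allele_a1 = "A", allele_a2 = "G",
               stringsAsFactors = FALSE),
    sort_markers = sort_markers)
}

random_dataset <- function(n_pops, sizes, L, miss_rate = 0.1) {
  N <- sum(sizes)
  breeds <- rep(sprintf("B%02d", seq_len(n_pops)), sizes)
  p <- matrix(stats::runif(n_pops * L, 0.02, 0.98), n_pops, L)
  calls <- matrix(stats::rbinom(N * L, 2, p[rep(seq_len(n_pops), sizes), ]),
                  N, L)
  if (miss_rate > 0) calls[stats::runif(N * L) < miss_rate] <- NA
  toy_dataset(calls, breeds)
}

# Literal two-level nested ANOVA on expanded gamete indicators: every
# individual becomes two 0/1 gametes, sums of squares are accumulated by
# explicit loops over populations, individuals and gametes.  Fully
# independent of the package's closed-form path.
oracle_fst <- function(dosages, pops) {
  keep <- !is.na(dosages) & !is.na(pops)
  d <- dosages[keep]
  pop <- droplevels(factor(pops[keep]))
  if (nlevels(pop) < 2) return(NA_real_)
  g1 <- as.numeric(d >= 1)
  g2 <- as.numeric(d == 2)
  y <- c(g1, g2)
  ind <- rep(seq_along(d), 2)
  pg <- rep(as.integer(pop), 2)
  grand <- mean(y)
  SSP <- 0; SSI <- 0; SSG <- 0
  for (k in seq_len(nlevels(pop))) {
    yk <- y[pg == k]
    SSP <- SSP + length(yk) * (mean(yk) - grand)^2
    for (i in unique(ind[pg == k])) {
      yi <- y[ind == i & pg == k]
      SSI <- SSI + length(yi) * (mean(yi) - mean(yk))^2
      SSG <- SSG + sum((yi - mean(yi))^2)
    }
  }
  s <- as.vector(table(pop))
  n <- nlevels(pop)
  S1 <- length(d)
  if (S1 - n <= 0) return(NA_real_)
  MSP <- SSP / (n - 1)
  MSI <- SSI / (S1 - n)
  MSG <- SSG / S1
  nc <- (S1 - sum(s^2) / S1) / (n - 1)
  den <- MSP + (nc - 1) * MSI + nc * MSG
  if (den <= 0) return(NA_real_)
  (MSP - MSI) / den
}

cluster_purity <- function(clusters, labels) {
  sum(apply(table(clusters, labels), 1, max)) / length(labels)
}
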