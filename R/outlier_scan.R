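# Empirical upper-quantile outlier detection on the genome-wide Fst
# distribution, per-chromosome track export, and the Fst-vs-distance
# correlation diagnostic.

#' Outlier-scan configuration
#'
#' @param quantiles empirical quantiles for which thresholds are reported
#'   (default `c(0.975, 0.99)`, the 97.5% and 99% lines).
#' @param selection_quantile quantile used to call outliers (default 0.99,
#'   i.e. the upper 1% of the distribution); must be one of `quantiles`.
#' @param distance_bin_bp width of the distance bins for the Fst-correlation
#'   diagnostic (default 50 kb).
#' @param max_distance_bp largest pair separation considered (default 1 Mb).
#' @param max_pairs_per_bin cap on sampled pairs per distance bin.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(quantiles = c(0.975, 0.99),
                        selection_quantile = 0.99,
                        distance_bin_bp = 50000,
                        max_distance_bp = 1e6,
                        max_pairs_per_bin = 10000) {
  stopifnot(all(quantiles > 0 & quantiles < 1),
            length(selection_quantile) == 1L,
            distance_bin_bp > 0, max_distance_bp >= distance_bin_bp,
            max_pairs_per_bin >= 10)
  if (!selection_quantile %in% quantiles)
    stop("selection_quantile must be one of the configured quantiles")
  structure(list(quantiles = sort(quantiles),
                 selection_quantile = selection_quantile,
                 distance_bin_bp = distance_bin_bp,
                 max_distance_bp = max_distance_bp,
                 max_pairs_per_bin = max_pairs_per_bin),
            class = "scan_config")
}

#' Empirical upper-quantile threshold
#'
#' The threshold is the order statistic of 1-based rank `ceiling(q * N)`
#' among the `N` defined values (no interpolation; the threshold is always
#' an element of the input).  Outliers are values strictly greater than the
#' threshold, so with `N` distinct values exactly `N - ceiling(q * N)` loci
#' exceed it.  A small guard (1e-9) protects `ceiling` against
#' floating-point noise when `q * N` is an exact integer.
#'
#' @param fst_values numeric vector of per-locus estimates (`NA`s dropped).
#' @param q quantile in (0, 1).
#' @return The threshold value.
#' @export
empirical_threshold <- function(fst_values, q) {
  v <- fst_values[!is.na(fst_values)]
  if (!length(v)) stop("empirical_threshold: no defined values")
  stopifnot(q > 0, q < 1)
  r <- as.integer(ceiling(q * length(v) - 1e-9))
  sort(v)[max(1L, r)]
}

#' Flag outlier SNPs in the upper tail of the Fst distribution
#'
#' Thresholds are computed for every configured quantile over the defined
#' Fst values only; flags are assigned at `selection_quantile` using the
#' strictly-greater rule.  Undefined (monomorphic) loci are never flagged
#' and do not enter the empirical distribution.
#'
#' @param table an `fst_table` from [fst_scan()].
#' @param config a [scan_config()].
#' @return A list of class `scan_result`: `thresholds` (named by quantile),
#'   `outlier_flags` (logical per marker), `n_outliers`, `n_defined`,
#'   `selection_quantile`, `marker_id`.
#' @export
select_outliers <- function(table, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  vals <- table$fst
  thresholds <- vapply(config$quantiles,
                       function(q) empirical_threshold(vals, q), numeric(1))
  names(thresholds) <- vapply(config$quantiles, function(q) format(q),
                              character(1))
  thr <- thresholds[[match(config$selection_quantile, config$quantiles)]]
  flags <- !is.na(vals) & vals > thr
  structure(list(thresholds = thresholds,
                 outlier_flags = flags,
                 n_outliers = sum(flags),
                 n_defined = sum(!is.na(vals)),
                 selection_quantile = config$selection_quantile,
                 marker_id = table$marker_id),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d/%d defined loci flagged at q=%s\nthresholds:\n",
              x$n_outliers, x$n_defined, format(x$selection_quantile)))
  print(x$thresholds)
  invisible(x)
}

#' Per-chromosome Fst track
#'
#' Emits mapped markers grouped by chromosome and ordered by position, with
#' positions in Mb and the outlier flag attached — the tabular content of a
#' per-chromosome genome-scan (Manhattan-style) plot, consumable by any
#' plotting tool.
#'
#' @param table an `fst_table`.
#' @param result optional `scan_result` over the same markers; if supplied,
#'   an `outlier` column is attached and thresholds stored as an attribute.
#' @return A data frame (`chrom`, `pos_mb`, `marker_id`, `fst`[, `outlier`])
#'   with attribute `thresholds`.
#' @export
per_chromosome_track <- function(table, result = NULL) {
  mapped <- !is_unmapped_marker(table$chrom, table$pos_bp)
  df <- data.frame(chrom = table$chrom[mapped],
                   pos_mb = table$pos_bp[mapped] / 1e6,
                   marker_id = table$marker_id[mapped],
                   fst = table$fst[mapped],
                   stringsAsFactors = FALSE)
  thr <- NULL
  if (!is.null(result)) {
    stopifnot(inherits(result, "scan_result"))
    df$outlier <- result$outlier_flags[mapped]
    thr <- result$thresholds
  }
  o <- marker_order(df$chrom, as.integer(round(df$pos_mb * 1e6)))
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "thresholds") <- thr
  df
}

#' Correlation of Fst between SNP pairs as a function of distance
#'
#' For each distance bin, same-chromosome SNP pairs whose separation falls
#' in the bin are collected (uniformly subsampled to `max_pairs_per_bin`
#' with a seeded generator when a bin overflows) and the Pearson correlation
#' between the two members' Fst values is computed with each pair entered
#' symmetrically, i.e. both (x, y) and (y, x).  Bins with fewer than 10
#' pairs are reported with `correlation = NA`.
#'
#' @param table an `fst_table` (markers in map order).
#' @param config a [scan_config()] supplying bin width, maximum distance and
#'   the per-bin sampling cap.
#' @param seed seed for pair subsampling (default 1).
#' @return A data frame of class `distance_correlation`: `bin_start_bp`,
#'   `bin_end_bp`, `n_pairs` (collected), `n_used` (after capping),
#'   `correlation`.
#' @export
fst_distance_correlation <- function(table, config = scan_config(), seed = 1L) {
  stopifnot(inherits(config, "scan_config"))
  ok <- !is.na(table$fst) & !is_unmapped_marker(table$chrom, table$pos_bp)
  chroms <- unique(table$chrom[ok])
  ii <- integer(0); jj <- integer(0); dd <- integer(0)
  idx_all <- which(ok)
  for (ch in chroms) {
    idx <- idx_all[table$chrom[idx_all] == ch]
    if (length(idx) < 2L) next
    idx <- idx[order(table$pos_bp[idx])]
    pos <- table$pos_bp[idx]
    hi <- findInterval(pos + config$max_distance_bp, pos)
    cnt <- hi - seq_along(pos)
    cnt[cnt < 0L] <- 0L
    if (!sum(cnt)) next
    i <- rep(seq_along(pos), cnt)
    j <- i + sequence(cnt)
    d <- pos[j] - pos[i]
    keep <- d >= 1L & d <= config$max_distance_bp
    ii <- c(ii, idx[i[keep]]); jj <- c(jj, idx[j[keep]])
    dd <- c(dd, d[keep])
  }
  n_bins <- ceiling(config$max_distance_bp / config$distance_bin_bp)
  out <- data.frame(
    bin_start_bp = (seq_len(n_bins) - 1L) * config$distance_bin_bp,
    bin_end_bp = pmin(seq_len(n_bins) * config$distance_bin_bp,
                      config$max_distance_bp),
    n_pairs = 0L, n_used = 0L, correlation = NA_real_)
  if (length(dd)) {
    bin <- pmin(ceiling(dd / config$distance_bin_bp), n_bins)
    with_seed(seed, {
      for (b in sort(unique(bin))) {
        sel <- which(bin == b)
        out$n_pairs[b] <- length(sel)
        if (length(sel) > config$max_pairs_per_bin)
          sel <- sample(sel, config$max_pairs_per_bin)
        out$n_used[b] <- length(sel)
        if (length(sel) >= 10L) {
          x <- table$fst[ii[sel]]; y <- table$fst[jj[sel]]
          xs <- c(x, y); ys <- c(y, x)
          if (stats::sd(xs) > 0 && stats::sd(ys) > 0)
            out$correlation[b] <- stats::cor(xs, ys)
        }
      }
    })
  }
  class(out) <- c("distance_correlation", "data.frame")
  out
}
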