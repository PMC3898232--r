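# Population-structure PCA on the genotype matrix with the drift-scaled
# (allele-frequency) standardization standard in population genetics.

#' Standardize a genotype matrix for structure PCA
#'
#' Missing calls are imputed to the per-marker mean dosage (which
#' contributes zero after centering); each marker column is centered by its
#' mean dosage `2*p_hat` and scaled by `sqrt(2*p_hat*(1 - p_hat))`, the
#' binomial (drift) standard deviation.  Monomorphic columns (estimated
#' allele frequency 0 or 1) and fully missing columns are dropped with a
#' warning.
#'
#' @param dataset a (typically QC-filtered) [genotype_dataset()].
#' @return A numeric matrix (individuals x polymorphic markers) with
#'   attribute `dropped_markers` (marker ids removed).
#' @export
standardize_genotypes <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$calls
  storage.mode(g) <- "double"
  cm <- colMeans(g, na.rm = TRUE)           # 2 * p_hat, NaN if all missing
  p <- cm / 2
  drop <- !is.finite(p) | p <= 0 | p >= 1
  if (any(drop))
    warning(sprintf("dropping %d monomorphic or fully missing marker(s)",
                    sum(drop)))
  keep <- which(!drop)
  if (!length(keep)) stop("no polymorphic markers to standardize")
  g <- g[, keep, drop = FALSE]
  cm <- cm[keep]; p <- p[keep]
  na <- which(is.na(g), arr.ind = TRUE)
  if (nrow(na)) g[na] <- cm[na[, 2L]]
  x <- sweep(g, 2L, cm)
  x <- sweep(x, 2L, sqrt(2 * p * (1 - p)), "/")
  attr(x, "dropped_markers") <- dataset$markers$marker_id[drop]
  x
}

#' Principal component analysis of a standardized genotype matrix
#'
#' Scores are the projections onto the top-`k` right singular directions of
#' the standardized matrix, computed from the eigendecomposition of the
#' individual-by-individual cross-product.  `variance_fraction[j]` is
#' eigenvalue j over the sum of all eigenvalues, so over the full rank the
#' fractions sum to 1.  A deterministic sign convention is applied: each
#' component's marker-loading vector is flipped so its sum is non-negative.
#'
#' @param x standardized matrix from [standardize_genotypes()] (individuals
#'   in rows).
#' @param k number of components to retain; truncated to the numerical rank
#'   with a warning if it exceeds it.
#' @return A list of class `pca_result` with `scores` (n x k, rownames kept
#'   from `x`), `loadings` (markers x k), `variance_fraction` (length k),
#'   `eigenvalues` (all), and `k`.
#' @export
run_pca <- function(x, k = 10L) {
  x <- as.matrix(x)
  if (k < 1L || k > min(dim(x)))
    stop("k must be between 1 and min(n_individuals, n_markers)")
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  total <- sum(lam)
  if (total <= 0) stop("zero total variance")
  rank <- sum(lam > lam[1L] * 1e-9)
  if (k > rank) {
    warning(sprintf("k = %d exceeds numerical rank %d; truncating", k, rank))
    k <- rank
  }
  d <- sqrt(lam[seq_len(k)])
  u <- e$vectors[, seq_len(k), drop = FALSE]
  v <- sweep(crossprod(x, u), 2L, d, "/")
  flip <- ifelse(colSums(v) < 0, -1, 1)
  v <- sweep(v, 2L, flip, "*")
  u <- sweep(u, 2L, flip, "*")
  scores <- sweep(u, 2L, d, "*")
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(v) <- colnames(scores)
  structure(list(scores = scores, loadings = v,
                 variance_fraction = lam[seq_len(k)] / total,
                 eigenvalues = lam, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d individuals, %d components\n",
              nrow(x$scores), x$k))
  cat("variance fractions:",
      paste(sprintf("%.4f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Structure PCA of a genotype dataset
#'
#' Convenience wrapper: [standardize_genotypes()] then [run_pca()], with
#' breed labels attached to the scores.
#'
#' @param dataset a [genotype_dataset()].
#' @param k components to retain.
#' @return A `pca_result` with an extra element `scores_df`: a data frame
#'   `individual_id`, `breed`, `PC1..PCk`.
#' @export
structure_pca <- function(dataset, k = 10L) {
  x <- standardize_genotypes(dataset)
  k <- min(k, dim(x))
  res <- run_pca(x, k)
  res$scores_df <- data.frame(
    individual_id = dataset$individuals$individual_id,
    breed = dataset$individuals$breed,
    res$scores, stringsAsFactors = FALSE)
  res
}
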