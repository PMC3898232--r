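# internal helpers shared across modules

#' @keywords internal
#' @noRd
is_unmapped_marker <- function(chrom, pos_bp) {
  ch <- as.character(chrom)
  is.na(ch) | ch == "" | ch == "0" | is.na(pos_bp) | pos_bp == 0
}

# Ordering for chromosome labels: numeric labels first (numerically), then
# non-numeric labels (X, Y, ...) alphabetically, unmapped markers last.
#' @keywords internal
#' @noRd
marker_order <- function(chrom, pos_bp) {
  ch <- as.character(chrom)
  num <- suppressWarnings(as.numeric(ch))
  unmapped <- is_unmapped_marker(ch, pos_bp)
  grp <- ifelse(unmapped, 3L, ifelse(is.na(num), 2L, 1L))
  num[is.na(num)] <- 0
  order(grp, num, ch, pos_bp)
}

#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
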