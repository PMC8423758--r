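#' Largest-remainder apportionment of an integer total
#'
#' Splits `total` into integer parts proportional to `props` (which need not
#' sum to 1; they are normalized). Remainders are resolved largest-first;
#' ties go to the earlier-listed entry, so the result is deterministic.
#'
#' @param props Non-negative numeric vector of proportions.
#' @param total Non-negative integer to apportion.
#' @return Integer vector of the same length as `props` summing to `total`.
#' @keywords internal
apportion_counts <- function(props, total) {
  stopifnot(all(props >= 0), sum(props) > 0, total >= 0)
  raw <- props / sum(props) * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE) # stable: ties to first listed
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Pearson correlation with a defined value for degenerate input
#'
#' Correlation of two vectors, returning 0 with a `degenerate` attribute when
#' either vector is constant (or empty), so downstream curves never carry NaN.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar correlation; attribute `degenerate` is TRUE when undefined.
#' @keywords internal
safe_cor <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(x, y), degenerate = FALSE)
}

# run-length encode an integer/character vector into (start, end, value) rows
rle_intervals <- function(x) {
  r <- rle(as.vector(x))
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end, value = r$values,
             stringsAsFactors = FALSE)
}
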