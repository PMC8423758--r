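#' Quantize genotype-frequency profiles
#'
#' Each population's genotype-class profile at a locus is reduced to a
#' 3-component binary vector: class g is set when its frequency is within
#' `delta` of the maximal class frequency, so the maximal class is always
#' set and near-ties are marked jointly. For example (0.9, 0.1, 0.0) with
#' delta 0.2 quantizes to (1, 0, 0): the homozygote-major class clearly
#' dominates.
#'
#' @param freqs Genotype-frequency array loci x populations x 3
#'   ([pop_genotype_freqs()]), or a length-3 vector for one profile.
#' @param delta Margin below the maximum within which a class is still set.
#' @return Logical array of the same shape (or length-3 logical vector).
#' @export
quantize_profile <- function(freqs, delta = 0.2) {
  if (is.null(dim(freqs))) {
    return(freqs >= max(freqs) - delta)
  }
  mx <- apply(freqs, c(1, 2), max)
  q <- freqs
  for (g in 1:3) q[, , g] <- freqs[, , g] >= mx - delta
  storage.mode(q) <- "logical"
  q
}

pattern_signature <- function(Q_locus) {
  # Q_locus: populations x 3 logical; identity is the population -> vector
  # map, written in population-name order so it is storage-order free
  pops <- rownames(Q_locus)
  bits <- apply(Q_locus, 1, function(v) paste(as.integer(v), collapse = ""))
  ord <- order(pops)
  paste(paste0(pops[ord], ":", bits[ord]), collapse = "|")
}

#' Count patterns of genotype changes across loci
#'
#' A pattern is the partition of the populations induced by equality of
#' their quantized genotype vectors at a locus, together with the vectors
#' themselves. Every locus maps to exactly one pattern; counts over all
#' patterns sum to the number of loci. The all-equal ("invariant") pattern
#' is flagged.
#'
#' @param Q Quantized array from [quantize_profile()] (loci x populations x 3).
#' @return Data frame sorted by descending count: `pattern` (signature
#'   string `pop:bits|...`), `count`, `rank`, `invariant`, `n_groups`.
#' @export
count_patterns <- function(Q) {
  pops <- dimnames(Q)[[2]]
  if (is.null(pops)) pops <- paste0("pop", seq_len(dim(Q)[2]))
  n <- dim(Q)[1]
  sigs <- character(n)
  groups <- integer(n)
  for (i in seq_len(n)) {
    Qi <- matrix(Q[i, , ], dim(Q)[2], 3, dimnames = list(pops, NULL))
    sigs[i] <- pattern_signature(Qi)
    groups[i] <- length(unique(apply(Qi, 1, paste, collapse = "")))
  }
  tab <- table(sigs)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$n_groups <- groups[match(out$pattern, sigs)]
  out$invariant <- out$n_groups == 1L
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("pattern", "count", "rank", "invariant", "n_groups")]
}

#' Mine dominant genotype-change patterns from a genotype matrix
#'
#' Convenience wrapper: tabulates per-population genotype frequencies,
#' quantizes them and counts patterns. Admixed populations can be excluded
#' (the analysis of between-population change assumes tree-like splits).
#'
#' @param X Loci x subjects genotype matrix.
#' @param panel Panel data frame (`subject`, `population`).
#' @param delta Quantization margin (see [quantize_profile()]).
#' @param exclude Populations to drop before counting.
#' @return Data frame from [count_patterns()].
#' @export
mine_patterns <- function(X, panel, delta = 0.2, exclude = character(0)) {
  pops <- setdiff(unique(panel$population), exclude)
  freqs <- pop_genotype_freqs(X, panel, pops)
  count_patterns(quantize_profile(freqs, delta))
}
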