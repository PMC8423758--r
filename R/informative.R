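#' Per-population genotype-class frequencies
#'
#' For each locus and each reference population, the relative frequencies of
#' the three genotype classes (0, 1, 2 minor alleles). These multinomial
#' profiles drive the allele-frequency selection criterion, the proxy
#' weights and the pattern mining.
#'
#' @param X Loci x subjects genotype matrix with values in \{0, 1, 2\}.
#' @param panel Data frame with `subject` and `population` in subject order,
#'   or a character vector of population labels per subject.
#' @param populations Populations to tabulate, in the desired order
#'   (default: unique labels in panel order).
#' @return 3-d array loci x populations x genotype classes (`"0"`, `"1"`,
#'   `"2"`), rows of each locus/population slice summing to 1.
#' @export
pop_genotype_freqs <- function(X, panel, populations = NULL) {
  labels <- if (is.data.frame(panel)) panel$population else panel
  if (length(labels) != ncol(X)) stop("panel does not match subjects")
  if (is.null(populations)) populations <- unique(labels)
  out <- array(NA_real_, dim = c(nrow(X), length(populations), 3L),
               dimnames = list(NULL, populations, c("0", "1", "2")))
  for (p in seq_along(populations)) {
    cols <- which(labels == populations[p])
    if (length(cols) == 0) stop("no subjects in population ", populations[p])
    Xp <- X[, cols, drop = FALSE]
    for (g in 0:2) out[, p, g + 1L] <- rowMeans(Xp == g)
  }
  out
}

#' Mean and standard deviation of a genotype-class profile
#'
#' Moments of the genotype value under the multinomial profile
#' f = (f0, f1, f2): mu = f1 + 2 f2 and sigma^2 = f1 + 4 f2 - mu^2.
#'
#' @param f Numeric vector of length 3 on the simplex, or a matrix with 3
#'   columns (one profile per row).
#' @return List with `mu` and `sigma` (scalars or vectors).
#' @export
genotype_moments <- function(f) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  g <- c(0, 1, 2)
  mu <- drop(f %*% g)
  v <- drop(f %*% g^2) - mu^2
  if (any(v < -1e-12)) stop("negative genotype variance beyond tolerance")
  list(mu = mu, sigma = sqrt(pmax(v, 0)))
}

# per-locus moments for every reference population: freqs is the array from
# pop_genotype_freqs(); returns mu and sigma matrices (loci x populations)
freq_moments <- function(freqs) {
  L <- dim(freqs)[2]
  mu <- matrix(NA_real_, dim(freqs)[1], L, dimnames = list(NULL, dimnames(freqs)[[2]]))
  sigma <- mu
  for (l in seq_len(L)) {
    m <- genotype_moments(freqs[, l, ])
    mu[, l] <- m$mu
    sigma[, l] <- m$sigma
  }
  list(mu = mu, sigma = sigma)
}

# non-strict monotonicity (either direction) of each row of a matrix
rows_monotone <- function(mu) {
  if (ncol(mu) < 2) stop("need at least 2 reference populations")
  d <- mu[, -1, drop = FALSE] - mu[, -ncol(mu), drop = FALSE]
  inc <- rowSums(d < 0) == 0
  dec <- rowSums(d > 0) == 0
  inc | dec
}

#' Allele-frequency separation criterion
#'
#' A locus qualifies when the mean genotype values of the reference
#' populations, taken in their projection order along the component, are
#' monotone (non-strictly increasing or decreasing). With exactly two
#' reference populations the one-sigma intervals around the two means must
#' additionally be disjoint.
#'
#' @param mu Loci x populations matrix of mean genotypes (population columns
#'   in projection order), or a vector for a single locus.
#' @param sigma Matching standard deviations (required when `ncol(mu) == 2`).
#' @return Logical vector, one value per locus.
#' @export
frequency_criterion <- function(mu, sigma = NULL) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (!is.null(sigma) && is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  ok <- rows_monotone(mu)
  if (ncol(mu) == 2) {
    if (is.null(sigma)) stop("sigma is required when L = 2")
    ok <- ok & (abs(mu[, 1] - mu[, 2]) >= sigma[, 1] + sigma[, 2])
  }
  ok
}

# loading order used by truncation/accretion: decreasing loading, ties by
# (chrom, pos) ascending when a locus table is supplied, else by index
loading_order <- function(gamma_k, loci = NULL) {
  if (is.null(loci)) {
    order(-gamma_k, seq_along(gamma_k))
  } else {
    order(-gamma_k, loci$chrom, loci$pos)
  }
}

# stage-wise removed/added index sets: at stage s, the top s*step and bottom
# s*step loci in loading order (clipped when the two ends meet)
stage_sets <- function(ord, step) {
  n <- length(ord)
  s_max <- ceiling(n / (2 * step))
  lapply(0:s_max, function(s) {
    k <- min(s * step, n)
    top <- ord[seq_len(min(k, n))]
    bot <- ord[n + 1 - seq_len(min(k, n))]
    unique(c(top, bot))
  })
}

curve_over_stages <- function(cg, loadings, k, step, loci, mode) {
  gamma_k <- loadings[, k]
  ord <- loading_order(gamma_k, loci)
  sets <- stage_sets(ord, step)
  full <- partial_projection(cg, loadings, seq_len(nrow(cg$Xc)), k)
  m <- ncol(cg$Xc)
  removed_sum <- numeric(m)
  prev <- integer(0)
  rows <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    new_idx <- setdiff(sets[[s]], prev)
    if (length(new_idx)) {
      removed_sum <- removed_sum + partial_projection(cg, loadings, new_idx, k)
    }
    prev <- sets[[s]]
    approx <- if (mode == "truncation") full - removed_sum else removed_sum
    r <- if (mode == "truncation" && length(prev) == nrow(cg$Xc)) {
      structure(0, degenerate = TRUE) # nothing left: empty-sum convention
    } else {
      safe_cor(full, approx)
    }
    rows[[s]] <- data.frame(stage = s - 1L,
                            per_side = min((s - 1L) * step, nrow(cg$Xc)),
                            n_selected = length(prev),
                            r = as.numeric(r),
                            degenerate = attr(r, "degenerate"))
  }
  do.call(rbind, rows)
}

#' Truncation curve: correlation after removing top/bottom ranking loci
#'
#' Starting from the full projection on component `k`, each stage removes
#' `step` more loci from the top and `step` more from the bottom of the
#' loading ranking, and records the Pearson correlation between the
#' truncated partial projection and the full projection. The curve starts
#' at r = 1; a degenerate (empty or constant) truncated projection is
#' reported as r = 0 with `degenerate = TRUE`.
#'
#' @param cg A `centered_genotypes` object.
#' @param loadings Loadings matrix.
#' @param k Component index.
#' @param step Loci removed per side per stage.
#' @param loci Optional locus table for deterministic tie-breaking.
#' @return Data frame: `stage`, `per_side`, `n_selected` (loci removed so
#'   far), `r`, `degenerate`.
#' @export
truncation_curve <- function(cg, loadings, k, step = NULL, loci = NULL) {
  if (is.null(step)) step <- max(1L, nrow(cg$Xc) %/% 1000L)
  stopifnot(step >= 1)
  curve_over_stages(cg, loadings, k, as.integer(step), loci, "truncation")
}

#' Accretion curve: correlation after adding top/bottom ranking loci
#'
#' Mirror of [truncation_curve()]: starting from an empty locus set, each
#' stage adds `step` loci from the top and `step` from the bottom of the
#' loading ranking and correlates the accrued partial projection with the
#' full projection. The curve ends at r = 1 when all loci are included.
#'
#' @inheritParams truncation_curve
#' @return Data frame as in [truncation_curve()] (`n_selected` = loci added).
#' @export
accretion_curve <- function(cg, loadings, k, step = NULL, loci = NULL) {
  if (is.null(step)) step <- max(1L, nrow(cg$Xc) %/% 1000L)
  stopifnot(step >= 1)
  curve_over_stages(cg, loadings, k, as.integer(step), loci, "accretion")
}

#' Select the necessary informative loci of a component
#'
#' Runs the truncation scan and keeps every top/bottom locus removed up to
#' the last stage whose truncated-vs-full correlation is still at or above
#' `threshold` (stages are consumed in order; the first stage that drops
#' below ends the scan). Loci passing the allele-frequency criterion are
#' united with the truncation component, with provenance recorded per locus.
#'
#' @param cg A `centered_genotypes` object.
#' @param loadings Loadings matrix.
#' @param k Component index.
#' @param threshold Correlation threshold in (0, 1); default 0.9.
#' @param step Loci removed per side per stage (see [truncation_curve()]).
#' @param freqs Optional genotype-frequency array ([pop_genotype_freqs()])
#'   whose population order is the component's projection order; enables the
#'   frequency criterion.
#' @param loci Optional locus table for tie-breaking and coordinates.
#' @return An `informative_loci` data frame: `locus`, `chrom`, `pos`, `pc`,
#'   `loading`, `sign_group` (+1/-1), `provenance` (`"truncation"` or
#'   `"frequency"`). Attributes: `threshold`, `achieved_r`, `pc`.
#' @export
select_necessary <- function(cg, loadings, k, threshold = 0.9, step = NULL,
                             freqs = NULL, loci = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(step)) step <- max(1L, nrow(cg$Xc) %/% 1000L)
  curve <- truncation_curve(cg, loadings, k, step, loci)
  below <- which(curve$r < threshold & !curve$degenerate)
  last_ok <- if (length(below) == 0) nrow(curve) else min(below) - 1L
  if (length(below) == 0) {
    warning("correlation never dropped below the threshold; selecting all loci")
  }
  ord <- loading_order(loadings[, k], loci)
  sel <- stage_sets(ord, as.integer(step))[[last_ok]]
  prov <- rep("truncation", length(sel))
  if (!is.null(freqs)) {
    mom <- freq_moments(freqs)
    fc <- which(frequency_criterion(mom$mu, mom$sigma))
    extra <- setdiff(fc, sel)
    sel <- c(sel, extra)
    prov <- c(prov, rep("frequency", length(extra)))
  }
  out <- data.frame(locus = sel,
                    chrom = if (is.null(loci)) rep(NA_character_, length(sel)) else loci$chrom[sel],
                    pos = if (is.null(loci)) rep(NA_integer_, length(sel)) else loci$pos[sel],
                    pc = rep(k, length(sel)),
                    loading = loadings[sel, k],
                    sign_group = sign(loadings[sel, k]),
                    provenance = prov,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "achieved_r") <- curve$r[last_ok]
  attr(out, "pc") <- k
  class(out) <- c("informative_loci", "data.frame")
  out
}

#' Allele-frequency proxy weights
#'
#' The weight of locus i on component k is the smallest margin between the
#' mean genotypes of consecutive reference populations (in projection
#' order), signed by the locus's loading, and zero whenever the means are
#' not monotone along that order.
#'
#' @param freqs Genotype-frequency array from [pop_genotype_freqs()], with
#'   population columns in the component's projection order.
#' @param gamma_k Loading vector for the component.
#' @return Numeric weight vector, one entry per locus.
#' @export
proxy_weights <- function(freqs, gamma_k) {
  mom <- freq_moments(freqs)
  mu <- mom$mu
  mono <- rows_monotone(mu)
  margins <- abs(mu[, -1, drop = FALSE] - mu[, -ncol(mu), drop = FALSE])
  w <- sign(gamma_k) * apply(margins, 1, min)
  w[!mono] <- 0
  w
}

#' Proxy projections as weighted allele sums
#'
#' Weighted sum of centered genotypes over the informative loci of a
#' component, using allele-frequency margin weights instead of SVD
#' loadings. High correlation with the full projection indicates that the
#' population identity is carried additively by the informative loci.
#'
#' @param cg A `centered_genotypes` object.
#' @param weights Weight vector over all loci ([proxy_weights()]).
#' @param subset Informative-locus indices (default: all loci).
#' @return Numeric vector of proxy projections, one per subject.
#' @export
proxy_projection <- function(cg, weights, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(cg$Xc))
  if (length(subset) == 0) return(numeric(ncol(cg$Xc)))
  drop(crossprod(cg$Xc[subset, , drop = FALSE], weights[subset]))
}

#' Homozygote genotype fractions over top informative loci
#'
#' For each subject, the fractions of homozygote major (genotype 0) and
#' homozygote minor (genotype 2) calls over the `K` largest-|loading| loci
#' of one sign group of an informative set. The two fractions per subject
#' sum to at most 1; their joint distribution across subjects reveals the
#' direction of genotype change along the component.
#'
#' @param X Loci x subjects genotype matrix.
#' @param iset `informative_loci` data frame.
#' @param K Number of loci used (clamped to the group size with a warning).
#' @param sign_group +1 for the positive (top-ranking) group, -1 for the
#'   negative (bottom-ranking) group.
#' @return Data frame: `subject` index, `frac0`, `frac2`.
#' @export
homozygote_fractions <- function(X, iset, K, sign_group = 1) {
  grp <- iset[iset$sign_group == sign_group, , drop = FALSE]
  if (nrow(grp) == 0) stop("empty sign group")
  if (K > nrow(grp)) {
    warning("K exceeds group size; clamping to ", nrow(grp))
    K <- nrow(grp)
  }
  top <- grp$locus[order(-abs(grp$loading))][seq_len(K)]
  Xs <- X[top, , drop = FALSE]
  data.frame(subject = seq_len(ncol(X)),
             frac0 = colMeans(Xs == 0),
             frac2 = colMeans(Xs == 2))
}

#' Score genes by their strongest informative locus
#'
#' A gene's score on component k is the maximum |loading| over the loci
#' inside its interval; genes containing no locus get no score and are
#' excluded from ranking.
#'
#' @param loadings Loadings matrix.
#' @param loci Locus table with `chrom` and `pos`.
#' @param genes Data frame with `gene`, `chrom`, `start`, `end` (positions on
#'   the same 1-based coordinate system as `loci`, interval inclusive).
#' @param k Component index (or vector of components).
#' @return Data frame `gene` plus one score column per requested component;
#'   genes without loci are dropped.
#' @export
score_genes <- function(loadings, loci, genes, k = 1) {
  scores <- matrix(NA_real_, nrow(genes), length(k),
                   dimnames = list(NULL, paste0("pc", k)))
  has <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- which(loci$chrom == genes$chrom[i] &
                   loci$pos >= genes$start[i] & loci$pos <= genes$end[i])
    if (length(hit)) {
      has[i] <- TRUE
      scores[i, ] <- apply(abs(loadings[hit, k, drop = FALSE]), 2, max)
    }
  }
  cbind(data.frame(gene = genes$gene[has], stringsAsFactors = FALSE),
        as.data.frame(scores[has, , drop = FALSE]))
}

#' Read gene intervals from a BED or GFF3 file
#'
#' Accepts BED (0-based half-open; converted to 1-based inclusive) with the
#' gene name in column 4, or GFF3 restricted to `gene` features with the
#' name taken from the `Name=` (fallback `ID=`) attribute. Parsed with
#' rtracklayer.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @param format Override the extension-based format guess.
#' @return Data frame `gene`, `chrom`, `start`, `end` (1-based inclusive),
#'   ready for [score_genes()].
#' @export
read_gene_intervals <- function(path, format = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_intervals needs the rtracklayer package")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    nm <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
    if (all(is.na(nm)) && !is.null(gr$ID)) nm <- as.character(gr$ID)
  } else {
    nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  }
  if (length(gr) == 0) stop("no gene intervals in ", path)
  if (all(is.na(nm))) nm <- paste0("gene", seq_along(gr))
  df <- as.data.frame(gr)
  data.frame(gene = nm,
             chrom = as.character(df$seqnames),
             start = df$start,
             end = df$end,
             stringsAsFactors = FALSE)
}

#' All-informative genes
#'
#' Genes whose score is in the top `top_fraction` of the ranked gene list on
#' every scored component.
#'
#' @param gene_scores Output of [score_genes()] over several components.
#' @param top_fraction Quantile fraction defining "top" (default 0.25).
#' @return Character vector of gene names.
#' @export
all_informative <- function(gene_scores, top_fraction = 0.25) {
  score_cols <- setdiff(names(gene_scores), "gene")
  keep <- rep(TRUE, nrow(gene_scores))
  for (cl in score_cols) {
    thr <- stats::quantile(gene_scores[[cl]], 1 - top_fraction, names = FALSE)
    keep <- keep & gene_scores[[cl]] >= thr
  }
  gene_scores$gene[keep]
}
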