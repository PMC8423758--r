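#' Tile loci into fixed-width genomic windows
#'
#' Counts loci per non-overlapping window of `window_size` bp on each
#' chromosome. A locus at 1-based position p falls into window
#' floor((p - 1) / window_size); trailing partial windows are kept, and
#' empty windows up to the last occupied one (or up to `chrom_lengths`) are
#' reported with count 0 so that windows tile each chromosome.
#'
#' @param loci Data frame with `chrom` and `pos` (1-based), e.g. a locus
#'   table or an informative set with coordinates.
#' @param window_size Window width in bp (default 1 Mb).
#' @param chrom_lengths Optional named vector of chromosome lengths in bp.
#' @return Data frame: `chrom`, `window` (0-based index), `start`, `end`
#'   (0-based half-open bp), `count`.
#' @export
window_counts <- function(loci, window_size = 1e6, chrom_lengths = NULL) {
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(loci$chrom)
  out <- lapply(chroms, function(ch) {
    pos <- loci$pos[loci$chrom == ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(pos)
    n_win <- max(1L, ceiling(len / window_size))
    w <- floor((pos - 1) / window_size)
    cnt <- tabulate(w + 1L, nbins = n_win)
    data.frame(chrom = ch, window = seq_len(n_win) - 1L,
               start = (seq_len(n_win) - 1L) * window_size,
               end = pmin(seq_len(n_win) * window_size, len),
               count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# log-space forward-backward for a Poisson-emission HMM with fixed sticky
# transitions; returns per-window state posteriors and the log-likelihood
poisson_hmm_posterior <- function(counts, rates, self_trans) {
  S <- length(rates)
  W <- length(counts)
  log_em <- sapply(rates, function(l) stats::dpois(counts, l, log = TRUE))
  log_em <- matrix(log_em, W, S)
  log_A <- matrix(log((1 - self_trans) / max(S - 1, 1)), S, S)
  diag(log_A) <- log(self_trans)
  if (S == 1) log_A <- matrix(0, 1, 1)
  log_pi <- rep(-log(S), S)
  la <- matrix(NA_real_, W, S)
  lb <- matrix(0, W, S)
  la[1, ] <- log_pi + log_em[1, ]
  for (w in seq_len(W)[-1]) {
    for (s in seq_len(S)) {
      la[w, s] <- log_em[w, s] + log_sum_exp(la[w - 1, ] + log_A[, s])
    }
  }
  for (w in rev(seq_len(W))[-1]) {
    for (s in seq_len(S)) {
      lb[w, s] <- log_sum_exp(log_A[s, ] + log_em[w + 1, ] + lb[w + 1, ])
    }
  }
  ll <- log_sum_exp(la[W, ])
  lg <- la + lb - ll
  list(posterior = exp(lg), loglik = ll)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fit the position-varying Poisson background of SNP density
#'
#' Window counts of all SNPs are modeled by a hidden Markov chain whose
#' states carry Poisson rates: consecutive windows tend to share a rate
#' (sticky transitions), so the fitted per-window background rate varies
#' smoothly along the chromosome. States are initialized at count
#' quantiles; rates are re-estimated by Baum-Welch iterations with the
#' transition structure held fixed. Chromosomes are independent chains
#' sharing one parameter set. With a single state the fit collapses to the
#' global Poisson maximum-likelihood rate (the mean count).
#'
#' @param wd Window-count data frame from [window_counts()] for all SNPs.
#' @param n_states Number of hidden rate states (default 10).
#' @param self_trans Self-transition probability (default 0.9); off-diagonal
#'   mass is uniform.
#' @param max_iter Maximum Baum-Welch iterations (default 100).
#' @param tol Convergence tolerance on the log-likelihood.
#' @return A `background_hmm`: `rates`, `self_trans`, `window_rate`
#'   (posterior-weighted rate per window, aligned with `wd`), `loglik`,
#'   `windows` (the input table).
#' @export
fit_background <- function(wd, n_states = 10, self_trans = 0.9,
                           max_iter = 100, tol = 1e-6) {
  counts <- wd$count
  if (length(counts) < 2) stop("need at least 2 windows")
  if (all(counts == 0)) stop("all window counts are zero; no background to fit")
  probs <- seq(0.05, 0.95, length.out = n_states)
  rates <- unique(pmax(stats::quantile(counts, probs, names = FALSE), 1e-3))
  if (length(rates) < n_states) {
    rates <- sort(unique(c(rates, seq(min(counts) + 1e-3, max(counts) + 1e-3,
                                      length.out = n_states))))[seq_len(n_states)]
    rates <- rates[!is.na(rates)]
  }
  chrom_idx <- split(seq_along(counts), wd$chrom)
  ll_old <- -Inf
  post <- NULL
  for (it in seq_len(max_iter)) {
    ll <- 0
    post <- matrix(NA_real_, length(counts), length(rates))
    for (idx in chrom_idx) {
      fb <- poisson_hmm_posterior(counts[idx], rates, self_trans)
      post[idx, ] <- fb$posterior
      ll <- ll + fb$loglik
    }
    num <- colSums(post * counts)
    den <- colSums(post)
    rates <- ifelse(den > 0, num / pmax(den, 1e-12), rates)
    rates <- pmax(rates, 1e-6)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  structure(list(rates = rates, self_trans = self_trans,
                 window_rate = drop(post %*% rates),
                 loglik = ll_old, windows = wd),
            class = "background_hmm")
}

#' Hotspot p-values for informative-locus density
#'
#' The expected informative count in a window is the fitted background rate
#' scaled by the global fraction of loci that are informative for the
#' component (informative loci are a thinned subset of all SNPs). The
#' p-value is the upper Poisson tail P(X >= observed) under that
#' expectation, computed in log space so magnitudes far below double
#' underflow remain exact. Windows at or below the threshold are hotspots;
#' adjacent significant windows are merged into hotspot intervals.
#'
#' @param inf_wd Window counts of the informative loci (aligned with the
#'   background's windows: same chromosomes and window grid).
#' @param bg A `background_hmm` from [fit_background()].
#' @param fraction Global informative fraction (informative loci / all loci).
#' @param threshold Hotspot p-value cutoff (default 1e-50, the genome-scale
#'   operating point; reduce for small simulated genomes).
#' @return Data frame: window coordinates, `count`, `expected`, `log10_p`,
#'   `rescaled` (observed/expected), `hotspot`, `interval` (merged hotspot
#'   interval id or NA).
#' @export
hotspot_pvalues <- function(inf_wd, bg, fraction, threshold = 1e-50) {
  wd <- bg$windows
  if (nrow(inf_wd) != nrow(wd) ||
      any(inf_wd$chrom != wd$chrom | inf_wd$window != wd$window)) {
    stop("informative windows are not aligned with the background windows")
  }
  lambda <- bg$window_rate * fraction
  obs <- inf_wd$count
  log_p <- ifelse(obs == 0, 0,
                  stats::ppois(obs - 1, lambda, lower.tail = FALSE, log.p = TRUE))
  log10_p <- log_p / log(10)
  hot <- log10_p <= log10(threshold)
  interval <- rep(NA_integer_, length(hot))
  iv <- 0L
  for (i in seq_along(hot)) {
    if (hot[i]) {
      new_block <- i == 1 || !hot[i - 1] || wd$chrom[i] != wd$chrom[i - 1]
      if (new_block) iv <- iv + 1L
      interval[i] <- iv
    }
  }
  data.frame(chrom = wd$chrom, window = wd$window,
             start = wd$start, end = wd$end,
             count = obs, expected = lambda,
             log10_p = log10_p,
             rescaled = ifelse(lambda > 0, obs / lambda, NA_real_),
             hotspot = hot, interval = interval,
             stringsAsFactors = FALSE)
}
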