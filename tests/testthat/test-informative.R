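# brute-force reference: correlation after truncating/accruing the top and
# bottom s*step loci, recomputed from scratch with plain sums
brute_curve <- function(Xc, gamma_k, step, mode) {
  n <- nrow(Xc)
  ord <- order(-gamma_k, seq_len(n))
  full <- as.numeric(t(Xc) %*% gamma_k)
  s_max <- ceiling(n / (2 * step))
  vapply(0:s_max, function(s) {
    k <- min(s * step, n)
    sel <- unique(c(ord[seq_len(k)], rev(ord)[seq_len(k)]))
    keep <- if (mode == "truncation") setdiff(seq_len(n), sel) else sel
    if (length(keep) == 0) return(0)
    approx <- as.numeric(t(Xc[keep, , drop = FALSE]) %*% gamma_k[keep])
    if (sd(approx) == 0) return(0)
    cor(full, approx)
  }, 0)
}

structured_fixture <- function() {
  memo("informative_fixture", {
    co <- two_pop_cohort()
    gm <- collapse_genotypes(co)
    sub <- 1:200 # 200-locus slice keeps the brute force instant
    X <- gm$X[sub, ]
    loci <- co$loci[sub, ]
    pca <- pca_genotypes(X, k_max = 3)
    list(X = X, loci = loci, pca = pca, panel = co$panel)
  })
}

test_that("truncation and accretion curves match brute-force recomputation", {
  fx <- structured_fixture()
  cg <- fx$pca$centered
  G <- fx$pca$loadings
  tc <- truncation_curve(cg, G, 1, step = 10)
  ac <- accretion_curve(cg, G, 1, step = 10)
  expect_equal(tc$r[1], 1)
  expect_true(tc$degenerate[nrow(tc)]) # everything removed: flagged r = 0
  expect_equal(ac$r[nrow(ac)], 1)
  expect_equal(tc$r, brute_curve(cg$Xc, G[, 1], 10, "truncation"), tolerance = 1e-9)
  expect_equal(ac$r, brute_curve(cg$Xc, G[, 1], 10, "accretion"), tolerance = 1e-9)
  # accretion reaches high correlation far sooner than truncation loses it
  expect_gt(ac$r[2], 0.9)
  expect_gt(tc$r[2], 0.9)
})

test_that("truncated and accrued partial projections add to the full projection", {
  fx <- structured_fixture()
  cg <- fx$pca$centered
  G <- fx$pca$loadings
  ord <- order(-G[, 1], seq_len(nrow(cg$Xc)))
  sel <- unique(c(ord[1:30], rev(ord)[1:30]))
  full <- partial_projection(cg, G, seq_len(nrow(cg$Xc)), 1)
  acc <- partial_projection(cg, G, sel, 1)
  tru <- partial_projection(cg, G, setdiff(seq_len(nrow(cg$Xc)), sel), 1)
  expect_lt(max(abs(acc + tru - full)), 1e-9)
})

test_that("necessary-loci selection reproduces an exhaustive stage scan", {
  fx <- structured_fixture()
  cg <- fx$pca$centered
  G <- fx$pca$loadings
  step <- 5
  r <- brute_curve(cg$Xc, G[, 1], step, "truncation")
  # independent scan: last stage of the contiguous prefix with r >= 0.9,
  # ignoring the degenerate all-removed tail
  degen <- vapply(seq_along(r) - 1L, function(s) min(s * step, nrow(cg$Xc)) * 2 >= 200, NA)
  ok <- r >= 0.9 | degen
  last_ok <- if (all(ok)) length(r) else min(which(!ok)) - 1L
  ord <- order(-G[, 1], seq_len(nrow(cg$Xc)))
  kk <- min((last_ok - 1L) * step, nrow(cg$Xc))
  expected <- sort(unique(c(ord[seq_len(kk)], rev(ord)[seq_len(kk)])))
  sel <- select_necessary(cg, G, 1, threshold = 0.9, step = step, loci = fx$loci)
  expect_setequal(sel$locus, expected)
  expect_gte(attr(sel, "achieved_r"), 0.9)
  expect_true(all(sel$provenance == "truncation"))
  expect_true(all(sel$loading[sel$sign_group == 1] > 0))
  expect_true(all(sel$loading[sel$sign_group == -1] < 0))
})

test_that("selection limits behave at extreme thresholds", {
  fx <- structured_fixture()
  cg <- fx$pca$centered
  G <- fx$pca$loadings
  hi <- select_necessary(cg, G, 1, threshold = 1 - 1e-12, step = 5)
  expect_equal(nrow(hi), 0) # first removal already drops below ~1
  lo <- suppressWarnings(select_necessary(cg, G, 1, threshold = 1e-12, step = 5))
  expect_equal(sort(lo$locus), seq_len(nrow(cg$Xc))) # everything survives the scan
  expect_warning(select_necessary(cg, G, 1, threshold = 1e-12, step = 5),
                 "never dropped")
})

test_that("selection is invariant to subject and locus storage order", {
  fx <- structured_fixture()
  base <- select_necessary(fx$pca$centered, fx$pca$loadings, 1,
                           threshold = 0.9, step = 5, loci = fx$loci)
  set.seed(31)
  perm_s <- sample(ncol(fx$X))
  perm_l <- sample(nrow(fx$X))
  pca2 <- pca_genotypes(fx$X[perm_l, perm_s], k_max = 3)
  sel2 <- select_necessary(pca2$centered, pca2$loadings, 1,
                           threshold = 0.9, step = 5,
                           loci = fx$loci[perm_l, ])
  expect_setequal(paste(base$chrom, base$pos), paste(sel2$chrom, sel2$pos))
})

test_that("genotype moments follow the multinomial closed forms", {
  expect_equal(genotype_moments(c(1, 0, 0)), list(mu = 0, sigma = 0))
  expect_equal(genotype_moments(c(0, 0, 1)), list(mu = 2, sigma = 0))
  m <- genotype_moments(c(0.25, 0.5, 0.25))
  expect_equal(m$mu, 1)
  expect_equal(m$sigma, sqrt(0.5))
  expect_error(genotype_moments(c(2, 0, -1)), "negative")
})

test_that("frequency criterion demands monotone means and L=2 interval separation", {
  expect_true(frequency_criterion(c(0.2, 0.9, 1.6)))
  expect_false(frequency_criterion(c(0.2, 1.6, 0.9)))
  # degenerate homozygote profiles: 0 +/- 0 vs 2 +/- 0, disjoint
  m1 <- genotype_moments(c(1, 0, 0))
  m2 <- genotype_moments(c(0, 0, 1))
  expect_true(frequency_criterion(c(m1$mu, m2$mu), c(m1$sigma, m2$sigma)))
  # overlapping one-sigma intervals fail at L = 2
  expect_false(frequency_criterion(c(0.9, 1.1), c(0.3, 0.3)))
  expect_true(frequency_criterion(c(0.2, 1.8), c(0.3, 0.3)))
})

test_that("proxy weights implement the minimal-margin rule with sign and veto", {
  mk_freqs <- function(mus) { # one locus, one population per mu, f1 = 0
    f <- array(0, c(1, length(mus), 3))
    f[1, , 3] <- mus / 2
    f[1, , 1] <- 1 - mus / 2
    f
  }
  expect_equal(proxy_weights(mk_freqs(c(0.2, 0.9, 1.6)), gamma_k = 2.5), 0.7)
  expect_equal(proxy_weights(mk_freqs(c(0.2, 1.6, 0.9)), gamma_k = 2.5), 0)
  expect_equal(proxy_weights(mk_freqs(c(0.0, 0.1, 1.9)), gamma_k = -1), -0.1)
})

test_that("proxy projections track full projections and scale linearly", {
  fx <- structured_fixture()
  cg <- fx$pca$centered
  freqs <- pop_genotype_freqs(fx$X, fx$panel)
  # order populations along PC 1 by mean projection
  P <- fx$pca$projections
  ord <- names(sort(tapply(P[, 1], fx$panel$population, mean)))
  freqs <- freqs[, ord, , drop = FALSE]
  w <- proxy_weights(freqs, fx$pca$loadings[, 1])
  expect_true(all(abs(w) <= 2))
  expect_true(all(sign(w[w != 0]) == sign(fx$pca$loadings[w != 0, 1])))
  prox <- proxy_projection(cg, w)
  expect_gt(abs(cor(prox, P[, 1])), 0.8)
  # rescaling weights rescales the proxy and leaves the correlation fixed
  prox2 <- proxy_projection(cg, 3 * w)
  expect_equal(prox2, 3 * prox)
  expect_true(all(proxy_projection(cg, numeric(nrow(fx$X))) == 0))
  # single locus with unit weight returns that centered row
  w1 <- numeric(nrow(fx$X)); w1[17] <- 1
  expect_equal(proxy_projection(cg, w1, 17), unname(cg$Xc[17, ]))
})

test_that("homozygote fractions count genotype classes over top loci", {
  iset <- data.frame(locus = 1:10, chrom = "1", pos = 1:10, pc = 1,
                     loading = 10:1, sign_group = 1, provenance = "truncation")
  X <- matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2), 2), 10, 2)
  hf <- homozygote_fractions(X, iset, K = 10, sign_group = 1)
  expect_equal(hf$frac0, c(0.4, 0.4))
  expect_equal(hf$frac2, c(0.3, 0.3))
  all0 <- homozygote_fractions(matrix(0, 10, 1), iset, 10, 1)
  expect_equal(c(all0$frac0, all0$frac2), c(1, 0))
  all1 <- homozygote_fractions(matrix(1, 10, 1), iset, 10, 1)
  expect_equal(c(all1$frac0, all1$frac2), c(0, 0))
  expect_warning(homozygote_fractions(X, iset, K = 50, sign_group = 1), "clamping")
})

test_that("gene intervals load from BED and GFF3 annotations", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t49\t150\tgA\t0\t+", "1\t249\t400\tgB\t0\t-"), bed)
  gb <- read_gene_intervals(bed)
  expect_equal(gb$gene, c("gA", "gB"))
  expect_equal(gb$start, c(50, 250)) # BED is 0-based half-open
  expect_equal(gb$end, c(150, 400))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t50\t150\t.\t+\t.\tID=g1;Name=gA",
               "1\tsrc\texon\t60\t90\t.\t+\t.\tID=e1;Parent=g1",
               "1\tsrc\tgene\t250\t400\t.\t-\t.\tID=g2;Name=gB"), gff)
  gg <- read_gene_intervals(gff)
  expect_equal(gg$gene, c("gA", "gB")) # exon feature is ignored
  expect_equal(gg$start, c(50, 250))
  expect_equal(gg$end, c(150, 400))
})

test_that("gene scores and the all-informative rule match a hand computation", {
  loci <- data.frame(chrom = "1", pos = seq(100, 1700, by = 200))
  loadings <- cbind(pc1 = c(1, 8, 3, 7, 2, 6, 4, 5, 9),
                    pc2 = c(9, 1, 8, 2, 7, 3, 6, 4, 5))
  genes <- data.frame(gene = paste0("g", 1:9), chrom = "1",
                      start = seq(50, 1650, by = 200),
                      end = seq(150, 1750, by = 200))
  gs <- score_genes(loadings, loci, genes, k = 1:2)
  expect_equal(gs$pc1, abs(loadings[, 1]))
  # a gene with a single locus scores that locus; a gene with none is dropped
  empty <- rbind(genes, data.frame(gene = "g10", chrom = "1",
                                   start = 5000, end = 6000))
  expect_equal(nrow(score_genes(loadings, loci, empty, 1)), 9)
  # top 25% per component: pc1 {g9, g2}, pc2 {g1, g3}; intersection empty
  expect_length(all_informative(gs, 0.25), 0)
  expect_setequal(all_informative(gs, 1.0), gs$gene)
  # make one gene top on both components
  loadings2 <- loadings; loadings2[5, ] <- c(8.5, 8.5)
  gs2 <- score_genes(loadings2, loci, genes, k = 1:2)
  expect_true("g5" %in% all_informative(gs2, 0.25))
})
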