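# tiny perfectly separated reference: popA haplotypes all 0, popB all 1
perfect_reference <- function(n_loci = 40, n_per_pop = 4) {
  haps <- cbind(matrix(0L, n_loci, 2 * n_per_pop),
                matrix(1L, n_loci, 2 * n_per_pop))
  X <- haps[, seq(1, ncol(haps), 2)] + haps[, seq(2, ncol(haps), 2)]
  pca <- pca_genotypes(X, k_max = 1)
  iset <- data.frame(locus = seq_len(n_loci), chrom = "1",
                     pos = seq_len(n_loci) * 1000L, pc = 1,
                     loading = pca$loadings[, 1],
                     sign_group = sign(pca$loadings[, 1]),
                     provenance = "truncation", stringsAsFactors = FALSE)
  list(haps = haps, grp = rep(c("A", "B"), each = 2 * n_per_pop),
       gamma = pca$loadings[, 1], rm = pca$centered$row_means, iset = iset)
}

test_that("saturated separation yields minimal tracts with infinite z", {
  fx <- perfect_reference()
  part <- partition_tracts(fx$haps, fx$grp, fx$iset, fx$gamma, fx$rm, alpha = 3)
  expect_equal(nrow(part$tracts), 40) # every single locus separates
  expect_true(all(part$tracts$n_loci == 1))
  expect_true(all(part$tracts$z >= 3))
  expect_false(any(part$tracts$low_confidence))
  # tracts tile the chromosome
  expect_equal(part$tracts$start[1], 0)
  expect_equal(part$tracts$start[-1], part$tracts$end[-nrow(part$tracts)])
})

test_that("a duplicated reference under two labels never separates", {
  fx <- perfect_reference()
  haps <- fx$haps[, fx$grp == "A"]
  haps <- cbind(haps, haps) # same population twice
  set.seed(2) # add noise so variance is nonzero
  noisy <- haps
  noisy[sample(length(noisy), 50)] <- 1L
  grp <- rep(c("L1", "L2"), each = ncol(haps) / 2)
  pca <- pca_genotypes(noisy[, seq(1, ncol(noisy), 2)] +
                         noisy[, seq(2, ncol(noisy), 2)], k_max = 1)
  part <- partition_tracts(noisy, grp, fx$iset, pca$loadings[, 1],
                           pca$centered$row_means, alpha = 3)
  expect_equal(nrow(part$tracts), 1) # single flagged chromosome-wide tract
  expect_true(all(part$tracts$low_confidence))
})

test_that("each emitted tract passes the separation test and minimality holds", {
  fx <- five_pop_fixture()
  an <- five_pop_ancestry()
  part <- an$model$root$partitions[[1]] # PC-1 AFR/nonAFR partition
  co <- fx$cohort
  haps <- co$phased[, rep(an$is_ref, each = 2)]
  grp <- ifelse(rep(co$panel$population[an$is_ref], each = 2) == "AFR",
                "AFR", "nonAFR")
  iset <- fx$isets[[1]]
  iset <- iset[order(iset$chrom, iset$pos), ]
  # independent re-evaluation of the criterion per tract and per prefix
  eval_z <- function(idx) {
    vals <- colSums((2 * haps[idx, , drop = FALSE] -
                       part$row_means[idx]) * part$gamma[idx])
    mu <- tapply(vals, grp, mean)
    v <- tapply(vals, grp, var)
    ng <- tapply(vals, grp, length)
    ps <- sqrt(sum((ng - 1) * v) / sum(ng - 1))
    if (ps > 0) abs(diff(mu)) / ps else Inf
  }
  checked <- 0
  for (ch in unique(part$tracts$chrom)) {
    rows <- which(part$tracts$chrom == ch & !part$tracts$low_confidence)
    if (length(rows) < 2) next
    for (t in utils::head(rows, -1)[1:min(3, length(rows) - 1)]) {
      idx <- part$loci_idx[[t]]
      expect_gte(eval_z(idx), 3)
      if (length(idx) > 1) { # one-locus-shorter window must fail
        expect_lt(eval_z(idx[-length(idx)]), 3)
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("training haplotypes classify to their own label on separated data", {
  fx <- perfect_reference()
  part <- partition_tracts(fx$haps, fx$grp, fx$iset, fx$gamma, fx$rm, alpha = 3)
  cls <- classify_tracts(part, fx$haps)
  expect_true(all(cls$label[, fx$grp == "A"] == "A"))
  expect_true(all(cls$label[, fx$grp == "B"] == "B"))
  expect_true(all(cls$score > 0))
  # a haplotype missing everywhere is unassigned
  cls_na <- classify_tracts(part, matrix(NA_integer_, 40, 1))
  expect_true(all(cls_na$label == "unassigned"))
})

test_that("centroid ties resolve by criterion", {
  part <- structure(list(
    tracts = data.frame(chrom = "1", start = 0, end = 1000, n_loci = 1,
                        z = 5, low_confidence = FALSE),
    loci_idx = list(1L), centroids = list(c(A = -1, B = 1)),
    pooled_sd = 0.5, gamma = 1, row_means = 1, groups = c("A", "B"),
    alpha = 3, chrom_lengths = c("1" = 1000)), class = "tract_partition")
  hap <- matrix(0.5, 1, 1) # projects to 2*0.5 - 1 = 0: equidistant
  relaxed <- classify_tracts(part, hap, criterion = "relaxed")
  stringent <- classify_tracts(part, hap, criterion = "stringent")
  expect_equal(relaxed$label[1, 1], "A") # first-listed group
  expect_equal(stringent$label[1, 1], "unassigned")
})

test_that("hierarchical aggregation respects agreement, disagreement and nesting", {
  an <- five_pop_ancestry()
  fx <- five_pop_fixture()
  co <- fx$cohort
  is_amr <- co$panel$population == "AMR"
  haps_amr <- co$phased[, rep(is_amr, each = 2)][, 1:20]
  subj <- co$panel$subject[is_amr][1:10]
  rel <- infer_ancestry(an$model, haps_amr, subj, criterion = "relaxed")
  str <- infer_ancestry(an$model, haps_amr, subj, criterion = "stringent")
  # tracts tile every haplotype over every chromosome
  for (tr in list(rel, str)) {
    len <- tapply(tr$end - tr$start, paste(tr$subject, tr$haplotype), sum)
    expect_true(all(len == sum(fx$chrom_lengths)))
  }
  # an interval labeled AFR at the root never carries an EUR/EAS refinement
  afr_rows <- grepl("^AFR", rel$path)
  expect_false(any(grepl("EUR|EAS", rel$path[afr_rows])))
  # stringent unanimity can only increase the unassigned fraction
  un_rel <- sum((rel$end - rel$start)[rel$label == "unassigned"])
  un_str <- sum((str$end - str$start)[str$label == "unassigned"])
  expect_lte(un_rel, un_str)
})

test_that("mosaic subjects recover their truth labels at the top level", {
  co <- two_pop_cohort()
  gm <- collapse_genotypes(co)
  pca <- pca_genotypes(gm, k_max = 1)
  iset <- select_necessary(pca$centered, pca$loadings, 1, loci = co$loci)
  chrlen <- tapply(co$loci$pos, co$loci$chrom, max)
  hier <- ancestry_decision(pcs = 1, groups = list(popA = "popA", popB = "popB"))
  model <- train_ancestry(co$phased, co$panel, hier, pca$loadings,
                          pca$centered$row_means, list(iset), alpha = 3,
                          chrom_lengths = chrlen)
  mo <- make_mosaic_subjects(co, 10,
                             breakpoint_law = list(type = "poisson", rate = 3),
                             seed = 5)
  tr <- infer_ancestry(model, mo$phased, mo$subjects, criterion = "relaxed")
  # length-weighted accuracy against exact truth, evaluated per locus
  sp <- co$scenario$locus_spacing_bp
  truth_lab <- function(sub, hap, ch) {
    rows <- mo$truth[mo$truth$subject == sub & mo$truth$haplotype == hap &
                       mo$truth$chrom == ch, ]
    rep(rows$lineage, rows$end_locus - rows$start_locus + 1L)
  }
  hits <- 0; tot <- 0
  for (sub in unique(tr$subject)) for (hap in 0:1) for (ch in names(chrlen)) {
    rows <- tr[tr$subject == sub & tr$haplotype == hap & tr$chrom == ch, ]
    lab <- character(chrlen[[ch]] / sp)
    for (i in seq_len(nrow(rows))) {
      sel <- which((seq_along(lab) - 0.5) * sp > rows$start[i] &
                     (seq_along(lab) - 0.5) * sp <= rows$end[i])
      lab[sel] <- rows$label[i]
    }
    tl <- truth_lab(sub, hap, ch)
    assigned <- lab != "unassigned"
    hits <- hits + sum(lab[assigned] == tl[assigned])
    tot <- tot + length(lab)
  }
  expect_gte(hits / tot, 0.8)
})

test_that("held-out reference subjects self-classify at the top level", {
  co <- two_pop_cohort()
  hold <- c(which(co$panel$population == "popA")[1:20],
            which(co$panel$population == "popB")[1:20])
  train_idx <- setdiff(seq_len(nrow(co$panel)), hold)
  gm <- collapse_genotypes(co)
  Xtr <- gm$X[, train_idx]
  pca <- pca_genotypes(Xtr, k_max = 1)
  iset <- select_necessary(pca$centered, pca$loadings, 1, loci = co$loci)
  chrlen <- tapply(co$loci$pos, co$loci$chrom, max)
  hier <- ancestry_decision(pcs = 1, groups = list(popA = "popA", popB = "popB"))
  model <- train_ancestry(co$phased[, rep(seq_len(nrow(co$panel)) %in% train_idx, each = 2)],
                          co$panel[train_idx, ], hier, pca$loadings,
                          pca$centered$row_means, list(iset), alpha = 3,
                          chrom_lengths = chrlen)
  tr <- infer_ancestry(model, co$phased[, rep(seq_len(nrow(co$panel)) %in% hold, each = 2)],
                       co$panel$subject[hold], criterion = "relaxed")
  tr$true_pop <- co$panel$population[match(tr$subject, co$panel$subject)]
  len <- tr$end - tr$start
  acc <- sum(len[tr$label == tr$true_pop]) / sum(len)
  expect_gte(acc, 0.9)
})

test_that("proportions sum to one and respect degenerate genomes", {
  tr <- data.frame(subject = "s1", haplotype = c(0, 1), chrom = "1",
                   start = 0, end = 100, path = "A", label = "A",
                   score = 1, criterion = "relaxed")
  pr <- summarize_proportions(tr)
  expect_equal(pr$A, 1)
  tr2 <- data.frame(subject = "s1", haplotype = c(0, 1), chrom = "1",
                    start = 0, end = 100, path = c("A", "B"),
                    label = c("A", "B"), score = 1, criterion = "relaxed")
  pr2 <- summarize_proportions(tr2)
  expect_equal(c(pr2$A, pr2$B), c(0.5, 0.5))
  an <- five_pop_ancestry()
  fx <- five_pop_fixture()
  is_amr <- fx$cohort$panel$population == "AMR"
  tr3 <- infer_ancestry(an$model, fx$cohort$phased[, rep(is_amr, each = 2)][, 1:10],
                        fx$cohort$panel$subject[is_amr][1:5], "stringent")
  pr3 <- summarize_proportions(tr3, level = 2)
  expect_equal(unname(rowSums(pr3[, -1])), rep(1, 5), tolerance = 1e-9)
})

test_that("proportions are robust to halving a reference population", {
  # the loadings are fixed; only the tract-partition training panel shrinks,
  # probing the sensitivity of partial projections to reference sizes
  fx <- five_pop_fixture()
  an <- five_pop_ancestry()
  co <- fx$cohort
  hier <- ancestry_decision(
    pcs = 1, groups = list(AFR = "AFR", nonAFR = c("EUR", "EAS")),
    children = list(nonAFR = ancestry_decision(
      pcs = c(2, 3), groups = list(EUR = "EUR", EAS = "EAS"))))
  keep <- an$is_ref
  keep[which(co$panel$population == "EAS")[c(TRUE, FALSE)]] <- FALSE
  half_model <- train_ancestry(co$phased[, rep(keep, each = 2)],
                               co$panel[keep, ], hier,
                               fx$pca$loadings, fx$pca$centered$row_means,
                               fx$isets, alpha = 3,
                               chrom_lengths = fx$chrom_lengths)
  is_amr <- co$panel$population == "AMR"
  test_cols <- rep(is_amr, each = 2)
  subj <- co$panel$subject[is_amr]
  full_pr <- summarize_proportions(
    infer_ancestry(an$model, co$phased[, test_cols][, 1:40],
                   subj[1:20], "relaxed"), level = 1)
  half_pr <- summarize_proportions(
    infer_ancestry(half_model, co$phased[, test_cols][, 1:40],
                   subj[1:20], "relaxed"), level = 1)
  shared <- intersect(colnames(full_pr), colnames(half_pr))
  shared <- setdiff(shared, "subject")
  d <- abs(as.matrix(full_pr[, shared]) - as.matrix(half_pr[, shared]))
  expect_lt(mean(d), 0.05)
  # per-subject changes are bounded by 5 points plus the label-resolution
  # floor of this genome: relabeling one root tract moves a proportion by
  # that tract's genome share, so the bound carries one largest-tract unit
  root <- an$model$root$partitions[[1]]$tracts
  tract_unit <- max(root$end - root$start) / sum(fx$chrom_lengths)
  expect_lt(max(d), 0.05 + tract_unit)
})
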