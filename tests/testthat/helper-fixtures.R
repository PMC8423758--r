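# shared fixtures, all generated in code under fixed seeds

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# random centered-genotype-like matrix fixture for linear-algebra tests
random_genotype_matrix <- function(n, m, seed) {
  set.seed(seed)
  matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.5, 0.3, 0.2)), n, m)
}

# small drift-separated two-population cohort (shared by informative-loci
# and ancestry tests); two chromosomes so tract logic sees boundaries
two_pop_cohort <- function() {
  memo("two_pop", {
    sc <- demographic_scenario(
      n_loci = 2000L,
      chromosomes = data.frame(name = c("1", "2"), n_loci = c(1000L, 1000L)),
      generations = 20L,
      ancestral = "popA",
      events = list(founding_event(4L, "popB", c(popA = 1))),
      capacity_default = 100L, founder_size_default = 15L,
      seed = 42L)
    run_scenario(sc)
  })
}

# full five-population preset over 10 chromosomes of 1000 loci (the layout
# used for ancestry and hotspot work) plus its PCA and informative sets
five_pop_fixture <- function() {
  memo("five_pop", {
    chroms <- data.frame(name = as.character(1:10), n_loci = 1000L)
    cohort <- run_scenario(preset_scenario("five-population", seed = 11L,
                                           chromosomes = chroms))
    gm <- collapse_genotypes(cohort)
    pca <- pca_genotypes(gm, k_max = 3)
    isets <- lapply(1:3, function(k) {
      select_necessary(pca$centered, pca$loadings, k, threshold = 0.9,
                       loci = cohort$loci)
    })
    list(cohort = cohort, gm = gm, pca = pca, isets = isets,
         chrom_lengths = tapply(cohort$loci$pos, cohort$loci$chrom, max))
  })
}

# trained hierarchical ancestry model on the five-population fixture
# (EUR / EAS / AFR references, root split on PC 1, EUR-vs-EAS on PCs 2-3)
five_pop_ancestry <- function() {
  memo("five_pop_ancestry", {
    fx <- five_pop_fixture()
    co <- fx$cohort
    is_ref <- co$panel$population %in% c("AFR", "EUR", "EAS")
    hier <- ancestry_decision(
      pcs = 1, groups = list(AFR = "AFR", nonAFR = c("EUR", "EAS")),
      children = list(nonAFR = ancestry_decision(
        pcs = c(2, 3), groups = list(EUR = "EUR", EAS = "EAS"))))
    model <- train_ancestry(co$phased[, rep(is_ref, each = 2)],
                            co$panel[is_ref, ], hier,
                            fx$pca$loadings, fx$pca$centered$row_means,
                            fx$isets, alpha = 3,
                            chrom_lengths = fx$chrom_lengths)
    list(model = model, is_ref = is_ref)
  })
}

# write a small plain-text VCF fixture and return its path
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(subjects) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t"))
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
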