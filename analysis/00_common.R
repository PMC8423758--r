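# Shared setup for the analysis scripts: builds (and caches under scratch/)
# the simulated five-population cohort, its PCA and the per-PC necessary
# informative sets. Every downstream script sources this file.

library(popinform)

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

COHORT_SEED <- 11L

# ten chromosomes of 1,000 loci: the genome layout used for tract- and
# window-level analyses (ten independent recombination targets per meiosis)
five_pop_chromosomes <- data.frame(name = as.character(1:10), n_loci = 1000L)

load_study <- function() {
  cache <- file.path(SCRATCH, sprintf("study_%d.rds", COHORT_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  message("simulating the five-population cohort (seed ", COHORT_SEED, ") ...")
  cohort <- run_scenario(preset_scenario("five-population", seed = COHORT_SEED,
                                         chromosomes = five_pop_chromosomes))
  gm <- collapse_genotypes(cohort)
  pca <- pca_genotypes(gm, k_max = 3)
  isets <- lapply(1:3, function(k) {
    select_necessary(pca$centered, pca$loadings, k, threshold = 0.9,
                     loci = cohort$loci)
  })
  study <- list(cohort = cohort, gm = gm, pca = pca, isets = isets,
                chrom_lengths = tapply(cohort$loci$pos, cohort$loci$chrom, max))
  saveRDS(study, cache)
  study
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path, " (", nrow(df), " rows)")
  invisible(path)
}
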