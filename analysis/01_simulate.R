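#!/usr/bin/env Rscript
# Simulate the three demographic presets and record what the founder-drift
# model produces: population sizes, and the exact founding-lineage shares
# carried by every population. The five-population cohort built here (and
# cached) feeds all downstream scripts.

source("analysis/00_common.R")

study <- load_study()
co <- study$cohort

message("populations at the final generation:")
print(table(co$panel$population))

lf <- lineage_fractions(co)
m <- merge(lf, co$panel, by = "subject")
lin_cols <- setdiff(names(lf), "subject")
by_pop <- aggregate(m[lin_cols], list(population = m$population), mean)
write_tsv(by_pop, "lineage_shares_by_population.tsv")

message("mean EUR lineage share: SAS = ",
        round(by_pop$EUR[by_pop$population == "SAS"], 3),
        " (founded at 60%), AMR = ",
        round(by_pop$EUR[by_pop$population == "AMR"], 3),
        " (founded at 40%)")

# the two three-population toy scenarios, at the default single-chromosome
# genome; their projections are examined in 02_pca.R
for (preset in c("sequential-3", "parallel-3")) {
  sc <- preset_scenario(preset, seed = COHORT_SEED)
  toy <- run_scenario(sc)
  saveRDS(toy, file.path(SCRATCH, paste0(preset, ".rds")))
  message(preset, ": ", nrow(toy$panel), " subjects in ",
          length(unique(toy$panel$population)), " populations")
}

# full on-disk export of the study cohort (VCF + panel + truth tracts)
export_cohort(co, file.path(SCRATCH, "five_population_cohort"))
message("cohort exported under ", file.path(SCRATCH, "five_population_cohort"))
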