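#!/usr/bin/env Rscript
# Dominant patterns of genotype change between populations, counted over
# all loci after quantizing each population's genotype-class profile. The
# admixed populations (SAS, AMR) are excluded: the partition analysis
# assumes tree-like splits. Expectation from the demographic model: most
# loci are invariant, and the top non-invariant pattern separates the
# first-split population (AFR) from everyone else.

source("analysis/00_common.R")

study <- load_study()

pats <- mine_patterns(study$gm$X, study$cohort$panel, delta = 0.2,
                      exclude = c("SAS", "AMR"))
write_tsv(head(pats, 50), "pattern_counts_top50.tsv")

n_loci <- sum(pats$count)
inv <- pats$count[pats$invariant]
message(sprintf("%d loci; invariant pattern covers %.1f%%",
                n_loci, 100 * sum(inv) / n_loci))
top <- pats[!pats$invariant, ][1, ]
message("top non-invariant pattern (", top$count, " loci): ", top$pattern)
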