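#!/usr/bin/env Rscript
# Transferability of reference-derived loadings: hold out 10% of the
# simulated subjects as an "external" cohort, recompute the reference PCA
# on the shared loci, and approximate the joint-data projections by
# loading-weighted sums. The matching table mirrors the per-PC signed
# correlations between joint-PCA and transferred projections, split into
# reference and external subjects.

source("analysis/00_common.R")

study <- load_study()
gm <- study$gm

set.seed(COHORT_SEED)
m <- ncol(gm$X)
ext_idx <- sort(sample(m, round(0.1 * m)))
mk <- function(cols) {
  structure(list(X = gm$X[, cols, drop = FALSE], loci = gm$loci,
                 subjects = study$cohort$subjects[cols]),
            class = "genotype_matrix")
}
hj <- harmonize_loci(mk(setdiff(seq_len(m), ext_idx)), mk(ext_idx))
message(sprintf("harmonized %d loci (%d discordant dropped); %d reference + %d external subjects",
                nrow(hj$loci), hj$n_discordant, sum(hj$is_ref), sum(!hj$is_ref)))

tp <- transfer_projection(hj, k_max = 3)
mp <- match_pcs(tp)
write_tsv(mp, "transfer_pc_matching.tsv")
message("per-PC correlations between joint-PCA and transferred projections:")
print(mp)

self <- transfer_projection(
  harmonize_loci(gm, structure(list(X = gm$X[, integer(0)], loci = gm$loci,
                                    subjects = character(0)),
                               class = "genotype_matrix")), k_max = 3)
message("self-transfer max |difference|: ",
        format(max(abs(self$transfer - self$joint)), digits = 3))
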