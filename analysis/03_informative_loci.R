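#!/usr/bin/env Rscript
# Necessary vs sufficient informative loci: truncation and accretion curves
# per PC, the selected necessary sets at the 0.9 correlation threshold,
# allele-frequency proxy projections, and homozygote-allele fractions of
# the top loci in each sign group.

source("analysis/00_common.R")

study <- load_study()
cg <- study$pca$centered
G <- study$pca$loadings
P <- study$pca$projections
co <- study$cohort

curves <- do.call(rbind, lapply(1:3, function(k) {
  tc <- truncation_curve(cg, G, k, step = 50, loci = co$loci)
  ac <- accretion_curve(cg, G, k, step = 50, loci = co$loci)
  rbind(cbind(pc = k, mode = "truncation", tc),
        cbind(pc = k, mode = "accretion", ac))
}))
write_tsv(curves, "truncation_accretion_curves.tsv")

for (k in 1:3) {
  tc <- curves[curves$pc == k & curves$mode == "truncation", ]
  ac <- curves[curves$pc == k & curves$mode == "accretion", ]
  n_keep9 <- max(tc$n_selected[tc$r >= 0.9 & !tc$degenerate])
  n_need9 <- min(ac$n_selected[ac$r >= 0.9])
  message(sprintf(
    "PC %d: r stays >= 0.9 after removing %d loci (necessary, dense); ",
    k, n_keep9),
    sprintf("r reaches 0.9 after adding only %d loci (sufficient, sparse)",
            n_need9))
}

iset_tab <- do.call(rbind, lapply(study$isets, function(s) {
  data.frame(pc = attr(s, "pc"), n_selected = nrow(s),
             achieved_r = attr(s, "achieved_r"),
             n_truncation = sum(s$provenance == "truncation"),
             n_frequency = sum(s$provenance == "frequency"))
}))
write_tsv(iset_tab, "necessary_loci_summary.tsv")

# proxy projections: population order per PC from the projections themselves
prox_tab <- do.call(rbind, lapply(1:3, function(k) {
  ord <- names(sort(tapply(P[, k], co$panel$population, mean)))
  freqs <- pop_genotype_freqs(study$gm$X, co$panel, ord)
  w <- proxy_weights(freqs, G[, k])
  iset <- study$isets[[k]]
  prox <- proxy_projection(cg, w, iset$locus)
  part <- partial_projection(cg, G, iset$locus, k)
  data.frame(pc = k,
             r_partial_vs_full = cor(part, P[, k]),
             r_proxy_vs_full = cor(prox, P[, k]),
             n_nonzero_weights = sum(w[iset$locus] != 0))
}))
write_tsv(prox_tab, "proxy_projection_correlations.tsv")
message("proxy vs full projection correlations: ",
        paste(sprintf("PC%d %.3f", prox_tab$pc, prox_tab$r_proxy_vs_full),
              collapse = ", "))

# homozygote fractions over the strongest loci of each sign group (PC 1-3)
hf_tab <- do.call(rbind, lapply(1:3, function(k) {
  iset <- study$isets[[k]]
  do.call(rbind, lapply(c(1, -1), function(sg) {
    K <- min(1000, sum(iset$sign_group == sg))
    hf <- homozygote_fractions(study$gm$X, iset, K, sg)
    data.frame(pc = k, sign_group = sg, subject = co$subjects[hf$subject],
               population = co$panel$population[hf$subject],
               frac0 = hf$frac0, frac2 = hf$frac2)
  }))
}))
hf_sum <- aggregate(hf_tab[c("frac0", "frac2")],
                    hf_tab[c("pc", "sign_group", "population")], mean)
write_tsv(hf_sum, "homozygote_fractions_by_population.tsv")
message("PC 1 positive-group mean homozygote fractions by population:")
print(hf_sum[hf_sum$pc == 1 & hf_sum$sign_group == 1, ])
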