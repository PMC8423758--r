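Package: popinform
Title: Necessary Informative Loci from Genotype PCA and Founder-Drift Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of population structure in diploid genotype data through
    principal component analysis and the necessary informative loci that carry
    it. Implements covariance-route PCA with per-locus SVD loadings,
    truncation/accretion selection of necessary and sufficient informative
    loci, allele-frequency proxy projections, genotype-change pattern mining,
    a Poisson hidden Markov scan for informative-locus hotspots, local
    ancestry deconvolution of admixed genomes by partial projections, and
    transfer of reference-derived loadings to external cohorts. Ships a
    forward-time founder-drift and admixture simulator with per-haplotype
    lineage truth used to validate the whole pipeline on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
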