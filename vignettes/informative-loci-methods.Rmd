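---
title: "Necessary informative loci: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Necessary informative loci: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Principal component analysis of a population genotype matrix separates
populations along a handful of leading components, but it does so through
millions of small per-locus contributions that are hard to interpret.
Classical ancestry-informative-marker (AIM) panels go the other way: a few
hundred loci *sufficient* to predict population identity. `popinform`
implements the complementary notion of **necessary informative loci** — the
loci whose *removal* degrades the PCA structure — together with everything
needed to study them: the projection algebra, the selection procedure,
allele-frequency proxy projections, genotype-change pattern mining, a
density hotspot scan, local-ancestry tract deconvolution and loading
transfer to external cohorts. Because real cohorts of the necessary scale
(millions of loci, thousands of subjects) are outside desk-scale testing,
the package also ships the forward-time founder-drift simulator that
generates all study inputs with exact per-haplotype lineage truth.

## Projection algebra

Let $X$ be the $n \times m$ genotype matrix (loci by subjects, minor-allele
counts in $\{0,1,2\}$) and $\tilde X = X - \bar X$ its row-centered form.
The package computes the eigendecomposition of the unscaled subject
covariance $C = \tilde X^{\mathsf T}\tilde X = E\Lambda E^{\mathsf T}$ and
the per-locus loadings $\Gamma = \tilde X E$, which equal $U\Sigma$ of the
SVD $\tilde X = U\Sigma V^{\mathsf T}$ without ever forming the
$n \times n$ side. Projections are available through two algebraically
identical routes, $P = E\Lambda$ and $P = \tilde X^{\mathsf T}\Gamma$, and
the identity is exercised in the test suite against a direct `svd()`
oracle. The **partial projection** over a locus subset $S$,
$P_{ik}(S) = \sum_{j \in S}\gamma_{jk}\tilde X_{ji}$, is the workhorse of
everything downstream: truncation/accretion curves, tract classification
and loading transfer are all partial projections over different subsets.

Numerical choices: eigenvalues below $10^{-9}$ of the largest are treated
as null space; each eigenvector is sign-oriented so its largest-magnitude
coordinate is positive, which makes loadings, selections and transfers
deterministic and invariant to subject permutation.

## Selecting necessary informative loci

Loci are ranked by loading; each truncation stage removes `step` more loci
from the top *and* the bottom of the ranking and records the Pearson
correlation between the truncated partial projection and the full
projection. The necessary set at threshold $r^\ast = 0.9$ is everything
removed up to the last stage still at $r \ge r^\ast$ (stages are consumed
in order; degenerate stages with an empty or constant remainder are
reported as $r = 0$ with a flag and do not terminate the scan). The union
with an allele-frequency criterion is taken afterwards: a locus also
qualifies when the per-population mean genotypes
$\mu^l = \sum_g f^l_g\, g$ are monotone along the component's population
order, and, for two-population components, when the one-sigma intervals
around the two means are disjoint. Ties in the loading ranking break by
(chromosome, position); the default step is $\max(1, n/1000)$ per side.

**Proxy projections** replace the loadings with allele-frequency margins:
$w_{ik} = \mathrm{sign}(\gamma_{ik})\min_l |\mu^l - \mu^{l+1}|$ when the
means are monotone and $0$ otherwise, so
$\hat P_{ik} = \sum_{j} w_{jk}\tilde X_{ji}$ needs only per-population
genotype frequencies. Monotonicity is non-strict: equal adjacent means give
margin zero, hence weight zero, so the boundary case is continuous.

## The founder-drift simulator

The simulator is the package's study-condition generator, not a fixture:
diploid individuals carry two haplotypes over `n_loci` biallelic loci; a
parallel lineage matrix records, for every allele, the founding lineage of
the segment it sits on. Its assumptions mirror the demographic model under
study: recombination is the only evolutionary mechanism (no mutation, no
selection, no post-founding migration); populations evolve by
non-overlapping-generation random mating (two distinct parents per
offspring, Poisson crossovers per chromosome at uniform inter-locus
boundaries); new populations appear by founder sampling from one parent (a
pure split) or two (an admixed founding with stated proportions), then
double per generation until carrying capacity.

Parameter defaults, chosen once as the study conditions:

* 10,000 loci, 20 generations, ancestral minor-allele frequencies
  Uniform(0.05, 0.95) — polymorphic with a spread of major/minor balance;
* capacity 200 diploids, founder size 20 for pure splits and 50 for
  admixed foundings — small enough for visible drift, large enough to keep
  founding-proportion variance a few percent;
* crossover rate 1 per chromosome per meiosis; one chromosome for the
  three- and five-population projection studies, ten chromosomes of 1,000
  loci wherever tract- or window-resolution matters (ancestry, hotspots).
  Twenty generations over a single chromosome leave long linkage blocks;
  ten chromosomes multiply the per-meiosis recombination events tenfold
  and are what makes minimal tracts a few hundred kilobases instead of
  megabases;
* mixed founder counts are apportioned by largest remainder (ties to the
  first-listed parent), so 60/40 at founder size 50 is exactly 30 + 20.

Lineage labels are rewritten to the new population at a pure split (the
split starts a new founding lineage) and copied unchanged at an admixed
founding, which is what makes the 60% EUR / 40% EAS founding of the SAS
analog (and 40/60 for AMR) a trackable ground truth. Founders are copied
from their parent population rather than removed; the parent persists
unchanged. The five-population preset is
AFR → Eurasian → {EUR, EAS} → {SAS = 0.6 EUR + 0.4 EAS,
AMR = 0.4 EUR + 0.6 EAS}; the intermediate Eurasian population keeps
evolving but is not reported in the output cohort.

What the simulator emulates — drift-driven population structure, founder
effects, admixture mosaics with exact truth — and what it does not:
mutation, selection, realistic recombination maps, continuous migration,
overlapping generations, genotyping error. Passing tests therefore show
that the algorithms recover drift-and-founding structure; they do not
certify behavior under selection, array artifacts or fine-scale
recombination heterogeneity.

## Pattern mining

Per-population genotype-class profiles $(f_0, f_1, f_2)$ are quantized to
3-bit vectors: class $g$ is set when $f_g \ge \max_{g'} f_{g'} - \delta$
with $\delta = 0.2$ — the maximal class is always set, near-ties are set
jointly. A locus's pattern is the population partition induced by equality
of the quantized vectors (identity is the population→vector map, free of
storage order); counts over loci are conservation-checked against the
locus total. The margin-to-max rule is a design choice: it is monotone,
symmetric in the classes and reproduces the clear-dominance example
(0.9, 0.1, 0.0) → (1,0,0). Admixed populations are excluded by default
since the partition reading assumes tree-like splits.

## Hotspot scan

Window counts of all loci (1 Mb tiling, locus at position $p$ in window
$\lfloor (p-1)/10^6 \rfloor$) are smoothed by a Poisson-emission hidden
Markov chain: 10 rate states initialized at count quantiles, sticky
transitions (self-probability 0.9, uniform otherwise), rates re-estimated
by up to 100 Baum–Welch sweeps (log-likelihood tolerance $10^{-6}$) with
the transition structure fixed. The per-window background rate is the
posterior-weighted state rate; a single state collapses to the global
Poisson MLE exactly. Informative-locus windows are tested against the
thinned expectation $\lambda_w = (\text{background rate}_w) \times
(\text{global informative fraction})$ with exact upper-tail Poisson
p-values computed in log space, so genome-scale magnitudes like
$10^{-50}$ are representable; adjacent significant windows merge into
hotspot intervals. The genome-scale calling threshold is $10^{-50}$;
simulated genomes of a few hundred windows use $10^{-10}$.

## Local-ancestry deconvolution

Training scans each chromosome's informative loci left to right and closes
a **minimal tract** as soon as the haplotype partial projections separate
every pair of reference groups by at least $\alpha = 3$ pooled
within-group standard deviations (a z-margin is scale-free, which is why
it was chosen over an absolute gap). A trailing window that never
separates merges into the previous tract; a chromosome that never
separates becomes one low-confidence tract. Haplotypes project with
doubled alleles centered by the training row means, so a haploid copy of a
homozygote lands on its diploid source. Tract bp boundaries are midpoints
between flanking informative loci, extended to the chromosome ends, so
every partition tiles the genome and partitions from different components
intersect cleanly.

Classification is nearest-centroid per tract with score = (second-best −
best distance)/pooled SD; haplotypes missing more than half a tract's loci
are unassigned. The hierarchy is configuration, not code: the shipped
simulation hierarchy is root PC 1 {AFR, nonAFR} with a nonAFR child on
PCs 2–3 {EUR, EAS}; the real-data hierarchy of the source analysis (PCs
2–4 for AMR/EUR, PC 6 for African and PC 7 for European subpopulations) is
expressible with the same constructor. Within a multi-component decision
the per-component tract labelings are intersected into refinement
intervals; the **relaxed** criterion keeps the strongest-scoring vote, the
**stringent** criterion requires unanimity and otherwise reports
"unassigned" — so relaxed assignments are always a superset. Exact
centroid ties go to the first-listed group under relaxed and to
"unassigned" under stringent.

Desk-scale caveat: with ten 10 Mb chromosomes the root partition has ~40
tracts, so one relabeled tract moves a per-subject proportion by ~2.5
points. The reference-size robustness check therefore bounds per-subject
changes by 5 points plus one largest-tract genome share — the
discretization unit of the statistic at this scale — while the mean change
stays well under 5 points.

## Loading transfer

External cohorts are harmonized by (chromosome, position) intersection;
loci whose major/minor allele sequences disagree between cohorts are
dropped and counted — without agreement there is no shared orientation.
The reference PCA is recomputed on the harmonized loci (coefficients come
from the reference data alone), the joint matrix is centered with joint
row means (reference-mean centering is exposed as an option; the choice is
a documented default, not a claim), and transferred projections are
partial projections of the joint data under the reference loadings.
Because nearby eigenvalues let components swap between the joint and
reference decompositions, matching is greedy by descending $|r|$ with
signed correlations reported separately for reference and external
subjects; pairs under $|r| = 0.2$ stay unmatched.

## Problem sizes and determinism

All analyses run on the simulated study conditions: the five-population
preset (1,000 subjects, 10,000 loci) for projections, selection, patterns,
ancestry and transfer; a 2,000-locus two-population cohort for
tract-level unit tests; 50–200 replicates at $N = 25$–50 for the
simulator calibration checks (neutral mean drift within 3 SE of zero,
drift variance near $p(1-p)/2N$, heterozygosity decay along
$(1-1/2N)^t$). Every stochastic step flows from a single seed — scenario
seeds drive the simulator, and scripts derive replicate seeds from their
`--seed` argument — so identical inputs give bit-identical outputs. The
acceptance script averages the inferred AMR EUR-tract proportion over five
replicate scenario seeds, reported as a percentage.

## Known limitations

* The simulator's genome is unrealistically small and uniformly spaced;
  tract resolution is bounded by the handful of recombination events that
  20 generations provide.
* The truncation scan orders loci once by full-data loading; interactions
  between removed loci (which could make "necessity" non-additive) are
  ignored, exactly as in the curve construction it implements.
* The hotspot background HMM is a smoother, not a mechanistic model; its
  state count and stickiness are tunable and the defaults are a
  reasonable operating point, not fitted constants.
* Pattern quantization with one margin parameter cannot express
  asymmetric dominance rules; $\delta$ is configurable.
* The local-ancestry classifier is 1-D per component by design (votes are
  aggregated across components); it does not model switch errors or use
  haplotype phase beyond the per-locus alleles.
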