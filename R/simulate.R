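#' @name simulate-population
#' @title Forward-time founder-drift simulator
#'
#' @description
#' Diploid populations are simulated forward in time under random mating with
#' recombination and no mutation. Each individual carries two haplotypes over
#' `n_loci` biallelic loci; alongside each allele the simulator tracks the
#' founding-lineage label of the haplotype segment it sits on, which yields
#' exact per-locus ancestry truth for every simulated subject. Populations
#' are represented as lists with an `alleles` matrix (loci x 2N, values 0/1),
#' a parallel integer `lineage` matrix with a `labels` vector decoding it,
#' a `name` and a `capacity`.
NULL

sample_init_freq <- function(law, n) {
  switch(law$law,
         uniform = stats::runif(n, law$min, law$max),
         fixed = rep(law$value, n),
         stop("unknown init_freq_law: ", law$law))
}

#' Initialize an ancestral population
#'
#' Draws per-locus ancestral minor-allele frequencies from the configured law
#' and samples every haplotype allele independently from them. All lineage
#' labels are set to the ancestral population.
#'
#' @param n_loci Number of biallelic loci.
#' @param size Number of diploid individuals (>= 2).
#' @param init_freq_law Frequency law, see [demographic_scenario()].
#' @param name Population label.
#' @param capacity Carrying capacity (defaults to `size`).
#' @return A population object; attribute `init_freq` stores the sampled
#'   per-locus frequencies.
#' @export
init_ancestral_population <- function(n_loci, size,
                                      init_freq_law = list(law = "uniform",
                                                           min = 0.05, max = 0.95),
                                      name = "ANC", capacity = NULL) {
  if (size < 2) stop("invalid scenario: ancestral population size must be >= 2")
  if (n_loci < 1) stop("invalid scenario: n_loci must be >= 1")
  freq <- sample_init_freq(init_freq_law, n_loci)
  alleles <- matrix(stats::rbinom(n_loci * 2L * size, 1L, freq),
                    nrow = n_loci, ncol = 2L * size)
  pop <- list(name = name,
              alleles = alleles,
              lineage = matrix(1L, n_loci, 2L * size),
              labels = name,
              capacity = if (is.null(capacity)) as.integer(size) else as.integer(capacity))
  attr(pop, "init_freq") <- freq
  class(pop) <- "sim_population"
  pop
}

# parental-haplotype choosers (1 or 2 per locus) for G gametes at once:
# per chromosome, each gamete gets a random starting phase and a
# Poisson(rate) number of crossovers at uniform inter-locus boundaries
# (two crossovers landing on the same boundary cancel, as in meiosis)
build_choosers <- function(chrom_sizes, rate, G) {
  blocks <- lapply(chrom_sizes, function(L) {
    phase <- sample.int(2L, G, replace = TRUE)
    if (L < 2L) return(matrix(phase, L, G, byrow = TRUE))
    ks <- stats::rpois(G, rate)
    tot <- sum(ks)
    if (tot == 0L) return(matrix(rep(phase, each = L), L, G))
    bp <- sample.int(L - 1L, tot, replace = TRUE)
    g_of <- rep.int(seq_len(G), ks)
    flips <- matrix(tabulate((g_of - 1L) * L + bp + 1L, nbins = L * G), L, G)
    switches <- apply(flips, 2, cumsum)
    matrix(1L + (rep(phase - 1L, each = L) + as.integer(switches)) %% 2L, L, G)
  })
  do.call(rbind, blocks)
}

#' Advance a population by one non-overlapping generation
#'
#' Each offspring draws two distinct parents uniformly at random; each
#' transmitted gamete recombines the parent's two haplotypes with a
#' Poisson(`crossover_rate`) number of crossovers per chromosome at uniform
#' inter-locus boundaries. Lineage labels ride through the same crossovers.
#' The population keeps its size, except below capacity, where it doubles
#' per generation until the capacity is reached (exponential growth phase).
#'
#' @param pop A population object.
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param chrom_sizes Integer vector of loci per chromosome (default: one
#'   chromosome spanning all loci).
#' @param target_size Override the next-generation size.
#' @return The next-generation population.
#' @export
advance_generation <- function(pop, crossover_rate = 1, chrom_sizes = NULL,
                               target_size = NULL) {
  n <- nrow(pop$alleles)
  N <- ncol(pop$alleles) %/% 2L
  if (N < 2) stop("population size must be >= 2 to mate")
  if (is.null(chrom_sizes)) chrom_sizes <- n
  if (is.null(target_size)) {
    cap <- if (is.null(pop$capacity)) N else pop$capacity
    target_size <- if (N < cap) min(2L * N, cap) else N
  }
  M <- as.integer(target_size)
  p1 <- sample.int(N, M, replace = TRUE)
  p2 <- sample.int(N - 1L, M, replace = TRUE)
  p2 <- p2 + (p2 >= p1) # distinct from p1, uniform over the rest
  parent_of_gamete <- as.vector(rbind(p1, p2))
  chooser <- build_choosers(chrom_sizes, crossover_rate, 2L * M)
  col_idx <- 2L * (rep(parent_of_gamete, each = n) - 1L) + as.vector(chooser)
  flat <- (col_idx - 1L) * n + rep.int(seq_len(n), 2L * M)
  out <- pop
  out$alleles <- matrix(pop$alleles[flat], n, 2L * M)
  out$lineage <- matrix(pop$lineage[flat], n, 2L * M)
  attr(out, "init_freq") <- NULL
  out
}

#' Found a new population from one or two parents
#'
#' Samples `founder_size` individuals without replacement, with per-parent
#' counts apportioned to the mixing proportions by the largest-remainder
#' rule. A pure (single-parent) split relabels the founders' lineage to the
#' new population, starting a new founding lineage; an admixed (two-parent)
#' founding copies the parents' labels unchanged so the mixture remains
#' trackable across later generations.
#'
#' @param event A [founding_event()].
#' @param pops Named list of existing population objects.
#' @param founder_size_default,capacity_default Scenario defaults used when
#'   the event does not override them.
#' @return The new population object at founder size.
#' @export
found_population <- function(event, pops,
                             founder_size_default = 20L,
                             capacity_default = 200L) {
  fs <- if (is.null(event$founder_size)) founder_size_default else event$founder_size
  cap <- if (is.null(event$capacity)) capacity_default else event$capacity
  counts <- apportion_counts(event$parents, fs)
  pure <- length(event$parents) == 1L
  labels <- unique(c(unlist(lapply(names(event$parents),
                                   function(p) pops[[p]]$labels)),
                     event$new_population))
  alleles <- list()
  lineage <- list()
  for (j in seq_along(event$parents)) {
    pname <- names(event$parents)[j]
    parent <- pops[[pname]]
    if (is.null(parent)) stop("invalid scenario: unknown parent population ", pname)
    Np <- ncol(parent$alleles) %/% 2L
    if (counts[j] > Np) {
      stop(sprintf("invalid scenario: founder draw of %d exceeds parent '%s' size %d",
                   counts[j], pname, Np))
    }
    idx <- sample.int(Np, counts[j])
    hap_cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    alleles[[j]] <- parent$alleles[, hap_cols, drop = FALSE]
    lin <- parent$lineage[, hap_cols, drop = FALSE]
    lineage[[j]] <- matrix(match(parent$labels, labels)[lin],
                           nrow(lin), ncol(lin))
  }
  lineage <- do.call(cbind, lineage)
  if (pure) lineage[] <- match(event$new_population, labels)
  structure(list(name = event$new_population,
                 alleles = do.call(cbind, alleles),
                 lineage = lineage,
                 labels = labels,
                 capacity = as.integer(cap)),
            class = "sim_population")
}

sim_locus_table <- function(sc) {
  data.frame(
    chrom = rep(sc$chromosomes$name, sc$chromosomes$n_loci),
    pos = unlist(lapply(sc$chromosomes$n_loci,
                        function(L) seq_len(L) * sc$locus_spacing_bp)),
    major = "A", minor = "B",
    call_rate = 1,
    stringsAsFactors = FALSE)
}

truth_from_lineage <- function(lineage, labels, subjects, loci) {
  chrom_r <- rle(loci$chrom)
  chrom_end <- cumsum(chrom_r$lengths)
  chrom_start <- chrom_end - chrom_r$lengths + 1L
  out <- vector("list", ncol(lineage))
  for (h in seq_len(ncol(lineage))) {
    per_chrom <- lapply(seq_along(chrom_r$values), function(ci) {
      iv <- rle_intervals(lineage[chrom_start[ci]:chrom_end[ci], h])
      data.frame(subject = subjects[(h + 1L) %/% 2L],
                 haplotype = (h + 1L) %% 2L, # 0 for odd column, 1 for even
                 chrom = chrom_r$values[ci],
                 start_locus = iv$start, end_locus = iv$end,
                 lineage = labels[iv$value],
                 stringsAsFactors = FALSE)
    })
    out[[h]] <- do.call(rbind, per_chrom)
  }
  do.call(rbind, out)
}

as_sim_cohort <- function(pops, sc) {
  report <- if (is.null(sc$report)) names(pops) else sc$report
  pops <- pops[report]
  labels <- unique(unlist(lapply(pops, `[[`, "labels")))
  alleles <- do.call(cbind, lapply(pops, `[[`, "alleles"))
  lineage <- do.call(cbind, lapply(pops, function(p) {
    matrix(match(p$labels, labels)[p$lineage], nrow(p$lineage), ncol(p$lineage))
  }))
  sizes <- vapply(pops, function(p) ncol(p$alleles) %/% 2L, integer(1))
  subjects <- unlist(lapply(names(pops), function(nm) {
    sprintf("%s_%03d", nm, seq_len(sizes[[nm]]))
  }), use.names = FALSE)
  panel <- data.frame(subject = subjects,
                      population = rep(names(pops), sizes),
                      stringsAsFactors = FALSE)
  loci <- sim_locus_table(sc)
  structure(list(phased = alleles,
                 loci = loci,
                 subjects = subjects,
                 panel = panel,
                 truth = truth_from_lineage(lineage, labels, subjects, loci),
                 lineage_labels = labels,
                 scenario = sc),
            class = "sim_cohort")
}

#' Run a demographic scenario
#'
#' Simulates the full scenario: the ancestral population is initialized at
#' carrying capacity, every generation all living populations advance by
#' random mating with recombination, and founding events create new
#' populations at their stated generations. Deterministic given the seed.
#'
#' @param sc A [demographic_scenario()].
#' @return A `sim_cohort`: `phased` (loci x 2m allele matrix), `loci` table,
#'   `panel` (subject to population), `truth` (per-haplotype lineage tracts),
#'   `lineage_labels` and the scenario itself.
#' @export
run_scenario <- function(sc) {
  validate_scenario(sc)
  set.seed(sc$seed)
  chrom_sizes <- sc$chromosomes$n_loci
  pops <- list()
  pops[[sc$ancestral]] <- init_ancestral_population(
    sc$n_loci, sc$capacity_default, sc$init_freq_law,
    name = sc$ancestral, capacity = sc$capacity_default)
  if (sc$generations > 0) {
    for (gen in seq_len(sc$generations)) {
      for (nm in names(pops)) {
        pops[[nm]] <- advance_generation(pops[[nm]], sc$crossover_rate, chrom_sizes)
      }
      for (e in sc$events) {
        if (e$generation == gen) {
          pops[[e$new_population]] <- found_population(
            e, pops, sc$founder_size_default, sc$capacity_default)
        }
      }
    }
  }
  as_sim_cohort(pops, sc)
}

#' Genome share of each founding lineage per subject
#'
#' Aggregates the exact lineage truth of a simulated cohort into per-subject
#' proportions: the fraction of the diploid genome (in locus units) carrying
#' each founding-lineage label.
#'
#' @param cohort A `sim_cohort` (or any truth data frame with `subject`,
#'   `start_locus`, `end_locus`, `lineage`).
#' @return Data frame with one row per subject and one column per lineage.
#' @export
lineage_fractions <- function(cohort) {
  truth <- if (is.data.frame(cohort)) cohort else cohort$truth
  len <- truth$end_locus - truth$start_locus + 1L
  tot <- tapply(len, truth$subject, sum)
  agg <- tapply(len, list(truth$subject, truth$lineage), sum, default = 0L)
  frac <- sweep(agg, 1, tot[rownames(agg)], "/")
  out <- data.frame(subject = rownames(frac), frac, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Build artificial admixed subjects with exact truth tracts
#'
#' Each haplotype of each artificial subject is a concatenation of segments
#' copied from randomly chosen reference haplotypes. Segment boundaries come
#' from the breakpoint law; each segment's source population is drawn from
#' the label mixture and then a haplotype of that population is copied
#' verbatim. The returned truth records the copied labels and breakpoints
#' exactly (segments are not merged even when adjacent labels coincide).
#'
#' @param reference A `sim_cohort` (or list with `phased`, `panel`, `loci`)
#'   providing labeled reference haplotypes from >= 1 population.
#' @param n_subjects Number of artificial diploid subjects.
#' @param breakpoint_law `list(type = "poisson", rate = r)` for Poisson(r)
#'   breakpoints per chromosome at uniform boundaries, or
#'   `list(type = "fixed", breaks = i)` for fixed within-chromosome boundary
#'   indices (a break at i splits loci 1..i from i+1..L).
#' @param label_probs Named mixture over source populations (default uniform).
#' @param seed Optional seed.
#' @return A `sim_cohort`-shaped list; `panel$population` is `"MIX"`.
#' @export
make_mosaic_subjects <- function(reference, n_subjects,
                                 breakpoint_law = list(type = "poisson", rate = 1),
                                 label_probs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haps <- reference$phased
  panel <- reference$panel
  if (is.null(haps) || is.null(panel) || nrow(panel) == 0) {
    stop("empty reference set")
  }
  pops <- unique(panel$population)
  if (is.null(label_probs)) {
    label_probs <- stats::setNames(rep(1 / length(pops), length(pops)), pops)
  }
  hap_pop <- rep(panel$population, each = 2L)
  n <- nrow(haps)
  loci <- reference$loci
  chrom_r <- rle(loci$chrom)
  chrom_end <- cumsum(chrom_r$lengths)
  chrom_start <- chrom_end - chrom_r$lengths + 1L
  subjects <- sprintf("mix_%03d", seq_len(n_subjects))
  alleles <- matrix(NA_integer_, n, 2L * n_subjects)
  truth <- list()
  for (h in seq_len(2L * n_subjects)) {
    for (ci in seq_along(chrom_r$values)) {
      L <- chrom_r$lengths[ci]
      off <- chrom_start[ci] - 1L
      breaks <- if (breakpoint_law$type == "fixed") {
        sort(unique(as.integer(breakpoint_law$breaks)))
      } else {
        k <- min(stats::rpois(1L, breakpoint_law$rate), L - 1L)
        if (k > 0L) sort(sample.int(L - 1L, k)) else integer(0)
      }
      breaks <- breaks[breaks >= 1L & breaks < L]
      seg_start <- c(1L, breaks + 1L)
      seg_end <- c(breaks, L)
      for (s in seq_along(seg_start)) {
        src_pop <- sample(names(label_probs), 1L, prob = label_probs)
        src_hap <- sample(which(hap_pop == src_pop), 1L)
        rows <- (off + seg_start[s]):(off + seg_end[s])
        alleles[rows, h] <- haps[rows, src_hap]
        truth[[length(truth) + 1L]] <- data.frame(
          subject = subjects[(h + 1L) %/% 2L],
          haplotype = (h + 1L) %% 2L,
          chrom = chrom_r$values[ci],
          start_locus = seg_start[s], end_locus = seg_end[s],
          lineage = src_pop, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(phased = alleles,
                 loci = loci,
                 subjects = subjects,
                 panel = data.frame(subject = subjects, population = "MIX",
                                    stringsAsFactors = FALSE),
                 truth = do.call(rbind, truth),
                 lineage_labels = names(label_probs)),
            class = "sim_cohort")
}
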