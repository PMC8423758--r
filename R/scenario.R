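#' Founding event of a new population
#'
#' A new population is created at `generation` by drawing `founder_size`
#' individuals from one parent population (a pure split) or from two parent
#' populations in stated mixing proportions (an admixed founding). The new
#' population then doubles each generation until it reaches `capacity`.
#'
#' @param generation Integer generation (>= 1) at which the population appears.
#' @param new_population Label of the population being founded.
#' @param parents Named numeric vector of mixing proportions, names are parent
#'   population labels. One parent must have proportion 1; two parents must
#'   have proportions in (0, 1) summing to 1.
#' @param founder_size Number of founding individuals (defaults from scenario).
#' @param capacity Carrying capacity (defaults from scenario).
#' @return A `founding_event` object.
#' @export
founding_event <- function(generation, new_population, parents,
                           founder_size = NULL, capacity = NULL) {
  if (is.null(names(parents)) || any(names(parents) == "")) {
    stop("`parents` must be a named vector of mixing proportions")
  }
  if (abs(sum(parents) - 1) > 1e-9) {
    stop("mixing proportions must sum to 1")
  }
  if (length(parents) == 1 && abs(parents[[1]] - 1) > 1e-9) {
    stop("a single-parent founding must have proportion 1")
  }
  if (length(parents) == 2 && any(parents <= 0 | parents >= 1)) {
    stop("a two-parent founding needs proportions strictly in (0, 1)")
  }
  if (length(parents) > 2) stop("at most two parent populations are supported")
  structure(list(generation = as.integer(generation),
                 new_population = as.character(new_population),
                 parents = parents,
                 founder_size = founder_size,
                 capacity = capacity),
            class = "founding_event")
}

#' Demographic scenario for the forward-time simulator
#'
#' Describes an ancestral population plus an ordered series of founding
#' events (splits and admixed foundings), the genome layout, and the
#' stochastic laws of the simulation. Random mating with recombination and
#' no mutation drives allele-frequency change, so population structure in
#' the simulated cohort arises purely from founder sampling and drift.
#'
#' @param n_loci Total number of biallelic loci.
#' @param chromosomes Data frame with columns `name` and `n_loci` partitioning
#'   the loci, or NULL for a single chromosome.
#' @param generations Total generations simulated after the ancestral state.
#' @param events List of [founding_event()] objects.
#' @param capacity_default Individuals per population at carrying capacity.
#' @param founder_size_default Individuals drawn at a founding event.
#' @param init_freq_law Ancestral minor-allele frequency law: a list with
#'   `law = "uniform"` (`min`, `max`) or `law = "fixed"` (`value`).
#' @param crossover_rate Expected crossovers per chromosome per meiosis
#'   (Poisson).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param ancestral Label of the ancestral population.
#' @param report Labels of populations included in the output cohort
#'   (default: all populations alive at the final generation).
#' @param locus_spacing_bp Physical spacing between adjacent loci in bp, used
#'   to assign positions on each chromosome.
#' @return A `demographic_scenario` object.
#' @export
demographic_scenario <- function(n_loci = 10000L,
                                 chromosomes = NULL,
                                 generations = 20L,
                                 events = list(),
                                 capacity_default = 200L,
                                 founder_size_default = 20L,
                                 init_freq_law = list(law = "uniform",
                                                      min = 0.05, max = 0.95),
                                 crossover_rate = 1,
                                 seed = 1L,
                                 ancestral = "ANC",
                                 report = NULL,
                                 locus_spacing_bp = 10000L) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(name = "1", n_loci = as.integer(n_loci),
                              stringsAsFactors = FALSE)
  }
  if (sum(chromosomes$n_loci) != n_loci) {
    stop("locus counts over chromosomes must sum to n_loci")
  }
  sc <- structure(list(n_loci = as.integer(n_loci),
                       chromosomes = chromosomes,
                       generations = as.integer(generations),
                       events = events,
                       capacity_default = as.integer(capacity_default),
                       founder_size_default = as.integer(founder_size_default),
                       init_freq_law = init_freq_law,
                       crossover_rate = crossover_rate,
                       seed = as.integer(seed),
                       ancestral = ancestral,
                       report = report,
                       locus_spacing_bp = as.integer(locus_spacing_bp)),
                  class = "demographic_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  founded <- stats::setNames(0L, sc$ancestral)
  gens <- vapply(sc$events, function(e) e$generation, integer(1))
  if (is.unsorted(gens)) stop("invalid scenario: events must be ordered by generation")
  for (e in sc$events) {
    if (!inherits(e, "founding_event")) stop("events must be founding_event objects")
    if (e$generation < 1 || e$generation > sc$generations) {
      stop("invalid scenario: event generation outside 1..generations")
    }
    for (p in names(e$parents)) {
      if (!p %in% names(founded)) {
        stop(sprintf("invalid scenario: parent '%s' of '%s' not founded earlier",
                     p, e$new_population))
      }
      if (founded[[p]] >= e$generation) {
        stop(sprintf("invalid scenario: parent '%s' not founded strictly before generation %d",
                     p, e$generation))
      }
    }
    if (e$new_population %in% names(founded)) {
      stop(sprintf("invalid scenario: population '%s' founded twice", e$new_population))
    }
    fs <- if (is.null(e$founder_size)) sc$founder_size_default else e$founder_size
    cap <- if (is.null(e$capacity)) sc$capacity_default else e$capacity
    if (fs < 1 || fs > cap) stop("invalid scenario: need 1 <= founder_size <= capacity")
    founded[e$new_population] <- e$generation
  }
  invisible(sc)
}

#' Preset demographic scenarios
#'
#' Three shipped scenarios over 10,000 loci and 20 generations:
#' \describe{
#'   \item{`sequential-3`}{pop1 -> pop2 -> pop3, successive pure splits.}
#'   \item{`parallel-3`}{pop2 <- pop1 -> pop3, two pure splits from pop1.}
#'   \item{`five-population`}{AFR -> EUA -> \{EUR, EAS\}; then SAS founded by
#'     mixing 60\% EUR with 40\% EAS and AMR by mixing 40\% EUR with 60\% EAS.
#'     The intermediate EUA population keeps evolving but is excluded from
#'     the reported cohort.}
#' }
#'
#' @param name One of `"sequential-3"`, `"parallel-3"`, `"five-population"`.
#' @param seed Integer seed.
#' @param n_loci Number of loci (default 10000).
#' @param chromosomes Optional chromosome layout (see [demographic_scenario()]).
#' @return A `demographic_scenario`.
#' @export
preset_scenario <- function(name, seed = 1L, n_loci = 10000L,
                            chromosomes = NULL) {
  name <- match.arg(name, c("sequential-3", "parallel-3", "five-population"))
  if (name == "sequential-3") {
    demographic_scenario(
      n_loci = n_loci, chromosomes = chromosomes, seed = seed,
      ancestral = "pop1",
      events = list(
        founding_event(6L, "pop2", c(pop1 = 1)),
        founding_event(12L, "pop3", c(pop2 = 1))))
  } else if (name == "parallel-3") {
    demographic_scenario(
      n_loci = n_loci, chromosomes = chromosomes, seed = seed,
      ancestral = "pop1",
      events = list(
        founding_event(6L, "pop2", c(pop1 = 1)),
        founding_event(6L, "pop3", c(pop1 = 1))))
  } else {
    demographic_scenario(
      n_loci = n_loci, chromosomes = chromosomes, seed = seed,
      ancestral = "AFR",
      report = c("AFR", "EUR", "EAS", "SAS", "AMR"),
      events = list(
        founding_event(4L, "EUA", c(AFR = 1)),
        founding_event(8L, "EUR", c(EUA = 1)),
        founding_event(8L, "EAS", c(EUA = 1)),
        founding_event(12L, "SAS", c(EUR = 0.6, EAS = 0.4), founder_size = 50L),
        founding_event(12L, "AMR", c(EUR = 0.4, EAS = 0.6), founder_size = 50L)))
  }
}

#' Read a demographic scenario from a YAML file
#'
#' Keys mirror the fields of [demographic_scenario()]; each event is a map
#' with `generation`, `new_population`, `parents` (label -> proportion) and
#' optional `founder_size` / `capacity`.
#'
#' @param path Path to a YAML scenario file.
#' @return A `demographic_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  events <- lapply(y$events, function(e) {
    founding_event(e$generation, e$new_population, unlist(e$parents),
                   founder_size = e$founder_size, capacity = e$capacity)
  })
  chromosomes <- if (!is.null(y$chromosomes)) {
    data.frame(name = vapply(y$chromosomes, function(ch) as.character(ch$name), ""),
               n_loci = vapply(y$chromosomes, function(ch) as.integer(ch$n_loci), 0L),
               stringsAsFactors = FALSE)
  } else NULL
  args <- y[setdiff(names(y), c("events", "chromosomes"))]
  do.call(demographic_scenario,
          c(args, list(events = events, chromosomes = chromosomes)))
}
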