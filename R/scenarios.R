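#' Scenario for simulating clone-by-substrate catabolic profiles
#'
#' Describes a set of replicate populations assayed on a multi-substrate
#' growth plate (one OD660 reading per clone per substrate, as on a Biolog
#' GN2 microplate). In `specialist` mode each clone is assigned one of
#' `n_specialist_types` disjoint substrate niches and grows at
#' `baseline_mean + specialist_gain` on its niche substrates and
#' `baseline_mean - specialist_loss` elsewhere (a growth trade-off). In
#' `generalist` mode every clone grows at `generalist_mean` on every
#' substrate. I.i.d. Gaussian noise with standard deviation `noise_sd` is
#' added and readings are truncated at zero.
#'
#' @param n_populations_per_treatment Number of replicate populations.
#' @param n_clones Clones sampled per population.
#' @param n_substrates Substrates on the plate.
#' @param baseline_mean,specialist_gain,specialist_loss Mean OD components
#'   for specialist populations (all in OD660 units).
#' @param niche_size Substrates per specialist niche.
#' @param n_specialist_types Number of disjoint niches per population;
#'   `niche_size * n_specialist_types` must not exceed `n_substrates`.
#' @param generalist_mean Mean OD for generalist populations.
#' @param noise_sd Standard deviation of the additive measurement noise.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list of class `biolog_scenario`.
#' @seealso [simulate_biolog()]
#' @export
biolog_scenario <- function(n_populations_per_treatment = 6,
                            n_clones = 10,
                            n_substrates = 96,
                            baseline_mean = 0.5,
                            specialist_gain = 0.5,
                            specialist_loss = 0.2,
                            niche_size = 12,
                            n_specialist_types = 4,
                            generalist_mean = 0.5,
                            noise_sd = 0.05,
                            seed = 1L) {
  if (n_clones < 1 || n_substrates < 1 || n_populations_per_treatment < 1) {
    abort("population, clone and substrate counts must be positive",
          class = "gxediv_config_error")
  }
  if (niche_size * n_specialist_types > n_substrates) {
    abort(paste0("niche capacity exceeded: ", n_specialist_types, " niches of ",
                 niche_size, " substrates do not fit on ", n_substrates,
                 " substrates"),
          class = "gxediv_config_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative", class = "gxediv_config_error")
  }
  structure(
    list(n_populations_per_treatment = as.integer(n_populations_per_treatment),
         n_clones = as.integer(n_clones),
         n_substrates = as.integer(n_substrates),
         baseline_mean = baseline_mean,
         specialist_gain = specialist_gain,
         specialist_loss = specialist_loss,
         niche_size = as.integer(niche_size),
         n_specialist_types = as.integer(n_specialist_types),
         generalist_mean = generalist_mean,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "biolog_scenario")
}

#' Scenario for simulating per-population variant-proportion tables
#'
#' Each population receives `Poisson(mean_variants_per_population)` private
#' variants whose pooled proportions are drawn from a
#' `Beta(proportion_alpha, proportion_beta)` distribution, plus any shared
#' variants defined in `shared_variant_spec` — a data frame with columns
#' `variant_id`, `treatment`, `fraction` (of that treatment's populations
#' carrying the variant) and optionally `proportion` (fixed pooled
#' proportion; `NA` draws from the Beta).
#'
#' @param n_populations Populations per treatment.
#' @param mean_variants_per_population Poisson mean for private variants.
#' @param proportion_alpha,proportion_beta Beta shape parameters (> 0).
#' @param shared_variant_spec Data frame as described above, or `NULL`.
#' @param seed Integer seed.
#'
#' @return A list of class `variant_scenario`.
#' @seealso [simulate_variant_tables()]
#' @export
variant_scenario <- function(n_populations = 6,
                             mean_variants_per_population = 2.5,
                             proportion_alpha = 1,
                             proportion_beta = 2,
                             shared_variant_spec = NULL,
                             seed = 1L) {
  if (proportion_alpha <= 0 || proportion_beta <= 0) {
    abort("Beta shape parameters must be positive",
          class = "gxediv_config_error")
  }
  if (mean_variants_per_population < 0) {
    abort("mean_variants_per_population must be non-negative",
          class = "gxediv_config_error")
  }
  if (!is.null(shared_variant_spec)) {
    shared_variant_spec <- as_tibble(shared_variant_spec)
    needed <- c("variant_id", "treatment", "fraction")
    if (!all(needed %in% names(shared_variant_spec))) {
      abort("shared_variant_spec needs columns variant_id, treatment, fraction",
            class = "gxediv_config_error")
    }
    if (!"proportion" %in% names(shared_variant_spec)) {
      shared_variant_spec$proportion <- NA_real_
    }
  }
  structure(
    list(n_populations = as.integer(n_populations),
         mean_variants_per_population = mean_variants_per_population,
         proportion_alpha = proportion_alpha,
         proportion_beta = proportion_beta,
         shared_variant_spec = shared_variant_spec,
         seed = as.integer(seed)),
    class = "variant_scenario")
}

#' Scenario for simulating a blue/white competition assay
#'
#' A focal (white, evolved) mix competes 50:50 against a marked (blue,
#' ancestral) strain. Growth between the two timepoints is deterministic and
#' chosen so that the odds ratio of the focal fractions equals
#' `true_relative_fitness`; all stochasticity comes from binomial sampling of
#' plated colonies, which isolates the behaviour of the fitness estimator.
#'
#' @param true_relative_fitness True odds-ratio fitness (> 0).
#' @param n0_total Total starting inoculum in CFU (split 50:50).
#' @param doublings Deterministic doublings of the reference strain over the
#'   assay (used only for the Malthusian bookkeeping).
#' @param plated_colonies_mean Expected colonies counted per plate.
#' @param seed Integer seed.
#'
#' @return A list of class `competition_scenario`.
#' @seealso [simulate_competition()]
#' @export
competition_scenario <- function(true_relative_fitness = 1.5,
                                 n0_total = 1e8,
                                 doublings = 10,
                                 plated_colonies_mean = 200L,
                                 seed = 1L) {
  if (true_relative_fitness <= 0) {
    abort("true_relative_fitness must be positive",
          class = "gxediv_config_error")
  }
  if (plated_colonies_mean < 2) {
    abort("plated_colonies_mean must be at least 2",
          class = "gxediv_config_error")
  }
  structure(
    list(true_relative_fitness = true_relative_fitness,
         n0_total = n0_total,
         doublings = doublings,
         plated_colonies_mean = as.integer(plated_colonies_mean),
         seed = as.integer(seed)),
    class = "competition_scenario")
}

#' Scenario for simulating per-clone sequencing reads with planted variants
#'
#' A random reference genome of `genome_length` bp is generated; each clone
#' is sequenced to `coverage_per_clone`-fold depth with uniformly placed
#' single-end reads. `planted_variants` is a data frame with columns `pos`
#' (1-based), `ref`, `alt` and `carriers` (a list-column of carrier clone
#' indices); carrier clones emit the alt base at the planted site, subject to
#' a per-base sequencing `error_rate` applied everywhere.
#'
#' @param genome_length Genome length in bp.
#' @param n_clones Number of clones.
#' @param planted_variants Data frame as described, or `NULL` for none.
#' @param read_length Read length in bp (must not exceed `genome_length`).
#' @param coverage_per_clone Fold coverage per clone.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#'
#' @return A list of class `read_scenario`.
#' @seealso [simulate_clone_reads()]
#' @export
read_scenario <- function(genome_length = 10000L,
                          n_clones = 10L,
                          planted_variants = NULL,
                          read_length = 100L,
                          coverage_per_clone = 20,
                          error_rate = 0,
                          seed = 1L) {
  if (read_length > genome_length) {
    abort("read_length exceeds genome_length", class = "gxediv_config_error")
  }
  if (error_rate < 0 || error_rate > 1) {
    abort("error_rate must lie in [0, 1]", class = "gxediv_config_error")
  }
  if (!is.null(planted_variants)) {
    planted_variants <- as_tibble(planted_variants)
    needed <- c("pos", "ref", "alt", "carriers")
    if (!all(needed %in% names(planted_variants))) {
      abort("planted_variants needs columns pos, ref, alt, carriers",
            class = "gxediv_config_error")
    }
    pos <- planted_variants$pos
    if (anyDuplicated(pos) || any(pos < 1) || any(pos > genome_length)) {
      abort("planted positions must be unique, 1-based and within the genome",
            class = "gxediv_config_error")
    }
  }
  structure(
    list(genome_length = as.integer(genome_length),
         n_clones = as.integer(n_clones),
         planted_variants = planted_variants,
         read_length = as.integer(read_length),
         coverage_per_clone = coverage_per_clone,
         error_rate = error_rate,
         seed = as.integer(seed)),
    class = "read_scenario")
}
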