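#' Run the full diversification analysis on a simulated experiment
#'
#' End-to-end driver mirroring the analysis of a two-treatment evolution
#' experiment: simulate catabolic profiles, competition assays and variant
#' tables; filter substrates; decompose growth into variance components and
#' compare treatments with nested-model F tests; estimate relative fitness
#' and run the targeted Holm-adjusted contrasts; compute per-population
#' diversity metrics with rank-sum treatment comparisons; and compare
#' treatment genetic composition with PERMANOVA, beta-dispersion and NMDS.
#' All outputs (TSV/CSV tables plus a JSON manifest recording seeds and
#' configuration) are written under `out_dir` when it is not `NULL`.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param biolog,variants,competition Scenario objects; defaults are the
#'   package's standard two-treatment experiment (6 populations per
#'   treatment, 10 clones, 96 substrates; Poisson(2.5) variants per
#'   population with one treatment-diagnostic shared variant per treatment;
#'   true fitness 1.5 with 200-colony plates).
#' @param od_threshold Substrate filter threshold (OD660).
#' @param min_prop Variant detection floor.
#' @param n_perm PERMANOVA permutations.
#'
#' @return A list with elements `growth`, `components`, `component_tests`,
#'   `fitness`, `contrasts`, `variants`, `diversity`, `diversity_tests`,
#'   `permanova`, `dispersion`, `nmds`.
#' @export
run_pipeline <- function(seed = 1L, out_dir = NULL,
                         biolog = NULL, variants = NULL, competition = NULL,
                         od_threshold = 0.1, min_prop = 0.1, n_perm = 9999) {
  seed <- as.integer(seed)
  biolog <- biolog %||% biolog_scenario(seed = seed)
  variants <- variants %||% variant_scenario(
    shared_variant_spec = tibble(
      variant_id = c("shared_het", "shared_hom"),
      treatment = c("heterogeneous", "homogeneous"),
      fraction = c(2 / 3, 1),
      proportion = c(NA_real_, 0.6)),
    seed = seed + 11L)

  # growth profiles -> variance components -> treatment comparison
  growth <- simulate_biolog_experiment(biolog) |> filter_substrates(od_threshold)
  components <- gxe_decompose(growth)
  component_tests <- purrr::map_dfr(
    c("V_P", "V_G", "V_E", "R", "I"),
    function(comp) dplyr::bind_cols(
      tibble(component = comp),
      lm_f_test(components[[comp]], components$treatment)))

  # competition assays per population x competition environment
  combos <- tidyr::expand_grid(
    evolution_env = c("heterogeneous", "homogeneous"),
    population = seq_len(biolog$n_populations_per_treatment),
    competition_env = c("heterogeneous", "homogeneous"))
  # local adaptation baked into the simulated truth: fitter at home
  combos$true_w <- ifelse(combos$evolution_env == combos$competition_env,
                          1.9, 1.2)
  fitness <- purrr::pmap_dfr(
    combos,
    function(evolution_env, population, competition_env, true_w) {
      sc <- competition %||% competition_scenario(
        true_relative_fitness = true_w,
        seed = seed + 101L * population +
          7L * (evolution_env == "homogeneous") +
          3L * (competition_env == "homogeneous"))
      dplyr::bind_cols(
        tibble(population_id = sprintf("%s_P%d", substr(evolution_env, 1, 3),
                                       population),
               evolution_env = evolution_env,
               competition_env = competition_env),
        simulate_competition(sc)[, c("white_T0", "blue_T0",
                                     "white_T7", "blue_T7")])
    }) |> assay_fitness()
  contrasts <- fitness_contrasts(fitness)

  # pooled variants -> diversity metrics + multivariate comparison
  vtab <- simulate_variant_tables(variants)
  diversity <- diversity_metrics(vtab, min_prop = min_prop)
  diversity_tests <- purrr::map_dfr(
    c("genetic_distance", "n_variants", "alpha"),
    function(metric) {
      x <- diversity[[metric]][diversity$treatment == "heterogeneous"]
      y <- diversity[[metric]][diversity$treatment == "homogeneous"]
      dplyr::bind_cols(tibble(metric = metric), ranksum_w(x, y))
    })
  fm <- variant_feature_matrix(vtab)
  grp <- vtab$treatment[match(rownames(fm), vtab$population_id)]
  dmat <- euclidean_distances(fm)
  perm <- permanova(dmat, grp, n_perm = n_perm, seed = seed + 17L)
  disp <- beta_dispersion(dmat, grp)
  ord <- nmds_ordination(dmat, k = 2, seed = seed + 19L, groups = grp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(components, file.path(out_dir, "variance_components.tsv"))
    readr::write_csv(component_tests,
                     file.path(out_dir, "component_tests.csv"))
    readr::write_csv(fitness, file.path(out_dir, "fitness.csv"))
    readr::write_csv(contrasts, file.path(out_dir, "fitness_contrasts.csv"))
    write_variant_table(vtab, file.path(out_dir, "variant_tables.tsv"))
    readr::write_tsv(diversity, file.path(out_dir, "diversity_metrics.tsv"))
    readr::write_csv(diversity_tests,
                     file.path(out_dir, "diversity_tests.csv"))
    readr::write_csv(tidy(perm), file.path(out_dir, "permanova.csv"))
    readr::write_csv(glance(disp), file.path(out_dir, "beta_dispersion.csv"))
    readr::write_tsv(tidy(ord), file.path(out_dir, "nmds_coordinates.tsv"))
    write_manifest(out_dir, seed,
                   config = list(od_threshold = od_threshold,
                                 min_prop = min_prop, n_perm = n_perm))
  }

  list(growth = growth, components = components,
       component_tests = component_tests,
       fitness = fitness, contrasts = contrasts,
       variants = vtab, diversity = diversity,
       diversity_tests = diversity_tests,
       permanova = perm, dispersion = disp, nmds = ord)
}
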