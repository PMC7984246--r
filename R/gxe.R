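#' Filter substrates by a minimum-growth rule across the whole experiment
#'
#' A substrate is retained only if every clone of every population in `data`
#' grew at least minimally on it — strictly, if the minimum OD over all
#' clones is greater than `threshold` (default 0.1 OD660; a reading exactly
#' at the threshold drops the substrate). Filtering on the global clone set
#' gives one common substrate panel for all populations, so variance
#' components are comparable across populations and treatments.
#'
#' @param data Long tibble with columns `clone_id`, `substrate_id`, `od`
#'   (and usually `population_id`, `treatment`).
#' @param threshold Minimum OD660; strict inequality.
#'
#' @return `data` restricted to the retained substrates, with the retained
#'   substrate ids in the `"retained_substrates"` attribute.
#' @export
filter_substrates <- function(data, threshold = 0.1) {
  check_od_data(data)
  keep <- data |>
    dplyr::group_by(.data$substrate_id) |>
    dplyr::summarise(min_od = min(.data$od), .groups = "drop") |>
    dplyr::filter(.data$min_od > threshold) |>
    dplyr::pull(.data$substrate_id)
  if (length(keep) == 0) {
    abort(paste0("no substrate passed the minimum-growth filter at OD > ",
                 threshold, "; review the threshold"),
          class = "gxediv_filter_error")
  }
  out <- dplyr::filter(data, .data$substrate_id %in% keep)
  attr(out, "retained_substrates") <- keep
  out
}

# long tibble (one population) -> clones x substrates base matrix
od_matrix <- function(data) {
  check_od_data(data)
  if ("population_id" %in% names(data) &&
      dplyr::n_distinct(data$population_id) > 1) {
    abort("data contains more than one population; group or split first",
          class = "gxediv_input_error")
  }
  wide <- data |>
    dplyr::select("clone_id", "substrate_id", "od") |>
    tidyr::pivot_wider(names_from = "substrate_id", values_from = "od")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$clone_id
  if (anyNA(m)) {
    abort("missing clone x substrate cells after reshaping",
          class = "gxediv_input_error")
  }
  m
}

check_od_data <- function(data) {
  if (!all(c("clone_id", "substrate_id", "od") %in% names(data))) {
    abort("need columns clone_id, substrate_id, od",
          class = "gxediv_input_error")
  }
  invisible(data)
}

check_dims <- function(m, need_clones = 2L, need_substrates = 1L) {
  if (nrow(m) < need_clones) {
    abort(sprintf("need at least %d clones, got %d", need_clones, nrow(m)),
          class = "gxediv_input_error")
  }
  if (ncol(m) < need_substrates) {
    abort(sprintf("need at least %d substrates, got %d", need_substrates,
                  ncol(m)),
          class = "gxediv_input_error")
  }
  invisible(m)
}

#' Phenotypic variance: mean pairwise Euclidean distance between clones
#'
#' V_P is the mean, over all unordered clone pairs, of the Euclidean
#' distance between the clones' growth profiles across substrates (OD
#' units).
#'
#' @param data Long tibble for a single population (`clone_id`,
#'   `substrate_id`, `od`).
#' @return A single number.
#' @export
phenotypic_variance <- function(data) {
  m <- check_dims(od_matrix(data), 2L, 1L)
  mean(dist(m))
}

#' Genotypic variance: between-clone variation in growth
#'
#' Two estimators of V_G (OD^2 units) are available. The default,
#' `"clone_means"`, is the sample variance across clones of each clone's
#' mean growth over substrates — between-clone variation in overall
#' performance. The alternative, `"substrate_mean_var"`, averages over
#' substrates the variance of growth across clones on that substrate; it
#' also absorbs clone-by-substrate interaction variance, which is why the
#' clone-means form is the default for a quantity meant to be orthogonal to
#' the G-by-E components.
#'
#' @inheritParams phenotypic_variance
#' @param estimator `"clone_means"` or `"substrate_mean_var"`.
#' @return A single number.
#' @export
genotypic_variance <- function(data,
                               estimator = c("clone_means",
                                             "substrate_mean_var")) {
  estimator <- match.arg(estimator)
  m <- check_dims(od_matrix(data), 2L, 1L)
  if (estimator == "clone_means") {
    var(rowMeans(m))
  } else {
    mean(apply(m, 2, var))
  }
}

#' Environmental variance: between-substrate variation in mean growth
#'
#' V_E is the sample variance, across substrates, of the per-substrate mean
#' growth over clones (OD^2 units).
#'
#' @inheritParams phenotypic_variance
#' @return A single number.
#' @export
environmental_variance <- function(data) {
  m <- check_dims(od_matrix(data), 1L, 2L)
  var(colMeans(m))
}

# per-clone SDs across substrates and pairwise Pearson correlations
clone_profile_stats <- function(m) {
  list(sigma = apply(m, 1, sd), rho = suppressWarnings(cor(t(m))))
}

#' Responsiveness: G-by-E variance from unequal environmental variances
#'
#' Responsiveness measures how much clones differ in the *magnitude* of
#' their environmental response:
#' \deqn{R = \sum_{i \ne j} \frac{(\sigma_i - \sigma_j)^2 / 2}{G(G-1)}}
#' where \eqn{\sigma_i} is clone i's sample standard deviation of growth
#' across substrates and the sum runs over ordered clone pairs. High R means
#' the population mixes generalists (flat profiles) with specialists (peaky
#' profiles).
#'
#' @inheritParams phenotypic_variance
#' @return A single number (OD^2 units), always non-negative.
#' @export
responsiveness <- function(data) {
  m <- check_dims(od_matrix(data), 2L, 2L)
  sigma <- apply(m, 1, sd)
  G <- length(sigma)
  sum(outer(sigma, sigma, "-")^2 / 2) / (G * (G - 1))
}

#' Inconsistency: G-by-E variance from rank switching between clones
#'
#' Inconsistency measures resource specialisation — the extent to which
#' clones' performance ranks switch between substrates:
#' \deqn{I = \sum_{i \ne j} \frac{\sigma_i \sigma_j (1 - \rho_{ij})}{G(G-1)}}
#' with \eqn{\rho_{ij}} the Pearson correlation of growth across substrates
#' between clones i and j, summed over ordered pairs. Negative correlations
#' (one clone best where another is worst) drive I up. A pair involving a
#' clone with zero variance contributes 0 (the correlation is undefined but
#' the product \eqn{\sigma_i\sigma_j(1-\rho)} vanishes in the limit of
#' vanishing signal).
#'
#' @inheritParams phenotypic_variance
#' @return A single number (OD^2 units), non-negative.
#' @export
inconsistency <- function(data) {
  m <- check_dims(od_matrix(data), 2L, 2L)
  st <- clone_profile_stats(m)
  cross <- outer(st$sigma, st$sigma) * (1 - st$rho)
  cross[!is.finite(cross)] <- 0          # sigma = 0 pairs
  diag(cross) <- 0
  G <- length(st$sigma)
  sum(cross) / (G * (G - 1))
}

#' Decompose growth profiles into variance components per population
#'
#' Runs the full decomposition — phenotypic variance V_P (mean pairwise
#' clone distance), genotypic variance V_G, environmental variance V_E and
#' the two genotype-by-environment components, responsiveness R and
#' inconsistency I — for every population in `data`.
#'
#' @param data Long tibble (`population_id`, `treatment`, `clone_id`,
#'   `substrate_id`, `od`) covering one or more populations, normally after
#'   [filter_substrates()].
#' @param verbose If `TRUE`, both V_G estimators are reported
#'   (`V_G_clone_means` and `V_G_substrate_mean_var`).
#'
#' @return A tibble with one row per population: `population_id`,
#'   `treatment` (if present), `V_P`, `V_G`, `V_E`, `R`, `I`.
#' @examples
#' sc <- biolog_scenario(n_populations_per_treatment = 2, seed = 11)
#' simulate_biolog_experiment(sc) |>
#'   filter_substrates() |>
#'   gxe_decompose()
#' @export
gxe_decompose <- function(data, verbose = FALSE) {
  check_od_data(data)
  if (!"population_id" %in% names(data)) data$population_id <- "pop1"
  has_treatment <- "treatment" %in% names(data)

  one <- function(d) {
    out <- tibble(V_P = phenotypic_variance(d),
                  V_G = genotypic_variance(d),
                  V_E = environmental_variance(d),
                  R = responsiveness(d),
                  I = inconsistency(d))
    if (verbose) {
      out$V_G_clone_means <- out$V_G
      out$V_G_substrate_mean_var <- genotypic_variance(d, "substrate_mean_var")
    }
    out
  }

  keys <- if (has_treatment) c("population_id", "treatment") else
    "population_id"
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}
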