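#' Odds-ratio relative fitness from mixture fractions
#'
#' The relative fitness of a focal strain competed against a reference is
#' the odds ratio of its mixture fractions at the end (`f7`) and start
#' (`f0`) of the competition:
#' \deqn{w = \frac{f_{T7}(1 - f_{T0})}{f_{T0}(1 - f_{T7})}}
#' Values above 1 mean the focal strain gained ground. Swapping the strains
#' gives the reciprocal. Fractions of exactly 0 or 1 (extinction/fixation)
#' leave the odds ratio undefined and raise an error rather than returning
#' an infinity.
#'
#' @param f0,f7 Focal-strain fractions at the two timepoints, strictly
#'   between 0 and 1. Vectorised.
#' @return Relative fitness (dimensionless, > 0).
#' @examples
#' relative_fitness(0.5, 0.75)  # 3
#' @export
relative_fitness <- function(f0, f7) {
  bad <- !is.na(f0) & !is.na(f7) & (f0 <= 0 | f0 >= 1 | f7 <= 0 | f7 >= 1)
  if (any(bad)) {
    abort("fixation/extinction: fitness undefined for fractions 0 or 1",
          class = "gxediv_fitness_error")
  }
  (f7 * (1 - f0)) / (f0 * (1 - f7))
}

#' Ratio of Malthusian parameters from absolute counts
#'
#' `ln(n_A7/n_A0) / ln(n_B7/n_B0)`: the ratio of the two strains' realised
#' Malthusian growth rates over the assay. Requires absolute abundances at
#' both timepoints (fractions are not enough) and that the reference strain
#' actually changed in abundance. The odds-ratio fitness of
#' [relative_fitness()] equals this ratio only approximately in general; the
#' two agree exactly when the reference strain's abundance is unchanged.
#'
#' @param n_A0,n_A7 Focal-strain counts at start and end (> 0).
#' @param n_B0,n_B7 Reference-strain counts at start and end (> 0).
#' @return Dimensionless ratio. Vectorised.
#' @examples
#' malthusian_ratio(10, 80, 10, 20)  # 3
#' @export
malthusian_ratio <- function(n_A0, n_A7, n_B0, n_B7) {
  if (any(c(n_A0, n_A7, n_B0, n_B7) <= 0)) {
    abort("all counts must be positive", class = "gxediv_fitness_error")
  }
  denom <- log(n_B7 / n_B0)
  if (any(denom == 0)) {
    abort("reference strain unchanged: Malthusian ratio undefined",
          class = "gxediv_fitness_error")
  }
  log(n_A7 / n_A0) / denom
}

#' Relative fitness for a table of competition assays
#'
#' Converts white/blue colony counts at T0 and T7 into focal-strain (white,
#' evolved) fractions and the odds-ratio relative fitness. Counts are used
#' as plated, without dilution-factor correction: fractions, and hence the
#' odds ratio, are dilution-invariant. The Malthusian ratio computed
#' directly from the raw plate counts is included for reference; it is only
#' meaningful when both timepoints were plated at the same dilution.
#'
#' @param data Data frame with columns `white_T0`, `blue_T0`, `white_T7`,
#'   `blue_T7` (non-negative integers; any other columns are carried
#'   through).
#' @return `data` with added columns `fraction_T0`, `fraction_T7`,
#'   `relative_fitness` and `malthusian_ratio` (`NA` for assays where the
#'   reference count did not change, which leaves the log-ratio undefined).
#' @examples
#' assay_fitness(data.frame(white_T0 = 50, blue_T0 = 50,
#'                          white_T7 = 75, blue_T7 = 25))
#' @export
assay_fitness <- function(data) {
  needed <- c("white_T0", "blue_T0", "white_T7", "blue_T7")
  if (!all(needed %in% names(data))) {
    abort(paste("need columns", paste(needed, collapse = ", ")),
          class = "gxediv_input_error")
  }
  tot0 <- data$white_T0 + data$blue_T0
  tot7 <- data$white_T7 + data$blue_T7
  if (any(tot0 == 0) || any(tot7 == 0)) {
    abort("zero total colony count at a timepoint",
          class = "gxediv_fitness_error")
  }
  out <- as_tibble(data)
  out$fraction_T0 <- data$white_T0 / tot0
  out$fraction_T7 <- data$white_T7 / tot7
  out$relative_fitness <- relative_fitness(out$fraction_T0, out$fraction_T7)
  out$malthusian_ratio <- purrr::pmap_dbl(
    data[, needed],
    function(white_T0, blue_T0, white_T7, blue_T7) {
      tryCatch(malthusian_ratio(white_T0, white_T7, blue_T0, blue_T7),
               gxediv_fitness_error = function(e) NA_real_)
    })
  out
}

#' Targeted pairwise contrasts of relative fitness between environments
#'
#' Compares group mean relative fitness between evolution-by-competition
#' environment combinations, mirroring the targeted-contrast structure of a
#' local-adaptation competition experiment. Groups are labelled
#' `"<evolution_env>:<competition_env>"`. A contrast between the two
#' competition environments of the *same* evolved populations is tested with
#' a paired t test (matched on `population_id`); contrasts between different
#' evolved population sets use Welch's t test. Raw p values are adjusted
#' over the requested family with the Holm step-down method.
#'
#' @param data Data frame with columns `population_id`, `evolution_env`,
#'   `competition_env` and `relative_fitness` (e.g. from [assay_fitness()]).
#' @param comparisons List of length-2 character vectors of group labels,
#'   each `"<evolution_env>:<competition_env>"`. The default reproduces the
#'   three classic local-adaptation contrasts for treatments
#'   `heterogeneous`/`homogeneous`.
#'
#' @return A tibble with one row per contrast: `contrast`, `estimate`
#'   (difference of group means), `se`, `df`, `t_ratio`, `p_value`,
#'   `p_adjusted`, `method`.
#' @export
fitness_contrasts <- function(data, comparisons = NULL) {
  needed <- c("population_id", "evolution_env", "competition_env",
              "relative_fitness")
  if (!all(needed %in% names(data))) {
    abort(paste("need columns", paste(needed, collapse = ", ")),
          class = "gxediv_input_error")
  }
  data <- dplyr::mutate(
    data, .group = paste(.data$evolution_env, .data$competition_env,
                         sep = ":"))
  if (is.null(comparisons)) {
    comparisons <- list(
      c("heterogeneous:heterogeneous", "heterogeneous:homogeneous"),
      c("heterogeneous:heterogeneous", "homogeneous:homogeneous"),
      c("homogeneous:heterogeneous", "homogeneous:homogeneous"))
  }
  known <- unique(data$.group)
  rows <- purrr::map(comparisons, function(cmp) {
    if (!all(cmp %in% known)) {
      abort(paste0("unknown group label: ",
                   paste(setdiff(cmp, known), collapse = ", ")),
            class = "gxediv_input_error")
    }
    a <- dplyr::filter(data, .data$.group == cmp[1])
    b <- dplyr::filter(data, .data$.group == cmp[2])
    same_evo <- sub(":.*", "", cmp[1]) == sub(":.*", "", cmp[2])
    paired <- same_evo && setequal(a$population_id, b$population_id) &&
      !anyDuplicated(a$population_id)
    if (paired) {
      b <- b[match(a$population_id, b$population_id), ]
      tt <- t.test(a$relative_fitness, b$relative_fitness, paired = TRUE)
    } else {
      tt <- t.test(a$relative_fitness, b$relative_fitness, var.equal = FALSE)
    }
    tibble(contrast = paste(cmp[1], "-", cmp[2]),
           estimate = mean(a$relative_fitness) - mean(b$relative_fitness),
           se = unname(tt$stderr),
           df = unname(tt$parameter),
           t_ratio = unname(tt$statistic),
           p_value = tt$p.value,
           method = if (paired) "paired t" else "Welch t")
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_adjust(out$p_value)
  dplyr::relocate(out, "p_adjusted", .after = "p_value")
}

#' Minimum generations implied by a serial-transfer design
#'
#' Transferring a fraction `transfer_fraction` of the culture to fresh
#' medium requires `log2(1/transfer_fraction)` doublings to regrow to the
#' pre-transfer density, so `n_transfers` serial transfers imply at least
#' `floor(n_transfers * log2(1/transfer_fraction))` generations (more if the
#' population turns over at equilibrium density).
#'
#' @param n_transfers Number of serial transfers.
#' @param transfer_fraction Fraction of the culture transferred each time.
#' @return Integer lower bound on generations.
#' @examples
#' serial_transfer_generations(8, 1 / 3)  # 12
#' @export
serial_transfer_generations <- function(n_transfers, transfer_fraction) {
  stopifnot(n_transfers >= 0, transfer_fraction > 0, transfer_fraction < 1)
  as.integer(floor(n_transfers * log2(1 / transfer_fraction)))
}
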