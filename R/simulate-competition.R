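#' Simulate a blue/white competition assay
#'
#' The focal (white) mix starts at fraction 0.5. Growth between the start
#' (T0) and end (T7) of the competition is deterministic: the final fraction
#' is the one whose odds ratio against the starting fraction equals the
#' scenario's true relative fitness, i.e.
#' `f7 = w * f0 / (1 - f0 + w * f0)`. Colony counts at each timepoint are
#' then drawn as `Binomial(n_plated, fraction)` with `n_plated` equal to the
#' scenario's expected plate count, so all estimator noise comes from
#' plating. Draws that would fix or lose the focal strain on a plate are
#' resampled (up to 100 times) because the odds-ratio estimator is undefined
#' at fractions 0 and 1.
#'
#' @param scenario A [competition_scenario()].
#' @param n_assays Number of independent assays to simulate.
#'
#' @return A tibble with one row per assay: `assay_id`, `white_T0`,
#'   `blue_T0`, `white_T7`, `blue_T7`, `true_fraction_T0`,
#'   `true_fraction_T7`, `true_relative_fitness`.
#' @examples
#' simulate_competition(competition_scenario(true_relative_fitness = 2))
#' @export
simulate_competition <- function(scenario, n_assays = 1L) {
  stopifnot(inherits(scenario, "competition_scenario"))
  w <- scenario$true_relative_fitness
  f0 <- 0.5
  f7 <- w * f0 / (1 - f0 + w * f0)
  n_plate <- scenario$plated_colonies_mean

  draw_fraction_counts <- function(f) {
    for (i in 1:100) {
      white <- rbinom(1, n_plate, f)
      if (white > 0 && white < n_plate) {
        return(c(white = white, blue = n_plate - white))
      }
    }
    abort("degenerate plate (fraction 0 or 1) after 100 resampling attempts",
          class = "gxediv_sampling_error")
  }

  withr::with_seed(scenario$seed, {
    rows <- purrr::map(seq_len(n_assays), function(a) {
      t0 <- draw_fraction_counts(f0)
      t7 <- draw_fraction_counts(f7)
      tibble(assay_id = sprintf("A%03d", a),
             white_T0 = t0[["white"]], blue_T0 = t0[["blue"]],
             white_T7 = t7[["white"]], blue_T7 = t7[["blue"]],
             true_fraction_T0 = f0, true_fraction_T7 = f7,
             true_relative_fitness = w)
    })
  })
  dplyr::bind_rows(rows)
}
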