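#' Reaction-norm plot of clone growth across substrates
#'
#' One line per clone over the substrate panel, facetted by population, with
#' the population mean overlaid — the standard way to eyeball G-by-E
#' structure (crossing lines = inconsistency, fanning lines =
#' responsiveness).
#'
#' @param data Long growth tibble (`population_id`, `clone_id`,
#'   `substrate_id`, `od`).
#' @return A ggplot object.
#' @export
plot_reaction_norms <- function(data) {
  check_od_data(data)
  if (!"population_id" %in% names(data)) data$population_id <- "pop1"
  means <- data |>
    dplyr::group_by(.data$population_id, .data$substrate_id) |>
    dplyr::summarise(od = mean(.data$od), .groups = "drop")
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$substrate_id, y = .data$od)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$clone_id),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1),
                       colour = "black", linewidth = 0.7) +
    ggplot2::facet_wrap(~population_id) +
    ggplot2::labs(x = "substrate", y = expression(OD[660])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.gxediv_nmds <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if ("group" %in% names(pts)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$group,
                                              colour = .data$group), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::labs(
    caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
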