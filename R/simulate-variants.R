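#' Simulate per-population variant-proportion tables
#'
#' Emulates the variant tables produced by a pooled-sequencing pipeline run
#' on replicate evolved populations. Each population of each treatment gains
#' a Poisson number of private variants (unique genomic positions, pooled
#' proportion drawn from the scenario's Beta distribution) plus any shared
#' variants the scenario prescribes: a shared variant with fraction `f` for
#' treatment `t` is planted in `round(f * n_populations)` randomly chosen
#' populations of that treatment and in no population of the other
#' treatment, emulating treatment-diagnostic mutations.
#'
#' @param scenario A [variant_scenario()].
#' @param treatments Character vector of treatment labels to simulate.
#'
#' @return A tibble with columns `population_id`, `treatment`, `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `type` (`"SNP"` or `"indel"`) and
#'   `proportion` (in (0, 1]).
#' @examples
#' simulate_variant_tables(variant_scenario(seed = 3))
#' @export
simulate_variant_tables <- function(scenario,
                                    treatments = c("heterogeneous",
                                                   "homogeneous")) {
  stopifnot(inherits(scenario, "variant_scenario"))
  bases <- c("A", "C", "G", "T")

  withr::with_seed(scenario$seed, {
    private <- purrr::map(treatments, function(tr) {
      purrr::map(seq_len(scenario$n_populations), function(p) {
        n <- rpois(1, scenario$mean_variants_per_population)
        if (n == 0) return(NULL)
        pos <- sample.int(7e6, n)           # unique positions per population
        ref <- sample(bases, n, replace = TRUE)
        alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
        type <- sample(c("SNP", "indel"), n, replace = TRUE, prob = c(0.7, 0.3))
        alt <- ifelse(type == "indel", paste0(alt, "A"), alt)
        prop <- stats::rbeta(n, scenario$proportion_alpha,
                             scenario$proportion_beta)
        prop[prop <= 0] <- .Machine$double.eps   # keep proportions in (0, 1]
        tibble(population_id = sprintf("%s_P%d", substr(tr, 1, 3), p),
               treatment = tr,
               variant_id = sprintf("%s_P%d_v%d", substr(tr, 1, 3), p,
                                    seq_len(n)),
               chrom = "chr1", pos = pos, ref = ref, alt = alt,
               type = type, proportion = prop)
      })
    })
    private <- dplyr::bind_rows(purrr::flatten(private))

    shared <- NULL
    spec <- scenario$shared_variant_spec
    if (!is.null(spec) && nrow(spec) > 0) {
      shared <- purrr::pmap(spec, function(variant_id, treatment, fraction,
                                           proportion, ...) {
        if (!treatment %in% treatments) return(NULL)
        k <- round(fraction * scenario$n_populations)
        if (k == 0) return(NULL)
        carriers <- sample.int(scenario$n_populations, k)
        pos <- sample.int(7e6, 1) + 7e6      # outside the private range
        ref <- sample(bases, 1)
        alt <- sample(setdiff(bases, ref), 1)
        prop <- if (is.na(proportion)) {
          stats::rbeta(k, scenario$proportion_alpha, scenario$proportion_beta)
        } else rep(proportion, k)
        tibble(population_id = sprintf("%s_P%d", substr(treatment, 1, 3),
                                       sort(carriers)),
               treatment = treatment,
               variant_id = variant_id,
               chrom = "chr1", pos = pos, ref = ref, alt = alt,
               type = "SNP", proportion = prop)
      })
      shared <- dplyr::bind_rows(shared)
    }
    out <- dplyr::bind_rows(private, shared)
  })
  if (nrow(out) == 0) return(empty_variant_table())
  dplyr::arrange(out, .data$treatment, .data$population_id, .data$pos)
}

empty_variant_table <- function() {
  tibble(population_id = character(), treatment = character(),
         variant_id = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), type = character(),
         proportion = double())
}
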