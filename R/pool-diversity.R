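#' Genetic distance from the reference: sum of variant proportions
#'
#' The pooled proportions of all SNPs/indels in a population are summed,
#' giving a distance of the population from the ancestral reference genome
#' (a fixed variant contributes 1, a variant carried by half the pool 0.5).
#' An empty table has distance 0.
#'
#' @param proportions Numeric vector of variant proportions in (0, 1].
#' @return A single number >= 0.
#' @examples
#' genetic_distance(c(0.3, 0.7))  # 1
#' @export
genetic_distance <- function(proportions) {
  check_proportions(proportions)
  sum(proportions)
}

#' Number of variants at or above a detection floor
#'
#' Counts the variants whose pooled proportion is at least `min_prop`. The
#' default floor of 0.1 matches the detection cut-off at which pooled
#' sequencing of a 10-clone mix can still see a variant carried by a single
#' clone.
#'
#' @inheritParams genetic_distance
#' @param min_prop Detection floor in \[0, 1\] (inclusive threshold).
#' @return Integer count.
#' @export
variant_count <- function(proportions, min_prop = 0.1) {
  check_proportions(proportions)
  stopifnot(min_prop >= 0, min_prop <= 1)
  sum(proportions >= min_prop)
}

#' Alpha diversity: summed expected heterozygosity over variant sites
#'
#' For each variant with pooled proportion p (and q = 1 - p),
#' `1 - p^2 - q^2 = 2 p (1 - p)` is the site's expected heterozygosity; the
#' sum over all variant sites is a within-population diversity. A site is
#' maximally diverse at p = 0.5 (contribution 0.5) and contributes nothing
#' when fixed or absent, so `alpha <= 0.5 * n_variants`.
#'
#' @inheritParams genetic_distance
#' @return A single number >= 0.
#' @examples
#' alpha_diversity(c(0.1, 0.2))  # 0.18 + 0.32 = 0.5
#' @export
alpha_diversity <- function(proportions) {
  check_proportions(proportions)
  sum(1 - proportions^2 - (1 - proportions)^2)
}

check_proportions <- function(p) {
  if (length(p) > 0 && (any(is.na(p)) || any(p < 0 | p > 1))) {
    abort("proportions must lie in [0, 1]", class = "gxediv_input_error")
  }
  invisible(p)
}

#' Per-population diversity metrics from a variant table
#'
#' Computes genetic distance, the variant count at the detection floor and
#' alpha diversity for every population in a long variant table.
#'
#' @param tables Tibble of variant records with columns `population_id` and
#'   `proportion` (plus `treatment`, carried through if present), e.g. from
#'   [simulate_variant_tables()] or [read_variant_table()].
#' @param min_prop Detection floor passed to [variant_count()].
#' @return A tibble with one row per population: `population_id`,
#'   (`treatment`), `genetic_distance`, `n_variants`, `alpha`.
#' @export
diversity_metrics <- function(tables, min_prop = 0.1) {
  if (!all(c("population_id", "proportion") %in% names(tables))) {
    abort("need columns population_id, proportion",
          class = "gxediv_input_error")
  }
  keys <- intersect(c("population_id", "treatment"), names(tables))
  tables |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      genetic_distance = genetic_distance(.data$proportion),
      n_variants = variant_count(.data$proportion, min_prop),
      alpha = alpha_diversity(.data$proportion),
      .groups = "drop")
}

#' Whitelist-filter pooled variants against clonal sequencing calls
#'
#' Conservative filter for pool-seq false positives: keep only the pooled
#' variants whose key `(chrom, pos, ref, alt)` was also identified in the
#' clonal (single-genome) sequencing. Idempotent, and never increases any
#' diversity metric.
#'
#' @param pool Tibble of pooled variant records (needs `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param clonal_variants Data frame of clonal calls with the same four key
#'   columns.
#' @return The filtered subset of `pool`.
#' @export
whitelist_filter <- function(pool, clonal_variants) {
  key <- c("chrom", "pos", "ref", "alt")
  if (!all(key %in% names(pool)) || !all(key %in% names(clonal_variants))) {
    abort("pool and clonal_variants need columns chrom, pos, ref, alt",
          class = "gxediv_input_error")
  }
  dplyr::semi_join(pool, dplyr::distinct(clonal_variants[, key]), by = key)
}

#' Expected pooled proportion of each variant from clone genotypes
#'
#' When clones are pooled in equal amounts, the expected proportion of a
#' variant in the pool is simply its carrier fraction: the mean of the
#' binary genotype column.
#'
#' @param genotypes Binary clones-by-variants matrix (rows = clones).
#' @return Named numeric vector of per-variant expected proportions.
#' @examples
#' g <- matrix(c(1, rep(0, 9)), ncol = 1, dimnames = list(NULL, "v1"))
#' expected_pool_proportion(g)  # v1 = 0.1
#' @export
expected_pool_proportion <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1))) {
    abort("genotypes must be binary", class = "gxediv_input_error")
  }
  colMeans(genotypes)
}

#' Simulate pooled variant detection at the allele-count level
#'
#' Models the statistical layer of pooled-sequencing variant detection
#' without re-running mapping or calling: at each variant site the alt read
#' count is `Binomial(depth, p_eff)` where `p_eff` is the carrier fraction
#' perturbed by the sequencing error rate
#' (`p_eff = p (1 - e) + (1 - p) e / 3`, errors uniform over the three
#' non-reference bases), the observed proportion is `alt / depth`, and a
#' variant is called detected iff the observed proportion reaches `cutoff`.
#'
#' @param genotypes Binary clones-by-variants matrix.
#' @param depth Reads covering each site in the pool (>= 1).
#' @param error_rate Per-base error probability.
#' @param cutoff Detection threshold on the observed proportion (>=,
#'   default 0.1).
#' @param seed Integer seed.
#'
#' @return An object of class `pool_detection`: a list with `calls` (tibble
#'   with `variant`, `true_proportion`, `alt_reads`, `observed_proportion`,
#'   `detected`) and `summary` (one-row tibble with `n_true`, `n_detected`,
#'   `false_negatives`, `sensitivity`). `tidy()` returns the calls,
#'   `glance()` the summary.
#' @export
simulate_pool_detection <- function(genotypes, depth, error_rate = 0,
                                    cutoff = 0.1, seed = 1L) {
  stopifnot(depth >= 1, cutoff >= 0, cutoff <= 1,
            error_rate >= 0, error_rate <= 1)
  p <- expected_pool_proportion(genotypes)
  p_eff <- p * (1 - error_rate) + (1 - p) * error_rate / 3
  calls <- withr::with_seed(as.integer(seed), {
    alt <- rbinom(length(p_eff), size = depth, prob = p_eff)
    tibble(variant = names(p) %||% paste0("v", seq_along(p)),
           true_proportion = unname(p),
           alt_reads = alt,
           observed_proportion = alt / depth,
           detected = alt / depth >= cutoff)
  })
  truth <- calls$true_proportion > 0
  summary <- tibble(
    n_true = sum(truth),
    n_detected = sum(calls$detected),
    false_negatives = sum(truth & !calls$detected),
    sensitivity = if (sum(truth) > 0) {
      sum(truth & calls$detected) / sum(truth)
    } else NA_real_)
  structure(list(calls = calls, summary = summary, depth = depth,
                 cutoff = cutoff, error_rate = error_rate, seed = seed),
            class = "pool_detection")
}

#' @exportS3Method generics::tidy
tidy.pool_detection <- function(x, ...) x$calls

#' @exportS3Method generics::glance
glance.pool_detection <- function(x, ...) x$summary

#' @export
print.pool_detection <- function(x, ...) {
  cat(sprintf(
    "Pooled detection at depth %d, cutoff %.3g, error rate %.3g\n",
    x$depth, x$cutoff, x$error_rate))
  print(x$summary)
  invisible(x)
}
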