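#' Populations-by-variants proportion matrix
#'
#' Spreads a long variant table into a numeric matrix with one row per
#' population and one column per distinct variant key
#' `(chrom, pos, ref, alt)`; a variant absent from a population has
#' proportion 0. This is the feature matrix behind the Euclidean distances
#' used for ordination and PERMANOVA.
#'
#' @param tables Long variant tibble (`population_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `proportion`).
#' @return Numeric matrix with population ids as row names and variant keys
#'   as column names.
#' @export
variant_feature_matrix <- function(tables) {
  needed <- c("population_id", "chrom", "pos", "ref", "alt", "proportion")
  if (!all(needed %in% names(tables))) {
    abort(paste("need columns", paste(needed, collapse = ", ")),
          class = "gxediv_input_error")
  }
  tables <- dplyr::mutate(
    tables, .key = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                         sep = ":"))
  dup <- tables |>
    dplyr::count(.data$population_id, .data$.key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate variant key %s in population %s",
                  dup$.key[1], dup$population_id[1]),
          class = "gxediv_input_error")
  }
  wide <- tables |>
    dplyr::select("population_id", ".key", "proportion") |>
    tidyr::pivot_wider(names_from = ".key", values_from = "proportion",
                       values_fill = 0) |>
    dplyr::arrange(.data$population_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$population_id
  m
}

#' Euclidean distance matrix between samples
#'
#' @param x Numeric samples-by-features matrix (e.g. from
#'   [variant_feature_matrix()]).
#' @return A [stats::dist] object.
#' @export
euclidean_distances <- function(x) {
  dist(as.matrix(x), method = "euclidean")
}

# sums of squares from a distance matrix, Anderson's direct formulation
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 1.0))
  c(total = ss_total, within = ss_within)
}

#' Permutational multivariate ANOVA (one factor)
#'
#' Partitions the total sum of squared inter-sample distances into between-
#' and within-group components and tests the group effect by permuting group
#' labels over whole samples. With squared distances d2:
#' `SS_total = (1/n) sum_{i<j} d2_ij`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d2_ij`, and
#' `pseudo-F = ((SS_total - SS_within)/(a-1)) / (SS_within/(n-a))`.
#' The permutation p value includes the observed statistic:
#' `p = (1 + #permuted F >= observed) / (n_perm + 1)`, so p is never 0 and
#' its resolution is `1/(n_perm + 1)`. On 1-D Euclidean data the pseudo-F
#' equals the classical one-way ANOVA F. If all within-group distances are
#' zero the F statistic is reported as `Inf` and the p value still comes
#' from the permutation distribution.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups).
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed for the permutations.
#'
#' @return An object of class `gxediv_permanova` with fields `pseudo_F`,
#'   `R2`, `p_value`, `df`, `ss`, `n_perm`, `seed`. `tidy()`/`glance()`
#'   return one-row tibbles.
#' @examples
#' d <- euclidean_distances(matrix(c(0, 2, 10, 12), ncol = 1))
#' permanova(d, c("a", "a", "b", "b"), n_perm = 999, seed = 1)
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- factor(groups)
  if (length(groups) != n) {
    abort("groups length must match distance matrix size",
          class = "gxediv_input_error")
  }
  a <- nlevels(groups)
  if (a < 2) abort("need at least 2 groups", class = "gxediv_input_error")
  if (n_perm < 1) abort("n_perm must be >= 1", class = "gxediv_input_error")
  d2 <- dm^2

  f_stat <- function(g) {
    ss <- permanova_ss(d2, g)
    between <- ss[["total"]] - ss[["within"]]
    (between / (a - 1)) / (ss[["within"]] / (n - a))
  }
  ss_obs <- permanova_ss(d2, groups)
  between <- ss_obs[["total"]] - ss_obs[["within"]]
  F_obs <- if (ss_obs[["within"]] == 0) Inf else
    (between / (a - 1)) / (ss_obs[["within"]] / (n - a))
  R2 <- if (ss_obs[["total"]] > 0) between / ss_obs[["total"]] else NA_real_

  perm_F <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) f_stat(sample(groups)), 1.0)
  })
  p <- (1 + sum(perm_F >= F_obs)) / (n_perm + 1)

  structure(list(pseudo_F = unname(F_obs), R2 = unname(R2), p_value = p,
                 df = c(df1 = a - 1L, df2 = n - a),
                 ss = c(total = ss_obs[["total"]],
                        between = unname(between),
                        within = ss_obs[["within"]]),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "gxediv_permanova")
}

#' @export
print.gxediv_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
    x$df[["df1"]], x$df[["df2"]], x$pseudo_F, x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gxediv_permanova <- function(x, ...) {
  tibble(df1 = x$df[["df1"]], df2 = x$df[["df2"]],
         SS_between = x$ss[["between"]], SS_within = x$ss[["within"]],
         pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
         n_perm = x$n_perm)
}

#' @exportS3Method generics::glance
glance.gxediv_permanova <- function(x, ...) tidy(x)

#' Multivariate homogeneity of group dispersions
#'
#' Tests whether groups differ in their spread around their own centroids
#' (beta-diversity). The distance matrix is embedded by principal-coordinate
#' decomposition; each sample's distance to its group centroid is computed
#' in that space, with the usual correction for negative eigenvalues
#' (squared distances in the imaginary axes are subtracted), and the
#' group effect on those distances is tested with a one-way ANOVA F test.
#'
#' @inheritParams permanova
#' @return An object of class `gxediv_dispersion` with per-sample distances
#'   to centroid (`distances`), `group_means`, and the ANOVA `statistic`,
#'   `df1`, `df2`, `p_value`. `tidy()` returns the per-sample distances,
#'   `glance()` the test.
#' @export
beta_dispersion <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- factor(groups)
  if (length(groups) != n) {
    abort("groups length must match distance matrix size",
          class = "gxediv_input_error")
  }
  if (nlevels(groups) < 2) {
    abort("need at least 2 groups", class = "gxediv_input_error")
  }

  # principal-coordinate embedding (Gower double-centring)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  lambda <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  coords <- sweep(vec, 2, sqrt(abs(lambda)), "*")
  pos <- lambda > 0

  dist_to_centroid <- vapply(seq_len(n), function(i) {
    idx <- which(groups == groups[i])
    cen <- colMeans(coords[idx, , drop = FALSE])
    dev2 <- (coords[i, ] - cen)^2
    z2 <- sum(dev2[pos]) - sum(dev2[!pos])
    sqrt(max(z2, 0))
  }, 1.0)

  test <- lm_f_test(dist_to_centroid, groups)
  structure(list(
    distances = tibble(sample = rownames(dm) %||% as.character(seq_len(n)),
                       group = as.character(groups),
                       distance_to_centroid = dist_to_centroid),
    group_means = tapply(dist_to_centroid, groups, mean),
    statistic = test$statistic, df1 = test$df1, df2 = test$df2,
    p_value = test$p_value),
    class = "gxediv_dispersion")
}

#' @export
print.gxediv_dispersion <- function(x, ...) {
  cat(sprintf("Beta-dispersion ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$statistic, x$p_value))
  print(round(x$group_means, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gxediv_dispersion <- function(x, ...) x$distances

#' @exportS3Method generics::glance
glance.gxediv_dispersion <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p_value = x$p_value)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Seeded wrapper around [vegan::metaMDS()] (Kruskal stress-1, monotone
#' regression, multiple random restarts keeping the best configuration),
#' returning a tidy coordinate table. Stress below ~0.05 is conventionally
#' an excellent representation of the distance ranks.
#'
#' @inheritParams permanova
#' @param k Embedding dimension (< number of samples).
#' @param trymax Maximum random restarts.
#' @return An object of class `gxediv_nmds`: list with `points` (tibble
#'   `sample`, `NMDS1`, ... plus `group` if supplied), `stress`, `k`.
#' @param groups Optional group labels attached to the coordinate table.
#' @export
nmds_ordination <- function(d, k = 2, seed = 1L, trymax = 20, groups = NULL) {
  dm <- as.matrix(d)
  if (all(dm == 0)) {
    abort("degenerate all-zero distance matrix", class = "gxediv_input_error")
  }
  if (k >= nrow(dm)) {
    abort("k must be smaller than the number of samples",
          class = "gxediv_input_error")
  }
  fit <- withr::with_seed(as.integer(seed), {
    vegan::metaMDS(stats::as.dist(dm), k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  })
  pts <- as_tibble(fit$points, .name_repair = "minimal")
  names(pts) <- paste0("NMDS", seq_len(k))
  pts <- dplyr::bind_cols(
    tibble(sample = rownames(dm) %||% as.character(seq_len(nrow(dm)))), pts)
  if (!is.null(groups)) pts$group <- as.character(groups)
  structure(list(points = pts, stress = fit$stress, k = k,
                 converged = isTRUE(fit$converged)),
            class = "gxediv_nmds")
}

#' @export
print.gxediv_nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d), stress = %.4g\n", x$k, x$stress))
  print(x$points)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gxediv_nmds <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.gxediv_nmds <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, converged = x$converged)
}
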