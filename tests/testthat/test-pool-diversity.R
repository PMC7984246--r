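test_that("genetic distance, variant count and alpha diversity match hand values", {
  expect_equal(genetic_distance(numeric(0)), 0)
  expect_equal(genetic_distance(c(0.3, 0.7)), 1)
  expect_equal(genetic_distance(rep(1, 3)), 3)

  expect_equal(variant_count(numeric(0)), 0)
  expect_equal(variant_count(c(0.05, 0.5), min_prop = 0.1), 1)
  expect_equal(variant_count(c(0.05, 0.5, 0.1), min_prop = 0), 3)
  expect_equal(variant_count(c(0.1, 0.09), min_prop = 0.1), 1)  # inclusive

  expect_equal(alpha_diversity(0.5), 0.5)
  expect_equal(alpha_diversity(c(0, 1)), 0)
  expect_equal(alpha_diversity(c(0.1, 0.2)), 0.5)
  # two algebraic forms agree
  withr::with_seed(31, p <- runif(50))
  expect_equal(alpha_diversity(p), sum(2 * p * (1 - p)), tolerance = 1e-12)
  expect_lte(alpha_diversity(p), 0.5 * length(p))

  expect_error(alpha_diversity(c(0.5, 1.2)), class = "gxediv_input_error")
})

test_that("distance and alpha are additive over disjoint variant subsets", {
  withr::with_seed(32, p <- runif(30, 0.01, 1))
  idx <- 1:12
  expect_equal(genetic_distance(p),
               genetic_distance(p[idx]) + genetic_distance(p[-idx]))
  expect_equal(alpha_diversity(p),
               alpha_diversity(p[idx]) + alpha_diversity(p[-idx]))
})

test_that("diversity_metrics summarises per population with the detection floor", {
  tab <- tibble::tibble(
    population_id = c("p1", "p1", "p2"),
    treatment = c("a", "a", "b"),
    proportion = c(0.5, 0.05, 1))
  out <- diversity_metrics(tab, min_prop = 0.1)
  expect_equal(out$genetic_distance, c(0.55, 1))
  expect_equal(out$n_variants, c(1L, 1L))
  expect_equal(out$alpha, c(0.5 + 2 * 0.05 * 0.95, 0))
})

test_that("whitelist filter is an idempotent key intersection that never adds variants", {
  pool <- tibble::tibble(chrom = "c1", pos = 1:3, ref = "A",
                         alt = c("T", "G", "C"), proportion = c(0.2, 0.5, 0.9))
  clonal <- tibble::tibble(chrom = "c1", pos = c(2, 3, 4), ref = "A",
                           alt = c("G", "C", "T"))
  kept <- whitelist_filter(pool, clonal)
  expect_equal(kept$pos, c(2L, 3L))
  expect_identical(whitelist_filter(kept, clonal), kept)   # idempotent
  expect_equal(nrow(whitelist_filter(pool, clonal[0, ])), 0)
  expect_identical(whitelist_filter(pool, pool), pool)     # pool subset of clonal
  # metrics never increase
  expect_lte(genetic_distance(kept$proportion),
             genetic_distance(pool$proportion))
  expect_lte(alpha_diversity(kept$proportion),
             alpha_diversity(pool$proportion))
})

test_that("expected pool proportions are carrier fractions", {
  g <- matrix(0, nrow = 10, ncol = 3,
              dimnames = list(NULL, c("v1", "v2", "v3")))
  g[1, 1] <- 1
  g[, 2] <- 1
  g[1:4, 3] <- 1
  expect_equal(expected_pool_proportion(g),
               c(v1 = 0.1, v2 = 1.0, v3 = 0.4))
  expect_error(expected_pool_proportion(matrix(2, 2, 2)),
               class = "gxediv_input_error")
})

test_that("pool detection follows the binomial sampling model", {
  g <- matrix(0, nrow = 10, ncol = 2, dimnames = list(NULL, c("v0", "v5")))
  g[1:5, 2] <- 1
  # absent variant never detected with zero error
  det <- simulate_pool_detection(g, depth = 1000, error_rate = 0,
                                 cutoff = 0.1, seed = 1)
  calls <- tidy(det)
  expect_false(calls$detected[calls$variant == "v0"])
  # p = 0.5 at depth 1000: detection virtually certain
  expect_true(calls$detected[calls$variant == "v5"])
  expect_equal(glance(det)$sensitivity, 1)
  expect_equal(glance(det)$false_negatives, 0)

  # repeated single-carrier sites at depth 100 reproduce the exact
  # binomial tail P(Binom(100, 0.1) >= 10)
  g1 <- matrix(0, nrow = 10, ncol = 4000)
  g1[1, ] <- 1
  det1 <- simulate_pool_detection(g1, depth = 100, error_rate = 0,
                                  cutoff = 0.1, seed = 2)
  p_exact <- pbinom(9, 100, 0.1, lower.tail = FALSE)
  expect_equal(glance(det1)$sensitivity, p_exact, tolerance = 0.05)
})

test_that("observed pool proportions converge to carrier fractions with depth", {
  g <- matrix(0, nrow = 10, ncol = 20)
  withr::with_seed(33, {
    for (j in 1:20) g[sample.int(10, sample.int(10, 1)), j] <- 1
  })
  truth <- expected_pool_proportion(g)
  mads <- vapply(1:20, function(s) {
    obs <- tidy(simulate_pool_detection(g, depth = 1e5, error_rate = 0,
                                        cutoff = 0.1, seed = s))
    mean(abs(obs$observed_proportion - truth))
  }, 1.0)
  expect_lt(mean(mads), 0.01)
})

test_that("pseudo-pool mixing subsamples each file at the requested fraction", {
  rs <- read_scenario(genome_length = 400, n_clones = 3, read_length = 40,
                      coverage_per_clone = 30, seed = 9)
  reads <- simulate_clone_reads(rs, tempfile())
  n_per_file <- 30 * 400 / 40

  all_out <- tempfile(fileext = ".fastq")
  log_all <- mix_pseudo_pool(reads$fastq_paths, all_out, fraction = 1, seed = 1)
  expect_equal(log_all$n_included, rep(n_per_file, 3))
  expect_identical(readLines(all_out),
                   unlist(lapply(reads$fastq_paths, readLines),
                          use.names = FALSE))

  none_out <- tempfile(fileext = ".fastq")
  log_none <- mix_pseudo_pool(reads$fastq_paths, none_out, fraction = 0,
                              seed = 1)
  expect_equal(sum(log_none$n_included), 0)
  expect_equal(length(readLines(none_out)), 0)

  ten_out <- tempfile(fileext = ".fastq")
  log_ten <- mix_pseudo_pool(reads$fastq_paths, ten_out, fraction = 0.1,
                             seed = 7)
  sd3 <- 3 * sqrt(n_per_file * 0.1 * 0.9)
  expect_true(all(abs(log_ten$n_included - n_per_file * 0.1) <= sd3))

  bad <- tempfile(); writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(mix_pseudo_pool(bad, tempfile(), 0.5, 1),
               class = "gxediv_parse_error")
})
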