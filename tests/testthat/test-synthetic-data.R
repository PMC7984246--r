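test_that("generators are deterministic for a fixed seed", {
  sc <- biolog_scenario(n_populations_per_treatment = 2, seed = 5)
  expect_identical(simulate_biolog(sc, "specialist"),
                   simulate_biolog(sc, "specialist"))

  vs <- variant_scenario(seed = 5)
  expect_identical(simulate_variant_tables(vs), simulate_variant_tables(vs))

  cs <- competition_scenario(seed = 5)
  expect_identical(simulate_competition(cs, 5), simulate_competition(cs, 5))

  rs <- read_scenario(genome_length = 500, n_clones = 2,
                      coverage_per_clone = 2, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- simulate_clone_reads(rs, d1)
  r2 <- simulate_clone_reads(rs, d2)
  expect_identical(readLines(r1$fastq_paths[[1]]),
                   readLines(r2$fastq_paths[[1]]))
  expect_identical(r1$truth, r2$truth)
})

test_that("noise-free generalist populations are uniform; specialist niches anticorrelate", {
  sc <- biolog_scenario(n_populations_per_treatment = 1, n_clones = 4,
                        n_substrates = 12, niche_size = 4,
                        n_specialist_types = 2, noise_sd = 0, seed = 1)
  gen <- simulate_biolog(sc, "generalist")
  m <- matrix(gen$od, nrow = 4)
  expect_true(all(m == sc$generalist_mean))
  comp <- gxe_decompose(gen)
  expect_equal(comp$R, 0)
  expect_equal(comp$I, 0)

  spec <- simulate_biolog(sc, "specialist")
  wide <- tidyr::pivot_wider(spec[, c("clone_id", "substrate_id", "od")],
                             names_from = "substrate_id", values_from = "od")
  ms <- as.matrix(wide[, -1])
  niche_cols <- 1:8  # the two disjoint niches
  # clones 1 and 2 carry different niche types (types are cycled)
  expect_lt(cor(ms[1, niche_cols], ms[2, niche_cols]), 0)
  expect_equal(cor(ms[1, niche_cols], ms[3, niche_cols]), 1)
})

test_that("niche capacity and invalid parameters are configuration errors", {
  expect_error(biolog_scenario(n_substrates = 10, niche_size = 6,
                               n_specialist_types = 2),
               class = "gxediv_config_error")
  expect_error(variant_scenario(proportion_alpha = 0),
               class = "gxediv_config_error")
  expect_error(competition_scenario(true_relative_fitness = 0),
               class = "gxediv_config_error")
  expect_error(read_scenario(genome_length = 50, read_length = 100),
               class = "gxediv_config_error")
})

test_that("variant generator honours Poisson mean and shared-variant spec", {
  none <- simulate_variant_tables(
    variant_scenario(mean_variants_per_population = 0, seed = 2))
  expect_equal(nrow(none), 0)

  spec <- variant_scenario(
    n_populations = 6, mean_variants_per_population = 0,
    shared_variant_spec = tibble::tibble(
      variant_id = "sv1", treatment = "homogeneous", fraction = 1,
      proportion = 0.6),
    seed = 2)
  tab <- simulate_variant_tables(spec)
  sv <- dplyr::filter(tab, variant_id == "sv1")
  expect_equal(nrow(sv), 6)
  expect_true(all(sv$treatment == "homogeneous"))
  expect_true(all(sv$proportion == 0.6))

  big <- simulate_variant_tables(variant_scenario(
    n_populations = 50, mean_variants_per_population = 3, seed = 3))
  expect_true(all(big$proportion > 0 & big$proportion <= 1))
  # per-population Poisson counts: mean near 3 over 100 populations
  counts <- dplyr::count(big, population_id)
  expect_equal(mean(counts$n), 3, tolerance = 0.2)
})

test_that("competition generator maps true fitness to final fractions exactly", {
  # truth 3.0, f0 = 0.5 -> f7 = 0.75 by the odds-ratio relation
  cs <- competition_scenario(true_relative_fitness = 3, seed = 1)
  out <- simulate_competition(cs)
  expect_equal(out$true_fraction_T7, 0.75)
  expect_equal(relative_fitness(out$true_fraction_T0, out$true_fraction_T7), 3)

  # truth 1.0 -> no change
  flat <- simulate_competition(competition_scenario(1, seed = 1))
  expect_equal(flat$true_fraction_T7, 0.5)

  # counts stay off the 0/1 boundary
  expect_true(all(out$white_T0 > 0 & out$blue_T0 > 0 &
                    out$white_T7 > 0 & out$blue_T7 > 0))
})

test_that("plating-noise fitness estimates recover the truth to within 5%", {
  for (w in c(1.0, 1.5, 2.0)) {
    sims <- simulate_competition(
      competition_scenario(true_relative_fitness = w, seed = round(100 * w)),
      n_assays = 1000)
    est <- assay_fitness(sims)$relative_fitness
    expect_equal(mean(est), w, tolerance = 0.05)
  }
})

test_that("read simulator plants variants faithfully at error rate zero", {
  pv <- tibble::tibble(pos = 250L, ref = "A", alt = "T",
                       carriers = list(1L))
  rs <- read_scenario(genome_length = 500, n_clones = 2,
                      planted_variants = pv, read_length = 50,
                      coverage_per_clone = 10, error_rate = 0, seed = 4)
  out <- simulate_clone_reads(rs, tempfile())
  expect_equal(out$truth$carrier_fraction, 0.5)
  expect_equal(substr(out$genome, 250, 250), "A")

  check_alleles <- function(path, expected) {
    lines <- readLines(path)
    starts <- as.integer(sub(".*_pos", "", lines[seq(1, length(lines), 4)]))
    seqs <- lines[seq(2, length(lines), 4)]
    over <- which(starts <= 250 & starts + 50 - 1 >= 250)
    expect_gt(length(over), 0)
    alleles <- substr(seqs[over], 250 - starts[over] + 1, 250 - starts[over] + 1)
    expect_true(all(alleles == expected))
  }
  check_alleles(out$fastq_paths[["clone01"]], "T")  # carrier emits alt
  check_alleles(out$fastq_paths[["clone02"]], "A")  # non-carrier emits ref

  # read count = coverage * genome / read_length
  n_reads <- length(readLines(out$fastq_paths[[1]])) / 4
  expect_equal(n_reads, 10 * 500 / 50)
})

test_that("specialist scenarios show higher inconsistency than generalist ones", {
  # matched scenarios across 20 seeds; effect size >= 2 x noise sd
  rejections <- 0L
  spec_means <- gen_means <- numeric(20)
  for (s in 1:20) {
    sc <- biolog_scenario(n_populations_per_treatment = 3, n_clones = 6,
                          n_substrates = 24, niche_size = 6,
                          n_specialist_types = 3, noise_sd = 0.05, seed = s)
    data <- simulate_biolog_experiment(sc) |> filter_substrates()
    comp <- gxe_decompose(data)
    spec_means[s] <- mean(comp$I[comp$treatment == "heterogeneous"])
    gen_means[s] <- mean(comp$I[comp$treatment == "homogeneous"])
    p <- lm_f_test(comp$I, comp$treatment)$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_true(all(spec_means > gen_means))
  expect_gte(rejections / 20, 0.8)
})
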