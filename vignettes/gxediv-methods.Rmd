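---
title: "Methods: quantifying diversification from growth profiles, competitions and pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying diversification from growth profiles, competitions and pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxediv)
```

`gxediv` analyses diversification in experimentally evolved microbial
populations from three complementary data streams: clone-by-substrate
catabolic profiles, blue/white competition assays, and pooled-sequencing
variant-proportion tables. This vignette documents the statistical models,
the tunable parameters and their defaults, the design decisions taken where
the design was genuinely open, and what the synthetic-data generators do and
do not emulate.

## Variance decomposition of catabolic profiles

A population is summarised by a matrix of OD660 endpoint readings for `G`
clones on `S` single-carbon-source substrates (e.g. a Biolog GN2 plate).
Before any decomposition, `filter_substrates()` keeps a substrate only if
*every* clone of *every* population grew at least minimally on it — strictly,
minimum OD660 > 0.1. The filter is applied to the global clone set rather
than per treatment, so one common substrate panel underlies all populations
and their components are directly comparable. The inequality is strict: a
reading exactly at the threshold drops the substrate.

Per population the decomposition yields:

* **V_P**, phenotypic variance: the mean Euclidean distance between the
  growth profiles of all `G(G-1)/2` clone pairs (OD units).
* **V_G**, genotypic variance: by default the sample variance across clones
  of each clone's mean growth (variation in overall performance). An
  alternative estimator — the per-substrate variance across clones averaged
  over substrates — is available via
  `genotypic_variance(..., estimator = "substrate_mean_var")` and reported
  alongside in `gxe_decompose(verbose = TRUE)`. The two differ because the
  substrate-wise form also absorbs clone-by-substrate interaction variance;
  the clone-means form is the default precisely because the interaction is
  reported separately as R and I. Neither is asserted to be "the" right
  estimator; both are exposed.
* **V_E**, environmental variance: the sample variance across substrates of
  the per-substrate mean over clones.
* **R**, responsiveness:
  $R = \sum_{i \neq j} \frac{(\sigma_i - \sigma_j)^2/2}{G(G-1)}$,
  with $\sigma_i$ the sample SD of clone $i$'s growth across substrates.
  High R means clones differ in how strongly they respond to the
  environment — a mix of generalists and specialists.
* **I**, inconsistency:
  $I = \sum_{i \neq j} \frac{\sigma_i \sigma_j (1 - \rho_{ij})}{G(G-1)}$,
  with $\rho_{ij}$ the Pearson correlation of the two clones' profiles.
  Negative correlations — rank switching, the signature of resource
  specialisation — drive I up.

Sums run over ordered pairs $i \neq j$, consistent with the `G(G-1)`
denominator (equivalent to unordered pairs times two). Sample (`n-1`)
variances and SDs are used throughout, matching the defaults of standard
statistical software. If a clone has zero variance its correlations are
undefined; the pair term $\sigma_i\sigma_j(1-\rho_{ij})$ is set to 0, its
limit as the signal vanishes.

A useful identity ties the two interaction components together: for every
matrix, $R + I$ equals the mean over ordered pairs of
$\mathrm{Var}_s(x_i - x_j)/2$, the variance of the difference profile. The
test suite verifies this to 1e-10 against an independent brute-force
implementation on random matrices; it is a strong whole-pipeline check
because the left side goes through SDs and correlations while the right side
never computes either.

Treatment differences in any component are tested with
`lm_f_test()` — the F test between the group-means model and the
intercept-only model, which for a single categorical predictor induces the
same ordering as the likelihood-ratio test between those nested Gaussian
models. Two-sided p values throughout.

## Competition fitness

Competition assays mix an evolved (white) population 50:50 with a marked
(blue) ancestor and plate at the start (T0) and end (T7). `assay_fitness()`
converts counts into fractions and the odds-ratio relative fitness

$$w = \frac{f_{T7}\,(1 - f_{T0})}{f_{T0}\,(1 - f_{T7})}.$$

Fractions are dilution-invariant, so raw plate counts are used without
dilution correction. Fractions of exactly 0 or 1 (extinction or fixation on
the plate) raise an explicit error: the odds ratio is undefined there and a
silent infinity would poison downstream means. The Malthusian-parameter
ratio $\ln(n_{A7}/n_{A0})/\ln(n_{B7}/n_{B0})$ is also reported; the two
statistics agree only under restrictive conditions (exactly, when the
reference strain's abundance is unchanged), so both are computed and neither
is presented as equivalent to the other. The Malthusian column is `NA` when
its denominator vanishes.

`fitness_contrasts()` runs targeted pairwise comparisons between
evolution-by-competition environment combinations: a paired t test when the
same evolved populations are compared across competition environments
(matched on `population_id`), Welch's t otherwise, with Holm step-down
adjustment over the requested family. This deliberately replaces a linear
mixed model with a population random effect and Kenward–Roger degrees of
freedom: with six populations per treatment and a paired design, the paired
t test conditions on the same between-population variation the random effect
would model, while keeping the machinery transparent. Exact replication of
mixed-model output is a non-goal; the contrast structure is preserved.

## Pooled-sequencing diversity

Variant tables carry one row per variant per population with a pooled
proportion $p \in (0,1]$. Variant identity is the VCF-style key
`(chrom, pos, ref, alt)` with 1-based positions; the SNP/indel `type` column
is annotation only. Three metrics summarise each population:

* genetic distance from the ancestor: $\sum_i p_i$;
* variant count: variants with $p \geq$ a detection floor (default 0.1, the
  proportion cut-off at which a pool of 10 clones can still show a variant
  carried by one clone; inclusive threshold);
* alpha diversity: $\alpha = \sum_i (1 - p_i^2 - q_i^2)$ with $q = 1-p$,
  i.e. summed expected heterozygosity $\sum 2p(1-p)$.

`whitelist_filter()` implements the conservative approach of keeping only
pooled calls whose key was also seen in clonal sequencing; it is a set
intersection, hence idempotent and incapable of increasing any metric.

Pooled *detection* is modelled at the allele-count level:
`simulate_pool_detection()` draws the alt count as
$\mathrm{Binomial}(\text{depth}, p_\text{eff})$ with
$p_\text{eff} = p(1-e) + (1-p)e/3$ (errors uniform over the three other
bases) and calls a variant detected when the observed proportion reaches the
cut-off. This isolates the statistical logic of pooled detection — the role
of the 0.1 cut-off and the false-negative behaviour near it — without
re-running read mapping and variant calling, which are outside this
package's scope. At the canonical operating point (single carrier among 10
clones, 100x pooled depth, cut-off 0.1) the detection probability is the
exact binomial tail $P(\mathrm{Bin}(100, 0.1) \geq 10) \approx 0.549$: even
a well-behaved pool misses singleton variants almost half the time, which is
why whitelisting against clonal calls matters. The `mix_pseudo_pool()`
helper builds in-silico pools by keeping each read of each clone's FASTQ
with a fixed probability (e.g. 10%), the standard pseudo-pool construction
for validating pooled pipelines against clonal truth.

## Multivariate comparison of populations

`variant_feature_matrix()` spreads the tables into a populations-by-variants
proportion matrix (absent variant = 0), from which Euclidean distances feed
three analyses:

* **PERMANOVA** (`permanova()`): with squared distances $d^2_{ij}$,
  $SS_\text{total} = \frac{1}{n}\sum_{i<j} d^2_{ij}$,
  $SS_\text{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$, and
  pseudo-$F = \frac{(SS_\text{total} - SS_\text{within})/(a-1)}
  {SS_\text{within}/(n-a)}$. Group labels are permuted over whole samples
  (no strata; the design has a single factor), and the p value includes the
  observed statistic in numerator and denominator,
  $p = (1 + \#\{F^* \geq F\})/(n_\text{perm}+1)$, so it is never zero and
  has resolution $1/(n_\text{perm}+1)$. The default 9,999 permutations give
  a p resolution of 1e-4. On 1-D Euclidean data the pseudo-F reduces
  exactly to the classical ANOVA F, which the tests exploit as an oracle;
  the implementation is also cross-checked against `vegan::adonis2()`.
  If all within-group distances vanish the statistic is reported as `Inf`
  and the p value still comes from the permutation distribution.
* **Beta-dispersion** (`beta_dispersion()`): samples are embedded by
  principal-coordinate decomposition; each sample's distance to its own
  group centroid is computed with the standard negative-eigenvalue
  correction (squared deviations along imaginary axes are subtracted, the
  result floored at zero before the square root), and the group effect on
  those distances is tested by one-way ANOVA. Centroids, not spatial
  medians, are used, matching the centroid variant of the standard
  dispersion test; the tests cross-check against
  `vegan::betadisper(type = "centroid")`.
* **NMDS** (`nmds_ordination()`): delegated to `vegan::metaMDS()` (Kruskal
  stress-1, monotone regression, random restarts keeping the best
  solution) under a fixed seed; the wrapper's contract is a seeded,
  rank-faithful embedding with its stress reported, and that is what the
  tests enforce (Procrustes agreement across repeated seeded runs, Spearman
  rank fidelity when stress < 0.05).

The pipeline applies the clonal whitelist before building the feature
matrix when a whitelist is supplied — consistent with filtering error-prone
calls from all subsequent analyses — but the filter can be skipped simply
by not supplying one.

## Synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, so every stage is testable without external data. They emulate the
*measured data layer* only: no compost chemistry, spatial diffusion or
mutation dynamics during the evolution phase.

**Growth profiles** (`simulate_biolog()`): specialist populations assign
each clone one of `n_specialist_types` disjoint niches (blocks of
`niche_size` substrates; disjointness is what forces the negative
cross-clone correlations that inconsistency detects); a clone grows at
`baseline_mean + specialist_gain` on its niche and
`baseline_mean - specialist_loss` elsewhere. Generalist populations grow at
`generalist_mean` everywhere. Noise is additive Gaussian truncated at zero —
the simplest model preserving OD non-negativity; no claim is made about the
real error structure of plate readers. Defaults (6 populations per
treatment, 10 clones, 96 substrates, baseline 0.5 OD, gain 0.5, loss 0.2,
four niches of 12, noise SD 0.05 OD) reflect a realistic two-treatment
plate experiment; the noise magnitude and substrate-level means are free
parameters documented here, not calibrated to any dataset. Off-niche growth
(0.3 OD) stays above the 0.1 filter so the simulated panel is not gutted by
filtering.

**Variant tables** (`simulate_variant_tables()`): private variants are
Poisson per population (default mean 2.5) with proportions drawn from
Beta(1, 2) (mean 1/3 — most variants segregate at low-to-middling pooled
proportions, occasional near-fixed ones). Shared, treatment-diagnostic
variants are planted via an explicit spec (which fraction of which
treatment's populations carry them, at what proportion).

**Competitions** (`simulate_competition()`): growth between timepoints is
deterministic — the final fraction is chosen so the odds ratio equals the
true fitness — and all stochasticity is binomial plating noise (default 200
colonies per plate). This isolates the estimator's sampling behaviour from
growth-model assumptions. Plates that would fix or lose a strain are
resampled (bounded at 100 attempts) because the estimator is undefined
there; at 200 colonies this is astronomically rare for interior fractions.

**Reads** (`simulate_clone_reads()`): uniform single-end reads over a
random genome, planted SNPs emitted by carrier clones, constant Phred 40
qualities, optional uniform substitution errors. This supports the
pseudo-pool workflow, not read-level realism (no quality decay, no indel
errors, no paired ends).

Passing tests on these generators therefore show that the estimators
recover known structure under the stated noise models — not that real
compost populations satisfy those models. In particular, real catabolic
profiles have correlated substrate panels and heteroscedastic noise, and
real pool-seq proportions carry mapping biases that the binomial model
ignores.

Every generator takes an integer seed and is bit-for-bit reproducible;
`run_pipeline()` derives fixed per-stage sub-seeds from one master seed and
records everything in a JSON manifest.

## Numerical choices and degenerate inputs

* Variances and SDs use the `n-1` denominator everywhere.
* Eigenvalues below `1e-10` times the largest magnitude are dropped in the
  principal-coordinate embedding; squared centroid distances are floored at
  zero before the square root.
* `lm_f_test()` raises an explicit error when both between- and
  within-group variance are zero (the statistic is 0/0); zero residual with
  nonzero signal yields an infinite statistic rather than an error.
* Rank-sum p values are exact for small untied samples and use the
  tie-corrected normal approximation otherwise (midranks for ties).
* Substrate filtering, variant detection and pooled detection all use the
  documented strict/inclusive conventions: OD must *exceed* the filter
  threshold; a proportion *at* the detection floor counts.

## Problem sizes used by the test and acceptance runs

The default verification runs use 20-seed replications of the full 6+6
population experiment for parameter recovery, 10,000 simulations for the F
test's type-I calibration, 200 replicate datasets at 199 permutations for
PERMANOVA null uniformity, 1,000 simulated assays per fitness truth value,
and 10,000 binomial sites for the detection-probability check. These sizes
put Monte-Carlo error well below each check's tolerance while keeping a
full run in the low tens of seconds.

## Known limitations

* Single-endpoint OD only; no kinetic growth-curve fitting.
* No mixed models; the paired/Welch contrast scheme assumes the
  population-level fitness values are exchangeable within groups.
* PERMANOVA is single-factor, unstratified; no multi-factor designs.
* Structural variants and the read-processing stages upstream of variant
  tables (trimming, mapping, calling) are out of scope; the pipeline starts
  from variant proportions.
* The pooled-detection model treats sites independently at fixed depth;
  real pools have variable depth and linked variants.
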