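# long growth tibble from a clones x substrates matrix
od_long <- function(m, population_id = "pop1", treatment = NA_character_) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  tibble::tibble(
    population_id = population_id,
    treatment = treatment,
    clone_id = rep(rownames(m), times = ncol(m)),
    substrate_id = rep(colnames(m), each = nrow(m)),
    od = as.vector(m))
}

# independent oracle for the G-by-E identity: mean over ordered clone pairs
# of the variance (across substrates) of the difference profile, halved
gxe_pair_oracle <- function(m) {
  G <- nrow(m)
  tot <- 0
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (i != j) tot <- tot + stats::var(m[i, ] - m[j, ]) / 2
    }
  }
  tot / (G * (G - 1))
}

random_od_matrix <- function(G = 5, S = 8) {
  matrix(stats::runif(G * S, 0, 2), nrow = G)
}
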