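#' Simulate per-clone FASTQ files with planted variants
#'
#' Writes one single-end FASTQ file per clone plus a truth table of the
#' planted variants. The reference genome is a uniform random nucleotide
#' sequence; reads start uniformly over the genome at the scenario's fold
#' coverage (`round(coverage * genome_length / read_length)` reads per
#' clone). Clones listed as carriers of a planted variant emit the alt base
#' at that site; every base is then independently substituted with
#' probability `error_rate` (uniformly to one of the three other bases).
#' Base qualities are constant Phred 40 (`"I"`, Phred+33).
#'
#' @param scenario A [read_scenario()].
#' @param dir Output directory (created if missing).
#'
#' @return Invisibly, a list with `fastq_paths` (named by clone), `genome`
#'   (the reference sequence as a string) and `truth` — a tibble with one
#'   row per planted variant: `chrom`, `pos`, `ref`, `alt`,
#'   `carrier_fraction`.
#' @export
simulate_clone_reads <- function(scenario, dir = tempfile("clone_reads")) {
  stopifnot(inherits(scenario, "read_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  L <- scenario$genome_length
  rl <- scenario$read_length
  n_reads <- round(scenario$coverage_per_clone * L / rl)

  pv <- scenario$planted_variants
  withr::with_seed(scenario$seed, {
    genome <- sample(bases, L, replace = TRUE)
    if (!is.null(pv)) genome[pv$pos] <- pv$ref  # reference carries ref allele

    paths <- setNames(
      file.path(dir, sprintf("clone%02d.fastq", seq_len(scenario$n_clones))),
      sprintf("clone%02d", seq_len(scenario$n_clones)))

    for (cl in seq_len(scenario$n_clones)) {
      clone_genome <- genome
      if (!is.null(pv)) {
        for (v in seq_len(nrow(pv))) {
          if (cl %in% pv$carriers[[v]]) {
            clone_genome[pv$pos[v]] <- pv$alt[v]
          }
        }
      }
      starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      recs <- character(4L * n_reads)
      qual <- strrep("I", rl)
      for (r in seq_len(n_reads)) {
        seq_r <- clone_genome[starts[r]:(starts[r] + rl - 1L)]
        if (scenario$error_rate > 0) {
          err <- runif(rl) < scenario$error_rate
          if (any(err)) {
            seq_r[err] <- vapply(seq_r[err],
                                 function(b) sample(setdiff(bases, b), 1), "")
          }
        }
        k <- 4L * (r - 1L)
        recs[k + 1L] <- sprintf("@clone%02d_read%05d_pos%d", cl, r, starts[r])
        recs[k + 2L] <- paste(seq_r, collapse = "")
        recs[k + 3L] <- "+"
        recs[k + 4L] <- qual
      }
      writeLines(recs, paths[[cl]])
    }
  })

  truth <- if (is.null(pv)) {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), carrier_fraction = double())
  } else {
    tibble(chrom = "chr1", pos = pv$pos, ref = pv$ref, alt = pv$alt,
           carrier_fraction = vapply(pv$carriers, length, 1L) /
             scenario$n_clones)
  }
  invisible(list(fastq_paths = paths,
                 genome = paste(genome, collapse = ""),
                 truth = truth))
}

#' Build a pseudo-pool by subsampling reads from per-clone FASTQ files
#'
#' Emulates in-silico pooling of clonal sequencing runs: every read of every
#' input file is independently kept with probability `fraction` (e.g. 0.1 to
#' take 10% of the reads from each of 10 clones) and the kept reads are
#' written to one merged FASTQ in input-file order. Deterministic for a
#' fixed seed.
#'
#' @param clone_fastqs Character vector of FASTQ paths.
#' @param out Path of the merged FASTQ to write.
#' @param fraction Per-read inclusion probability in \[0, 1\].
#' @param seed Integer seed.
#'
#' @return Invisibly, a tibble with `file`, `n_reads` and `n_included`
#'   per input file.
#' @export
mix_pseudo_pool <- function(clone_fastqs, out, fraction = 0.1, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  con <- file(out, open = "w")
  on.exit(close(con))
  log <- withr::with_seed(as.integer(seed), {
    purrr::map(clone_fastqs, function(path) {
      lines <- readLines(path)
      if (length(lines) %% 4L != 0L) {
        abort(sprintf("malformed FASTQ (%d lines, not a multiple of 4): %s",
                      length(lines), path),
              class = "gxediv_parse_error")
      }
      n <- length(lines) %/% 4L
      if (n > 0) {
        at <- substr(lines[seq(1L, length(lines), by = 4L)], 1L, 1L)
        bad <- which(at != "@")
        if (length(bad) > 0) {
          abort(sprintf("malformed FASTQ record %d in %s", bad[1], path),
                class = "gxediv_parse_error")
        }
      }
      keep <- which(runif(n) < fraction)
      if (length(keep) > 0) {
        idx <- as.vector(vapply(keep, function(r) (4L * (r - 1L) + 1L):(4L * r),
                                integer(4)))
        writeLines(lines[idx], con)
      }
      tibble(file = path, n_reads = n, n_included = length(keep))
    })
  })
  invisible(dplyr::bind_rows(log))
}
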