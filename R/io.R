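#' Write / read one population's OD matrix as TSV
#'
#' The on-disk format is a wide TSV: one row per clone, a first column
#' `clone_id`, then one column per substrate id. Metadata columns
#' (`population_id`, `treatment`) are supplied separately on read.
#'
#' @param data Long tibble for a single population (`clone_id`,
#'   `substrate_id`, `od`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_od_matrix <- function(data, path) {
  m <- od_matrix(data)
  wide <- dplyr::bind_cols(tibble(clone_id = rownames(m)),
                           as_tibble(as.data.frame(m)))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_od_matrix
#' @param population_id,treatment Labels attached to every row on read.
#' @return `read_od_matrix()`: a validated long tibble (`population_id`,
#'   `treatment`, `clone_id`, `substrate_id`, `od`).
#' @export
read_od_matrix <- function(path, population_id = "pop1",
                           treatment = NA_character_) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(wide)[1] != "clone_id") {
    abort(sprintf("parse error in %s: first column must be clone_id", path),
          class = "gxediv_parse_error")
  }
  long <- tidyr::pivot_longer(wide, -"clone_id",
                              names_to = "substrate_id", values_to = "od")
  if (!is.numeric(long$od) || anyNA(long$od)) {
    abort(sprintf("parse error in %s: non-numeric or missing OD values", path),
          class = "gxediv_parse_error")
  }
  bad <- which(long$od < 0)
  if (length(bad) > 0) {
    abort(sprintf("validation error in %s: negative OD at row %d", path,
                  bad[1]),
          class = "gxediv_validation_error")
  }
  dplyr::bind_cols(tibble(population_id = population_id,
                          treatment = treatment,
                          .rows = nrow(long)),
                   long)
}

#' Write / read variant tables as TSV
#'
#' Columns: `variant_id`, `chrom`, `pos`, `ref`, `alt`, `type`
#' (`SNP`/`indel`), `population_id`, `proportion`; an optional `treatment`
#' column is preserved. Positions are 1-based (VCF convention). Proportions
#' must lie in (0, 1] and variant keys `(chrom, pos, ref, alt)` must be
#' unique within a population.
#'
#' @param tables Variant tibble.
#' @param path File path.
#' @return `path` invisibly (write); a validated tibble (read).
#' @export
write_variant_table <- function(tables, path) {
  cols <- c("variant_id", "chrom", "pos", "ref", "alt", "type",
            "population_id", "proportion")
  extra <- intersect("treatment", names(tables))
  readr::write_tsv(tables[, c(cols, extra)], path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("variant_id", "chrom", "pos", "ref", "alt", "type",
              "population_id", "proportion")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("parse error in %s: missing column %s", path,
                  missing_cols[1]),
          class = "gxediv_parse_error")
  }
  bad <- which(is.na(tab$proportion) | tab$proportion <= 0 |
                 tab$proportion > 1)
  if (length(bad) > 0) {
    abort(sprintf("validation error in %s: proportion out of (0,1] at row %d",
                  path, bad[1]),
          class = "gxediv_validation_error")
  }
  dup <- tab |>
    dplyr::count(.data$population_id, .data$chrom, .data$pos, .data$ref,
                 .data$alt) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("validation error in %s: duplicate variant key at %s:%d",
                  path, dup$chrom[1], dup$pos[1]),
          class = "gxediv_validation_error")
  }
  tab
}

#' Write / read competition assay tables as CSV
#'
#' Columns: `population_id`, `evolution_env`, `competition_env`,
#' `white_T0`, `blue_T0`, `white_T7`, `blue_T7` (counts must be
#' non-negative with a positive total at each timepoint).
#'
#' @param data Assay tibble.
#' @param path File path.
#' @return `path` invisibly (write); a validated tibble (read).
#' @export
write_competitions <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_competitions
#' @export
read_competitions <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("population_id", "evolution_env", "competition_env",
              "white_T0", "blue_T0", "white_T7", "blue_T7")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("parse error in %s: missing column %s", path,
                  missing_cols[1]),
          class = "gxediv_parse_error")
  }
  counts <- as.matrix(tab[, c("white_T0", "blue_T0", "white_T7", "blue_T7")])
  bad <- which(rowSums(counts < 0 | is.na(counts)) > 0)
  if (length(bad) > 0) {
    abort(sprintf("validation error in %s: bad colony count at row %d", path,
                  bad[1]),
          class = "gxediv_validation_error")
  }
  tab
}

#' Read pooled variant proportions from a minimal VCF
#'
#' Accepts a VCF whose per-variant pooled proportion is carried in an INFO
#' key (default `AF`). Only the fixed columns and that key are used;
#' genotype columns are ignored. Requires the `vcfR` package.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param population_id,treatment Labels attached to the records.
#' @param info_key INFO key holding the pooled proportion.
#' @return A variant tibble in the package's standard layout.
#' @export
read_pool_vcf <- function(path, population_id = "pop1",
                          treatment = NA_character_, info_key = "AF") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_pool_vcf() requires the vcfR package",
          class = "gxediv_dependency_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  prop <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = info_key)))
  if (anyNA(prop)) {
    abort(sprintf("parse error in %s: INFO key %s missing or non-numeric",
                  path, info_key),
          class = "gxediv_parse_error")
  }
  tibble(variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                             paste0(fix$CHROM, ":", fix$POS), fix$ID),
         chrom = fix$CHROM,
         pos = as.integer(fix$POS),
         ref = fix$REF,
         alt = fix$ALT,
         type = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1,
                       "SNP", "indel"),
         population_id = population_id,
         treatment = treatment,
         proportion = prop)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the package version, the master seed, the thresholds in force
#' and any extra configuration as JSON next to the run's outputs, so any
#' output file can be traced to the exact configuration that produced it.
#'
#' @param dir Output directory.
#' @param seed Master seed of the run.
#' @param config Named list of configuration values.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed, config = list()) {
  manifest <- list(
    package = "gxediv",
    version = as.character(utils::packageVersion("gxediv")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
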