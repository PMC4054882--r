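#' @keywords internal
#' Parse printed coordinates: tolerate thousands separators and embedded
#' whitespace ("5,601,528", "84322711"). Errors name the offending file line
#' (header is line 1).
parse_coord <- function(x, col, file = "input") {
  cleaned <- gsub("[,\\s]", "", x, perl = TRUE)
  out <- suppressWarnings(as.numeric(cleaned))
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad)) {
    abort(sprintf(
      "Non-numeric `%s` value '%s' at line %d of %s.",
      col, x[bad[[1]]], bad[[1]] + 1L, file
    ))
  }
  out
}

assembly_for_species <- function(species) {
  dplyr::case_match(species, "rat" ~ "rn4", "human" ~ "GRCh37",
                    .default = species)
}

#' Read a locus table in the shared locus-TSV dialect
#'
#' The dialect has columns `locus_name`, `species` (`rat`/`human`),
#' `chromosome`, `start`, `end`, `role` (`rat_source`/`human_ortholog`),
#' `carcinogen` (`DMBA`/`estradiol`/`none`) and an optional `overlap_group`
#' (comma-separated labels of loci this locus overlaps). Coordinates may
#' carry thousands separators as printed in the source tables. Each locus
#' has one `rat_source` row and one or more `human_ortholog` fragment rows.
#'
#' @param path Path to a tab-separated locus table.
#' @return A long tibble with columns `locus`, `role`, `assembly`,
#'   `chromosome`, `start`, `end`, `carcinogen`, `overlap_group`.
#' @seealso [rat_mammary_loci()], [random_rat_regions()] for the packaged
#'   tables; [locus_rat_intervals()] and [locus_human_fragments()] to pull
#'   out one side.
#' @export
read_locus_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("locus_name", "species", "chromosome", "start", "end", "role", "carcinogen")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Locus table %s lacks column(s): %s.", path, toString(missing_cols)))
  }
  out <- tibble(
    locus = raw$locus_name,
    role = raw$role,
    assembly = assembly_for_species(raw$species),
    chromosome = raw$chromosome,
    start = parse_coord(raw$start, "start", path),
    end = parse_coord(raw$end, "end", path),
    carcinogen = raw$carcinogen,
    overlap_group = if ("overlap_group" %in% names(raw)) raw$overlap_group else NA_character_
  )
  bad <- which(out$end < out$start)
  if (length(bad)) {
    abort(sprintf("end < start at line %d of %s.", bad[[1]] + 1L, path))
  }
  bad_role <- setdiff(unique(out$role), c("rat_source", "human_ortholog"))
  if (length(bad_role)) {
    abort(sprintf("Unknown role(s) in %s: %s.", path, toString(bad_role)))
  }
  out
}

#' Extract the rat-side source intervals of a locus table
#'
#' @param loci A locus tibble from [read_locus_table()].
#' @return An interval tibble (one row per locus) with `locus`,
#'   `carcinogen` and `overlap_group` carried along.
#' @export
locus_rat_intervals <- function(loci) {
  out <- loci |>
    dplyr::filter(.data$role == "rat_source") |>
    dplyr::select("assembly", "chromosome", "start", "end",
                  "locus", "carcinogen", "overlap_group")
  if (anyDuplicated(out$locus)) {
    abort("Each locus must have exactly one rat_source row.")
  }
  out
}

#' Extract the human ortholog fragments of a locus table
#'
#' @param loci A locus tibble from [read_locus_table()].
#' @return An interval tibble (one row per fragment) with `locus`,
#'   `carcinogen` and a `bases_mapped` column defaulting to the fragment
#'   length (used by [filter_fragments()] when aligned-base counts are
#'   unknown).
#' @export
locus_human_fragments <- function(loci) {
  loci |>
    dplyr::filter(.data$role == "human_ortholog") |>
    dplyr::select("assembly", "chromosome", "start", "end",
                  "locus", "carcinogen") |>
    dplyr::mutate(bases_mapped = .data$end - .data$start)
}

#' Packaged rat mammary cancer locus table
#'
#' The 24 rat mammary cancer susceptibility loci (14 DMBA-induced
#' `Mcs`/`Mcsm` loci plus `Mcstm1-2`, `Mcsta1` and the estradiol-induced
#' `Emca` loci) with their rn4 source coordinates and GRCh37 ortholog
#' fragments, as transcribed from the published locus table.
#'
#' @return A locus tibble (see [read_locus_table()]).
#' @examples
#' loci <- rat_mammary_loci()
#' dplyr::count(loci, role)
#' @export
rat_mammary_loci <- function() {
  read_locus_table(system.file("extdata", "rat_mcs_loci.tsv",
                               package = "orthoenrich", mustWork = TRUE))
}

#' Packaged random rat control regions
#'
#' The 14 published random rat genome segments with their GRCh37 ortholog
#' fragments, transcribed as printed. Note the printed rat spans are
#' 24,322,710/11 bp even though the stated sampling length is 22,322,710 bp;
#' the table is shipped verbatim and [sample_control_regions()] uses the
#' stated length as its default.
#'
#' @return A locus tibble (see [read_locus_table()]).
#' @export
random_rat_regions <- function() {
  read_locus_table(system.file("extdata", "random_rat_regions.tsv",
                               package = "orthoenrich", mustWork = TRUE))
}

#' Read and write BED3
#'
#' Three-column tab-separated intervals. Coordinates in this package are
#' already half-open on the printed scale, so BED import/export applies no
#' coordinate shift.
#'
#' @param path File path.
#' @param assembly Assembly label to attach on read.
#' @return `read_bed3()` returns an interval tibble; `write_bed3()` returns
#'   `x` invisibly.
#' @export
read_bed3 <- function(path, assembly = "GRCh37") {
  raw <- readr::read_tsv(path,
    col_names = c("chromosome", "start", "end"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  out <- tibble(
    assembly = assembly,
    chromosome = raw$chromosome,
    start = parse_coord(raw$start, "start", path),
    end = parse_coord(raw$end, "end", path)
  )
  bad <- which(out$end < out$start)
  if (length(bad)) abort(sprintf("end < start at line %d of %s.", bad[[1]], path))
  validate_intervals(out, path)
  out
}

#' @rdname read_bed3
#' @param x Interval tibble to write.
#' @export
write_bed3 <- function(x, path) {
  validate_intervals(x)
  readr::write_tsv(
    dplyr::transmute(x, .data$chromosome,
                     start = format(.data$start, scientific = FALSE, trim = TRUE),
                     end = format(.data$end, scientific = FALSE, trim = TRUE)),
    path, col_names = FALSE
  )
  invisible(x)
}

#' Read a liftover-style fragment BED
#'
#' Adapter for precomputed assembly-conversion output: a BED file whose
#' 4th (name) column carries the source locus label, one fragment per
#' record. The result has the same shape as [locus_human_fragments()].
#'
#' @param path BED file with at least 4 columns.
#' @param assembly Assembly of the fragment coordinates.
#' @return Fragment tibble with `locus` and `bases_mapped` columns.
#' @export
read_liftover_bed <- function(path, assembly = "GRCh37") {
  raw <- readr::read_tsv(path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (ncol(raw) < 4) abort(sprintf("%s needs 4 BED columns (chrom, start, end, name).", path))
  tibble(
    assembly = assembly,
    chromosome = raw[[1]],
    start = parse_coord(raw[[2]], "start", path),
    end = parse_coord(raw[[3]], "end", path),
    locus = raw[[4]],
    carcinogen = NA_character_
  ) |>
    dplyr::mutate(bases_mapped = .data$end - .data$start)
}

#' Read a SNP catalog
#'
#' Tab-separated with a required header and columns `rsid`, `chrom`, `pos`
#' (1-based), `study`, `population`, `class` (`associated` or `potential`),
#' `or`, `ci_low`, `ci_high`, `pvalue`. Empty fields are allowed in the
#' optional effect-size columns and in `rsid` (records without an rsID are
#' keyed by position during deduplication).
#'
#' @param path File path.
#' @param assembly Assembly the positions refer to.
#' @return A tibble with columns `rsid`, `assembly`, `chromosome`,
#'   `position`, `study`, `population`, `assoc_class`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
read_snp_catalog <- function(path, assembly = "GRCh37") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("rsid", "chrom", "pos", "study", "population", "class")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("SNP catalog %s lacks column(s): %s.", path, toString(missing_cols)))
  }
  num_or_na <- function(col) {
    if (col %in% names(raw)) parse_coord(raw[[col]], col, path) else NA_real_
  }
  out <- tibble(
    rsid = dplyr::na_if(raw$rsid, ""),
    assembly = assembly,
    chromosome = raw$chrom,
    position = parse_coord(raw$pos, "pos", path),
    study = raw$study,
    population = raw$population,
    assoc_class = raw$class,
    odds_ratio = num_or_na("or"),
    ci_low = num_or_na("ci_low"),
    ci_high = num_or_na("ci_high"),
    p_value = num_or_na("pvalue")
  )
  if (any(is.na(out$position) | out$position < 1)) {
    abort(sprintf("SNP positions in %s must be present and >= 1 (1-based).", path))
  }
  bad_class <- setdiff(unique(out$assoc_class), c("associated", "potential"))
  if (length(bad_class)) {
    abort(sprintf("Unknown association class(es) in %s: %s.", path, toString(bad_class)))
  }
  out
}

#' @rdname read_snp_catalog
#' @param x SNP tibble (shape of [read_snp_catalog()] output) to write.
#' @export
write_snp_catalog <- function(x, path) {
  out <- dplyr::transmute(x,
    rsid = .data$rsid, chrom = .data$chromosome,
    pos = format(.data$position, scientific = FALSE, trim = TRUE),
    study = .data$study, population = .data$population,
    class = .data$assoc_class, or = .data$odds_ratio,
    ci_low = .data$ci_low, ci_high = .data$ci_high, pvalue = .data$p_value
  )
  readr::write_tsv(out, path)
  invisible(x)
}
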