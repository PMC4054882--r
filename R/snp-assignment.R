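#' Deduplicate a SNP catalog across studies
#'
#' GWA studies overlap, so one SNP may be reported by several studies. The
#' key is the rsID when present, otherwise `(chromosome, position)`. One
#' representative per key is kept: the record with the smallest p-value
#' (missing p-values sort last; remaining ties broken by study label, so
#' the result is independent of input order). Study labels of merged
#' records are collected in a `studies` column.
#'
#' @param snps SNP tibble (shape of [read_snp_catalog()]).
#' @return A tibble of unique SNPs with added columns `studies`
#'   (comma-joined) and `n_studies`; the number of SNPs seen in two or
#'   more studies is attached as attribute `n_multistudy`.
#' @examples
#' cat <- tibble::tibble(
#'   rsid = c("rs1", "rs1", "rs2"), assembly = "GRCh37",
#'   chromosome = "chr1", position = c(100, 100, 500),
#'   study = c("a", "b", "a"), population = "European",
#'   assoc_class = "potential", odds_ratio = NA_real_, ci_low = NA_real_,
#'   ci_high = NA_real_, p_value = c(1e-4, 1e-6, 1e-3)
#' )
#' u <- dedup_snp_catalog(cat)
#' attr(u, "n_multistudy")
#' @export
dedup_snp_catalog <- function(snps) {
  snps <- dplyr::mutate(snps,
    .key = dplyr::if_else(
      is.na(.data$rsid) | .data$rsid == "",
      paste0(.data$chromosome, ":", .data$position),
      .data$rsid
    )
  )
  conflict <- snps |>
    dplyr::filter(!is.na(.data$rsid)) |>
    dplyr::distinct(.data$rsid, .data$chromosome, .data$position) |>
    dplyr::count(.data$rsid) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(sprintf(
      "Conflicting genomic positions for rsID(s): %s.",
      toString(conflict$rsid)
    ))
  }
  out <- snps |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$p_value)), .data$p_value,
                   .data$study, .by_group = TRUE) |>
    dplyr::mutate(
      studies = paste(sort(unique(.data$study)), collapse = ","),
      n_studies = dplyr::n_distinct(.data$study)
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chromosome, .data$position, .data$.key) |>
    dplyr::select(-".key")
  attr(out, "n_multistudy") <- sum(out$n_studies >= 2)
  out
}

snp_hits <- function(snps, regions) {
  ## 1-based SNP position into the half-open frame: start <= pos-1 < end
  dplyr::inner_join(
    dplyr::select(snps, ".snp_id", "chromosome", "position"),
    regions,
    by = "chromosome", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$position - 1 >= .data$start,
                  .data$position - 1 < .data$end)
}

#' Assign unique SNPs to locus-ortholog, control, or neither territory
#'
#' Each SNP lands in `region_group = "loci"` when its position falls inside
#' at least one human ortholog fragment of at least one locus (all hit loci
#' are recorded, but the SNP contributes exactly once to the loci count,
#' because overlapping loci may not be independent), in `"control"` when it
#' falls inside control-ortholog territory, and in `"neither"` otherwise.
#' Locus and control territories must be disjoint; any overlap between the
#' two is a configuration error detected up front.
#'
#' Containment converts the 1-based SNP position into the half-open
#' coordinate frame: a fragment `[start, end)` contains position `pos`
#' when `start <= pos - 1 < end`.
#'
#' @param snps Unique-SNP tibble (from [dedup_snp_catalog()]).
#' @param loci Locus tibble ([read_locus_table()] shape); its
#'   `human_ortholog` rows are the loci territory.
#' @param controls Human interval tibble of control-ortholog territory
#'   (e.g. `locus_human_fragments(random_rat_regions())`).
#' @return `snps` with added columns `region_group`, `hit_loci`
#'   (comma-joined sorted locus labels, `NA` outside loci territory) and
#'   `n_hit_loci`.
#' @export
assign_snps <- function(snps, loci, controls) {
  frags <- locus_human_fragments(loci)
  validate_intervals(controls, "controls")
  if (nrow(frags) && nrow(controls) &&
      !identical(unique(frags$assembly), unique(controls$assembly))) {
    abort("Loci fragments and controls must share one assembly.")
  }
  snp_asm <- unique(snps$assembly)
  if (nrow(snps) && nrow(frags) && length(snp_asm) &&
      !all(snp_asm == unique(frags$assembly))) {
    abort(sprintf(
      "SNP assembly (%s) differs from territory assembly (%s).",
      toString(snp_asm), toString(unique(frags$assembly))
    ))
  }
  if (overlaps_any(frags, controls)) {
    abort(paste(
      "Configuration error: locus-ortholog and control territories overlap;",
      "the enrichment contrast requires exclusive groups."
    ))
  }
  snps <- dplyr::mutate(snps, .snp_id = dplyr::row_number())
  locus_hit <- snp_hits(snps, frags) |>
    dplyr::group_by(.data$.snp_id) |>
    dplyr::summarise(
      hit_loci = paste(sort(unique(.data$locus)), collapse = ","),
      n_hit_loci = dplyr::n_distinct(.data$locus)
    )
  control_hit <- dplyr::distinct(snp_hits(snps, controls), .data$.snp_id) |>
    dplyr::mutate(in_control = TRUE)
  snps |>
    dplyr::left_join(locus_hit, by = ".snp_id") |>
    dplyr::left_join(control_hit, by = ".snp_id") |>
    dplyr::mutate(
      region_group = dplyr::case_when(
        !is.na(.data$n_hit_loci) ~ "loci",
        !is.na(.data$in_control) ~ "control",
        .default = "neither"
      ),
      n_hit_loci = dplyr::coalesce(.data$n_hit_loci, 0L)
    ) |>
    dplyr::select(-".snp_id", -"in_control")
}

#' Tally assigned SNPs by population, association class and carcinogen
#'
#' Counts unique SNPs per `region_group` within each population and
#' association-class stratum, and separately per carcinogen induction
#' group. A SNP hitting overlapping loci of both induction types (one
#' DMBA-identified, one estradiol-identified) is counted once in the DMBA
#' group and once in the estradiol group, so carcinogen counts may
#' double-count by design.
#'
#' @param assignments Output of [assign_snps()].
#' @param loci Locus tibble supplying each locus's carcinogen tag.
#' @param n_multistudy Optional count of multi-study SNPs (defaults to the
#'   attribute left by [dedup_snp_catalog()], if present).
#' @return An object of class `assignment_tally`: list with
#'   `by_population` (population x assoc_class x region_group counts,
#'   zero-filled), `by_carcinogen`, `n_unique_snps`, `n_multistudy`.
#' @export
tally_assignments <- function(assignments, loci, n_multistudy = NULL) {
  n_multistudy <- n_multistudy %||% attr(assignments, "n_multistudy") %||% NA_integer_
  by_population <- assignments |>
    dplyr::count(.data$population, .data$assoc_class, .data$region_group) |>
    tidyr::complete(
      .data$population, .data$assoc_class,
      region_group = c("loci", "control", "neither"),
      fill = list(n = 0L)
    )
  carcinogen_of <- loci |>
    dplyr::filter(.data$role == "rat_source") |>
    dplyr::distinct(.data$locus, .data$carcinogen)
  by_carcinogen <- assignments |>
    dplyr::filter(.data$region_group == "loci") |>
    dplyr::mutate(.snp_id = dplyr::row_number()) |>
    tidyr::separate_longer_delim("hit_loci", delim = ",") |>
    dplyr::left_join(carcinogen_of, by = c(hit_loci = "locus")) |>
    dplyr::distinct(.data$.snp_id, .data$carcinogen) |>
    dplyr::count(.data$carcinogen)
  structure(
    list(
      by_population = by_population,
      by_carcinogen = by_carcinogen,
      n_unique_snps = nrow(assignments),
      n_multistudy = n_multistudy
    ),
    class = "assignment_tally"
  )
}

#' @export
print.assignment_tally <- function(x, ...) {
  cat(sprintf("<assignment_tally> %d unique SNPs (%s in >1 study)\n",
              x$n_unique_snps,
              ifelse(is.na(x$n_multistudy), "?", x$n_multistudy)))
  print(tidyr::pivot_wider(x$by_population,
                           names_from = "region_group", values_from = "n"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.assignment_tally <- function(x, ...) x$by_population
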