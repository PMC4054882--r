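#' Run the full cross-species enrichment analysis
#'
#' Chains the stages end to end: SNP catalog deduplication, count-once
#' assignment to locus-ortholog versus control territory, coverage
#' accounting of the rat-side regions, the per-population
#' observed-versus-expected chi-square, the 2x2 logistic regression of
#' territory on association class, and size-normalised count ratios. Each
#' stage logs its record counts via [rlang::inform()].
#'
#' @param snps SNP catalog tibble ([read_snp_catalog()] shape), possibly
#'   with multi-study duplicates.
#' @param loci Locus tibble ([read_locus_table()] shape).
#' @param controls Human interval tibble of control-ortholog territory.
#' @param control_rat Optional rat-side control interval tibble; needed
#'   for the coverage row of the controls and for the base-ratio
#'   denominator. Pass `locus_rat_intervals(random_rat_regions())` for the
#'   packaged controls or `sample_control_regions()$regions` for fresh
#'   draws.
#' @param rat_genome [genome_model()] for coverage fractions.
#' @param locus_subsets Optional named list of locus-label vectors; each
#'   gets its own rat-side coverage row (e.g. the Mcs/Mcsm subset).
#' @return Object of class `enrichment_report`: list with `coverage`,
#'   `assignments`, `tally`, `chisq` (one row per population with
#'   observed, expected, statistic, p, ratios), `logistic` (per-stratum
#'   Wald/LRT results, `NULL` when not estimable), `n_unique_snps`,
#'   `n_multistudy`.
#' @examples
#' ls <- simulate_landscape(n_loci = 8, seed = 1)
#' sim <- simulate_snp_catalog(300, ls, enrichment = 3, seed = 2)
#' rep <- run_enrichment_analysis(sim$catalog, ls$loci, ls$controls)
#' rep$chisq
#' @export
run_enrichment_analysis <- function(snps, loci, controls,
                                    control_rat = NULL,
                                    rat_genome = rat_genome_model(),
                                    locus_subsets = NULL) {
  stage <- function(name, fmt, ...) {
    rlang::inform(sprintf(paste0("[%s] ", fmt), name, ...))
  }
  rat <- locus_rat_intervals(loci)
  coverage <- coverage_summary(rat, rat_genome, name = "all_loci")
  for (nm in names(locus_subsets)) {
    sub <- dplyr::filter(rat, .data$locus %in% locus_subsets[[nm]])
    coverage <- dplyr::bind_rows(coverage, coverage_summary(sub, rat_genome, name = nm))
  }
  if (!is.null(control_rat)) {
    coverage <- dplyr::bind_rows(
      coverage, coverage_summary(control_rat, rat_genome, name = "controls")
    )
  }
  stage("coverage", "%d region set(s) summarised", nrow(coverage))

  unique_snps <- dedup_snp_catalog(snps)
  n_multistudy <- attr(unique_snps, "n_multistudy")
  stage("dedup", "%d records -> %d unique SNPs (%d multi-study)",
        nrow(snps), nrow(unique_snps), n_multistudy)

  assignments <- assign_snps(unique_snps, loci, controls)
  tally <- tally_assignments(assignments, loci, n_multistudy = n_multistudy)
  stage("assign", "loci %d / control %d / neither %d",
        sum(assignments$region_group == "loci"),
        sum(assignments$region_group == "control"),
        sum(assignments$region_group == "neither"))

  loci_unique <- coverage$unique_bases[coverage$name == "all_loci"]
  control_total <- if (!is.null(control_rat)) {
    coverage$total_bases[coverage$name == "controls"]
  } else {
    NA_real_
  }

  counts <- assignments |>
    dplyr::count(.data$population, .data$region_group) |>
    tidyr::pivot_wider(names_from = "region_group", values_from = "n",
                       values_fill = 0L)
  for (col in c("loci", "control", "neither")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  chisq <- counts |>
    dplyr::rowwise() |>
    dplyr::mutate(
      statistic = ifelse(.data$control > 0,
                         (.data$loci - .data$control)^2 / .data$control, NA_real_),
      p_value = ifelse(.data$control > 0,
                       pchisq(.data$statistic, 1, lower.tail = FALSE), NA_real_),
      snp_ratio = ifelse(.data$control > 0, .data$loci / .data$control, NA_real_),
      base_ratio = ifelse(is.na(control_total), NA_real_,
                          loci_unique / control_total),
      normalized_ratio = .data$snp_ratio / .data$base_ratio
    ) |>
    dplyr::ungroup() |>
    dplyr::rename(observed = "loci", expected = "control")
  if (nrow(chisq)) stage("enrich", "chi-square computed for %d population stratum/strata", nrow(chisq))

  cells <- assignments |>
    dplyr::filter(.data$region_group %in% c("loci", "control")) |>
    dplyr::count(.data$population, .data$assoc_class, .data$region_group)
  logistic_for <- function(sub) {
    get_cell <- function(cls, grp) {
      v <- sub$n[sub$assoc_class == cls & sub$region_group == grp]
      if (length(v)) v else 0L
    }
    cellv <- c(get_cell("associated", "loci"), get_cell("associated", "control"),
               get_cell("potential", "loci"), get_cell("potential", "control"))
    if (any(cellv == 0)) return(NULL)
    fit <- logistic_2x2(cellv[1], cellv[2], cellv[3], cellv[4])
    dplyr::bind_cols(
      tibble(loci_associated = cellv[1], control_associated = cellv[2],
             loci_potential = cellv[3], control_potential = cellv[4]),
      glance(fit)
    )
  }
  strata <- unique(cells$population)
  logistic <- purrr::map(
    setNames(strata, strata),
    function(p) logistic_for(dplyr::filter(cells, .data$population == p))
  )
  logistic$combined <- logistic_for(
    dplyr::summarise(cells, n = sum(.data$n),
                     .by = c("assoc_class", "region_group"))
  )
  logistic <- purrr::compact(logistic)
  logistic <- if (length(logistic)) {
    dplyr::bind_rows(logistic, .id = "stratum")
  } else {
    NULL
  }
  if (!is.null(logistic)) stage("logistic", "%d stratum/strata fitted", nrow(logistic))

  structure(
    list(
      coverage = coverage, assignments = assignments, tally = tally,
      chisq = chisq, logistic = logistic,
      n_unique_snps = nrow(assignments), n_multistudy = n_multistudy,
      loci_unique_bases = loci_unique, control_total_bases = control_total
    ),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> %d unique SNPs (%s multi-study)\n",
              x$n_unique_snps, format(x$n_multistudy)))
  cat("\nCoverage:\n"); print(x$coverage)
  cat("\nEnrichment by population:\n"); print(x$chisq)
  if (!is.null(x$logistic)) {
    cat("\nAssociation-class logistic regression:\n"); print(x$logistic)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enrichment_report <- function(x, ...) x$chisq

#' @exportS3Method generics::glance
glance.enrichment_report <- function(x, ...) {
  tibble(
    n_unique_snps = x$n_unique_snps,
    n_multistudy = x$n_multistudy,
    loci_unique_bases = x$loci_unique_bases,
    control_total_bases = x$control_total_bases
  )
}

fmt_num <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)

#' Write an enrichment report bundle to disk
#'
#' Emits `coverage.tsv`, `assignments.tsv`, `counts.tsv`,
#' `statistics.tsv`, machine-readable `report.json` (full precision) and a
#' human-readable `report.txt` (bases as integers, percentages to one
#' decimal, ratios to one/two decimals, p-values to two decimals). Output
#' depends only on the report contents, so reruns of the same seeded
#' analysis are byte-identical.
#'
#' @param report An `enrichment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_enrichment_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$coverage, file.path(dir, "coverage.tsv"))
  readr::write_tsv(report$assignments, file.path(dir, "assignments.tsv"))
  readr::write_tsv(report$tally$by_population, file.path(dir, "counts.tsv"))
  stats_tbl <- report$chisq
  if (!is.null(report$logistic)) {
    readr::write_tsv(report$logistic, file.path(dir, "logistic.tsv"))
  }
  readr::write_tsv(stats_tbl, file.path(dir, "statistics.tsv"))
  jsonlite::write_json(
    list(
      coverage = report$coverage,
      counts = report$tally$by_population,
      by_carcinogen = report$tally$by_carcinogen,
      chisq = report$chisq,
      logistic = report$logistic,
      n_unique_snps = report$n_unique_snps,
      n_multistudy = report$n_multistudy
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  txt <- c(
    "Cross-species SNP enrichment report",
    "===================================",
    "",
    sprintf("Unique SNPs: %d (reported in >1 study: %s)",
            report$n_unique_snps, format(report$n_multistudy)),
    "",
    "Coverage (bases):",
    sprintf("  %-12s n=%2d total=%s overlapping=%s unique=%s genome=%0.1f%%",
            report$coverage$name, report$coverage$n_loci,
            fmt_num(report$coverage$total_bases),
            fmt_num(report$coverage$overlapping_bases),
            fmt_num(report$coverage$unique_bases),
            report$coverage$genome_fraction),
    ""
  )
  if (nrow(report$chisq)) {
    txt <- c(txt, "Observed vs expected SNP counts:",
      sprintf("  %-18s O=%4d E=%4d chi2=%6.2f p=%s ratio=%s normalized=%s",
              report$chisq$population, report$chisq$observed,
              report$chisq$expected,
              report$chisq$statistic,
              ifelse(is.na(report$chisq$p_value), "NA",
                     sprintf("%.2f", report$chisq$p_value)),
              ifelse(is.na(report$chisq$snp_ratio), "NA",
                     sprintf("%.1f", report$chisq$snp_ratio)),
              ifelse(is.na(report$chisq$normalized_ratio), "NA",
                     sprintf("%.2f", report$chisq$normalized_ratio))))
  } else {
    txt <- c(txt, "No SNPs: statistics skipped.")
  }
  if (!is.null(report$logistic)) {
    txt <- c(txt, "",
      "Association-class logistic regression (territory ~ class):",
      sprintf("  %-18s slope=%7.4f Wald p=%.2f LRT p=%.2f",
              report$logistic$stratum, report$logistic$slope,
              report$logistic$p_value, report$logistic$lrt_p_value))
  }
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Locus labels of the Mcs/Mcsm subset
#'
#' The 14 DMBA-identified `Mcs`/`Mcsm` loci (the compact subset analysed
#' first, before the larger `Mcstm`/`Mcsta`/`Emca` loci are added).
#'
#' @return Character vector of 14 locus labels.
#' @export
mcs_mcsm_locus_names <- function() {
  c("Mcs1a", "Mcs1b", "Mcs1c", "Mcs2", "Mcs3", "Mcs4",
    "Mcs5a1", "Mcs5a2", "Mcs5b", "Mcs5c", "Mcs6", "Mcs7", "Mcs8", "Mcsm1")
}
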