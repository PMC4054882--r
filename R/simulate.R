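#' Simulate a locus/control/background landscape
#'
#' Generates a synthetic region landscape with the structure the
#' enrichment analysis assumes: a set of named loci with human ortholog
#' fragments (a stated fraction of which overlap pairwise, to exercise the
#' count-once rule), a set of control regions disjoint from loci
#' territory, and a background territory holding the rest of the simulated
#' genome. Defaults mirror the study design in miniature: 24 loci and 14
#' controls, with background territory `background_multiple` times the
#' loci unique bases.
#'
#' Overlap structure: `k = round(overlap_fraction * n_loci)` loci are each
#' placed to overlap one distinct partner locus, yielding exactly `k`
#' overlapping pairs; `overlap_fraction` must therefore be at most 0.5.
#' All other loci are pairwise disjoint.
#'
#' @param n_loci Number of loci.
#' @param locus_size_range Length-2 numeric range of locus sizes (bases).
#' @param overlap_fraction Fraction of loci placed as overlappers.
#' @param n_controls,control_length Control count and fixed length.
#' @param background_multiple Background bases as a multiple of loci
#'   unique bases.
#' @param seed Integer seed; the landscape is deterministic given it.
#' @return Object of class `sim_landscape`: list with `loci` (long locus
#'   tibble as from [read_locus_table()]), `controls` (interval tibble),
#'   `background` (interval tibble), `territory` (bases per group) and the
#'   configuration.
#' @examples
#' ls <- simulate_landscape(n_loci = 6, overlap_fraction = 0, seed = 1)
#' ls$territory
#' @export
simulate_landscape <- function(n_loci = 24,
                               locus_size_range = c(2e5, 2e6),
                               overlap_fraction = 0.25,
                               n_controls = 14,
                               control_length = 1e6,
                               background_multiple = 8,
                               seed = 1) {
  if (n_loci < 1 || n_controls < 1) abort("Need at least one locus and one control.")
  if (any(locus_size_range <= 0) || control_length <= 0) {
    abort("Sizes must be positive.")
  }
  if (overlap_fraction < 0 || overlap_fraction > 0.5) {
    abort("`overlap_fraction` must lie in [0, 0.5]: each overlapper needs its own partner.")
  }
  set.seed(seed)
  k <- round(overlap_fraction * n_loci)
  n_base <- n_loci - k
  if (k > n_base) abort("Infeasible overlap packing.")
  sizes <- round(runif(n_loci, locus_size_range[[1]], locus_size_range[[2]]))
  ## base loci laid out left to right with gaps wider than any locus, so
  ## an overlapper started inside its partner can only touch that partner
  gap_floor <- locus_size_range[[2]]
  starts <- numeric(n_loci)
  cursor <- 1e6
  for (i in seq_len(n_base)) {
    starts[i] <- cursor
    cursor <- cursor + sizes[i] + gap_floor + round(runif(1, 1e5, 1e6))
  }
  partners <- seq_len(k) # overlapper n_base + j overlaps base locus j
  for (j in seq_len(k)) {
    p <- partners[[j]]
    starts[n_base + j] <- starts[p] + round(0.5 * sizes[p])
  }
  locus_names <- sprintf("simlocus_%02d", seq_len(n_loci))
  carcinogen <- rep(c("DMBA", "estradiol"), length.out = n_loci)
  overlap_group <- rep(NA_character_, n_loci)
  for (j in seq_len(k)) {
    overlap_group[partners[[j]]] <- locus_names[n_base + j]
    overlap_group[n_base + j] <- locus_names[partners[[j]]]
  }
  human <- tibble(
    locus = locus_names, role = "human_ortholog", assembly = "simH",
    chromosome = "chrS1", start = starts, end = starts + sizes,
    carcinogen = carcinogen, overlap_group = overlap_group
  )
  rat <- dplyr::mutate(human, role = "rat_source", assembly = "simR",
                       chromosome = "RNOS1")
  loci <- dplyr::arrange(dplyr::bind_rows(rat, human), .data$locus, .data$role)

  ## controls on their own chromosome: disjoint from loci by construction
  ctrl_starts <- 1e6 + (seq_len(n_controls) - 1) * (control_length + 5e5)
  controls <- tibble(
    assembly = "simH", chromosome = "chrS2",
    start = ctrl_starts, end = ctrl_starts + control_length,
    locus = sprintf("simcontrol_%02d", seq_len(n_controls))
  )
  loci_unique <- sum(interval_lengths(merge_intervals(human))$length)
  background <- tibble(
    assembly = "simH", chromosome = "chrS3",
    start = 1e6, end = 1e6 + background_multiple * loci_unique
  )
  territory <- tibble(
    group = c("loci", "control", "background"),
    bases = c(loci_unique, n_controls * control_length,
              background_multiple * loci_unique)
  )
  structure(
    list(
      loci = loci, controls = controls, background = background,
      territory = territory,
      config = list(
        n_loci = n_loci, overlap_fraction = overlap_fraction,
        n_overlapping_pairs = k, n_controls = n_controls,
        control_length = control_length,
        background_multiple = background_multiple, seed = seed
      )
    ),
    class = "sim_landscape"
  )
}

#' @export
print.sim_landscape <- function(x, ...) {
  cat(sprintf(
    "<sim_landscape> %d loci (%d overlapping pairs), %d controls, seed %s\n",
    x$config$n_loci, x$config$n_overlapping_pairs, x$config$n_controls,
    format(x$config$seed)
  ))
  print(x$territory)
  invisible(x)
}

draw_positions <- function(territory, n) {
  lens <- territory$end - territory$start
  idx <- sample.int(nrow(territory), n, replace = TRUE, prob = lens)
  offset <- floor(runif(n) * lens[idx]) + 1 # pos in (start, end], 1-based
  tibble(chromosome = territory$chromosome[idx],
         position = territory$start[idx] + offset)
}

#' Simulate a SNP catalog over a landscape
#'
#' Each SNP's territory (loci / control / background) is drawn with
#' probability proportional to territory bases times a density weight —
#' `enrichment` (rho) for loci territory, 1 elsewhere — and its position is
#' uniform within the territory. A fraction of SNPs is duplicated under a
#' second study label to emulate multi-study reporting; association class
#' is assigned independently of territory. Odds-ratio, confidence-interval
#' and p-value fields are placeholder draws.
#'
#' @param n_snps Number of unique SNPs.
#' @param landscape A [simulate_landscape()] result.
#' @param enrichment Density multiplier rho (>= 0) of loci territory
#'   relative to control/background; 1 is the null, 0 puts no SNP at loci.
#' @param frac_associated Fraction of SNPs labelled `associated`.
#' @param populations Named weight vector of population labels.
#' @param frac_multistudy Fraction of unique SNPs reported by a second
#'   study (duplicated records).
#' @param seed Integer seed.
#' @return List with `catalog` (SNP tibble as from [read_snp_catalog()])
#'   and `truth` (per-SNP territory labels, configured rho and realized
#'   per-territory counts).
#' @examples
#' ls <- simulate_landscape(n_loci = 6, seed = 2)
#' sim <- simulate_snp_catalog(200, ls, enrichment = 3.5, seed = 3)
#' sim$truth$realized
#' @export
simulate_snp_catalog <- function(n_snps, landscape,
                                 enrichment = 1,
                                 frac_associated = 0.12,
                                 populations = c(European = 1),
                                 frac_multistudy = 0.107,
                                 seed = 1) {
  if (n_snps < 1) abort("`n_snps` must be >= 1.")
  if (enrichment < 0) abort("`enrichment` must be >= 0.")
  if (frac_associated < 0 || frac_associated > 1 ||
      frac_multistudy < 0 || frac_multistudy > 1) {
    abort("Fractions must lie in [0, 1].")
  }
  set.seed(seed)
  terr <- list(
    loci = merge_intervals(locus_human_fragments(landscape$loci)),
    control = merge_intervals(landscape$controls),
    background = landscape$background
  )
  bases <- vapply(terr, function(t) sum(t$end - t$start), numeric(1))
  if (any(bases <= 0)) abort("Landscape territories must be non-empty.")
  w <- bases * c(enrichment, 1, 1)
  group <- sample(names(terr), n_snps, replace = TRUE, prob = w)
  pos <- tibble(chromosome = character(n_snps), position = numeric(n_snps))
  for (g in names(terr)) {
    sel <- group == g
    if (any(sel)) pos[sel, ] <- draw_positions(terr[[g]], sum(sel))
  }
  assoc <- ifelse(runif(n_snps) < frac_associated, "associated", "potential")
  catalog <- tibble(
    rsid = sprintf("rs%07d", seq_len(n_snps)),
    assembly = "simH",
    chromosome = pos$chromosome,
    position = pos$position,
    study = "sim_study_a",
    population = sample(names(populations), n_snps, replace = TRUE,
                        prob = populations),
    assoc_class = assoc,
    odds_ratio = round(rlnorm(n_snps, 0.1, 0.15), 2),
    ci_low = NA_real_, ci_high = NA_real_,
    p_value = 10^-runif(n_snps, ifelse(assoc == "associated", 8, 2),
                        ifelse(assoc == "associated", 12, 6))
  ) |>
    dplyr::mutate(ci_low = round(.data$odds_ratio * 0.9, 2),
                  ci_high = round(.data$odds_ratio * 1.1, 2))
  n_dup <- round(frac_multistudy * n_snps)
  if (n_dup > 0) {
    dup <- catalog[sample.int(n_snps, n_dup), ] |>
      dplyr::mutate(study = "sim_study_b",
                    p_value = .data$p_value * 10^runif(n_dup, -0.5, 0.5))
    catalog <- dplyr::bind_rows(catalog, dup)
  }
  realized <- as.list(table(factor(group, levels = names(terr))))
  list(
    catalog = catalog,
    truth = list(
      territory = tibble(rsid = sprintf("rs%07d", seq_len(n_snps)),
                         territory = group),
      rho = enrichment,
      realized = realized,
      n_multistudy = n_dup
    )
  )
}

#' Simulate ortholog fragments with prescribed base/span fractions
#'
#' Builds fragment fixtures for the retention rule: each entry of
#' `fragment_spec` is a pair `(base_fraction, span_fraction)` of the source
#' length; the realized fragment spans `round(span_fraction *
#' source_length)` bases and carries `round(base_fraction * source_length)`
#' aligned bases.
#'
#' @param source_length Source locus length in bases.
#' @param fragment_spec List of numeric pairs `c(base_fraction,
#'   span_fraction)` with `base_fraction <= span_fraction`.
#' @param seed Optional seed for the inter-fragment gap jitter.
#' @return Fragment tibble with `bases_mapped`, in spec order.
#' @examples
#' simulate_fragments(1e6, list(c(0.5, 0.5), c(0.009, 0.009)))
#' @export
simulate_fragments <- function(source_length, fragment_spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (source_length <= 0) abort("`source_length` must be > 0.")
  if (!length(fragment_spec)) {
    return(tibble(assembly = character(), chromosome = character(),
                  start = numeric(), end = numeric(), bases_mapped = numeric()))
  }
  spec <- do.call(rbind, lapply(fragment_spec, function(p) {
    if (length(p) != 2) abort("Each fragment spec must be c(base_fraction, span_fraction).")
    p
  }))
  if (any(spec < 0)) abort("Spec fractions must be >= 0.")
  if (any(spec[, 1] > spec[, 2])) {
    abort("`base_fraction` cannot exceed `span_fraction` within a fragment.")
  }
  if (sum(spec[, 1]) > 1) {
    abort("Base fractions sum to more than 1: more aligned bases than the source has.")
  }
  spans <- round(spec[, 2] * source_length)
  gaps <- round(runif(nrow(spec), 1e3, 1e4))
  starts <- cumsum(c(1e4, head(spans + gaps, -1)))
  tibble(
    assembly = "simH", chromosome = "chrF1",
    start = starts, end = starts + spans,
    bases_mapped = round(spec[, 1] * source_length)
  )
}
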