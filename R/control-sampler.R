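overlaps_any <- function(frags, regions) {
  if (is.null(regions) || !nrow(regions) || !nrow(frags)) return(FALSE)
  joined <- dplyr::inner_join(
    dplyr::select(frags, "chromosome", f_start = "start", f_end = "end"),
    dplyr::select(regions, "chromosome", r_start = "start", r_end = "end"),
    by = "chromosome", relationship = "many-to-many"
  )
  any(pmax(joined$f_start, joined$r_start) < pmin(joined$f_end, joined$r_end))
}

#' Exclusion territory for control sampling
#'
#' @param locus_orthologs Human interval tibble of locus-ortholog
#'   territory; a candidate whose resolved human fragments touch it is
#'   rejected.
#' @param centromeres Human interval tibble of centromeric regions
#'   (underrepresented in GWA genotyping); same rejection rule.
#' @return A list of class `exclusion_set`.
#' @export
exclusion_set <- function(locus_orthologs = NULL, centromeres = NULL) {
  for (x in list(locus_orthologs, centromeres)) {
    if (!is.null(x)) validate_intervals(x, "exclusion regions")
  }
  structure(list(locus_orthologs = locus_orthologs, centromeres = centromeres),
            class = "exclusion_set")
}

#' Draw one candidate control region
#'
#' One candidate per call: a chromosome index uniform on
#' `1..n_chromosomes` (drawn first), then a start uniform on
#' `1..start_max`, with `end = start + region_length` (half-open, so the
#' region covers exactly `region_length` bases). The genome model is the
#' idealised equal-length-chromosome genome, so candidates may overhang
#' real chromosome ends.
#'
#' @param genome A [genome_model()].
#' @param region_length Region length in bases.
#' @param start_max Upper bound for the random start (defaults to the
#'   genome's per-chromosome length hint).
#' @return One-row interval tibble. Consumes the R random stream.
#' @export
draw_candidate <- function(genome = rat_genome_model(),
                           region_length = 22322710,
                           start_max = genome$chromosome_length_hint) {
  chrom <- sample.int(genome$n_chromosomes, 1L)
  start <- sample.int(start_max, 1L)
  tibble(
    assembly = genome$assembly,
    chromosome = genome$chromosome_names[[chrom]],
    start = as.numeric(start),
    end = as.numeric(start) + region_length
  )
}

#' Check a candidate control region against the exclusion rules
#'
#' A candidate is a valid control when none of its resolved human ortholog
#' fragments overlaps known locus-ortholog territory and none falls in a
#' centromeric region. A candidate with no resolvable human orthology is
#' valid (nothing places it at an excluded human region).
#'
#' @param candidate One-row rat interval tibble.
#' @param exclusions An [exclusion_set()] (or `NULL` for none).
#' @param resolver `function(candidate) -> human fragment tibble`, e.g.
#'   from [make_table_resolver()]; `NULL` means no orthology is available
#'   and every candidate is valid.
#' @return One-row tibble with `valid` (logical) and `reason`
#'   (`NA`, `"locus_overlap"` or `"centromere"`). Errors raised by the
#'   resolver propagate and are distinct from an invalid verdict.
#' @export
is_valid_control <- function(candidate, exclusions = NULL, resolver = NULL) {
  validate_intervals(candidate, "candidate")
  frags <- if (is.null(resolver)) candidate[0, ] else resolver(candidate)
  reason <- NA_character_
  if (!is.null(exclusions) && nrow(frags)) {
    if (overlaps_any(frags, exclusions$locus_orthologs)) {
      reason <- "locus_overlap"
    } else if (overlaps_any(frags, exclusions$centromeres)) {
      reason <- "centromere"
    }
  }
  tibble(valid = is.na(reason), reason = reason)
}

#' Sample random control regions by rejection
#'
#' Reproduces the random-region null construction: candidates are drawn on
#' an idealised rat genome (21 equal chromosomes of 130,952,381 bp within
#' a 2.75 Gb genome) and rejected when their human orthologous sequence
#' overlaps known locus-ortholog territory or a centromere. Candidates are
#' drawn independently, so two controls may overlap each other unless
#' `allow_self_overlap = FALSE`. Setting `chromosome_lengths` (a named
#' vector of real lengths) additionally rejects candidates overhanging a
#' real chromosome end; this strict mode is off by default for fidelity to
#' the idealised procedure.
#'
#' @inheritParams draw_candidate
#' @inheritParams is_valid_control
#' @param n_regions Number of controls to accept (study value: 14).
#' @param region_length Length of every control (study value: 22,322,710).
#' @param seed Integer seed; the draw sequence (chromosome, then start,
#'   per candidate) is a single reproducible stream.
#' @param max_attempts Abort after this many candidate draws.
#' @param chromosome_lengths Optional named numeric vector for strict
#'   end-overhang rejection.
#' @param allow_self_overlap Permit mutual overlap among accepted controls.
#' @return An object of class `control_sample`: list with `regions` (an
#'   interval tibble with a `locus` label column), `log` (every candidate
#'   with `accepted` and `reason`), and the configuration.
#' @examples
#' cs <- sample_control_regions(n_regions = 3, seed = 7)
#' cs$regions
#' @export
sample_control_regions <- function(n_regions = 14,
                                   region_length = 22322710,
                                   genome = rat_genome_model(),
                                   exclusions = NULL,
                                   resolver = NULL,
                                   seed = 1,
                                   start_max = genome$chromosome_length_hint,
                                   max_attempts = 10000,
                                   chromosome_lengths = NULL,
                                   allow_self_overlap = TRUE) {
  if (n_regions < 1 || region_length < 1 || start_max < 1) {
    abort("`n_regions`, `region_length` and `start_max` must be >= 1.")
  }
  set.seed(seed)
  accepted <- vector("list", n_regions)
  log_rows <- list()
  n_ok <- 0L
  attempt <- 0L
  while (n_ok < n_regions) {
    if (attempt >= max_attempts) {
      abort(sprintf(
        "max_attempts (%d) exceeded with %d/%d controls accepted (acceptance rate %.3f).",
        max_attempts, n_ok, n_regions, n_ok / attempt
      ))
    }
    attempt <- attempt + 1L
    cand <- draw_candidate(genome, region_length, start_max)
    verdict <- is_valid_control(cand, exclusions, resolver)
    reason <- verdict$reason
    if (verdict$valid && !is.null(chromosome_lengths)) {
      lim <- chromosome_lengths[[cand$chromosome]]
      if (!is.null(lim) && !is.na(lim) && cand$end > lim) reason <- "chromosome_end"
    }
    if (is.na(reason) && !allow_self_overlap && n_ok > 0) {
      prior <- dplyr::bind_rows(accepted[seq_len(n_ok)])
      if (overlaps_any(cand, prior)) reason <- "self_overlap"
    }
    ok <- is.na(reason)
    log_rows[[attempt]] <- dplyr::mutate(cand, attempt = attempt,
                                         accepted = ok, reason = reason)
    if (ok) {
      n_ok <- n_ok + 1L
      accepted[[n_ok]] <- dplyr::mutate(cand, locus = paste0("control_", n_ok))
    }
  }
  structure(
    list(
      regions = dplyr::bind_rows(accepted),
      log = dplyr::bind_rows(log_rows),
      config = list(
        n_regions = n_regions, region_length = region_length,
        seed = seed, start_max = start_max, max_attempts = max_attempts,
        allow_self_overlap = allow_self_overlap, assembly = genome$assembly
      )
    ),
    class = "control_sample"
  )
}

#' @export
print.control_sample <- function(x, ...) {
  cat(sprintf(
    "<control_sample> %d regions of %s bp (seed %s); %d candidate draw(s), %d rejected\n",
    nrow(x$regions),
    format(x$config$region_length, big.mark = ","),
    format(x$config$seed), nrow(x$log), sum(!x$log$accepted)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.control_sample <- function(x, ...) x$regions
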