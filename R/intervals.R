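#' Build a table of genomic intervals
#'
#' Intervals are plain tibbles with columns `assembly`, `chromosome`,
#' `start` and `end`. Coordinates are kept on the printed scale of the
#' source tables and interpreted as half-open: an interval covers
#' `end - start` bases and two intervals sharing a boundary are adjacent,
#' not overlapping. A zero-length interval (`start == end`) is permitted
#' and covers no bases.
#'
#' @param chromosome Character vector of chromosome labels.
#' @param start,end Numeric coordinates, `end >= start`, half-open.
#' @param assembly Assembly label shared by all intervals (recycled).
#' @return A tibble with columns `assembly`, `chromosome`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chromosome, start, end, assembly = "GRCh37") {
  x <- tibble(
    assembly = as.character(assembly),
    chromosome = as.character(chromosome),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the interval contract: required columns present, a single
#' assembly, non-empty chromosome labels, and `end >= start` everywhere.
#'
#' @param x Interval tibble.
#' @param arg Name used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, arg = "intervals") {
  req <- c("chromosome", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    abort(sprintf("`%s` lacks column(s): %s.", arg, toString(missing_cols)))
  }
  if (!"assembly" %in% names(x)) {
    abort(sprintf("`%s` lacks an `assembly` column.", arg))
  }
  if (nrow(x)) {
    if (length(unique(x$assembly)) > 1) {
      abort(sprintf("`%s` mixes assemblies: %s.", arg, toString(unique(x$assembly))))
    }
    if (any(is.na(x$chromosome) | x$chromosome == "")) {
      abort(sprintf("`%s` has empty chromosome labels.", arg))
    }
    bad <- which(x$end < x$start)
    if (length(bad)) {
      abort(sprintf("`%s` has end < start at row(s) %s.", arg, toString(head(bad, 5))))
    }
  }
  invisible(x)
}

#' Interval lengths under the half-open convention
#'
#' @param x Interval tibble.
#' @return `x` with an added `length` column equal to `end - start`.
#' @examples
#' interval_lengths(genomic_intervals("RNO7", 22382725, 55384873, "rn4"))
#' @export
interval_lengths <- function(x) {
  validate_intervals(x)
  dplyr::mutate(x, length = .data$end - .data$start)
}

#' Intersect two genomic intervals
#'
#' @param a,b One-row interval tibbles on the same assembly.
#' @return A tibble with one row (the overlap) or zero rows when the
#'   intervals are on different chromosomes or do not overlap. Touching
#'   half-open intervals (`end_a == start_b`) do not overlap.
#' @examples
#' mcs2 <- genomic_intervals("RNO7", 4936704, 86028057, "rn4")
#' mcs6 <- genomic_intervals("RNO7", 22382725, 55384873, "rn4")
#' intersect_intervals(mcs2, mcs6)
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a, "a")
  validate_intervals(b, "b")
  if (nrow(a) != 1 || nrow(b) != 1) {
    abort("`intersect_intervals()` expects one-row interval tables.")
  }
  if (!identical(a$assembly, b$assembly)) {
    abort(sprintf(
      "Assembly mismatch: '%s' vs '%s'; intervals are not comparable.",
      a$assembly, b$assembly
    ))
  }
  empty <- a[0, c("assembly", "chromosome", "start", "end")]
  if (a$chromosome != b$chromosome) return(empty)
  lo <- max(a$start, b$start)
  hi <- min(a$end, b$end)
  if (lo >= hi) return(empty)
  tibble(assembly = a$assembly, chromosome = a$chromosome, start = lo, end = hi)
}

## Half-open [start, end) on the printed scale <-> 1-based closed IRanges.
## Zero-length intervals carry no bases and are dropped before conversion.
as_iranges_by_chrom <- function(x) {
  x <- dplyr::filter(x, .data$end > .data$start)
  split(
    IRanges::IRanges(start = as.integer(x$start + 1), end = as.integer(x$end)),
    x$chromosome
  )
}

#' Merge an interval set into its union
#'
#' Per chromosome, overlapping intervals and intervals adjacent at a shared
#' half-open boundary are merged; the result is sorted and pairwise
#' disjoint and covers exactly the same bases as the input. Zero-length
#' intervals are dropped.
#'
#' @param x Interval tibble.
#' @return A merged interval tibble sorted by chromosome and start.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0, 50), c(60, 100)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  x <- dplyr::filter(x, .data$end > .data$start)
  if (!nrow(x)) {
    return(x[, c("assembly", "chromosome", "start", "end")])
  }
  asm <- x$assembly[[1]]
  by_chrom <- as_iranges_by_chrom(x)
  merged <- purrr::map(by_chrom, IRanges::reduce, min.gapwidth = 1L)
  out <- purrr::imap_dfr(merged, function(ir, chrom) {
    tibble(
      assembly = asm,
      chromosome = chrom,
      start = as.numeric(IRanges::start(ir)) - 1,
      end = as.numeric(IRanges::end(ir))
    )
  })
  dplyr::arrange(out, .data$chromosome, .data$start)
}

#' Coverage accounting for a region set
#'
#' Computes the locus-count, total bases (interval lengths summed with
#' multiplicity), unique bases (size of the per-chromosome union),
#' overlapping bases (total minus unique) and the percentage of the genome
#' covered, for one set of regions.
#'
#' @param x Interval tibble (one region per row; regions may overlap).
#' @param genome A [genome_model()] supplying `total_genome_size`.
#' @param name Optional label for the region set.
#' @return One-row tibble with columns `name`, `n_loci`, `total_bases`,
#'   `overlapping_bases`, `unique_bases`, `genome_fraction` (percent,
#'   rounded to one decimal).
#' @examples
#' regions <- genomic_intervals("chr1", c(0, 50), c(100, 150))
#' coverage_summary(regions, genome_model(), name = "demo")
#' @export
coverage_summary <- function(x, genome = rat_genome_model(), name = NA_character_) {
  validate_intervals(x)
  if (!nrow(x)) {
    return(tibble(
      name = name, n_loci = 0L, total_bases = 0, overlapping_bases = 0,
      unique_bases = 0, genome_fraction = 0
    ))
  }
  total <- sum(x$end - x$start)
  merged <- merge_intervals(x)
  unique_bases <- sum(merged$end - merged$start)
  tibble(
    name = name,
    n_loci = nrow(x),
    total_bases = total,
    overlapping_bases = total - unique_bases,
    unique_bases = unique_bases,
    genome_fraction = genome_fraction(unique_bases, genome)
  )
}

#' Percentage of the genome covered by a number of unique bases
#'
#' @param unique_bases Non-negative base count.
#' @param genome A [genome_model()].
#' @return `100 * unique_bases / total_genome_size`, rounded to one
#'   decimal, matching the precision coverage tables are reported at.
#' @examples
#' genome_fraction(905100793, genome_model())
#' @export
genome_fraction <- function(unique_bases, genome = rat_genome_model()) {
  if (genome$total_genome_size <= 0) abort("Genome size must be > 0.")
  if (any(unique_bases < 0)) abort("`unique_bases` must be >= 0.")
  round(100 * unique_bases / genome$total_genome_size, 1)
}
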