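#' Genome model used for coverage fractions and control sampling
#'
#' A light container for the assembly-level constants the analysis needs:
#' how many chromosomes the genome has, the nominal per-chromosome length
#' used when drawing random regions, and the total genome size used as the
#' denominator of coverage fractions.
#'
#' The defaults describe the rat genome as a deliberately simplified model:
#' 2.75 Gb split evenly across 21 chromosomes (including the sex
#' chromosome), i.e. 130,952,381 bp per chromosome. Random control regions
#' are drawn on this idealised genome, so candidate regions may overhang
#' real chromosome ends; see [sample_control_regions()].
#'
#' @param assembly Assembly label, e.g. `"rn4"`.
#' @param n_chromosomes Number of chromosomes available to the sampler.
#' @param chromosome_length_hint Nominal bases per chromosome used as the
#'   upper bound for random start positions.
#' @param total_genome_size Total genome size in bases; denominator of
#'   [genome_fraction()].
#' @param chromosome_names Optional character vector of chromosome labels
#'   (length `n_chromosomes`). Defaults to `RNO1..RNO20, RNOX` for the rat
#'   model and `<assembly>_chr<i>` otherwise.
#'
#' @return An object of class `genome_model`: a list with fields
#'   `assembly`, `n_chromosomes`, `chromosome_length_hint`,
#'   `total_genome_size` and `chromosome_names`.
#' @examples
#' gm <- genome_model()
#' gm$total_genome_size
#' @export
genome_model <- function(assembly = "rn4",
                         n_chromosomes = 21L,
                         chromosome_length_hint = 130952381,
                         total_genome_size = 2.75e9,
                         chromosome_names = NULL) {
  if (total_genome_size <= 0) abort("`total_genome_size` must be > 0.")
  if (n_chromosomes < 1) abort("`n_chromosomes` must be >= 1.")
  if (chromosome_length_hint <= 0) abort("`chromosome_length_hint` must be > 0.")
  if (is.null(chromosome_names)) {
    chromosome_names <- if (identical(assembly, "rn4") && n_chromosomes == 21L) {
      c(paste0("RNO", 1:20), "RNOX")
    } else {
      paste0(assembly, "_chr", seq_len(n_chromosomes))
    }
  }
  if (length(chromosome_names) != n_chromosomes) {
    abort("`chromosome_names` must have length `n_chromosomes`.")
  }
  structure(
    list(
      assembly = assembly,
      n_chromosomes = as.integer(n_chromosomes),
      chromosome_length_hint = chromosome_length_hint,
      total_genome_size = total_genome_size,
      chromosome_names = chromosome_names
    ),
    class = "genome_model"
  )
}

#' @rdname genome_model
#' @export
rat_genome_model <- function() genome_model()

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %s: %d chromosomes, %s bp total (%s bp/chromosome hint)\n",
    x$assembly, x$n_chromosomes,
    format(x$total_genome_size, big.mark = ",", scientific = FALSE),
    format(x$chromosome_length_hint, big.mark = ",", scientific = FALSE)
  ))
  invisible(x)
}
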