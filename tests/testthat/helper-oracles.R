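# Brute-force per-base oracles for the interval algebra, and small fixture
# builders shared across test files. The oracles enumerate every integer
# base b with start <= b < end (half-open), so they are exact but only
# usable on small coordinates.

oracle_base_set <- function(x) {
  if (!nrow(x)) return(character())
  unlist(purrr::pmap(
    list(x$chromosome, x$start, x$end),
    function(chrom, s, e) if (e > s) paste(chrom, seq(s, e - 1)) else character()
  ))
}

oracle_unique_bases <- function(x) length(unique(oracle_base_set(x)))

oracle_total_bases <- function(x) length(oracle_base_set(x))

oracle_intersect_bases <- function(a, b) {
  intersect(unique(oracle_base_set(a)), unique(oracle_base_set(b)))
}

random_interval_set <- function(n, n_chroms = 3, max_coord = 1e4,
                                max_len = 1e4, assembly = "testasm") {
  chrom <- paste0("chr", sample.int(n_chroms, n, replace = TRUE))
  start <- sample.int(max_coord, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(chrom, start, start + len, assembly = assembly)
}

# minimal SNP catalog with the read_snp_catalog() column contract
make_snps <- function(chromosome, position, rsid = NULL, study = "s1",
                      population = "European", assoc_class = "potential",
                      p_value = NA_real_, assembly = "GRCh37") {
  n <- length(position)
  tibble::tibble(
    rsid = rsid %||% sprintf("rs%d", seq_len(n)),
    assembly = assembly,
    chromosome = rep_len(chromosome, n),
    position = position,
    study = rep_len(study, n),
    population = rep_len(population, n),
    assoc_class = rep_len(assoc_class, n),
    odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = rep_len(p_value, n)
  )
}

`%||%` <- rlang::`%||%`

# two-locus toy landscape: loc_a (DMBA) overlaps loc_b (estradiol) on the
# human side; control territory on its own chromosome
toy_loci <- function() {
  tibble::tribble(
    ~locus, ~role, ~assembly, ~chromosome, ~start, ~end, ~carcinogen, ~overlap_group,
    "loc_a", "rat_source", "rn4", "RNO1", 1000, 2000, "DMBA", "loc_b",
    "loc_a", "human_ortholog", "GRCh37", "chr1", 100, 300, "DMBA", "loc_b",
    "loc_b", "rat_source", "rn4", "RNO1", 1500, 2500, "estradiol", "loc_a",
    "loc_b", "human_ortholog", "GRCh37", "chr1", 200, 400, "estradiol", "loc_a",
    "loc_c", "rat_source", "rn4", "RNO2", 5000, 6000, "DMBA", NA,
    "loc_c", "human_ortholog", "GRCh37", "chr2", 1000, 1200, "DMBA", NA
  )
}

toy_controls <- function() {
  genomic_intervals("chr3", c(100, 1000), c(500, 1400), assembly = "GRCh37")
}
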