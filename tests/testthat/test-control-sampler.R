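test_that("candidate draws are seeded, in range, and of exact length", {
  gm <- rat_genome_model()
  set.seed(99)
  a <- draw_candidate(gm)
  set.seed(99)
  b <- draw_candidate(gm)
  expect_equal(a, b)

  set.seed(5)
  for (i in 1:200) {
    cand <- draw_candidate(gm)
    expect_true(cand$chromosome %in% gm$chromosome_names)
    expect_gte(cand$start, 1)
    expect_lte(cand$start, gm$chromosome_length_hint)
    expect_equal(cand$end - cand$start, 22322710)
  }
})

test_that("chromosome choice is uniform across the 21 chromosomes", {
  gm <- rat_genome_model()
  set.seed(2024)
  chroms <- character(5000)
  for (i in seq_along(chroms)) chroms[i] <- draw_candidate(gm)$chromosome
  counts <- table(factor(chroms, levels = gm$chromosome_names))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("validity checking distinguishes locus overlap, centromere, and valid", {
  loci <- rat_mammary_loci()
  resolver <- make_table_resolver(loci)
  excl <- exclusion_set(
    locus_orthologs = genomic_intervals("chr15", 80282370, 102265870),
    centromeres = genomic_intervals("chr15", 38000000, 40000000)
  )
  # candidate inside the Mcs3 rat span resolves to the excluded chr15 ortholog
  inside_mcs3 <- genomic_intervals("RNO1", 95000000, 96000000, assembly = "rn4")
  v <- is_valid_control(inside_mcs3, excl, resolver)
  expect_false(v$valid)
  expect_equal(v$reason, "locus_overlap")

  # candidate with no registered orthology is valid
  nowhere <- genomic_intervals("RNO12", 1, 1000, assembly = "rn4")
  expect_true(is_valid_control(nowhere, excl, resolver)$valid)

  # constructed centromere hit
  cen_loci <- tibble::tribble(
    ~locus, ~role, ~assembly, ~chromosome, ~start, ~end, ~carcinogen, ~overlap_group,
    "cen", "rat_source", "rn4", "RNO1", 100, 200, "none", NA,
    "cen", "human_ortholog", "GRCh37", "chr15", 38500000, 39000000, "none", NA
  )
  v2 <- is_valid_control(genomic_intervals("RNO1", 120, 180, assembly = "rn4"),
                         excl, make_table_resolver(cen_loci))
  expect_false(v2$valid)
  expect_equal(v2$reason, "centromere")
})

test_that("sampling with empty exclusions accepts every candidate", {
  cs <- sample_control_regions(n_regions = 14, seed = 3)
  expect_equal(nrow(cs$regions), 14)
  expect_equal(sum(cs$regions$end - cs$regions$start), 312517940)
  expect_true(all(cs$log$accepted))
  expect_equal(nrow(cs$log), 14)
})

test_that("sampling is byte-reproducible given the seed", {
  a <- sample_control_regions(n_regions = 5, seed = 77)
  b <- sample_control_regions(n_regions = 5, seed = 77)
  expect_identical(readr::format_tsv(a$regions), readr::format_tsv(b$regions))
  expect_identical(readr::format_tsv(a$log), readr::format_tsv(b$log))
})

test_that("accepted regions re-validate and rejections are logged with reasons", {
  # resolver mapping the candidate to an identity human fragment
  identity_resolver <- function(cand) {
    genomic_intervals(cand$chromosome, cand$start, cand$end, assembly = "GRCh37h")
  }
  excl <- exclusion_set(
    locus_orthologs = genomic_intervals(
      paste0("RNO", 1:10), rep(1, 10), rep(130952381, 10), assembly = "GRCh37h"
    )
  )
  cs <- sample_control_regions(
    n_regions = 6, seed = 42, exclusions = excl, resolver = identity_resolver
  )
  expect_equal(nrow(cs$regions), 6)
  for (i in seq_len(nrow(cs$regions))) {
    expect_true(is_valid_control(cs$regions[i, ], excl, identity_resolver)$valid)
  }
  rejected <- dplyr::filter(cs$log, !accepted)
  expect_gt(nrow(rejected), 0)
  expect_true(all(rejected$reason == "locus_overlap"))
  # roughly half the idealised chromosomes are excluded wholesale
  expect_equal(sum(cs$log$accepted), 6)
})

test_that("rejection rate approaches the excluded territory fraction", {
  f <- 0.3
  gm <- rat_genome_model()
  point_resolver <- function(cand) {
    genomic_intervals("h1", cand$start, cand$start + 1, assembly = "GRCh37h")
  }
  excl <- exclusion_set(locus_orthologs = genomic_intervals(
    "h1", 0, f * gm$chromosome_length_hint, assembly = "GRCh37h"
  ))
  set.seed(8)
  n <- 2000
  rejected <- 0L
  for (i in seq_len(n)) {
    cand <- draw_candidate(gm)
    if (!is_valid_control(cand, excl, point_resolver)$valid) rejected <- rejected + 1L
  }
  rate <- rejected / n
  expect_lt(abs(rate - f), 3 * sqrt(f * (1 - f) / n))
})

test_that("strict mode rejects candidates overhanging real chromosome ends", {
  lens <- setNames(rep(60e6, 21), rat_genome_model()$chromosome_names)
  cs <- sample_control_regions(
    n_regions = 3, region_length = 22322710, seed = 12,
    chromosome_lengths = lens, max_attempts = 2000
  )
  expect_true(all(cs$regions$end <= 60e6))
  expect_true(any(cs$log$reason == "chromosome_end", na.rm = TRUE))
})

test_that("exhausting max_attempts reports the acceptance rate", {
  always_hit <- function(cand) genomic_intervals("h1", 0, 10, assembly = "x")
  excl <- exclusion_set(locus_orthologs = genomic_intervals("h1", 0, 100, assembly = "x"))
  expect_error(
    sample_control_regions(n_regions = 1, seed = 1, exclusions = excl,
                           resolver = always_hit, max_attempts = 25),
    "max_attempts"
  )
})
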