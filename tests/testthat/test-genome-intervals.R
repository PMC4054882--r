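test_that("interval length follows the half-open end - start convention", {
  mcs6 <- genomic_intervals("RNO7", 22382725, 55384873, assembly = "rn4")
  expect_equal(interval_lengths(mcs6)$length, 33002148)
  expect_equal(interval_lengths(genomic_intervals("chr1", 100, 100))$length, 0)
  expect_equal(
    interval_lengths(genomic_intervals("chr5", 89216702, 93113337))$length,
    3896635
  )
  expect_error(genomic_intervals("chr1", 200, 100), "end < start")
})

test_that("intersection handles containment, disjoint chromosomes and assemblies", {
  mcs2 <- genomic_intervals("RNO7", 4936704, 86028057, assembly = "rn4")
  mcs6 <- genomic_intervals("RNO7", 22382725, 55384873, assembly = "rn4")
  hit <- intersect_intervals(mcs2, mcs6)
  expect_equal(hit$start, 22382725)
  expect_equal(hit$end, 55384873)

  expect_equal(nrow(intersect_intervals(
    genomic_intervals("chr1", 0, 10), genomic_intervals("chr2", 0, 10)
  )), 0)
  # touching half-open intervals share no base
  expect_equal(nrow(intersect_intervals(
    genomic_intervals("chr1", 0, 10), genomic_intervals("chr1", 10, 20)
  )), 0)
  expect_error(
    intersect_intervals(
      genomic_intervals("chr1", 0, 10, assembly = "GRCh37"),
      genomic_intervals("chr1", 0, 10, assembly = "rn4")
    ),
    "Assembly mismatch"
  )
})

test_that("intersection of random pairs equals the per-base membership oracle", {
  set.seed(42)
  for (i in 1:40) {
    a <- random_interval_set(1)
    b <- random_interval_set(1)
    got <- intersect_intervals(a, b)
    want <- oracle_intersect_bases(a, b)
    if (nrow(got)) {
      expect_setequal(oracle_base_set(got), want)
    } else {
      expect_length(want, 0)
    }
  }
})

test_that("merge produces sorted disjoint intervals covering the same bases", {
  set.seed(7)
  for (i in 1:25) {
    x <- random_interval_set(sample.int(20, 1))
    m <- merge_intervals(x)
    # same base content as input, exactly
    expect_setequal(oracle_base_set(m), unique(oracle_base_set(x)))
    # pairwise disjoint and sorted within chromosome, no touching neighbours
    by_chrom <- split(m, m$chromosome)
    for (g in by_chrom) {
      if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    }
    # idempotent
    expect_equal(merge_intervals(m), m)
    # order-invariant
    perm <- x[sample.int(nrow(x)), ]
    expect_equal(merge_intervals(perm), m)
  }
})

test_that("adjacent intervals at a shared half-open boundary merge", {
  m <- merge_intervals(genomic_intervals("chr1", c(0, 10), c(10, 20)))
  expect_equal(nrow(m), 1)
  expect_equal(m$end - m$start, 20)
})

test_that("coverage summary satisfies the total = unique + overlapping identity", {
  two <- genomic_intervals("chr1", c(0, 500), c(100, 600))
  cs <- coverage_summary(two, genome_model())
  expect_equal(cs$total_bases, 200)
  expect_equal(cs$overlapping_bases, 0)
  expect_equal(cs$unique_bases, 200)

  set.seed(11)
  for (i in 1:20) {
    x <- random_interval_set(sample.int(15, 1))
    cs <- coverage_summary(x, genome_model())
    expect_equal(cs$total_bases, cs$unique_bases + cs$overlapping_bases)
    expect_equal(cs$unique_bases, oracle_unique_bases(x))
    expect_equal(cs$total_bases, oracle_total_bases(x))
    # coverage of the merged set: no overlap, same union
    csm <- coverage_summary(merge_intervals(x), genome_model())
    expect_equal(csm$overlapping_bases, 0)
    expect_equal(csm$unique_bases, cs$unique_bases)
  }
})

test_that("an empty region set yields an all-zero summary, not an error", {
  empty <- genomic_intervals(character(), numeric(), numeric())
  cs <- coverage_summary(empty, genome_model())
  expect_equal(cs$total_bases, 0)
  expect_equal(cs$genome_fraction, 0)
  expect_equal(cs$n_loci, 0L)
})

test_that("genome fraction is a one-decimal percentage of total genome size", {
  gm <- genome_model()
  expect_equal(genome_fraction(905100793, gm), 32.9)
  expect_equal(genome_fraction(312321457, gm), 11.4)
  expect_equal(genome_fraction(0, gm), 0)
  broken <- genome_model()
  broken$total_genome_size <- 0
  expect_error(genome_fraction(1, broken), "Genome size")
})

test_that("locus TSV parsing strips separators and aggregates fragments per locus", {
  loci <- rat_mammary_loci()
  mcs1c <- dplyr::filter(loci, locus == "Mcs1c")
  rat <- dplyr::filter(mcs1c, role == "rat_source")
  expect_equal(nrow(rat), 1)
  expect_equal(rat$chromosome, "RNO2")
  expect_equal(rat$start, 13909383)
  expect_equal(rat$end, 20666092)
  expect_equal(sum(mcs1c$role == "human_ortholog"), 2)
  expect_equal(length(unique(loci$locus)), 24)
})

test_that("malformed locus rows fail with the offending line number", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(
    "locus_name\tspecies\tchromosome\tstart\tend\trole\tcarcinogen\toverlap_group",
    "l1\trat\tRNO1\t100\t200\trat_source\tDMBA\t",
    "l2\trat\tRNO1\t300\t250\trat_source\tDMBA\t"
  ), bad)
  expect_error(read_locus_table(bad), "line 3")

  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "locus_name\tspecies\tchromosome\tstart\tend\trole\tcarcinogen\toverlap_group",
    "l1\trat\tRNO1\toops\t200\trat_source\tDMBA\t"
  ), bad2)
  expect_error(read_locus_table(bad2), "line 2")
})

test_that("BED3 round-trips without any coordinate shift", {
  x <- genomic_intervals(c("chr1", "chr2"), c(100, 5000), c(200, 6000))
  f <- tempfile(fileext = ".bed")
  write_bed3(x, f)
  y <- read_bed3(f)
  expect_equal(y, x)
  expect_equal(readLines(f)[1], "chr1\t100\t200")
})

test_that("liftover-BED fragments are tagged with their source locus", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300\tlocA", "chr2\t50\t80\tlocA", "chr1\t900\t950\tlocB"), f)
  frags <- read_liftover_bed(f)
  expect_equal(nrow(frags), 3)
  expect_equal(frags$locus, c("locA", "locA", "locB"))
  expect_equal(frags$bases_mapped, c(200, 30, 50))
})
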