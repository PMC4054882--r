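test_that("deduplication keys on rsid, counts multi-study SNPs, keeps min p", {
  cat1 <- make_snps("chr1", c(100, 100, 500),
                    rsid = c("rs1", "rs1", "rs2"),
                    study = c("a", "b", "a"),
                    p_value = c(1e-4, 1e-6, 1e-3))
  u <- dedup_snp_catalog(cat1)
  expect_equal(nrow(u), 2)
  expect_equal(attr(u, "n_multistudy"), 1)
  rs1 <- dplyr::filter(u, rsid == "rs1")
  expect_equal(rs1$p_value, 1e-6)
  expect_equal(rs1$studies, "a,b")
  expect_equal(rs1$n_studies, 2)
})

test_that("dedup counts follow the keys: 3 doubled + 4 singleton = 7 unique", {
  keys <- c("rs1", "rs1", "rs2", "rs2", "rs3", "rs3", "rs4", "rs5", "rs6", "rs7")
  cat1 <- make_snps("chr1", seq_along(keys) * 10, rsid = keys,
                    study = rep(c("a", "b"), 5))
  cat1$position <- as.numeric(factor(keys)) * 100 # one position per key
  u <- dedup_snp_catalog(cat1)
  expect_equal(nrow(u), 7)
  expect_equal(attr(u, "n_multistudy"), 3)
})

test_that("records without rsid fall back to the position key", {
  cat1 <- make_snps("chr2", c(700, 700), rsid = c(NA, NA),
                    study = c("a", "b"))
  u <- dedup_snp_catalog(cat1)
  expect_equal(nrow(u), 1)
  expect_equal(attr(u, "n_multistudy"), 1)
})

test_that("conflicting positions for one rsid raise an error naming it", {
  cat1 <- make_snps("chr1", c(100, 200), rsid = c("rs9", "rs9"),
                    study = c("a", "b"))
  expect_error(dedup_snp_catalog(cat1), "rs9")
})

test_that("dedup output is independent of record order", {
  set.seed(31)
  cat1 <- make_snps("chr1", rep(c(100, 200, 300), 2),
                    rsid = rep(c("rs1", "rs2", "rs3"), 2),
                    study = rep(c("a", "b"), each = 3),
                    p_value = runif(6))
  u1 <- dedup_snp_catalog(cat1)
  u2 <- dedup_snp_catalog(cat1[sample.int(6), ])
  expect_equal(as.data.frame(u1), as.data.frame(u2))
})

test_that("assignment places SNPs at loci, control or neither with BED containment", {
  loci <- rat_mammary_loci()
  controls <- locus_human_fragments(random_rat_regions()) |>
    dplyr::select(assembly, chromosome, start, end)
  snps <- make_snps(
    c("chr9", "chr22", "chr2"),
    c(37580000, 1000, 100000000), # Mcs5a1 fragment / nowhere / random_1 fragment
    rsid = c("rsA", "rsB", "rsC")
  )
  asg <- assign_snps(snps, loci, controls)
  a <- dplyr::filter(asg, rsid == "rsA")
  expect_equal(a$region_group, "loci")
  expect_match(a$hit_loci, "Mcs5a1")
  expect_equal(dplyr::filter(asg, rsid == "rsB")$region_group, "neither")
  expect_equal(dplyr::filter(asg, rsid == "rsC")$region_group, "control")
})

test_that("a SNP in overlapping loci counts once but records every hit locus", {
  loci <- toy_loci()
  snps <- make_snps("chr1", 250, rsid = "rsX", assembly = "GRCh37")
  asg <- assign_snps(snps, loci, toy_controls())
  expect_equal(nrow(asg), 1)
  expect_equal(asg$region_group, "loci")
  expect_equal(asg$n_hit_loci, 2L)
  expect_equal(asg$hit_loci, "loc_a,loc_b")
  # duplicating a locus record never changes the per-SNP contribution
  dup <- dplyr::bind_rows(loci, dplyr::filter(loci, locus == "loc_a"))
  tal1 <- tally_assignments(asg, loci)
  tal2 <- tally_assignments(assign_snps(snps, dup, toy_controls()), dup)
  expect_equal(tal1$by_population, tal2$by_population)
})

test_that("containment converts the 1-based position into the half-open frame", {
  loci <- toy_loci() # loc_c human fragment chr2:[1000, 1200)
  ctrl <- toy_controls()
  pos_in <- function(p) {
    asg <- assign_snps(make_snps("chr2", p, rsid = "rs1"), loci, ctrl)
    asg$region_group == "loci"
  }
  expect_false(pos_in(1000)) # pos - 1 = 999 < start
  expect_true(pos_in(1001)) # first covered base
  expect_true(pos_in(1200)) # pos - 1 = 1199, last covered base
  expect_false(pos_in(1201)) # pos - 1 = 1200 = end: outside
})

test_that("loci/control territory overlap is rejected as a configuration error", {
  loci <- toy_loci()
  bad_controls <- genomic_intervals("chr1", 150, 600, assembly = "GRCh37")
  expect_error(
    assign_snps(make_snps("chr1", 1, rsid = "rs1"), loci, bad_controls),
    "Configuration error"
  )
})

test_that("assignment conserves counts and ignores input order", {
  set.seed(17)
  loci <- toy_loci()
  ctrl <- toy_controls()
  snps <- make_snps(
    sample(c("chr1", "chr2", "chr3"), 60, replace = TRUE),
    sample.int(2000, 60),
    population = sample(c("European", "Asian"), 60, replace = TRUE)
  )
  asg <- assign_snps(snps, loci, ctrl)
  tal <- tally_assignments(asg, loci)
  # conservation per population
  per_pop <- tal$by_population |>
    dplyr::summarise(n = sum(n), .by = population)
  expect_equal(
    dplyr::arrange(per_pop, population)$n,
    as.vector(table(snps$population))
  )
  expect_equal(tal$n_unique_snps, 60)
  # row-order invariance (compare sorted)
  asg2 <- assign_snps(snps[sample.int(60), ], loci[sample.int(nrow(loci)), ], ctrl)
  key <- function(d) dplyr::arrange(d, rsid)[, c("rsid", "region_group", "hit_loci")]
  expect_equal(key(asg2), key(asg))
})

test_that("carcinogen tallies double-count SNPs at mixed overlapping loci", {
  loci <- toy_loci()
  ctrl <- toy_controls()
  snps <- make_snps("chr1", c(250, 150), rsid = c("rsBoth", "rsA_only"))
  tal <- tally_assignments(assign_snps(snps, loci, ctrl), loci)
  by_carc <- setNames(tal$by_carcinogen$n, tal$by_carcinogen$carcinogen)
  # rsBoth hits DMBA loc_a + estradiol loc_b; rsA_only hits only loc_a
  expect_equal(by_carc[["DMBA"]], 2L)
  expect_equal(by_carc[["estradiol"]], 1L)
  # loci-group population count still counts each SNP once
  loci_n <- tal$by_population |>
    dplyr::filter(region_group == "loci") |>
    dplyr::summarise(n = sum(n))
  expect_equal(loci_n$n, 2L)
})

test_that("an empty assignment list yields an all-zero tally", {
  loci <- toy_loci()
  asg <- assign_snps(make_snps(character(), numeric())[0, ], loci, toy_controls())
  tal <- tally_assignments(asg, loci)
  expect_equal(tal$n_unique_snps, 0)
  expect_equal(sum(tal$by_population$n), 0)
  expect_equal(nrow(tal$by_carcinogen), 0)
})
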