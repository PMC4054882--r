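---
title: "Cross-species SNP enrichment: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species SNP enrichment: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoenrich)
library(dplyr)
```

# The analysis in one paragraph

Human GWA studies of breast cancer nominate two classes of SNPs:
*associated* (genome-wide significant, p ≲ 1e-7) and *potentially
associated* (carried into the final validation stage but failing the
study's threshold). Rat genetics independently maps mammary carcinoma
susceptibility loci (*Mcs*, *Mcsm*, *Mcstm*, *Mcsta*, *Emca*). The
analysis asks whether unique GWA-nominated SNPs fall inside the human
orthologs of the rat loci more often than inside the human orthologs of
random rat regions of matched construction, using the count at control
orthologs as the expectation of a 1-df chi-square, a 2×2 logistic
regression for the effect of the significance threshold, and
territory-size-normalised count ratios.

# Coordinate convention

All coordinates are kept on the printed scale of the source locus tables
and interpreted as **half-open**: an interval covers `end − start` bases,
and intervals sharing a boundary are adjacent, not overlapping. This
convention is forced by the tables themselves: the overlapping-base count
of the compact locus set equals `end − start` of the nested `Mcs6` locus
exactly, while an inclusive (+1 per interval) reading would miss by the
number of intervals involved. Consequences:

- BED import/export applies **no coordinate shift** (the coordinates are
  documented as BED-like already).
- A 1-based SNP position `pos` (dbSNP convention) is converted to the
  half-open frame by `pos − 1`; a fragment `[start, end)` contains the
  SNP when `start ≤ pos − 1 < end`. This is the standard BED containment
  rule; it places a SNP printed exactly at `start` outside and one at
  `end` inside, a one-base edge that affects no reported quantity.
- Thousands separators and embedded whitespace in printed coordinates are
  stripped on parse.

Interval merging (the "unique bases" union) is delegated to
`IRanges::reduce()` after converting half-open spans to 1-based closed
ranges; zero-length intervals carry no bases and are dropped first.
Adjacent intervals merge, consistent with half-open adjacency.

# Coverage accounting

For a region set: `total_bases` sums interval lengths with multiplicity,
`unique_bases` is the size of the per-chromosome union,
`overlapping_bases = total − unique`, and `genome_fraction = 100 ×
unique / G` rounded to one decimal, with `G = 2.75e9` for the rat genome.
Recomputing the published table from the printed locus coordinates
reproduces both unions exactly (905,100,793 unique bases for all 24 loci;
33,002,148 overlapping bases for the 14 compact loci) while the summed
totals differ from the printed totals by ~100 and ~54,100 bases
(0.00003% and 0.004%). The printed totals cannot be derived from the
printed coordinates; this package reports the recomputed values.

```{r coverage}
rat <- locus_rat_intervals(rat_mammary_loci())
coverage_summary(rat, name = "all_loci")
```

# Ortholog fragments and the 1% retention rule

Assembly conversion splits a large rat locus into many human fragments.
The retention rule keeps a fragment unless **both** its aligned bases and
its span fall strictly below 1% of the source locus length
(`filter_fragments()`). Two readings of the rule are possible: applied
per fragment, or cumulatively ("record fragments until they reach less
than 1%"). The per-fragment reading is implemented as the default and is
the one validated by tests; the cumulative reading (truncate the
conversion-ordered list at the first fragment failing both criteria) is
exposed as `mode = "cumulative"` but unvalidated. Fragment order is
preserved because it reflects conversion order.

Real chain-file liftover is out of scope: fragments arrive either from
the packaged locus tables, via the resolver contract
(`make_table_resolver()`, mapping any rat interval to the fragments of
overlapping registered loci), or from precomputed liftover BED output
(`read_liftover_bed()`).

# Random control regions

Controls reproduce the published construction on a deliberately
idealised genome: 2.75 Gb divided evenly over 21 chromosomes gives
130,952,381 bp per chromosome; a candidate is a uniformly drawn
chromosome (drawn first) and a uniform start in 1..130,952,381, extended
to exactly 22,322,710 bases (half-open). Candidates are rejected when
their resolved human orthologs overlap known locus-ortholog territory or
centromeric regions (underrepresented in GWA genotyping), and the
accepted set plus a complete rejection log is returned reproducibly from
one integer seed.

Fidelity notes:

- Candidates may overhang real chromosome ends, exactly as the idealised
  procedure allows; a strict mode rejecting overhangs against a supplied
  chromosome-length table exists but is off by default.
- Controls are drawn independently, so two controls may overlap each
  other (the packaged control table indeed contains two fragments that
  overlap on chr13); a no-self-overlap option exists, off by default.
- The packaged control table prints rat spans of 24,322,710/11 bases
  while the stated sampling length is 22,322,710; the stated length is
  the sampler default (14 × 22,322,710 = 312,517,940 matches the
  published coverage table) and the printed table ships verbatim.

# SNP assignment and counting rules

Catalogs are deduplicated on rsID (falling back to chromosome:position),
keeping the minimum-p record per key — an arbitrary but deterministic
representative — and counting keys seen in two or more studies as
multi-study SNPs. Each unique SNP is then assigned to `loci` territory if
it falls in any ortholog fragment of any locus, else to `control`
territory, else to `neither`. Because several rat loci overlap
extensively and it is unknown whether they fine-map to shared or
independent sub-loci, a SNP hitting fragments of several loci counts
**once** toward the loci total (all hit loci are recorded). Loci and
control territories are required to be disjoint — the sampler guarantees
this by construction, and assignment re-validates it, treating any
overlap as a configuration error since the chi-square needs exclusive
groups. For carcinogen-stratified tallies, a SNP at overlapping loci of
both induction types counts once in the DMBA group *and* once in the
beta-estradiol group, so those tallies may double-count by design.

# Statistics

**Chi-square.** The test is the single-term goodness-of-fit form
`(O − E)² / E` on 1 df with the control count as `E` — not a two-cell or
2×2 contingency test. Only this form reproduces the published
significance call for O = 66, E = 51 (χ² = 4.41, p = 0.036); a two-cell
equal-probability test would give p ≈ 0.17. The form is exactly
calibrated when `E` is a model expectation; when `E` is itself a sampled
count of comparable size, the statistic is approximately `2·χ²₁` under
the null and therefore anticonservative (~17% rejection at α = 0.05).
This is a property of the published procedure that users should know
when interpreting borderline p-values; the package's calibration checks
therefore use the model expectation as `E` (see below). No continuity
correction or multiple-testing adjustment is applied anywhere, matching
the original analysis.

**Logistic regression.** The 2×2 of association class × territory is fit
by binomial IRLS (`stats::glm`) with convergence tolerance 1e-14 on the
relative deviance change — tight enough that slope, standard error and
Wald p agree with the closed forms `ln(ad/bc)` and `√(1/a+1/b+1/c+1/d)`
to better than 1e-6, which the tests verify against that independent
oracle on 1,000 random tables. The deviance criterion needs to be well
below the headline 1e-8 because the reported standard error comes from
the IRLS information one step behind the coefficients, making its error
scale like the square root of the tolerance. Wald is the primary p-value
and the likelihood-ratio p is reported alongside (both round to 0.54 on
the published table, so the distinction is immaterial there). A zero
cell is an error: continuity corrections are out of contract.

**Ratios.** `snp_ratio = O/E`, `base_ratio = loci unique bases / control
total bases`, `normalized_ratio = snp_ratio / base_ratio` (the per-base
enrichment). Full precision is returned; display rounds ratios to one
decimal and normalised ratios to two, matching the published precision.

# The synthetic-data generator

`simulate_landscape()` + `simulate_snp_catalog()` emulate the statistical
structure the analysis assumes and nothing more: SNPs fall uniformly
within a territory, and territories differ only in density — loci
territory is weighted by the enrichment multiplier ρ, control and
background by 1. Generator defaults mirror the study in miniature: 24
loci and 14 controls; locus sizes 0.2–2 Mb (a scaled-down territory —
the statistics depend on base totals only through their ratios, and
small coordinates keep the per-base test oracles exact); a quarter of
loci placed to overlap a partner (the study's loci overlap extensively;
`overlap_fraction` f yields exactly `round(f·n)` overlapping pairs);
background territory 8× the loci unique bases, so roughly a third of
SNPs land at loci when ρ ≈ 3.5, echoing the study's observed proportion.
Association class is assigned independently of territory (the null of
the logistic regression), and a configurable fraction of SNPs is
duplicated under a second study label to exercise deduplication.

What the generator does **not** emulate: linkage disequilibrium (SNPs
are placed independently), realistic allele frequencies or effect sizes
(odds-ratio and p-value fields are placeholder draws), chromosome-scale
structure, and the fragmentation statistics of real assembly conversion.
Passing simulation tests therefore validates the counting and inference
machinery, not the biological claim; real-data conclusions inherit all
caveats of GWA curation and liftover quality.

# Calibration and recovery checks

Two simulation checks accompany the suite and the acceptance script,
both seeded and scaled to run in minutes on one CPU:

- **Type-I calibration**: 500 null catalogs (ρ = 1, equal loci/control
  territories, 1,000 SNPs each); `chisq_obs_exp(O, n·p)` with the
  loci-territory share `p` as expectation rejects at 5% within three
  binomial standard errors. (With a finite territory share the binomial
  variance factor (1 − p) ≈ 0.9 makes the test mildly conservative,
  ~4% — inside the band.)
- **Recovery**: 100 catalogs of 5,000 SNPs at ρ = 3.5 run through
  deduplication and assignment; the median normalised ratio recovers
  ρ within 10%.

# Degenerate inputs and numerical choices

Empty region sets summarise to zeros rather than erroring; zero-length
intervals are legal and carry no bases; an empty SNP catalog produces a
zero-tally report with no statistics. Assembly mismatches, zero 2×2
cells, zero expectations, conflicting rsID positions and
locus/control-territory overlap are errors, each naming the offending
input. Ties in deduplication break deterministically (p-value, then
study label), making every pipeline output invariant to input row order;
all randomness flows from single integer seeds through R's default
generator, and reruns are byte-identical.

# Known limitations

- The observed-vs-observed chi-square is anticonservative under the
  null, as discussed above; a permutation p-value would be the natural
  extension but is deliberately not part of this reproduction.
- The per-fragment reading of the 1% retention rule is a documented
  interpretation; the cumulative alternative is available but unvalidated.
- The control sampler reproduces the idealised uniform-chromosome genome,
  including its artefacts (overhanging ends, duplicate-prone draws).
- Published per-SNP counts from the curated GWA catalogs are inputs, not
  recomputable outputs: the underlying SNP lists live in supplementary
  material outside this package's scope, so SNP-level machinery is
  validated on synthetic catalogs with known truth instead.
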