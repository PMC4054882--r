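# orthoenrich

Cross-species enrichment analysis of GWAS-nominated breast cancer risk
SNPs in human orthologs of rat mammary cancer susceptibility loci.

## The problem

Genome-wide association (GWA) studies of breast cancer apply stringent
genome-wide significance thresholds (~1e-7) that protect against false
positives at the cost of many false negatives. The laboratory rat offers an
independent line of evidence: linkage and congenic-strain mapping have
identified 24 mammary carcinoma susceptibility loci (*Mcs*, *Mcsm*,
*Mcstm*, *Mcsta* and estradiol-induced *Emca* loci). If human risk alleles
concentrate in the human genome regions orthologous to these rat loci,
comparative genomics can help rank GWA associations that failed validation.

`orthoenrich` implements that comparison as a tested, reusable pipeline for
analysts working with SNP catalogs and cross-species locus tables:

- **Interval algebra and coverage accounting** over genomic region sets on
  a half-open coordinate convention: total bases (with multiplicity),
  overlapping bases, unique (union) bases and genome fraction.
- **Ortholog fragment mapping** with the 1% retention rule: when a rat
  locus converts into many human fragments, a fragment is dropped only
  when it holds *less than 1% of the bases* **and** *spans less than 1%*
  of the source locus.
- **Random control regions** by seeded rejection sampling on an idealised
  rat genome (2.75 Gb, 21 equal chromosomes of 130,952,381 bp), rejecting
  candidates whose human orthologs touch known locus territory or
  centromeres.
- **SNP assignment** with multi-study deduplication and the count-once
  rule for overlapping loci, and tallies by population, association class
  and carcinogen induction group.
- **Enrichment statistics**: the observed-vs-expected goodness-of-fit
  chi-square `(O − E)² / E` on 1 df, where `O` is the SNP count at locus
  orthologs and `E` the count at control orthologs; a 2×2 logistic
  regression (Wald and likelihood-ratio p-values) of territory on
  association class; and territory-size-normalised count ratios
  `(O/E) / (loci bases / control bases)`.
- **A synthetic-data generator** with a configurable enrichment
  multiplier ρ, so every stage is testable end to end with known truth.

The published locus tables (24 rat loci and 14 random control regions,
with rn4 source coordinates and GRCh37 ortholog fragments) ship as
packaged fixtures.

## Worked example

```r
library(orthoenrich)
library(dplyr)

loci <- rat_mammary_loci()
rat  <- locus_rat_intervals(loci)
bind_rows(
  coverage_summary(filter(rat, locus %in% mcs_mcsm_locus_names()), name = "mcs_mcsm"),
  coverage_summary(rat, name = "all_loci")
)
#> # A tibble: 2 × 6
#>   name     n_loci total_bases overlapping_bases unique_bases genome_fraction
#>   <chr>     <int>       <dbl>             <dbl>        <dbl>           <dbl>
#> 1 mcs_mcsm     14   345323705          33002148    312321557            11.4
#> 2 all_loci     24  1230541216         325440423    905100793            32.9
```

The 14 compact `Mcs`/`Mcsm` loci cover 312 Mb of unique rat sequence
(11.4% of the genome; the 33.0 Mb of overlapping bases is `Mcs6` nested
inside `Mcs2`), and all 24 loci cover 905 Mb (32.9%).

```r
chisq_obs_exp(66, 51)           # European-descent SNPs, Mcs/Mcsm vs controls
#> O = 66 vs E = 51: chi-square(1) = 4.412, p = 0.03569

logistic_2x2(19, 7, 160, 44)    # associated vs potentially associated
#> logistic 2x2: slope = -0.2925 (SE 0.4738), Wald z = -0.617, p = 0.537 (LRT p = 0.544)

ratio_summary(179, 51, 905100793, 312517940)
#> # A tibble: 1 × 3
#>   snp_ratio base_ratio normalized_ratio
#>       <dbl>      <dbl>            <dbl>
#> 1      3.51       2.90             1.21
```

So 66 SNPs at `Mcs/Mcsm` orthologs versus 51 at control orthologs is a
significant excess (p < 0.05); whether a SNP cleared genome-wide
significance does not predict which territory it lands in (p = 0.54); and
with all 24 loci, SNPs are 3.5× as frequent at locus orthologs against a
2.9× larger territory — a 1.21-fold per-base enrichment.

The full pipeline — deduplication, count-once assignment, per-population
chi-square, logistic fit and report files — runs through
`run_enrichment_analysis()` / `write_enrichment_report()`, and
`simulate_landscape()` + `simulate_snp_catalog()` generate synthetic
inputs with known enrichment. `plot_snp_counts()` and
`plot_carcinogen_counts()` draw the corresponding bar charts.

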