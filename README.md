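# strainassoc

Case/control allelic association screening with crowd-sourced strain
phenotypes.

Public databases describe named crop strains — *Cannabis* cultivars being
the motivating case — with hundreds of phenotypes: measured chemical
content (THC, CBD, CBN), growth traits, and anecdotal taste / affect /
medicinal descriptors. The reports are noisy, partially overlapping
between websites, and of uneven quality. `strainassoc` implements a
complete screening pipeline to test whether such data can support
genome-wide association, plus a synthetic-data module that simulates
whole studies with planted causal variants so every stage is validated
against known ground truth.

## What it does

1. **Phenotype catalog** — loads per-source strain-by-trait tables,
   averages chemical values across sources (at least 2 sources per
   strain), derives a configurable ratio trait, and encodes every
   quantitative trait into reciprocal percentile case/control catalogs:
   for each direction (top / bottom) and fraction *f* in
   {5, 10, 25, 50}%, the `ceiling(f * m)` most extreme of the *m*
   non-missing strains are cases, the rest controls. Ties are broken
   deterministically; catalogs with fewer than 10 strains are excluded
   and logged.
2. **Variant filtering** — reads a multi-sample VCF, keeps bi-allelic
   SNPs, applies hard filters (remove when QD < 20, FS > 60, MQ < 45,
   MQRankSum < −0.2, ReadPosRankSum < −1.0, or SOR > 2.0; absent
   annotations never fail), and LD-prunes at r² > 0.5 in sliding
   windows of 50 SNPs advanced by 10.
3. **Association battery** — the classic 1-df allelic chi-square on each
   (SNP, catalog) 2×2 allele-count table,
   `X² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, without continuity
   correction, vectorized so the full default-scale battery runs in
   seconds.
4. **Consensus methods** — four increasingly conservative rules, all at
   an inclusive `p ≤ 1e-9`: every significant pair (Method 1); ≥ 3
   supporting tests within a phenotypic subcategory (Method 2) or a
   major chemical / non-chemical category with pleiotropy flags
   (Method 3); and a balanced bootstrap (Method 4) that subsamples the
   larger group to the size of the smaller via a Fisher–Yates shuffle,
   100 times, keeping SNPs significant in ≥ 95 replicates.
5. **Annotation** — genes within 25 kb of each significant SNP,
   per-chromosome summaries with top-5% tallies, and GO-term
   over-representation (one-sided Fisher exact test, Bonferroni
   correction, two-fold enrichment flag) against a user-supplied
   gene-to-term map.

## Worked example

Simulate a 300-strain study with one planted THC effect (2 trait-SD per
alternate allele), three noisy phenotype sources, a null CBN trait and a
pure-noise binary "affect" trait; then run the battery and consensus:

```r
library(strainassoc)

cfg <- sim_config(n_strains = 300, n_snps = 500, n_chromosomes = 2,
                  seed = 42)
panel <- simulate_genotypes(cfg)
panel
#> genotype_panel: 300 strains x 500 SNPs on 2 chromosome(s), 3.0% missing calls

pruned <- ld_prune(filter_biallelic_snps(panel))
planted <- pruned$variants$snp_id[25]
pheno <- simulate_phenotypes(
  panel,
  effects = data.frame(snp_id = planted, trait_name = "THC",
                       effect_size = 2),
  sources = default_sources(noise_sd = 0.5),
  traits = data.frame(
    name = c("THC", "CBN", "affect"),
    kind = c("quantitative", "quantitative", "binary"),
    baseline = c(15, 1, 0)),
  seed = 43)

battery <- enumerate_test_battery(pheno, ratio_numerator = NULL,
                                  ratio_denominator = NULL)
nrow(battery$manifest)
#> [1] 67

results <- run_battery(pruned, battery$catalogs)
cfg9 <- consensus_config(alpha = 1e-9, seed = 44)
m1 <- method1_hits(results, cfg9)
table(sub("\\|.*", "", m1$test_id))
#> THC
#>  48

m2 <- method2_hits(results, battery$manifest, cfg9)
m2[, c("snp_id", "grouping", "n_supporting")]
#>          snp_id    grouping n_supporting
#> 1 chr1_24460693 THC content           20
#> 2 chr1_24603445 THC content            6
#> 3 chr1_25328545 THC content            8
#> 4 chr1_25505922 THC content           14

m4 <- method4_bootstrap(pruned, battery$catalogs[["THC|averaged|top|25"]],
                        cfg9)
m4[m4$hit, c("snp_id", "n_significant", "retention")]
#>           snp_id n_significant retention
#> 25 chr1_24460693           100         1

planted
#> [1] "chr1_24460693"
```

All 48 Method-1 hits come from THC tests: the null CBN trait and the
noise "affect" trait stay silent at `p ≤ 1e-9`. The planted SNP
(`chr1_24460693`) is the strongest Method-2 hit (20 supporting tests;
the three other hits are its LD-block neighbors) and survives every one
of the 100 balanced bootstrap replicates.

For file-based runs, `run_pipeline(pipeline_config(...))` drives the
whole analysis from a VCF, a directory of phenotype tables and an
optional GFF3 / term map, writing hit tables, a prune report, a battery
manifest and a JSON run manifest. A thin command-line wrapper lives at
`inst/cli/strainassoc.R` (`simulate` and `run` subcommands).

## Method details

The methods vignette (`vignettes/strain-phenotype-gwas.Rmd`) documents
the model and its assumptions, every tunable threshold with its default
and rationale, the synthetic-data generator's scope (and what passing
tests do and do not demonstrate about real data), numerical edge-case
handling, and known limitations.
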