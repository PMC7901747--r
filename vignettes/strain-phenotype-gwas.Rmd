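---
title: "Screening crowd-sourced strain phenotypes for genetic associations"
author: "strainassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening crowd-sourced strain phenotypes for genetic associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Named crop strains — *Cannabis* cultivars being the motivating case — are
described in public online databases by hundreds of phenotypes: measured
chemical content (THC, CBD, CBN), growth characteristics, and anecdotal
traits such as taste, physiological affect and medicinal use. These
reports are noisy, partially overlapping between websites, and of very
uneven quality, yet they cover far more strains than any controlled
phenotyping effort. `strainassoc` implements a screening pipeline that
asks whether such data are good enough to support genome-wide
association: it collates multi-source trait tables, encodes each trait
into reciprocal percentile case/control contrasts, runs a classic allelic
association battery over a hard-filtered, LD-pruned SNP panel, and then
applies four increasingly conservative consensus rules to separate
signal from the noise floor. A synthetic-data module generates complete
studies with planted causal variants so every stage is testable without
any external data.

## Phenotype collation and encoding

Each source contributes one strain-by-trait table. Chemical traits are
additionally averaged across sources, but only for strains reported by at
least `min_sources = 2` sources — a value seen by a single website is not
considered corroborated. A ratio trait is derived per source from a
configurable numerator and denominator (default CBN/THC). The numerator
and denominator are deliberately configuration rather than a constant:
published descriptions of such ratios are inconsistent about orientation,
and the choice does not affect the association machinery, only the
labeling of the extremes.

A quantitative trait with `m` non-missing strains is encoded into
case/control catalogs by taking, for each direction (top, bottom) and
each fraction `f` in {0.05, 0.10, 0.25, 0.50}, the `ceiling(f * m)` most
extreme strains as cases and every other non-missing strain as a control.
The ceiling guarantees at least one case for any `m`. Ties at the cut are
broken by stable `(value, strain_id)` order, so the encoding is
deterministic under any row order of the input, and re-running the
enumeration reproduces identical test identifiers and memberships.
Binary traits admit only the direct encoding (cases are the strains
scored 1). Catalogs whose trait has fewer than `min_strains = 10`
non-missing strains are excluded: very small case or control groups
produce effectively random associations, and the exclusion is logged in
the battery manifest rather than applied silently.

## Variant filtering

The pipeline consumes a genotyped multi-sample VCF and fixes the stage
order: bi-allelic SNP selection, then per-site hard filters, then LD
pruning. The hard filters remove a site when any *present* annotation
violates QD < 20, FS > 60, MQ < 45, MQRankSum < -0.2,
ReadPosRankSum < -1.0 or SOR > 2.0. All inequalities are strict — a site
exactly at a threshold passes — and absent annotations never fail a
filter, since rank-sum statistics are undefined at sites without
heterozygotes and discarding such sites would remove perfectly valid
homozygous-difference markers.

LD pruning slides a 50-SNP window along each chromosome in 10-SNP steps.
Within each window, pairs of surviving SNPs are scanned in coordinate
order and one SNP of every pair with squared dosage correlation
r² > 0.5 is removed. r² is the squared Pearson correlation between
dosage vectors over pairwise-complete strains; phase is not required.
Sites monomorphic over the shared strains have undefined r² and are
treated as unlinked. Which SNP of a violating pair to drop is not
dictated by the statistic; the package removes the SNP with the smaller
minor-allele frequency (ties: the later coordinate), the common practice
that preferentially retains the more informative marker. The test suite
asserts the defining postcondition independently of this choice: after
pruning, an exhaustive re-scan of every window position finds no
surviving pair above the threshold.

## The allelic test and the consensus methods

Every (SNP, catalog) pair is scored with the 1-df allelic chi-square on
the 2×2 allele-count table — each non-missing diploid genotype
contributes `dosage` alternate and `2 - dosage` reference alleles to its
group:

    X² = N (ad − bc)² / ((a+b)(c+d)(a+c)(b+d))

with `a, b` the case alternate/reference counts and `c, d` the control
counts. No continuity correction is applied, matching the default allelic
test of standard GWAS tooling. Monomorphic tables are flagged untested
rather than raising; odds ratios are reported only when all four cells
are positive; p-values that underflow are clamped to the smallest
positive double and flagged. There is no covariate model and no
population-structure correction — a documented limitation of the
screening design, partially compensated by the consensus rules below.

Four rules extract hits from the battery, all using an *inclusive*
cutoff (`p <= alpha`, default `alpha = 1e-9`):

1. **Method 1** — every (SNP, test) pair at or below the cutoff.
2. **Method 2** — SNPs significant in at least `min_tests = 3` distinct
   tests of a single phenotypic subcategory (e.g. THC content).
3. **Method 3** — the same count within a major category (chemical /
   non-chemical); each hit also reports the set of subcategories among
   its supporting tests and is flagged pleiotropic when that set has
   more than one element. Method 2 hits are necessarily contained in
   Method 3 hits.
4. **Method 4** — a balanced bootstrap: the larger of the two groups is
   subsampled without replacement, via a partial Fisher–Yates shuffle,
   down to the size of the smaller group; the battery is re-run on each
   of `n_bootstrap = 100` balanced replicates, and a SNP is a hit when
   significant in at least `ceiling(retention * n_bootstrap)` replicates
   (default 95 of 100). When cases outnumber controls the case group is
   subsampled instead — the symmetric generalization of balancing.

Reciprocal encodings (top vs bottom, different fractions) of one trait
count as distinct tests for Methods 2–3: the test identifier, not the
trait, is the unit of support. All catalogs are eligible for Method 4 by
default; `pipeline_config(bootstrap_tests = ...)` restricts it.

Randomness in Method 4 is organized as one master seed spawning one
substream per replicate (and one block of substreams per catalog), so a
single replicate can be reproduced without re-running its predecessors
and identical configurations give byte-identical hit tables.

## Interpretation

For significant SNPs the annotation stage reports every gene whose
interval lies within 25 kb of the variant (a 50 kb window in total). The
boundary is inclusive at exactly 25,000 bp, distance is measured to the
nearest gene edge (0 inside the gene), and inclusion is strand-agnostic.
The chromosomal summary tabulates significant SNPs per chromosome and
display category and flags the globally top 5% by p-value
(ceiling count), split into chemical and non-chemical tallies.

GO over-representation uses the one-sided Fisher exact test
(hypergeometric upper tail) per term on the in-list × has-term table,
against a user-supplied gene-to-term map — the statistic is generic, so
results are only as current as the supplied map. Bonferroni correction
multiplies by the number of terms with at least one list gene; terms
absent from the list report fold enrichment 0 and are never flagged.
Flagged terms need corrected p ≤ 0.05 and fold enrichment ≥ 2.

## The synthetic-data generator

The generator's defaults emulate the scale of an amplicon-sequenced
strain panel: 845 strains × 4,351 bi-allelic SNPs on 10 chromosomes of
100 Mb, MAF drawn uniformly from [0.05, 0.5], 3% missing calls, and
three phenotype sources with coverages 0.85/0.75/0.65, biases
+0.5/−0.5/0 trait units and a common report noise (default 0.5 trait
units). These source parameters are free choices — multi-source
crowd-sourced data show between-site disagreement, but no published
noise model exists to estimate them from.

Local LD is produced by block-copying: within each block of
`ld_block_size` consecutive SNPs, non-anchor SNPs copy the anchor's
dosage vector and independently resample each call with probability
`1 − sqrt(r2)`, making the expected anchor–copy correlation `sqrt(r2)`
and the squared correlation the target. This is deliberately the
simplest controllable LD model: it is sufficient to exercise the pruning
logic and to create realistic proxy-hit behavior around planted
variants, but it does not model recombination gradients, population
structure, or relatedness between strains. Missingness is uniform at
random per call, as no missingness model is available for the source
data. Binary anecdotal traits use a liability threshold (genetic value
plus unit residual, thresholded at the population median), so
"low-quality trait" fixtures are obtained by planting no effects — the
liability is then pure noise and downstream methods should stay silent.
Every simulated study includes a designated null quantitative trait
(default CBN, an oxidation product rather than a directly synthesized
compound, hence the natural negative control).

Passing the recovery tests therefore shows that the pipeline detects
additive signals of the planted architecture under multi-source noise
and local LD — not that it is robust to confounding by population
structure, batch effects between websites, or systematic strain
misnaming, none of which the generator emulates.

## Numerical and testing choices

* The chi-square statistic is validated two ways: against the
  independent `chisq.test(correct = FALSE)` implementation, and against
  a 10,000-draw label-permutation null on small tables. Because the
  permutation statistic is discrete, the asymptotic p cannot coincide
  with the permutation tail exactly; the test requires the asymptotic p
  to fall inside the envelope `[P(X² > obs), P(X² ≥ obs)]` widened by
  four Monte-Carlo standard errors, which is the sharpest check the
  discreteness admits.
* Enrichment p-values are checked against an explicit `choose()`-sum
  enumeration of the hypergeometric tail to 10 significant digits;
  proximity queries are checked against a brute-force all-pairs scan.
* Recovery and calibration tests run at the generator's default scale
  (845 × 4,351): ten independently seeded studies for planted-signal
  recovery, and twenty fully null batteries (about 131 tests each, so
  roughly 5.7 million p-values) for the zero-hit calibration at
  `alpha = 1e-9`.
* Degenerate inputs are handled as data, not errors, wherever a scan
  must continue: monomorphic markers are flagged untested, empty gene
  neighborhoods are empty results, and a trait too sparse to encode is a
  logged exclusion.

## Known limitations

The allelic test assumes Hardy–Weinberg-like allele counting within
groups and is asymptotic; sparse extreme-percentile catalogs lean on the
consensus rules, not on exact small-sample inference. No multiplicity
adjustment is applied across the battery — the design philosophy is
threshold-plus-consensus, and the p ≤ 10⁻⁹ cutoff is far beyond
conventional genome-wide significance. Strain-name harmonization across
sources is exact-match only. The GO stage implements the statistic, not
a curated ontology: term-set quality is the caller's responsibility.
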