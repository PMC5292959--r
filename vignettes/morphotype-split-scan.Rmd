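---
title: "Detecting morphotype split markers, haplotypes and copy-number variants in structured crop panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting morphotype split markers, haplotypes and copy-number variants in structured crop panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosplit)
library(dplyr)
```

## The problem

Cultivated *Brassica napus* falls into morphotypes — winter and spring
oilseed rape, semi-winter forms, and swedes — that differ most
conspicuously in their vernalisation requirement. Because breeders cross
within morphotype pools, loci controlling the winter/spring life cycle sit
on near-fixed, pool-diagnostic haplotypes, while most of the genome drifts
freely across pools. morphosplit implements an analysis chain that finds
those diagnostic loci in a genotyped diversity panel: merge and
quality-filter markers from a SNP array and targeted sequencing, confirm
the panel's pool structure, scan every marker with a two-stage chi-square
statistic, classify each accession's haplotype across the detected regions,
and call copy-number variants (including homoeologous A/C exchanges) from
target-capture read depth.

The motivating panel has 271 inbred accessions — 139 winter, 7 semi-winter,
114 spring and 11 swedes — and a few tens of thousands of biallelic
markers. Those numbers are the package defaults throughout.

## The two-stage split statistic

Alleles are first *polarized*. For each biallelic marker the alternate
allele frequency is computed in a winter polarization pool (winter +
swedes, which are winter-habit) and a spring polarization pool
(semi-winter + spring); the frequency ratio assigns the allele the winter
(w) or spring (s) label. A ratio of exactly 1 carries no information and
the marker is excluded — it cannot be given a pool label.

Counts are then taken over the *test* pools — winter without swedes
(N1 = 139) versus spring without semi-winter (N2 = 114) — giving the
four cells (w in winter, w in spring, s in winter, s in spring).

**Stage 1 — suitability.** The concordant counts (w in winter, s in
spring) are tested against the full-concordance expectation (N1, N2) with
a 1-df chi-square; markers with p > 0.1 proceed. This gate does the heavy
lifting: a marker that is common in *both* pools (say, frequency 0.95
everywhere) deviates wildly from the stage-2 expectation below and would
score an enormous statistic, yet it says nothing about the morphotype
split. Such markers can never show near-full concordance in both pools at
once, so the gate removes them while letting genuinely differential
markers through — e.g. observed (132, 101) gives chi-square
`r round(49/139 + 169/114, 2)`, p about 0.18, pass.

The expectation is taken literally as (N1, N2) rather than renormalized to
the observed total; both conventions agree on every published worked
example, and the literal form is the default (switchable with
`suit_expected = "observed_total"`). The literal form slightly penalizes
markers with many missing calls, which is consistent with treating poor
call support as evidence against a clean diagnostic haplotype.

**Stage 2 — the split test.** The four cells are compared with the
equal-frequency expectation (N1/2, N2/2, N1/2, N2/2) — 69.5/57/69.5/57
for winter versus spring — with a 3-df chi-square. Expected counts stay at
half the *full* pool sizes even when calls are missing at the marker; this
is what reproduces the published worked values (a row whose cells sum to
250 of 253 genotypes still yields −log10 p = 39.3). Degrees of freedom 3
and the base-10 logarithm are likewise fixed by the worked examples:

```{r}
split_chisq_cells(n11 = 132, n12 = 13, n21 = 4, n22 = 101,
                  n1 = 139, n2 = 114)
```

Statistics of 200–300 correspond to p-values far below double-precision
underflow, so tails are evaluated through the log survival function
(`pchisq(log.p = TRUE)`) and only ever handled as −log10 p. The test suite
checks this path against an independent closed-form chi-square(3) survival
function to 10^-3 over the full working range.

**Selection and regions.** Split markers are the top 0.1% of −log10 p
(`top_frac = 0.001`): `n_keep = ceiling(top_frac * n_scanned)`, threshold
at the n_keep-th largest value among suitability passers, ties included.
The denominator is the number of markers entering the scan, not the
(much smaller) number passing the gate — with ~34,000 markers the top
0.1% is ~34 markers, matching the scale of the published split-marker
tables. Selected markers within 1 Mb of each other on a chromosome are
chained into split regions (single linkage; the 1 Mb default matches the
candidate-gene window).

The same machinery runs the swede contrast: swedes (N2 = 11) against all
other accessions (N1 = 260), expectation 130/5.5/130/5.5.

## Haplotype classification

Within each split region an accession is *clear* for a pool when every
non-missing split-marker call carries that pool's allele, *mixed* when
both pool alleles occur, and *deleted* when every member marker is
missing — an all-missing haplotype across a genomic region in inbred
material is most parsimoniously a missing segment rather than independent
call failures (`require_complete = TRUE` switches to the stricter reading
under which partial missingness is not clear). Single-marker regions
cannot be internally discordant, so their mixed count is reported as not
applicable. Per-accession counts of clear regions exclude mixed calls.

## Population structure

Distances are modified Rogers distances: the Euclidean allele-frequency
distance sqrt((1/2m) sum (p − q)^2), computed over the loci non-missing in
both accessions (pairwise-complete; the data give no basis for
imputation). For inbred, homozygous-only data this is exactly the square
root of the fraction of discordant loci, giving the closed-form anchors 0,
sqrt(0.5) and 1 used in the tests. "PCA on genetic distances" is
implemented as classical metric scaling (PCoA) of that matrix — the
decomposition is not otherwise pinned down, and PCoA is the standard
reading; negative eigenvalues are truncated to zero and excluded from the
variance denominator. A genotype-matrix PCA would be a reasonable
alternative but is not needed by any downstream step. k-means (best of 25
random restarts, squared Euclidean on the top 4 components) is run for
k = 1..15 and the within-cluster sum of squares curve inspected; the
intended workflow is to pick k from the elbow plot, with an automatic
fallback choosing the largest relative WSS drop. WSS is forced
nonincreasing in k by warm-starting from the previous solution whenever
random restarts fail to beat it, which also makes the curve a valid elbow
diagnostic.

## Copy-number calling

Read counts per captured region are normalized as
reads × genome length / (total aligned reads × read length), i.e.
coverage relative to the genotype's genome-wide average. The population
reference per region is the arithmetic mean over all genotypes — the mean
(not an otherwise-undefined aggregate) is the natural reading, with the
median available via `ref_stat = "median"`; the tested genotype is
included, which with ~271 genotypes shifts the reference by under 0.4%.
Ratios strictly below 0.5 are deletions, strictly above 1.5 duplications;
the boundary values themselves are normal. Regions whose reference falls
below 10 are excluded as uninformative, mirroring the minimum-coverage
region definition used for target capture. HNRT (homoeologous
non-reciprocal translocation) candidates are genotypes whose A-subgenome
region is duplicated while the paired C-subgenome region is deleted.

## What the generator emulates — and what it does not

`simulate_panel()` produces the study conditions end to end: the
271-accession panel, background markers sharing one allele frequency
across pools (drawn U(0.05, 0.95) per marker), diagnostic blocks in which
exactly round(concordance × pool size) members of each pool carry their
pool's allele, independent per-call missingness, and Poisson coverage with
log-normal library sizes (total reads ~ LN(log 2e7, 0.2)) and per-region
baselines spanning 0.7–1.7× the 1000× mean, matching the coverage range
of captured genes. Defaults: concordance 0.95, missingness 0.05, 12
markers per diagnostic block — the block size follows from the panel's
marker density (~34k markers over a ~850 Mb genome is ~40 markers/Mb, so
a ~300 kb diagnostic haplotype spans ~12 markers). Carriers are drawn once
per region, so haplotype blocks are internally identical, as in the
package's strictest reading of a diagnostic haplotype.

The generator deliberately omits linkage-disequilibrium decay, genotyping
error, pool-specific background drift and GC or capture-efficiency bias in
coverage. Passing tests therefore demonstrate that the statistics and
callers behave as specified under their own model — clean two-pool
differentiation and Poisson depth — not that real array intensities or
capture libraries are free of artefacts. On real data the suitability gate
and QC filters absorb some but not all of those effects.

Numerical and edge-case choices worth knowing: heterozygous calls become
missing on ingest (the panel is inbred; residual heterozygosity is treated
as no-call); QC inequalities are strict as printed (call rate > 0.9,
MAF > 0.01, individual call rate > 0.8), so the boundary values are
excluded, and marker filters run once before the individual filter;
duplicate markers at one (chromosome, position, allele pair) collapse to
the copy with fewest missing calls, first seen winning ties; InDels are
recoded reference → AA, insertion → CC, deletion → TT before merging;
accession pairs sharing no non-missing locus get a missing distance with a
warning; all-zero distance matrices ordinate to all-zero coordinates.

## Problem sizes used in validation

The shipped tests and the acceptance script exercise: the seven published
worked-example rows (exact to the printed decimal); 1,000 random 4-cell
tables against the independent chi-square(3) oracle; a 10,000-marker null
panel (no marker passes the gate and exceeds the winter-spring cutoff
38.9); twenty replicate 10,000-marker panels with 10 injected split
regions at concordance 0.95/missingness 0.05 (all recovered, nothing
spurious, with the selection quantile 0.012 sized to cover the 120
injected markers); one hundred 20-region coverage panels for CNV precision
and recall; and closed-form distance and three-blob clustering checks.
Dataset-level published figures (33,944 retained markers, 12 and 13
regions, 24.1% PC1 variance) depend on the unreleased panel itself and are
covered qualitatively by the null and recovery experiments, not asserted
numerically.

## A worked synthetic run

```{r, fig.width = 6, fig.height = 4}
cfg <- sim_config(n_markers = 4000, n_split_regions_ws = 4,
                  n_split_regions_swede = 2, seed = 7)
sim <- simulate_panel(cfg)
sim

scan <- split_scan(sim$genotypes, sim$panel, "winter_spring",
                   top_frac = 48 / 4000)
scan
scan$regions[, c("region_id", "n_markers", "best_neg_log10_p")]
autoplot(scan)

calls <- classify_haplotypes(sim$genotypes, scan)
haplotype_distribution(calls, sim$panel, scan$regions)$by_region

norm <- normalize_coverage(sim$coverage$counts, sim$coverage$totals,
                           genome_length = cfg$genome_length,
                           read_length = cfg$read_length)
cnv <- call_cnv(norm)
dplyr::count(cnv, call)
```

The full chain, driven by one seeded configuration and writing every
stage's tables plus a manifest, is `run_pipeline()`; see `?run_pipeline`.
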