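---
title: "Methods: bulked-segregant QTL-seq mapping with bulkmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant QTL-seq mapping with bulkmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmapr)
```

## The measurement model

A bulk-segregant sequencing experiment compares pooled allele frequencies
between the two phenotypic extremes of a segregating population. At a
marker where the inbred parents carry different alleles, the observed
alt-read fraction of a bulk is a two-stage sample: the pool's true allele
frequency is the mean allele dosage of its $k$ members divided by two
(composition sampling), and the reads are then drawn binomially at the
site's depth (sequencing sampling). Both statistics implemented here are
functions of the two bulks' frequencies:

* **ED**: $D = \sqrt{\sum_b (N_{mut,b} - N_{wt,b})^2}$ over per-base
  frequencies, raised to the 5th power to suppress background, smoothed
  over physical distance, and thresholded at
  $\mathrm{median} + 3\,\mathrm{SD}$ of the fitted track.
* **ΔSNP-index**: $M_{aa}/(M_{aa}+P_{aa}) - M_{ab}/(M_{ab}+P_{ab})$, where
  $M$ and $P$ are read depths attributed to the female and male parent
  alleles and $aa$/$ab$ denote the low and high bulk; window means are
  compared against simulated null quantiles.

Attributing reads to parents requires both parents homozygous for
different alleles, which is why the parent-consistency filter removes
heterozygous-parent sites outright rather than attempting a partial
attribution.

## Filters

The six passes run in a fixed order — quality, InDel proximity, variant
clusters, biallelic, bulk depth, parent consistency — and each logs its
removal count. The thresholds (QUAL < 30, QD < 2, SNPs within 5 bp of an
InDel, InDel pairs within 10 bp, more than 2 variants within 5 bp, bulk
depth < 4) are the conventional QTL-seq settings and are all exposed in
`filter_config()`. Three behaviours are deliberate choices where
convention leaves room:

* the cluster rule removes the *whole* maximal run of linked variants, the
  conservative reading when only a count limit is stated;
* records lacking a QD annotation pass the QD test (absence of an
  annotation is not evidence of low quality);
* a bulk allele carried by neither parent triggers removal only when its
  frequency exceeds twice the configured sequencing error rate
  (`seq_error_rate`, default 0.001); below that it is treated as noise.
  Without this floor a single miscalled read would discard an otherwise
  perfect site at 50X.

Each pass is idempotent, and on clean simulated data (marker spacing far
above 10 bp) the positional filters remove nothing — both properties are
tested.

## Smoothing, thresholds and bounds

**ED fitting.** The per-site ED⁵ values are smoothed with a tricube-kernel
weighted mean over physical distance,
$w_{ij} = (1-(d_{ij}/h)^3)^3$ for $d_{ij} < h$, with bandwidth
$h = 2\,\mathrm{Mb}$ by default. A distance-kernel local mean is the
standard realisation of "distance fitting" for genome tracks; tricube
keeps the estimate local while down-weighting the window edges. The
bandwidth matters more than the kernel: it should cover enough sites to
average out sequencing noise (≥ ~50 at typical densities) while remaining
narrow against chromosome length. The implementation restricts the kernel
sum to the sites inside the support, and is tested to $10^{-10}$ against a
naive $O(n^2)$ double loop.

**ED threshold.** `median(fitted) + 3 * sd(fitted)`, pooled across
chromosomes per marker class, with the sample ($n-1$) standard deviation.
The median resists inflation by true signal; the SD term does not, which
is intentional — a genome with strong signal gets a higher bar.

**ΔSNP-index bounds.** The null distribution is simulated: each bulk
independently pools `pool_size` individuals drawn from the generation's
segregation ratios (3/8 : 1/4 : 3/8 for an F₃ produced by two rounds of
selfing; 1/4 : 1/2 : 1/4 for an F₂), reads are Binomial(depth, pooled
frequency), and the $(1\pm c)/2$ quantiles of the resulting Δ form the
bounds at confidence $c = 0.99$. Bounds are computed on a depth grid
(4–200 in steps of 2 by default), keyed by the *smaller* of the two bulk
depths, interpolated linearly between grid points and clamped beyond
them. The same pooled-frequency draws are reused across the depth grid so
that bounds shrink monotonically with depth instead of rattling with
simulation noise. Pool members are drawn with replacement from the
segregation distribution; for unlinked null markers this is exact
regardless of the finite population size, so `n_individuals` only
validates `pool_size`.

**Region calling.** Sites (or windows) beyond the threshold/bounds are
snapped to 10-kb bins (`floor(pos/grid)·grid`), and bins separated by at
most `merge_gap` are merged; regions are half-open $[start, end)$ so
`size_mb = (end-start)/10^6` exactly. The default `merge_gap = grid`
(10 kb) is appropriate for real marker densities of one site per few
hundred bp. On sparse simulated maps (one marker per 20 kb) adjacent
informative sites can sit further apart than the default gap, so the
pipeline examples use a merge gap on the order of the sparser marker
class's spacing (100 kb); this widens calls but does not move them.

## What the simulator emulates — and what it does not

`simulate_bsa_experiment()` generates the full causal chain: two fully
homozygous, fully divergent inbred parents; meiosis under a Haldane model
(crossovers Poisson with a uniform 4 cM/Mb map, rice-typical; no
interference, no hot spots); an F₂ from selfed F₁ gametes or an F₃ in
which each individual is one selfed seed of an independent F₂ plant (the
mixed-harvest design; family structure is fixed to independent F₂
parents rather than exposed as an option, since sharing families would
only inflate pool correlations that the analysis does not model either);
a purely additive phenotype with Gaussian noise scaled so that
$h^2$ = `heritability` in expectation; extreme-tail pools of
`round(pool_fraction × n)` (round half up, ties broken by individual
index); and pooled sequencing with Poisson total depth, binomial allele
sampling and a symmetric per-read error (default $10^{-3}$). The defaults
describe the reference design: 299 F₃ individuals, 10% tails (pools of
30), bulks at 50X, parents at 31X, markers every 20 kb with ~20% small
InDels.

Real data differ in ways the simulator deliberately omits: dominance and
epistasis, segregation distortion, mapping bias around InDels,
non-uniform recombination and marker density, GC-dependent coverage, and
contaminated or mis-phenotyped pool members. Passing calibration and
recovery tests therefore demonstrates that the *statistics and their
thresholds* behave as designed under the stated sampling model — not that
any given field experiment will localise its loci this cleanly.

## Calibration and power under the reference design

Two experiment helpers run the design end to end
(`evaluate_null_calibration()`, `evaluate_qtl_recovery()`), each over 20
independent seeds on a 5 × 30 Mb genome — sizes chosen to make a full run
a one-minute job on a single core while keeping per-chromosome site counts
(1,500) representative.

With zero QTLs, the ΔSNP-index track stays essentially entirely inside
its 0.99 bounds (window exceedance ~0%, comfortably under the 2.5% one
would tolerate for correlated windows). The ED track is a different
story: the median + 3 SD rule still calls ~2–3% of the genome. This is
not an implementation artifact — it reproduces with noise-free pooled
frequencies — but a property of the statistic at this pool size: with
pools of 30 the null frequency difference has SD ≈ 0.11 and multi-Mb
linkage correlation, and the 5th power makes the fitted field strongly
right-skewed, so more than 1% of it sits above median + 3 SD. Users
should treat isolated short ED calls with corresponding caution and rely
on the intersection with the ΔSNP-index track, which is exactly the
published practice.

With one additive QTL of 0.8 phenotypic SD (for a single F₃ locus with
unit effect this means $h^2 = 0.75 \times 0.8^2 = 0.48$), both algorithms
cover the true position in essentially every seed once each algorithm's
SNP-track and InDel-track calls are pooled — necessary because the causal
marker belongs to one class or the other. The ED region midpoint
localises the QTL to well within 2 Mb; the ΔSNP-index sweep typically
spans most of the carrier chromosome under selection this strong, so its
region midpoint is a much weaker localiser (within 2 Mb in roughly
two-thirds of seeds). That asymmetry — ED localises, ΔSNP-index
corroborates — is the practical reason to run both.

## Numerical conventions and degenerate inputs

* Coordinates are half-open 0-based internally; 1-based only at VCF
  ingestion and in human-readable output. Interval algebra is delegated
  to GenomicRanges behind the tidy interface, and is property-tested
  against a per-bp bitmap oracle.
* ED frequency vectors must sum to 1 within $10^{-9}$; violations are
  errors, not silent renormalisations.
* Zero-depth bulks give an `NA` index/delta and the site is skipped by
  windows (never imputed as 0); empty windows are absent from the track
  rather than zero.
* Single-site chromosomes are fitted as themselves, with a warning.
* Ts/Tv is reported as `NA` when there are no transversions.
* Threshold comparisons are strict (`>`), so a threshold equal to the
  maximum calls nothing.
* All randomness flows from explicit integer seeds; a fixed seed
  reproduces populations, VCF bytes and pipeline outputs exactly.

## Known limitations

Beyond the simulator's scope above: the ED null false-call length at
small pool sizes (see calibration), the breadth of ΔSNP-index sweeps
under strong selection, no support for more than two bulks or for
G-statistic/likelihood alternatives, and no multi-QTL deconvolution —
closely linked QTLs will merge into one call. Gene counting uses
any-overlap by default (`mode = "midpoint"` is available); with
any-overlap a gene spanning a region boundary counts in each region it
touches, and deduplicated totals are provided separately.
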