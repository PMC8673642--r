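---
title: "Genomic prediction from low-coverage sequencing: methods and design"
author: "skimGEBV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction from low-coverage sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimGEBV)
```

## The problem

Genomic breeding values (GEBVs) and polygenic scores are dosage-weighted
sums of marker effects: with an $n \times m$ genotype matrix $\mathbf{M}$
coded 0/1/2 in copies of the alternate allele and a per-trait effect
vector $\hat{g}$, the SNP-BLUP prediction is
$\hat{b} = \mathbf{M}\hat{g}$. Arrays deliver $\mathbf{M}$ essentially
error-free; low-coverage ("skim") sequencing instead yields, per target
SNP, a few error-prone reads — often zero. This package implements and
evaluates the sequencing arm: call genotypes from per-locus allele
counts with depth-aware thresholds, fill loci with no reads by one of
three strategies, form $\hat{a} = \mathbf{N}\hat{g}$ from the resulting
matrix $\mathbf{N}$, and compare $\hat{a}$ against the array reference
$\hat{b}$ through Pearson correlation and the bias regression of
$\hat{b}$ on $\hat{a}$.

## Variable minimum-allele-count genotyping

A heterozygote sequenced to depth $d$ shows alternate reads
$X \sim \mathrm{Binomial}(d, \tfrac12)$. Demanding at least $t$ reads of
*each* allele before calling a heterozygote filters sequencing errors,
but costs true heterozygotes whenever $X < t$ or $X > d - t$. The
threshold used here is the largest $t \ge 1$ with

$$P(t \le X \le d - t) \ \ge\ 0.95,$$

computed per exact integer depth — the finest possible version of
grouping loci of similar coverage. At $d < 6$ no $t \ge 1$ attains 0.95
and the floor $t = 1$ applies. Calls follow the depth: zero usable reads
leave the locus missing for a fill method; a single read forces a
homozygous call for the observed allele (one read cannot show both
alleles); at $d \ge 2$, both counts $\ge t$ give a heterozygote,
otherwise the majority allele's homozygote. Ties with both counts at or
above $t$ are heterozygotes (and a tie below $t$ cannot occur, since the
majority count is at least $\lceil d/2 \rceil \ge t$). Depth is
`ref + alt` only: reads showing a third base are recorded but excluded,
so errors at non-target bases cannot shift thresholds.

A consequence worth stating plainly: because $t(d)$ is pushed as high as
the 95% condition allows at *every* depth, heterozygote detection sits
in $[0.95, 1)$ even at high coverage — e.g. $t(20) = 6$ detects 95.86%
of heterozygotes. Exact recovery of all genotypes is therefore not
attainable under this rule even with error-free reads; the test suite
checks observed miscalls against the exact binomial expectation implied
by the realized depth distribution rather than against an idealized
100%.

## Filling missing genotypes

Three strategies complete $\mathbf{N}$:

* **homref** codes missing loci 0. Those loci then contribute nothing
  to $\hat{a}$, so individuals with more missing data are pulled toward
  zero — the mechanism behind this method's strong bias at low
  coverage.
* **af** inserts the Hardy–Weinberg expected dosage
  $0(1-p)^2 + 1\cdot 2p(1-p) + 2p^2 = 2p$ from the population alternate
  allele frequency $p$. An individual with *all* loci missing receives
  exactly the population-mean prediction $\sum_i 2p_i\hat{g}_i$;
  partial missingness regresses predictions toward that mean, which
  preserves ranking (high correlations) while inflating the bias slope.
* **ld** is a windowed haplotype-pair matcher against a phased
  reference panel: for each missing cell, the up-to-$K$ (default 10)
  nearest called loci on each side are scored against every ordered
  pair of panel haplotypes (number of dosage matches in the window);
  the cell takes the mean dosage of the best-scoring pairs at that
  locus. Ties are averaged — deterministically, possibly fractional —
  with off-diagonal pairs weighted twice so the average is over ordered
  pairs. Individuals with no called loci at all fall back to the `af`
  dosage and are counted. This is deliberately *not* a reimplementation
  of Beagle's HMM; it is the simplest deterministic imputer that
  exploits the same information (local LD with a panel), so the
  pipeline's third arm is testable at desk scale. An adapter to an
  external Beagle 5.1 executable (`beagleImpute`, ne = 100000,
  window = 100, widened for very sparse data) is provided for users who
  have it; nothing in the package requires it.

No fill method ever alters a called cell, and all outputs stay in
$[0, 2]$.

## Evaluation

Concordance compares hard calls only, scoring each cell by correctly
called alleles $2 - |g_\text{test} - g_\text{ref}|$ (2, 1 or 0); missing
cells are excluded and counted. The bias statistic is the OLS slope of
$\hat{b}$ on $\hat{a}$ *with* intercept (an intercept-free fit would
conflate location and scale bias); slope > 1 means the sequence-derived
predictions are under-dispersed. Covariate screening regresses the
residuals of $\hat{b} \sim \hat{a}$ on one covariate at a time,
reporting the two-sided t-test p-value with significance declared at
0.01 and no multiple-testing correction — the conventional reporting
style for a handful of individually examined run covariates.

## The synthetic-data generator

No suitable public dataset pairs low-coverage pileups with array
genotypes and effects at desk scale, so the generator builds one with
the statistical features the method relies on:

* **Panel**: `nFounders` founder haplotypes with per-locus alternate
  frequency $p_i \sim U(0.1, 0.9)$; each of `nPanelHaplotypes` panel
  haplotypes copies one founder and switches template between adjacent
  markers with probability `switchRate`. Small founder pools and switch
  rates give long shared segments — the LD a panel-based imputer
  exploits. Marker order is the only positional structure; genetic map
  distances are not modelled.
* **Individuals** are sums of two fresh mosaics over the panel, so the
  population has the panel's LD and known ground truth (both source
  haplotypes are retained).
* **Pileups**: depth $\sim$ Poisson(coverage) per cell; read alleles
  from the true genotype (fair coin at heterozygotes) flipped with
  probability $10^{-Q/10}$, or routed to a third-base bucket when
  `errorToOther` is set. Reads collapse directly to allele counts; read
  lengths and mapping are not simulated, and run-level covariates are
  treated as given numbers.
* **Marker effects**: a latent i.i.d. Gaussian polygenic vector per
  trait, projected through the empirical panel LD (banded correlation
  smoothing over 50 flanking markers) and rescaled to the trait's
  `effectSd`. The projection matters: real SNP-BLUP solutions are
  back-solved from data and therefore spread signal across markers in
  LD with aligned signs. With effects instead drawn independently of
  the LD structure, the cross-locus term
  $\sum_{i \ne j}\hat{g}_i\hat{g}_j\,\mathrm{cov}(g_i, g_j)$ averages
  to zero and one can show the homref bias slope is bounded by 1 — the
  under-dispersion bias that motivates imputation simply cannot appear.
  LD-aligned effects restore the realistic regime in which prediction
  signal is concentrated on shared haplotype segments, observed-marker
  subsets still track it, and missingness shrinks
  $\mathrm{var}(\hat{a})$ faster than noise grows. Passing no panel to
  `simulateEffects` yields the plain i.i.d. vector for tests that want
  it. Either way effects are marginally Gaussian and highly polygenic
  (largest single-marker share of $\sum|E|$ of order $1/m$).

Defaults describe a cattle-like study and are fixed conventions, not
estimates: 2000 markers; 40 panel haplotypes from 8 founders with
`switchRate = 0.01`; 19 individuals; full coverage 6.3x; base quality
Q = 20.54 (0.88% error); four traits with effect SDs 0.0011, 0.00063,
0.00048 and 0.00041 — the magnitudes typical of back-solved solutions
for hip height, body weight, fertility and condition scores on
600k-marker panels.

Seeding: every stochastic operation derives a documented substream from
one master seed (`seed + k * 100003 mod 2^31 - 1`, a distinct offset $k$
per operation), so identical configurations are bit-reproducible
end-to-end and operations stay independent of call order.

## What the checks do and do not show

The full sweep used by the test suite and the acceptance script runs
200 individuals by 2000 markers over coverages 6.3/4/2/1/0.5x, all
three fill methods and five seeds (about one to two minutes per seed on
one CPU). On that grid the package reproduces the expected qualitative
behaviour: correlations fall monotonically with coverage, homref and af
slopes rise well above 1 at 0.5x with af above homref, and the panel
imputer's slope stays nearest 1. These are properties of the method on
data whose generator is known to satisfy its assumptions. They do not
certify numeric performance on real sequencing data, where mapping
bias, non-uniform coverage, index hopping, cryptic relatedness to the
panel and array genotyping error all enter; the published analyses this
machinery mirrors were run on real animals whose sequence data are not
public, so their exact correlations and biases are not reproduced here.

## Numerical choices and degenerate inputs

* Tie-break at equal allele counts (both $\ge t$): heterozygote.
* Depth-1 loci are *called* (homozygous), not missing — the fill
  methods see only depth-0 loci.
* Coordinates are 1-based (mpileup/VCF convention); ref/alt are assumed
  on the forward strand; multi-allelic sites and indels are out of
  scope.
* Thinning to a lower coverage keeps each read independently with
  probability `target/full` — distributionally equivalent to
  subsampling reads before pileup when coverage is uniform.
* The mpileup base-quality column is ignored; quality enters only
  through the simulator's error rate and the run-summary statistics.
* Prediction refuses missing cells and misaligned locus lists
  (alignment is by chrom:pos:ref:alt; swapped-allele effect records are
  sign-flipped by `alignEffects`, never silently reordered).
* Degenerate evaluation inputs (zero-variance predictions, constant
  covariates, all-zero effects) raise errors rather than returning
  NaN.
* Monomorphic panel loci have undefined LD weights; they are skipped in
  the effect projection (weight 0) and contribute dosage `2p`
  ($0$ or $2$) under `af` fill.

## Known limitations

The mosaic panel is not a coalescent: allele-frequency spectra,
recombination hotspots and mutation are absent, and LD magnitude is
governed by just `nFounders` and `switchRate`. The LD imputer uses
marker-count windows, not genetic distance, and scales quadratically in
panel haplotypes (fine at 40; not designed for 2400). The 95% rule's
residual heterozygote loss (see above) is inherent to the genotyping
method, not an implementation artifact. GCTA-style back-solving of
effects from phenotypes, genotype likelihood models and HMM-based
low-coverage imputation are intentionally out of scope.
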