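# skimGEBV

Genomic breeding values (GEBVs) from low-coverage sequencing pileups.

Breeding values and polygenic scores are linear SNP-BLUP predictions: a
genotype matrix coded 0/1/2 in alternate-allele copies times a vector of
per-marker effects, `b̂ = M ĝ`. SNP arrays supply `M` essentially
error-free but slowly; portable sequencers can genotype the same loci
in-situ, at the price of few, error-prone reads per locus. skimGEBV is
for quantitative geneticists who want to quantify that price. It
provides:

* **Variable minimum-allele-count genotyping.** At depth `d`, a true
  heterozygote's alternate-read count is Binomial(d, ½). The caller
  demands at least `t(d)` reads of *each* allele, with `t(d)` the
  largest threshold retaining `P(t ≤ X ≤ d−t) ≥ 0.95` — as strict as
  possible against sequencing errors while keeping a 95% chance of
  seeing both alleles of a heterozygote. Zero-depth loci stay missing;
  single reads force a homozygous call.
* **Three missing-genotype strategies**: homozygous-reference (code 0),
  Hardy–Weinberg allele-frequency dosage (`2p`, continuous), and
  windowed haplotype-panel imputation exploiting linkage
  disequilibrium (plus an optional adapter to an external Beagle 5.1).
* **SNP-BLUP prediction and evaluation**: `â = N ĝ` from the
  sequence-derived matrix, compared to the array reference via genotype
  concordance classes (both / one / zero alleles correct), Pearson
  correlation, and the prediction-bias slope of the OLS regression of
  `b̂` on `â` (slope > 1 = under-dispersed predictions).
* **A founder-mosaic simulator** producing LD-structured haplotype
  panels, diploid individuals, polygenic LD-aligned marker effects and
  Poisson/Phred-error pileups, so the whole pipeline runs and is tested
  without any external data.

Standard formats are supported: samtools mpileup text in, VCF 4.2 and
TSV in/out.

## Worked example

Simulate a 50-animal study at 6.3x mean coverage over 1000 SNPs, thin
to 1x and 0.5x, genotype, fill missing loci all three ways, and compare
sequence-derived against array predictions:

```r
library(skimGEBV)

cfg <- simConfig(nMarkers = 1000, nIndividuals = 50,
                 coverage = 6.3, seed = 7)
report <- runExperiment(cfg, coverages = c(6.3, 1, 0.5),
                        methods = c("homref", "af", "ld"))
report[report$trait == "hip_height",
       c("coverage", "method", "pearson_r", "bias_slope",
         "conc_both_correct", "missing_rate")]
#>  coverage method pearson_r bias_slope conc_both_correct missing_rate
#>       6.3 homref     0.993      1.029             0.945      0.00196
#>       6.3     af     0.993      1.027             0.945      0.00196
#>       6.3     ld     0.993      1.026             0.945      0.00196
#>       1.0 homref     0.881      1.186             0.734      0.36674
#>       1.0     af     0.946      1.433             0.734      0.36674
#>       1.0     ld     0.949      0.910             0.734      0.36674
#>       0.5 homref     0.821      1.592             0.692      0.60528
#>       0.5     af     0.902      1.937             0.692      0.60528
#>       0.5     ld     0.896      0.809             0.692      0.60528
```

Reading the table: at full coverage all three fill methods agree with
the array predictions (r ≈ 0.99, slope ≈ 1). As coverage falls,
correlations drop and the two quick fills develop the characteristic
upward bias — slope 1.59 (homref) and 1.94 (af) at 0.5x, because
zero- or mean-filled loci shrink each individual's prediction toward 0
or the population mean while the reference spread is unchanged. The
panel imputer keeps the slope nearest 1 (0.81 at 0.5x) by recovering
genotypes from flanking called markers. `conc_both_correct` is the
fraction of called genotypes matching truth in both alleles before any
fill; `missing_rate` the fraction of zero-depth cells handed to the
fill method.

The threshold table itself:

```r
minAlleleCountTable(12)
#>    depth threshold    p_both
#> 1      1         1 0.0000000
#> 2      2         1 0.5000000
#> ...
#> 8      8         1 0.9921875
#> 9      9         2 0.9609375
#> 12    12         3 0.9614258
```

Lower-level entry points mirror the pipeline stages: `readMpileup()`,
`thinCounts()`, `genotypeAll()`, `fillHomref()` / `fillAF()` /
`imputeLD()`, `predictGebv()`, `concordance()`, `biasRegression()`,
`covariateEffect()`, and `runPipeline()` for a config-driven run that
writes all intermediate artifacts plus a provenance manifest. See the
vignette in `vignettes/` for the model, the simulator's design and its
limitations.

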