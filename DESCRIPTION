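Package: skimGEBV
Title: Genomic Breeding Values from Low-Coverage Sequencing Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic prediction from low-coverage (skim)
    sequencing of diploid individuals. Implements a variable
    minimum-allele-count genotyper that chooses depth-specific thresholds
    guaranteeing a target probability of observing both alleles of a
    heterozygote, three strategies for filling missing genotypes
    (homozygous-reference, Hardy-Weinberg allele-frequency dosage, and
    windowed haplotype-panel imputation with an optional adapter to an
    external Beagle executable), SNP-BLUP breeding-value prediction from
    dosage matrices and marker effects, and an evaluation layer reporting
    genotype concordance classes, prediction correlations and bias
    regression slopes against array-based references. A founder-mosaic
    simulator generates linkage-disequilibrium-structured haplotype
    panels, diploid individuals, polygenic marker effects and error-prone
    sequencing pileups so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
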