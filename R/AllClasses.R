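#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

LOCUS_COLUMNS <- c("chrom", "pos", "ref", "alt", "alt_freq", "locus_id")
CALL_SOURCES <- c("called", "missing", "filled-homref", "filled-af", "imputed-ld")

validLoci <- function(loci) {
    msg <- character()
    if (!all(LOCUS_COLUMNS %in% colnames(loci)))
        msg <- c(msg, paste("locus table must have columns:",
                            paste(LOCUS_COLUMNS, collapse = ", ")))
    else {
        if (any(loci$ref == loci$alt))
            msg <- c(msg, "ref and alt alleles must differ at every locus")
        if (any(loci$alt_freq < 0 | loci$alt_freq > 1))
            msg <- c(msg, "alt_freq must lie in [0, 1]")
        if (anyDuplicated(paste(loci$chrom, loci$pos)))
            msg <- c(msg, "(chrom, pos) must be unique within a locus list")
        if (any(loci$pos < 1))
            msg <- c(msg, "pos must be a 1-based positive coordinate")
    }
    msg
}

#' Haplotype reference panel
#'
#' A set of phased haplotypes over an ordered list of biallelic SNP loci,
#' used as the linkage-disequilibrium source for panel-based imputation.
#' Alleles are stored as a loci x haplotypes 0/1 matrix (0 = reference,
#' 1 = alternate). The locus table records, per locus, chromosome,
#' 1-based position, ref/alt alleles and the panel alternate-allele
#' frequency, which downstream allele-frequency imputation uses as the
#' population frequency.
#'
#' @slot alleles integer matrix, loci in rows, haplotypes in columns,
#'   entries 0 or 1.
#' @slot loci a \linkS4class{DataFrame} with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{alt_freq}, \code{locus_id}.
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
    slots = c(alleles = "matrix", loci = "DataFrame"))

setValidity("HaplotypePanel", function(object) {
    msg <- validLoci(object@loci)
    if (nrow(object@alleles) != nrow(object@loci))
        msg <- c(msg, "allele matrix row count must equal locus count")
    if (length(object@alleles) && !all(object@alleles %in% c(0L, 1L)))
        msg <- c(msg, "panel alleles must be 0 (ref) or 1 (alt)")
    if (ncol(object@alleles) < 1L)
        msg <- c(msg, "panel must contain at least one haplotype")
    if (length(msg)) msg else TRUE
})

#' Per-locus allele counts from a sequencing pileup
#'
#' A \linkS4class{SummarizedExperiment} holding, per locus (rows) and
#' individual (columns), the number of reads supporting the reference
#' allele, the alternate allele, and any other base. Depth for genotyping
#' purposes is \code{ref + alt}; other-allele reads are recorded but take
#' no part in calling (they would otherwise let sequencing errors at third
#' bases shift depth-dependent thresholds).
#'
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
    msg <- character()
    an <- names(assays(object))
    if (!all(c("ref", "alt", "other") %in% an))
        msg <- c(msg, "AlleleCounts needs assays 'ref', 'alt', 'other'")
    else {
        for (a in c("ref", "alt", "other"))
            if (any(assay(object, a) < 0))
                msg <- c(msg, paste0("assay '", a, "' has negative counts"))
    }
    msg <- c(msg, validLoci(rowData(object)))
    if (length(msg)) msg else TRUE
})

#' Genotype calls with provenance
#'
#' A \linkS4class{SummarizedExperiment} with a \code{dosage} assay
#' (alternate-allele dosage per locus and individual; \code{NA} while a
#' cell is missing) and a \code{source} assay recording where each value
#' came from: \code{"called"} (from read counts), \code{"missing"},
#' or one of the fill methods (\code{"filled-homref"}, \code{"filled-af"},
#' \code{"imputed-ld"}). Called cells always carry integer dosages in
#' \{0, 1, 2\}; allele-frequency fills are continuous in [0, 2].
#'
#' @exportClass GenotypeCalls
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
    msg <- character()
    an <- names(assays(object))
    if (!all(c("dosage", "source") %in% an))
        msg <- c(msg, "GenotypeCalls needs assays 'dosage' and 'source'")
    else {
        d <- assay(object, "dosage")
        s <- assay(object, "source")
        if (!all(s %in% CALL_SOURCES))
            msg <- c(msg, paste("source entries must be one of:",
                                paste(CALL_SOURCES, collapse = ", ")))
        if (any(is.na(d) != (s == "missing")))
            msg <- c(msg, "dosage must be NA exactly where source is 'missing'")
        dd <- d[!is.na(d)]
        if (length(dd) && (any(dd < 0) || any(dd > 2)))
            msg <- c(msg, "dosages must lie in [0, 2]")
        called <- !is.na(d) & s == "called"
        if (any(called) && !all(d[called] %in% c(0, 1, 2)))
            msg <- c(msg, "called dosages must be integers in {0, 1, 2}")
    }
    msg <- c(msg, validLoci(rowData(object)))
    if (length(msg)) msg else TRUE
})

#' Simulated true genotypes
#'
#' A \linkS4class{GenotypeCalls} object that additionally stores the two
#' realized haplotypes (\code{hap1}, \code{hap2} assays) each diploid
#' individual was built from, so that \code{dosage == hap1 + hap2} holds
#' by construction and recovery tests can reach the ground truth.
#'
#' @exportClass TrueGenotypes
setClass("TrueGenotypes", contains = "GenotypeCalls")

setValidity("TrueGenotypes", function(object) {
    msg <- character()
    an <- names(assays(object))
    if (!all(c("hap1", "hap2") %in% an))
        msg <- c(msg, "TrueGenotypes needs assays 'hap1' and 'hap2'")
    else {
        d <- assay(object, "dosage")
        h <- assay(object, "hap1") + assay(object, "hap2")
        if (any(d != h))
            msg <- c(msg, "dosage must equal hap1 + hap2")
    }
    if (length(msg)) msg else TRUE
})

#' Per-marker SNP-BLUP effects
#'
#' Additive effects of one copy of the alternate allele, one column per
#' trait, aligned to an ordered locus list. These are the back-solved
#' BLUP solutions a SNP-BLUP prediction multiplies a dosage matrix by;
#' estimating them from phenotypes is outside this package's scope.
#'
#' @slot loci locus table (same schema as \linkS4class{HaplotypePanel}).
#' @slot effects numeric matrix, loci x traits, finite values.
#' @exportClass MarkerEffects
setClass("MarkerEffects",
    slots = c(loci = "DataFrame", effects = "matrix"))

setValidity("MarkerEffects", function(object) {
    msg <- validLoci(object@loci)
    if (nrow(object@effects) != nrow(object@loci))
        msg <- c(msg, "effects matrix row count must equal locus count")
    if (!is.numeric(object@effects) || any(!is.finite(object@effects)))
        msg <- c(msg, "effects must be finite numeric values")
    if (is.null(colnames(object@effects)))
        msg <- c(msg, "effects matrix must have trait names as colnames")
    if (length(msg)) msg else TRUE
})

#' Genomic estimated breeding values
#'
#' Per-individual predictions (one column per trait) with provenance:
#' which genotype matrix role produced them (array reference \code{M} or
#' sequence-derived \code{N}), at what coverage, and after which fill
#' method.
#'
#' @slot values numeric matrix, individuals x traits.
#' @slot provenance named character vector (\code{role}, \code{coverage},
#'   \code{method}).
#' @exportClass GebvSet
setClass("GebvSet",
    slots = c(values = "matrix", provenance = "character"))

setValidity("GebvSet", function(object) {
    msg <- character()
    if (!is.numeric(object@values))
        msg <- c(msg, "values must be numeric")
    if (is.null(rownames(object@values)))
        msg <- c(msg, "values must carry sample ids as rownames")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the founder-mosaic simulator. Defaults describe a
#' desk-scale cattle-like study: 2000 markers, a 40-haplotype panel built
#' from 8 founders with a 1\% per-interval template switch rate, 19 study
#' individuals, mean coverage 6.3x, Phred base quality 20.54, and four
#' traits whose per-marker effect standard deviations are 0.0011,
#' 0.00063, 0.00048 and 0.00041.
#'
#' @slot nMarkers,nPanelHaplotypes,nIndividuals,nFounders positive integers.
#' @slot switchRate probability per adjacent-marker interval of switching
#'   founder template.
#' @slot afLow,afHigh bounds of the uniform founder alternate-allele
#'   frequency distribution.
#' @slot effectSd per-trait effect standard deviation (recycled to
#'   \code{nTraits}).
#' @slot nTraits number of traits; \code{traitNames} their labels.
#' @slot coverage mean reads per locus (x).
#' @slot baseQuality Phred-scaled base quality Q; per-base error rate is
#'   \code{10^(-Q/10)}.
#' @slot errorToOther if TRUE, erroneous reads land in the "other" count
#'   bucket rather than flipping ref<->alt.
#' @slot seed master RNG seed; operations draw documented substreams.
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        nMarkers = "integer", nPanelHaplotypes = "integer",
        nIndividuals = "integer", nFounders = "integer",
        switchRate = "numeric", afLow = "numeric", afHigh = "numeric",
        effectSd = "numeric", nTraits = "integer", traitNames = "character",
        coverage = "numeric", baseQuality = "numeric",
        errorToOther = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    for (s in c("nMarkers", "nPanelHaplotypes", "nIndividuals", "nFounders"))
        if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
    if (object@afLow <= 0 || object@afHigh >= 1 || object@afLow > object@afHigh)
        msg <- c(msg, "need 0 < afLow <= afHigh < 1")
    if (object@switchRate < 0 || object@switchRate > 1)
        msg <- c(msg, "switchRate must lie in [0, 1]")
    if (object@coverage < 0) msg <- c(msg, "coverage must be >= 0")
    if (object@baseQuality <= 0) msg <- c(msg, "baseQuality must be > 0")
    if (any(object@effectSd <= 0)) msg <- c(msg, "effectSd must be > 0")
    if (length(object@effectSd) != object@nTraits)
        msg <- c(msg, "effectSd length must equal nTraits")
    if (length(object@traitNames) != object@nTraits)
        msg <- c(msg, "traitNames length must equal nTraits")
    if (length(msg)) msg else TRUE
})
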