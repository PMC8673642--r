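#' Accessors for skimGEBV classes
#'
#' \code{dosage} returns the loci x individuals dosage matrix of a
#' \linkS4class{GenotypeCalls} object (NA = missing); \code{callSource}
#' the matching provenance matrix; \code{lociInfo} the locus table of any
#' locus-bearing object; \code{panelAlleles} the 0/1 allele matrix of a
#' \linkS4class{HaplotypePanel}; \code{effectValues} the loci x traits
#' effect matrix of a \linkS4class{MarkerEffects}; \code{gebvValues} the
#' individuals x traits prediction matrix of a \linkS4class{GebvSet};
#' \code{missingRate} the per-individual fraction of missing cells.
#'
#' @param x the object.
#' @return see details above.
#' @name accessors
#' @aliases dosage callSource lociInfo panelAlleles effectValues
#'   gebvValues missingRate
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("callSource", function(x) standardGeneric("callSource"))

#' @rdname accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname accessors
#' @export
setGeneric("panelAlleles", function(x) standardGeneric("panelAlleles"))

#' @rdname accessors
#' @export
setGeneric("effectValues", function(x) standardGeneric("effectValues"))

#' @rdname accessors
#' @export
setGeneric("gebvValues", function(x) standardGeneric("gebvValues"))

#' @rdname accessors
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))

#' @rdname accessors
setMethod("dosage", "GenotypeCalls", function(x) assay(x, "dosage"))

#' @rdname accessors
setMethod("callSource", "GenotypeCalls", function(x) assay(x, "source"))

#' @rdname accessors
setMethod("lociInfo", "SummarizedExperiment", function(x) rowData(x))

#' @rdname accessors
setMethod("lociInfo", "HaplotypePanel", function(x) x@loci)

#' @rdname accessors
setMethod("lociInfo", "MarkerEffects", function(x) x@loci)

#' @rdname accessors
setMethod("panelAlleles", "HaplotypePanel", function(x) x@alleles)

#' @rdname accessors
setMethod("effectValues", "MarkerEffects", function(x) x@effects)

#' @rdname accessors
setMethod("gebvValues", "GebvSet", function(x) x@values)

#' @rdname accessors
setMethod("missingRate", "GenotypeCalls",
    function(x) colMeans(is.na(assay(x, "dosage"))))

setMethod("show", "HaplotypePanel", function(object) {
    cat("HaplotypePanel:", ncol(object@alleles), "phased haplotypes x",
        nrow(object@alleles), "loci\n")
    af <- object@loci$alt_freq
    cat("  panel alt-allele frequency: ",
        sprintf("%.3f-%.3f (median %.3f)\n",
                min(af), max(af), stats::median(af)))
})

setMethod("show", "GenotypeCalls", function(object) {
    d <- assay(object, "dosage")
    cat(class(object), ":", nrow(d), "loci x", ncol(d), "individuals\n")
    src <- table(assay(object, "source"))
    cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
    cat(sprintf("  missing: %.1f%% of cells\n", 100 * mean(is.na(d))))
})

setMethod("show", "MarkerEffects", function(object) {
    cat("MarkerEffects:", nrow(object@effects), "loci x",
        ncol(object@effects), "traits (",
        paste(colnames(object@effects), collapse = ", "), ")\n")
})

setMethod("show", "GebvSet", function(object) {
    cat("GebvSet:", nrow(object@values), "individuals x",
        ncol(object@values), "traits\n")
    if (length(object@provenance))
        cat("  provenance:",
            paste(names(object@provenance), object@provenance,
                  sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nMarkers, "markers,",
        object@nPanelHaplotypes, "panel haplotypes (",
        object@nFounders, "founders, switch rate", object@switchRate, "),",
        object@nIndividuals, "individuals\n")
    cat("  coverage", object@coverage, "x, base quality Q",
        object@baseQuality, ", seed", object@seed, "\n")
})
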