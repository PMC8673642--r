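#' SNP-BLUP genomic prediction
#'
#' Computes per-individual predictions as the dosage-weighted sum of
#' marker effects: with an n x m dosage matrix (alternate-allele counts,
#' possibly continuous after imputation) and per-trait effect vectors,
#' the prediction is the matrix product of genotype dosages and effects —
#' the array-based reference prediction when the matrix holds array
#' calls, the sequence-derived prediction when it holds low-coverage
#' calls. Locus alignment between matrix and effects is verified by
#' (chrom, pos, ref, alt) identity; mismatches are an error, never
#' silently reordered, and any remaining MISSING cell is refused.
#'
#' @param calls a \linkS4class{GenotypeCalls} with no missing cells (run
#'   a fill method first).
#' @param effects a \linkS4class{MarkerEffects} over the same ordered
#'   loci.
#' @param role matrix role for provenance: \code{"M"} (array reference)
#'   or \code{"N"} (sequence-derived).
#' @param coverage,method optional provenance annotations.
#' @return a \linkS4class{GebvSet} (individuals x traits).
#' @export
#' @examples
#' loci <- S4Vectors::DataFrame(chrom = "1", pos = 100L, ref = "A",
#'     alt = "G", alt_freq = 0.5, locus_id = "snp1")
#' eff <- new("MarkerEffects", loci = loci,
#'     effects = matrix(0.5, 1, 1, dimnames = list("snp1", "bw")))
#' g <- matrix(2, 1, 1, dimnames = list("snp1", "ind1"))
#' s <- matrix("called", 1, 1, dimnames = dimnames(g))
#' calls <- skimGEBV:::newGenotypeCalls(g, s, loci)
#' gebvValues(predictGebv(calls, eff))   # 1.0
predictGebv <- function(calls, effects, role = c("N", "M"),
                        coverage = NA_character_,
                        method = NA_character_) {
    role <- match.arg(role)
    validObject(calls); validObject(effects)
    assertLociAligned(rowData(calls), effects@loci,
                      "genotype and marker-effect locus lists")
    g <- assay(calls, "dosage")
    if (anyNA(g)) {
        bad <- which(is.na(g), arr.ind = TRUE)[1L, ]
        stop("MISSING genotype at locus ",
             rowData(calls)$locus_id[bad[1L]], ", sample ",
             colnames(g)[bad[2L]],
             "; fill missing genotypes before prediction", call. = FALSE)
    }
    vals <- t(g) %*% effects@effects
    new("GebvSet", values = vals,
        provenance = c(role = role, coverage = as.character(coverage),
                       method = as.character(method)))
}

#' Per-marker share of the total SNP effect
#'
#' Returns, per trait, the signed proportion \code{E_i / sum(|E|)} each
#' marker contributes to the summed magnitude of all marker effects.
#' Absolute shares sum to 1 by construction; under a highly polygenic
#' architecture the largest share is of order 1/m.
#'
#' @param effects a \linkS4class{MarkerEffects}.
#' @return a loci x traits matrix of signed shares.
#' @export
#' @examples
#' # effects (1, -1) give shares (0.5, -0.5)
effectShare <- function(effects) {
    validObject(effects)
    tot <- colSums(abs(effects@effects))
    if (any(tot == 0))
        stop("all-zero effects for trait(s): ",
             paste(colnames(effects@effects)[tot == 0], collapse = ", "),
             call. = FALSE)
    sweep(effects@effects, 2L, tot, "/")
}

#' Align a marker-effects table to a locus list
#'
#' Reorders effect records (keyed by chrom, pos, ref, alt) to the target
#' locus order. Records whose ref/alt are swapped relative to the target
#' list have their alleles swapped and effect signs flipped (dosage
#' recoding d -> 2 - d changes the slope sign and moves the constant into
#' the intercept, which the evaluation regressions absorb). Unmatched
#' records and target loci without effects are reported in attributes.
#'
#' @param effectsTable data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and one numeric column per trait.
#' @param loci target locus table.
#' @return a \linkS4class{MarkerEffects} over \code{loci}; loci with no
#'   matching record get zero effects and are listed in the
#'   \code{"unmatchedLoci"} attribute; leftover records in
#'   \code{"unmatchedRecords"}.
#' @export
alignEffects <- function(effectsTable, loci) {
    loci <- lociAsDataFrame(loci)
    keyCols <- c("chrom", "pos", "ref", "alt")
    if (!all(keyCols %in% colnames(effectsTable)))
        stop("effects table needs columns chrom, pos, ref, alt",
             call. = FALSE)
    recKey <- do.call(paste, c(effectsTable[keyCols], sep = ":"))
    if (anyDuplicated(recKey))
        stop("duplicate (chrom, pos, ref, alt) keys in effects table",
             call. = FALSE)
    traitCols <- setdiff(colnames(effectsTable), keyCols)
    targetKey <- locusKey(loci)
    swappedKey <- paste(loci$chrom, loci$pos, loci$alt, loci$ref,
                        sep = ":")
    direct <- match(targetKey, recKey)
    swapped <- match(swappedKey, recKey)
    eff <- matrix(0, nrow = nrow(loci), ncol = length(traitCols),
                  dimnames = list(loci$locus_id, traitCols))
    sign <- ifelse(!is.na(direct), 1, ifelse(!is.na(swapped), -1, NA))
    take <- ifelse(!is.na(direct), direct, swapped)
    ok <- !is.na(take)
    for (tc in seq_along(traitCols))
        eff[ok, tc] <- sign[ok] * effectsTable[[traitCols[tc]]][take[ok]]
    out <- new("MarkerEffects", loci = loci, effects = eff)
    attr(out, "unmatchedLoci") <- loci$locus_id[!ok]
    attr(out, "unmatchedRecords") <-
        recKey[!seq_along(recKey) %in% take[ok]]
    out
}

#' Read and write marker-effect TSVs
#'
#' Columns \code{chrom}, \code{pos}, \code{ref}, \code{alt}, then one
#' column per trait.
#'
#' @param effects a \linkS4class{MarkerEffects}; \code{file} a path;
#'   \code{loci} target locus table for alignment on read.
#' @return \code{readEffectsTsv} a \linkS4class{MarkerEffects} aligned to
#'   \code{loci}; \code{writeEffectsTsv} the path, invisibly.
#' @name effectsTsv
NULL

#' @rdname effectsTsv
#' @export
writeEffectsTsv <- function(effects, file) {
    df <- cbind(as.data.frame(effects@loci[c("chrom", "pos", "ref", "alt")]),
                as.data.frame(effects@effects))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname effectsTsv
#' @export
readEffectsTsv <- function(file, loci) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
    alignEffects(df, loci)
}
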