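# Internal helpers shared across modules.

# Derived substream seeds: one master seed per run, each stochastic
# operation uses offset k so streams are reproducible and independent of
# call order. Kept below 2^31-1 so the result is a valid integer seed.
substreamSeed <- function(seed, k) {
    as.integer((as.numeric(seed) + k * 100003) %% 2147483647)
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# Locus identity key used wherever two locus lists must agree.
locusKey <- function(loci) {
    paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = ":")
}

assertLociAligned <- function(a, b, what = "locus lists") {
    ka <- locusKey(a); kb <- locusKey(b)
    if (length(ka) != length(kb) || any(ka != kb)) {
        bad <- if (length(ka) == length(kb)) which(ka != kb)[1L] else NA_integer_
        stop(what, " are not aligned",
             if (!is.na(bad)) paste0(" (first mismatch at index ", bad,
                                     ": ", ka[bad], " vs ", kb[bad], ")"),
             call. = FALSE)
    }
    invisible(TRUE)
}

lociAsDataFrame <- function(loci) {
    if (is.data.frame(loci)) loci <- S4Vectors::DataFrame(loci)
    loci
}

newGenotypeCalls <- function(dosage, source, loci, class = "GenotypeCalls",
                             extraAssays = list()) {
    se <- SummarizedExperiment(
        assays = c(list(dosage = dosage, source = source), extraAssays),
        rowData = lociAsDataFrame(loci))
    rownames(se) <- loci$locus_id
    new(class, se)
}
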