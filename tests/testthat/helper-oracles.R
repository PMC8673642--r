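suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

# Independent threshold oracle: enumerate all 2^d equally likely read
# outcomes of a heterozygote (each read ref or alt with probability 1/2)
# and find the largest t >= 1 whose central condition t <= #alt <= d - t
# holds in at least `target` of outcomes. No binomial CDF involved.
bruteForceThreshold <- function(d, target = 0.95) {
    outcomes <- 0:(2^d - 1)
    altCounts <- vapply(outcomes, function(x)
        sum(as.integer(intToBits(x)[1:d])), integer(1))
    for (t in rev(seq_len(max(1L, d %/% 2L)))) {
        ok <- mean(altCounts >= t & altCounts <= d - t)
        if (ok >= target) return(t)
    }
    1L
}

# Small locus table for constructed examples.
toyLoci <- function(m, p = rep(0.5, m)) {
    S4Vectors::DataFrame(
        chrom = rep("1", m), pos = seq_len(m) * 100L,
        ref = rep("A", m), alt = rep("G", m),
        alt_freq = p, locus_id = sprintf("L%03d", seq_len(m)))
}

# Wrap a dosage matrix (NA = missing) as GenotypeCalls.
toyCalls <- function(g, loci = toyLoci(nrow(g))) {
    if (is.null(colnames(g)))
        colnames(g) <- sprintf("s%02d", seq_len(ncol(g)))
    rownames(g) <- loci$locus_id
    src <- matrix(ifelse(is.na(g), "missing",
                         ifelse(g %% 1 == 0, "called", "filled-af")),
                  nrow = nrow(g), dimnames = dimnames(g))
    skimGEBV:::newGenotypeCalls(g, src, loci)
}

toyEffects <- function(eff, loci = toyLoci(nrow(as.matrix(eff)))) {
    eff <- as.matrix(eff)
    if (is.null(colnames(eff)))
        colnames(eff) <- paste0("t", seq_len(ncol(eff)))
    rownames(eff) <- loci$locus_id
    new("MarkerEffects", loci = loci, effects = eff)
}
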