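#' Depth-specific minimum allele count for heterozygote detection
#'
#' At sequencing depth \code{d}, the alternate-read count of a true
#' heterozygote is Binomial(d, 1/2). The threshold is the largest integer
#' \code{t >= 1} such that both alleles reach \code{t} reads with
#' probability at least \code{target}, i.e. \code{P(t <= X <= d - t) >=
#' target}. Demanding the largest such \code{t} filters as many
#' error-driven false heterozygotes as possible while still giving a true
#' heterozygote at least a \code{target} chance of showing both alleles.
#' At depths too small for any \code{t} to satisfy the condition
#' (\code{d < 6} at the default 0.95) the threshold falls back to 1.
#'
#' @param d read depth(s), >= 1; vectorized.
#' @param target required probability of observing both alleles of a
#'   heterozygote (default 0.95).
#' @return integer threshold(s) \code{t(d)}.
#' @export
#' @examples
#' minAlleleCount(c(1, 6, 10))   # 1, 1, 2
minAlleleCount <- function(d, target = 0.95) {
    if (any(d < 1)) stop("depth must be >= 1", call. = FALSE)
    if (target <= 0 || target >= 1)
        stop("target must lie in (0, 1)", call. = FALSE)
    one <- function(di) {
        for (t in rev(seq_len(max(1L, di %/% 2L)))) {
            p <- stats::pbinom(di - t, di, 0.5) - stats::pbinom(t - 1L, di, 0.5)
            if (p >= target) return(t)
        }
        1L
    }
    vapply(as.integer(d), one, integer(1))
}

#' Tabulate minimum allele counts by depth
#'
#' @param maxDepth largest depth to tabulate.
#' @param target both-allele probability (see [minAlleleCount()]).
#' @return data.frame with columns \code{depth}, \code{threshold} and the
#'   achieved central probability \code{p_both}.
#' @export
minAlleleCountTable <- function(maxDepth, target = 0.95) {
    d <- seq_len(maxDepth)
    t <- minAlleleCount(d, target)
    data.frame(depth = d, threshold = t,
               p_both = stats::pbinom(d - t, d, 0.5) -
                        stats::pbinom(t - 1L, d, 0.5))
}

#' Call one genotype from allele counts
#'
#' Depth (\code{ref + alt}; other-allele reads excluded) 0 yields
#' MISSING (NA); depth 1 a homozygous call for the single observed allele
#' (a heterozygote cannot be detected from one read); at depth >= 2, with
#' threshold \code{t = minAlleleCount(depth, target)}, both counts at or
#' above \code{t} give a heterozygote and otherwise the majority allele's
#' homozygote. Equal counts both reaching \code{t} are a heterozygote.
#'
#' @param refCount,altCount non-negative read counts.
#' @param target both-allele probability for the threshold rule.
#' @return dosage 0, 1, 2 or NA (missing).
#' @export
#' @examples
#' callGenotype(0, 1)   # 2: single-read homozygous rule
#' callGenotype(3, 3)   # 1
callGenotype <- function(refCount, altCount, target = 0.95) {
    d <- refCount + altCount
    if (d == 0) return(NA_real_)
    if (d == 1) return(if (altCount == 1) 2 else 0)
    t <- minAlleleCount(d, target)
    if (refCount >= t && altCount >= t) 1
    else if (altCount > refCount) 2
    else 0
}

#' Genotype all loci and samples by the variable allele count method
#'
#' Vectorized application of the depth-specific threshold rule across an
#' allele-count matrix: loci are grouped by exact integer depth and each
#' group is called against its own minimum allele count — the finest
#' version of grouping loci with similar coverage. Cells with zero
#' usable depth are left MISSING for a fill method to handle.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param target both-allele probability (default 0.95).
#' @return a \linkS4class{GenotypeCalls}; per-sample missingness is
#'   available via [missingRate()].
#' @export
genotypeAll <- function(counts, target = 0.95) {
    validObject(counts)
    refC <- assay(counts, "ref")
    altC <- assay(counts, "alt")
    d <- refC + altC
    g <- matrix(NA_real_, nrow = nrow(d), ncol = ncol(d),
                dimnames = dimnames(d))
    # depth 1: homozygous for the observed allele
    g[d == 1 & altC == 1] <- 2
    g[d == 1 & refC == 1] <- 0
    ge2 <- d >= 2
    if (any(ge2)) {
        tmap <- minAlleleCount(seq_len(max(d)), target)
        t <- matrix(0L, nrow = nrow(d), ncol = ncol(d))
        t[ge2] <- tmap[d[ge2]]
        het <- ge2 & refC >= t & altC >= t
        g[het] <- 1
        hom <- ge2 & !het
        g[hom & altC > refC] <- 2
        g[hom & refC >= altC] <- 0
    }
    src <- matrix(ifelse(is.na(g), "missing", "called"),
                  nrow = nrow(g), dimnames = dimnames(g))
    newGenotypeCalls(g, src, rowData(counts))
}
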