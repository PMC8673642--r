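#' Fill missing genotypes as homozygous reference
#'
#' The non-imputed strategy: every MISSING cell becomes dosage 0
#' (source \code{"filled-homref"}); called cells are untouched. Because a
#' homozygous-reference cell contributes nothing to a SNP-BLUP product,
#' individuals with more missing loci receive systematically smaller
#' predictions, which is the mechanism behind the method's upward bias
#' slope at low coverage.
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @return a \linkS4class{GenotypeCalls} with no missing cells.
#' @export
fillHomref <- function(calls) {
    validObject(calls)
    g <- assay(calls, "dosage")
    s <- assay(calls, "source")
    miss <- is.na(g)
    g[miss] <- 0
    s[miss] <- "filled-homref"
    newGenotypeCalls(g, s, rowData(calls))
}

#' Fill missing genotypes with the Hardy-Weinberg expected dosage
#'
#' The allele-frequency strategy: a MISSING cell at a locus with
#' population alternate-allele frequency \code{p} receives the continuous
#' dosage \code{0*(1-p)^2 + 1*2p(1-p) + 2*p^2 = 2p}, the expected
#' genotype code under Hardy-Weinberg equilibrium. This keeps every
#' individual's prediction centred on the population mean at missing
#' loci — accurate on average but regressing individual predictions
#' toward the mean as missingness grows.
#'
#' @param calls a \linkS4class{GenotypeCalls} whose locus table carries
#'   \code{alt_freq}.
#' @return a \linkS4class{GenotypeCalls} with no missing cells; filled
#'   dosages are continuous in [0, 2].
#' @export
fillAF <- function(calls) {
    validObject(calls)
    p <- rowData(calls)$alt_freq
    if (any(p < 0 | p > 1))
        stop("alt_freq outside [0, 1]", call. = FALSE)
    g <- assay(calls, "dosage")
    s <- assay(calls, "source")
    miss <- is.na(g)
    g[miss] <- (2 * p)[row(g)[miss]]
    s[miss] <- "filled-af"
    newGenotypeCalls(g, s, rowData(calls))
}

#' Impute missing genotypes from a haplotype panel
#'
#' A windowed haplotype-pair matcher exploiting local linkage
#' disequilibrium: for each missing cell, the up-to-\code{K} nearest
#' called loci on each side form a window; every (ordered) pair of panel
#' haplotypes is scored by how many window loci its summed dosage matches
#' the individual's calls at; the cell is imputed as the mean dosage of
#' all best-scoring pairs at that locus (ties averaged, so the result is
#' deterministic and may be fractional). Cells of individuals with no
#' called loci at all fall back to the Hardy-Weinberg dosage \code{2p}
#' (the count of such cells is recorded in the \code{"afFallbackCells"}
#' attribute).
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param panel a \linkS4class{HaplotypePanel} over the same ordered
#'   loci.
#' @param K maximum called loci per window side (default 10).
#' @return a \linkS4class{GenotypeCalls} with no missing cells.
#' @export
imputeLD <- function(calls, panel, K = 10L) {
    validObject(calls); validObject(panel)
    if (ncol(panel@alleles) < 1L)
        stop("empty haplotype panel", call. = FALSE)
    assertLociAligned(rowData(calls), panel@loci,
                      "genotype and panel locus lists")
    H <- ncol(panel@alleles)
    # unordered pair index (i <= j); off-diagonal pairs occur twice among
    # ordered pairs, so they get weight 2 in tie averaging
    pi1 <- rep(seq_len(H), times = H - seq_len(H) + 1L)
    pi2 <- unlist(lapply(seq_len(H), function(i) i:H))
    w <- ifelse(pi1 == pi2, 1, 2)
    pairDosage <- panel@alleles[, pi1, drop = FALSE] +
                  panel@alleles[, pi2, drop = FALSE]   # m x P
    g <- assay(calls, "dosage")
    s <- assay(calls, "source")
    p2 <- 2 * rowData(calls)$alt_freq
    nFallback <- 0L
    P <- length(pi1)
    for (ind in seq_len(ncol(g))) {
        gi <- g[, ind]
        missIdx <- which(is.na(gi))
        if (!length(missIdx)) next
        calledIdx <- which(!is.na(gi))
        if (!length(calledIdx)) {
            g[missIdx, ind] <- p2[missIdx]
            s[missIdx, ind] <- "filled-af"
            nFallback <- nFallback + length(missIdx)
            next
        }
        nc <- length(calledIdx)
        # nCalled x P match indicators, column-cumulated so any window
        # score is one subtraction; per-column cumsum done on the
        # flattened vector with column-boundary correction (no apply)
        C <- pairDosage[calledIdx, , drop = FALSE] == gi[calledIdx]
        csFlat <- cumsum(as.vector(C))
        colEnd <- csFlat[seq_len(P) * nc]
        cs <- matrix(csFlat, nrow = nc) -
              rep(c(0, colEnd[-P]), each = nc)
        j <- findInterval(missIdx, calledIdx)
        lo <- pmax(1L, j - K + 1L)
        hi <- pmin(nc, j + K)
        S <- cs[hi, , drop = FALSE] -
             rbind(0, cs)[lo, , drop = FALSE]   # nMiss x P window scores
        bestVal <- S[cbind(seq_along(missIdx), max.col(S, ties.method = "first"))]
        best <- S == bestVal
        Dm <- pairDosage[missIdx, , drop = FALSE]
        g[missIdx, ind] <- as.vector(((best * Dm) %*% w) / (best %*% w))
        s[missIdx, ind] <- "imputed-ld"
    }
    out <- newGenotypeCalls(g, s, rowData(calls))
    attr(out, "afFallbackCells") <- nFallback
    out
}

#' Impute missing genotypes with an external Beagle executable
#'
#' Adapter around Beagle v5.1: writes the called genotypes as a VCF with
#' missing GT fields, invokes the external program against a phased
#' reference panel VCF with effective population size \code{ne} (default
#' 100000) and the given \code{window} setting (100, raised towards a
#' whole-chromosome window such as 158 cM for very sparse 0.5x data so
#' called markers overlap the panel on every chromosome), and reads the
#' imputed genotypes back as dosages. The executable is an optional
#' dependency: when absent this function stops with an informative error
#' and [imputeLD()] is the built-in alternative.
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param panelVcf path to the phased reference panel VCF.
#' @param beagleJar path to the Beagle jar (default: \code{beagle.jar} on
#'   the search path).
#' @param javaBin java executable.
#' @param ne effective population size parameter.
#' @param window Beagle window parameter.
#' @param workDir scratch directory for intermediate files.
#' @return a \linkS4class{GenotypeCalls} with no missing cells.
#' @export
beagleImpute <- function(calls, panelVcf,
                         beagleJar = Sys.which("beagle.jar"),
                         javaBin = Sys.which("java"),
                         ne = 100000, window = 100,
                         workDir = tempfile("beagle")) {
    validObject(calls)
    if (!nzchar(beagleJar) || !file.exists(beagleJar) || !nzchar(javaBin))
        stop("external Beagle executable not available; install Beagle ",
             "v5.1 and pass beagleJar=, or use imputeLD() for the ",
             "built-in haplotype-panel imputer", call. = FALSE)
    dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
    gtVcf <- file.path(workDir, "calls.vcf")
    writeGenotypeVcf(calls, gtVcf)
    outPrefix <- file.path(workDir, "imputed")
    status <- system2(javaBin,
        c("-jar", shQuote(beagleJar),
          paste0("gt=", gtVcf), paste0("ref=", panelVcf),
          paste0("ne=", format(ne, scientific = FALSE)),
          paste0("window=", window),
          paste0("out=", outPrefix)),
        stdout = file.path(workDir, "beagle.log"),
        stderr = file.path(workDir, "beagle.log"))
    if (status != 0)
        stop("Beagle exited with status ", status, "; see ",
             file.path(workDir, "beagle.log"), call. = FALSE)
    imputed <- readGenotypeVcf(paste0(outPrefix, ".vcf.gz"),
                               rowData(calls))
    g0 <- assay(calls, "dosage")
    s <- assay(calls, "source")
    s[is.na(g0)] <- "imputed-ld"
    newGenotypeCalls(assay(imputed, "dosage"), s, rowData(calls))
}

#' Apply a fill method by name
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param method one of \code{"homref"}, \code{"af"}, \code{"ld"}.
#' @param panel haplotype panel (required for \code{"ld"}).
#' @param K window size for \code{"ld"}.
#' @return a filled \linkS4class{GenotypeCalls}.
#' @export
fillMissing <- function(calls, method = c("homref", "af", "ld"),
                        panel = NULL, K = 10L) {
    method <- match.arg(method)
    switch(method,
        homref = fillHomref(calls),
        af = fillAF(calls),
        ld = {
            if (is.null(panel))
                stop("method 'ld' needs a haplotype panel", call. = FALSE)
            imputeLD(calls, panel, K)
        })
}
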