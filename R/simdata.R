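#' Build a simulation configuration
#'
#' Constructor with desk-scale defaults for a cattle-like low-coverage
#' genotyping study: a linkage-disequilibrium-structured haplotype panel
#' built as founder mosaics, 19 diploid study individuals, mean
#' sequencing coverage 6.3x at Phred base quality 20.54, and four highly
#' polygenic traits whose per-marker effect standard deviations follow
#' typical back-solved SNP-BLUP solutions (order 1e-3 and below).
#'
#' @param nMarkers number of biallelic SNP loci.
#' @param nPanelHaplotypes phased haplotypes in the reference panel.
#' @param nIndividuals diploid study individuals.
#' @param nFounders founder haplotypes the mosaics copy from.
#' @param switchRate per-interval probability of switching founder
#'   template; 0 gives exact founder copies (maximal LD), 1 destroys LD.
#' @param afLow,afHigh founder alternate-allele frequency bounds
#'   (Uniform).
#' @param effectSd per-trait marker-effect standard deviation; recycled
#'   or truncated to \code{nTraits}.
#' @param nTraits number of traits.
#' @param traitNames trait labels.
#' @param coverage mean reads per locus (x).
#' @param baseQuality Phred-scaled per-base quality Q; error rate
#'   \code{10^(-Q/10)}.
#' @param errorToOther route erroneous bases to the "other" allele bucket
#'   instead of flipping ref<->alt (exercises other-allele handling).
#' @param seed master seed; every operation derives a documented
#'   substream from it.
#' @return a validated \linkS4class{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(nMarkers = 200, nIndividuals = 10, seed = 1)
#' cfg
simConfig <- function(nMarkers = 2000L, nPanelHaplotypes = 40L,
                      nIndividuals = 19L, nFounders = 8L,
                      switchRate = 0.01, afLow = 0.1, afHigh = 0.9,
                      effectSd = c(0.0011, 0.00063, 0.00048, 0.00041),
                      nTraits = 4L,
                      traitNames = c("hip_height", "body_weight",
                                     "cl_score", "body_condition_score"),
                      coverage = 6.3, baseQuality = 20.54,
                      errorToOther = FALSE, seed = 1L) {
    nTraits <- as.integer(nTraits)
    effectSd <- rep_len(effectSd, nTraits)
    if (length(traitNames) != nTraits)
        traitNames <- paste0("trait", seq_len(nTraits))
    new("SimConfig",
        nMarkers = as.integer(nMarkers),
        nPanelHaplotypes = as.integer(nPanelHaplotypes),
        nIndividuals = as.integer(nIndividuals),
        nFounders = as.integer(nFounders),
        switchRate = switchRate, afLow = afLow, afHigh = afHigh,
        effectSd = effectSd, nTraits = nTraits, traitNames = traitNames,
        coverage = coverage, baseQuality = baseQuality,
        errorToOther = errorToOther, seed = as.integer(seed))
}

# Mosaic copying shared by panel construction and individual sampling:
# each output haplotype copies one template, switching to a uniformly
# drawn template between adjacent markers with probability switchRate.
mosaicFrom <- function(templates, nOut, switchRate) {
    m <- nrow(templates)
    nT <- ncol(templates)
    out <- matrix(0L, nrow = m, ncol = nOut)
    for (j in seq_len(nOut)) {
        seg <- if (m > 1L)
            cumsum(c(1L, stats::runif(m - 1L) < switchRate))
        else 1L
        picks <- sample.int(nT, max(seg), replace = TRUE)
        out[, j] <- templates[cbind(seq_len(m), picks[seg])]
    }
    out
}

makeLocusTable <- function(m, altFreq) {
    S4Vectors::DataFrame(
        chrom = rep("1", m),
        pos = seq_len(m) * 1000L,
        ref = rep("A", m),
        alt = rep("G", m),
        alt_freq = altFreq,
        locus_id = sprintf("snp%05d", seq_len(m)))
}

#' Simulate an LD-structured haplotype reference panel
#'
#' Draws \code{nFounders} founder haplotypes marker-wise
#' Bernoulli(\code{p_i}) with \code{p_i ~ Uniform(afLow, afHigh)}, then
#' builds each panel haplotype as a founder mosaic: copy one founder,
#' switching to a uniformly drawn founder between adjacent markers with
#' probability \code{switchRate}. Small switch rates give long shared
#' haplotype stretches (strong local LD for panel-based imputation to
#' exploit); \code{switchRate = 1} reduces adjacent-marker correlation to
#' the founder-frequency baseline. The locus table records the empirical
#' panel alternate-allele frequency, which downstream allele-frequency
#' imputation treats as the population frequency.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{HaplotypePanel}; deterministic given
#'   \code{cfg@seed}.
#' @export
#' @examples
#' panel <- simulatePanel(simConfig(nMarkers = 100, seed = 7))
#' dim(panelAlleles(panel))
simulatePanel <- function(cfg) {
    validObject(cfg)
    withSeed(substreamSeed(cfg@seed, 1L), {
        m <- cfg@nMarkers
        p <- stats::runif(m, cfg@afLow, cfg@afHigh)
        founders <- matrix(
            as.integer(stats::runif(m * cfg@nFounders) < p),
            nrow = m, ncol = cfg@nFounders)
        alleles <- mosaicFrom(founders, cfg@nPanelHaplotypes, cfg@switchRate)
        colnames(alleles) <- sprintf("hap%03d", seq_len(ncol(alleles)))
        loci <- makeLocusTable(m, rowMeans(alleles))
        new("HaplotypePanel", alleles = alleles, loci = loci)
    })
}

#' Sample diploid individuals from a haplotype panel
#'
#' Each individual receives two haplotypes generated by the same mosaic
#' process used to build the panel, this time copying panel haplotypes as
#' templates; the genotype dosage is their sum. The realized haplotypes
#' are kept so recovery tests can compare against ground truth.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param nIndividuals number of diploid individuals (>= 1).
#' @param seed RNG seed for this operation.
#' @param switchRate mosaic switch probability (match the panel's for a
#'   population with the panel's LD structure).
#' @return a \linkS4class{TrueGenotypes}.
#' @export
sampleIndividuals <- function(panel, nIndividuals, seed,
                              switchRate = 0.01) {
    validObject(panel)
    if (nIndividuals < 1L)
        stop("nIndividuals must be >= 1", call. = FALSE)
    withSeed(substreamSeed(seed, 2L), {
        h1 <- mosaicFrom(panel@alleles, nIndividuals, switchRate)
        h2 <- mosaicFrom(panel@alleles, nIndividuals, switchRate)
        d <- h1 + h2
        ids <- sprintf("ind%03d", seq_len(nIndividuals))
        colnames(d) <- colnames(h1) <- colnames(h2) <- ids
        src <- matrix("called", nrow = nrow(d), ncol = ncol(d),
                      dimnames = dimnames(d))
        newGenotypeCalls(d, src, panel@loci, class = "TrueGenotypes",
                         extraAssays = list(hap1 = h1, hap2 = h2))
    })
}

#' Simulate polygenic marker effects
#'
#' Per-trait effects for a highly polygenic architecture in which no
#' single marker carries more than a vanishing share of the summed
#' absolute effect. An i.i.d. Normal(0, 1) latent polygenic vector is
#' drawn per trait; when a panel is supplied the reported marker effects
#' are its projection through the empirical panel linkage
#' disequilibrium (a banded correlation smoothing over
#' \code{ldWindow} flanking markers), rescaled so each trait's marker
#' effects have standard deviation \code{effectSd}. This mimics
#' back-solved SNP-BLUP solutions, which spread each underlying signal
#' across markers in LD with aligned signs — the property that makes
#' array and sequence-derived predictions of the same individuals agree
#' through different subsets of observed markers. Without a panel the
#' latent vector is returned directly (pure i.i.d. effects).
#' Marginally the effects are Gaussian either way. The largest
#' per-marker share \code{|E_i| / sum(|E|)} is recorded as attribute
#' \code{"maxShare"} for inspection; nothing is rejected.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param panel optional \linkS4class{HaplotypePanel} supplying the
#'   empirical LD structure (and the locus table).
#' @param loci locus table when no panel is given (defaults to a
#'   generic table of \code{cfg@nMarkers} loci).
#' @param ldWindow flanking markers on each side used for the LD
#'   projection (default 50).
#' @return a \linkS4class{MarkerEffects}; deterministic given
#'   \code{cfg@seed}.
#' @export
simulateEffects <- function(cfg, panel = NULL, loci = NULL,
                            ldWindow = 50L) {
    validObject(cfg)
    if (!is.null(panel)) loci <- panel@loci
    if (is.null(loci))
        loci <- makeLocusTable(cfg@nMarkers, rep(0.5, cfg@nMarkers))
    withSeed(substreamSeed(cfg@seed, 3L), {
        m <- nrow(loci)
        beta <- matrix(stats::rnorm(m * cfg@nTraits), nrow = m)
        if (!is.null(panel) && ldWindow > 0L) {
            Z <- panelZScores(panel@alleles)
            eff <- beta
            H1 <- ncol(panel@alleles) - 1L
            for (k in seq_len(min(ldWindow, m - 1L))) {
                i <- seq_len(m - k)
                rk <- rowSums(Z[i, , drop = FALSE] *
                              Z[i + k, , drop = FALSE]) / H1
                eff[i, ] <- eff[i, ] + rk * beta[i + k, , drop = FALSE]
                eff[i + k, ] <- eff[i + k, ] + rk * beta[i, , drop = FALSE]
            }
        } else {
            eff <- beta
        }
        eff <- sweep(eff, 2L, cfg@effectSd / apply(eff, 2L, stats::sd), "*")
        dimnames(eff) <- list(loci$locus_id, cfg@traitNames)
        me <- new("MarkerEffects", loci = lociAsDataFrame(loci),
                  effects = eff)
        attr(me, "maxShare") <- max(abs(
            sweep(eff, 2L, colSums(abs(eff)), "/")))
        me
    })
}

# Standardized panel allele rows (monomorphic loci -> all zero).
panelZScores <- function(alleles) {
    mu <- rowMeans(alleles)
    sd <- apply(alleles, 1L, stats::sd)
    Z <- (alleles - mu) / ifelse(sd == 0, Inf, sd)
    Z
}

#' Simulate a low-coverage sequencing pileup
#'
#' Per individual and locus, read depth is Poisson(\code{coverage}); each
#' read's allele is drawn from the true genotype (homozygote: that
#' allele; heterozygote: fair coin) and then corrupted at the per-base
#' error rate \code{e = 10^(-baseQuality/10)} — by default flipped to the
#' opposite allele; with \code{errorToOther = TRUE} recorded as a third
#' ("other") base instead. Reads are collapsed directly to per-locus
#' allele counts; read lengths and mapping are not modelled.
#'
#' @param truth a \linkS4class{TrueGenotypes}.
#' @param cfg a \linkS4class{SimConfig} (supplies coverage, base quality
#'   and the error routing switch).
#' @return an \linkS4class{AlleleCounts}; deterministic given
#'   \code{cfg@seed}.
#' @export
simulatePileup <- function(truth, cfg) {
    validObject(truth); validObject(cfg)
    withSeed(substreamSeed(cfg@seed, 4L), {
        g <- assay(truth, "dosage")
        n <- length(g)
        depth <- matrix(stats::rpois(n, cfg@coverage),
                        nrow = nrow(g), dimnames = dimnames(g))
        e <- phredErrorRate(cfg@baseQuality)
        if (cfg@errorToOther) {
            other <- matrix(stats::rbinom(n, depth, e), nrow = nrow(g))
            clean <- depth - other
            pAlt <- g / 2
            alt <- matrix(stats::rbinom(n, clean, pAlt), nrow = nrow(g))
            ref <- clean - alt
        } else {
            # P(read reports alt) by true dosage: e, 1/2, 1-e
            pAlt <- matrix(c(e, 0.5, 1 - e)[g + 1L], nrow = nrow(g))
            alt <- matrix(stats::rbinom(n, depth, pAlt), nrow = nrow(g))
            ref <- depth - alt
            other <- matrix(0L, nrow = nrow(g), ncol = ncol(g))
        }
        dimnames(ref) <- dimnames(alt) <- dimnames(other) <- dimnames(g)
        AlleleCounts(ref, alt, other, rowData(truth))
    })
}

#' Construct an AlleleCounts object from count matrices
#'
#' @param ref,alt,other loci x individuals non-negative integer matrices.
#' @param loci locus table (see \linkS4class{HaplotypePanel}).
#' @return an \linkS4class{AlleleCounts}.
#' @export
AlleleCounts <- function(ref, alt, other = NULL, loci) {
    if (is.null(other))
        other <- matrix(0L, nrow = nrow(ref), ncol = ncol(ref),
                        dimnames = dimnames(ref))
    loci <- lociAsDataFrame(loci)
    se <- SummarizedExperiment(
        assays = list(ref = ref, alt = alt, other = other),
        rowData = loci)
    rownames(se) <- loci$locus_id
    new("AlleleCounts", se)
}
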