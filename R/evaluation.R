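#' Genotype concordance classes
#'
#' Compares two hard-called dosage matrices cell by cell and scores each
#' comparison by the number of correctly called alleles: \code{2 -
#' |g_test - g_ref|}, i.e. 2 (both alleles agree), 1 (one allele wrong —
#' typically a heterozygote called homozygous at low depth) or 0
#' (opposing homozygotes). Cells that are MISSING in either matrix are
#' excluded from the proportions and counted separately.
#'
#' @param test,ref \linkS4class{GenotypeCalls} or integer dosage
#'   matrices of the same shape and locus order, hard-called (integer
#'   dosages only).
#' @return named list: \code{proportions} (\code{both_correct},
#'   \code{one_wrong}, \code{both_wrong}; sums to 1), \code{nCompared},
#'   \code{nMissing}.
#' @export
#' @examples
#' concordance(matrix(c(0, 1, 2)), matrix(c(0, 2, 0)))
concordance <- function(test, ref) {
    gt <- if (is(test, "GenotypeCalls")) assay(test, "dosage") else test
    gr <- if (is(ref, "GenotypeCalls")) assay(ref, "dosage") else ref
    if (!all(dim(gt) == dim(gr)))
        stop("matrices must have identical shape", call. = FALSE)
    ok <- !is.na(gt) & !is.na(gr)
    if (any(gt[ok] %% 1 != 0) || any(gr[ok] %% 1 != 0))
        stop("concordance requires hard calls (integer dosages)",
             call. = FALSE)
    correct <- 2 - abs(gt[ok] - gr[ok])
    n <- sum(ok)
    props <- c(both_correct = sum(correct == 2),
               one_wrong = sum(correct == 1),
               both_wrong = sum(correct == 0)) / n
    list(proportions = props, nCompared = n,
         nMissing = sum(!ok))
}

#' Prediction bias regression
#'
#' Ordinary least squares of the reference (array) predictions on the
#' test (sequence-derived) predictions, with intercept. The slope is the
#' bias statistic: 1 means the test predictions are on the same scale as
#' the reference; slope > 1 means they are under-dispersed
#' (under-estimated spread), as happens when missing genotypes are
#' filled with zeros or population means.
#'
#' @param bHat reference predictions (numeric vector or single-trait
#'   \linkS4class{GebvSet}).
#' @param aHat test predictions, same individuals.
#' @return named list: \code{slope}, \code{intercept}.
#' @export
#' @examples
#' biasRegression(c(0, 1, 2), c(0, 0.5, 1))$slope   # 2
biasRegression <- function(bHat, aHat) {
    b <- asPredVector(bHat); a <- asPredVector(aHat)
    if (length(a) != length(b))
        stop("prediction vectors must have equal length", call. = FALSE)
    if (stats::var(a) == 0)
        stop("zero variance in test predictions; bias undefined",
             call. = FALSE)
    fit <- stats::lm(b ~ a)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]))
}

asPredVector <- function(x) {
    if (is(x, "GebvSet")) {
        if (ncol(x@values) != 1L)
            stop("pass one trait at a time (single-column GebvSet)",
                 call. = FALSE)
        as.vector(x@values)
    } else as.numeric(x)
}

#' Pearson correlation of two prediction vectors
#'
#' @param bHat,aHat numeric vectors or single-trait
#'   \linkS4class{GebvSet}s over the same individuals.
#' @return Pearson product-moment correlation.
#' @export
gebvCorrelation <- function(bHat, aHat) {
    b <- asPredVector(bHat); a <- asPredVector(aHat)
    if (stats::var(a) == 0 || stats::var(b) == 0)
        stop("degenerate (zero-variance) prediction vector", call. = FALSE)
    stats::cor(b, a)
}

#' Covariate effect on prediction residuals
#'
#' Two-stage test of whether a per-individual covariate (read length,
#' base quality, effective mapping percentage, ...) explains disagreement
#' between reference and test predictions: stage 1 regresses the
#' reference predictions on the test predictions; stage 2 regresses the
#' stage-1 residuals on the covariate and reports the slope, its
#' standard error and the two-sided t-test p-value. Following the usual
#' reporting convention for a handful of individually examined
#' covariates, no multiple-testing correction is applied and
#' significance is declared at p <= 0.01.
#'
#' @param bHat,aHat prediction vectors (reference, test).
#' @param x covariate values, one per individual.
#' @param alpha significance threshold (default 0.01).
#' @return named list: \code{slope}, \code{se}, \code{p},
#'   \code{significant}.
#' @export
covariateEffect <- function(bHat, aHat, x, alpha = 0.01) {
    b <- asPredVector(bHat); a <- asPredVector(aHat)
    x <- as.numeric(x)
    if (length(unique(x)) < 2L)
        stop("degenerate covariate", call. = FALSE)
    if (length(b) < 4L)
        stop("need at least 4 individuals", call. = FALSE)
    r <- stats::resid(stats::lm(b ~ a))
    fit <- stats::lm(r ~ x)
    sm <- summary(fit)$coefficients
    list(slope = sm["x", "Estimate"], se = sm["x", "Std. Error"],
         p = sm["x", "Pr(>|t|)"],
         significant = sm["x", "Pr(>|t|)"] <= alpha)
}
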