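#' Run a full simulated coverage x fill-method x trait sweep
#'
#' Orchestrates the whole pipeline on synthetic data: simulate an
#' LD-structured haplotype panel, diploid individuals and polygenic
#' marker effects; take the true genotypes as the array reference matrix
#' M and compute reference predictions; simulate a full-coverage pileup,
#' thin it to each target coverage, genotype with the variable minimum
#' allele count rule, fill missing cells by each requested method, and
#' predict. Each (trait, coverage, method) cell reports the Pearson
#' correlation between sequence-derived and reference predictions, the
#' bias regression slope and intercept, the pre-fill concordance class
#' proportions of the called genotypes against truth, and the mean
#' missing rate.
#'
#' @param cfg a \linkS4class{SimConfig}; \code{cfg@coverage} is the full
#'   coverage the pileup is simulated at.
#' @param coverages coverage grid; values below \code{cfg@coverage} are
#'   obtained by binomial thinning of the full-coverage counts (the full
#'   coverage itself is included by default).
#' @param methods fill methods to sweep over.
#' @param K window size for the LD imputer.
#' @param target both-allele probability for the genotyper.
#' @return a data.frame, one row per (trait, coverage, method), columns
#'   \code{trait}, \code{coverage}, \code{method}, \code{pearson_r},
#'   \code{bias_slope}, \code{bias_intercept}, \code{conc_both_correct},
#'   \code{conc_one_wrong}, \code{conc_both_wrong}, \code{missing_rate},
#'   \code{n_individuals}, \code{n_loci}. Deterministic given
#'   \code{cfg@seed}.
#' @export
#' @examples
#' cfg <- simConfig(nMarkers = 300, nIndividuals = 30, coverage = 4,
#'                  seed = 11)
#' rep <- runExperiment(cfg, coverages = c(4, 1),
#'                      methods = c("homref", "af"))
#' head(rep)
runExperiment <- function(cfg,
                          coverages = c(cfg@coverage, 4, 2, 1, 0.5),
                          methods = c("homref", "af", "ld"),
                          K = 10L, target = 0.95) {
    validObject(cfg)
    coverages <- sort(unique(pmin(coverages, cfg@coverage)),
                      decreasing = TRUE)
    panel <- simulatePanel(cfg)
    truth <- sampleIndividuals(panel, cfg@nIndividuals, cfg@seed,
                               switchRate = cfg@switchRate)
    effects <- simulateEffects(cfg, panel = panel)
    bHat <- predictGebv(truth, effects, role = "M",
                        coverage = "array", method = "array")
    countsFull <- simulatePileup(truth, cfg)
    rows <- list()
    for (cv in coverages) {
        counts <- if (cv >= cfg@coverage) countsFull
                  else thinCounts(countsFull, cfg@coverage, cv,
                                  seed = substreamSeed(cfg@seed,
                                                       10L + round(100 * cv)))
        calls <- genotypeAll(counts, target = target)
        conc <- concordance(calls, truth)
        missRate <- mean(is.na(assay(calls, "dosage")))
        for (mth in methods) {
            filled <- fillMissing(calls, mth, panel = panel, K = K)
            aHat <- predictGebv(filled, effects, role = "N",
                                coverage = as.character(cv), method = mth)
            for (tr in cfg@traitNames) {
                b <- gebvValues(bHat)[, tr]
                a <- gebvValues(aHat)[, tr]
                bias <- biasRegression(b, a)
                rows[[length(rows) + 1L]] <- data.frame(
                    trait = tr, coverage = cv, method = mth,
                    pearson_r = gebvCorrelation(b, a),
                    bias_slope = bias$slope,
                    bias_intercept = bias$intercept,
                    conc_both_correct = conc$proportions[["both_correct"]],
                    conc_one_wrong = conc$proportions[["one_wrong"]],
                    conc_both_wrong = conc$proportions[["both_wrong"]],
                    missing_rate = missRate,
                    n_individuals = cfg@nIndividuals,
                    n_loci = cfg@nMarkers)
            }
        }
    }
    do.call(rbind, rows)
}
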