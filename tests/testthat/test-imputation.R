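missingPattern <- function() {
    g <- matrix(c(0, 1, NA,  NA, 2, 1,  0, NA, NA), nrow = 3)
    toyCalls(g, toyLoci(3, p = c(0.25, 0.5, 0.8)))
}

test_that("homozygous-reference fill zeroes missing cells only", {
    calls <- missingPattern()
    filled <- fillHomref(calls)
    miss <- is.na(dosage(calls))
    expect_true(all(dosage(filled)[miss] == 0))
    expect_identical(dosage(filled)[!miss], dosage(calls)[!miss])
    expect_equal(sum(callSource(filled) == "filled-homref"), sum(miss))
    # no missing cells: identity
    full <- toyCalls(matrix(c(0, 1, 2), nrow = 3))
    expect_identical(dosage(fillHomref(full)), dosage(full))
})

test_that("allele-frequency fill inserts the Hardy-Weinberg dosage 2p", {
    calls <- missingPattern()
    filled <- fillAF(calls)
    d <- dosage(filled)
    # p = 0.25 -> 0*(1-p)^2 + 1*2p(1-p) + 2*p^2 = 0.5; p = 0.8 -> 1.6
    expect_equal(d[3, 1], 1.6)    # p = 0.8
    expect_equal(d[1, 2], 0.5)    # p = 0.25
    expect_equal(d[2, 3], 1.0)    # p = 0.5
    expect_equal(d[3, 3], 1.6)
    expect_identical(d[!is.na(dosage(calls))],
                     dosage(calls)[!is.na(dosage(calls))])
    # monomorphic limits
    mono <- toyCalls(matrix(NA_real_, 2, 1), toyLoci(2, p = c(0, 1)))
    expect_equal(unname(dosage(fillAF(mono))[, 1]), c(0, 2))
})

test_that("an all-missing individual gets the population-mean prediction", {
    p <- c(0.2, 0.5, 0.9)
    loci <- toyLoci(3, p = p)
    calls <- toyCalls(matrix(NA_real_, 3, 1), loci)
    eff <- toyEffects(c(0.5, -0.2, 0.1), loci)
    gebv <- predictGebv(fillAF(calls), eff)
    expect_equal(unname(gebvValues(gebv)[1, 1]),
                 sum(2 * p * c(0.5, -0.2, 0.1)))
})

test_that("panel imputation reproduces exactly matching haplotype pairs", {
    # four distinct haplotypes; the individual's calls (all het) are
    # matched at every called locus only by complementary pairs, all of
    # which dose the hidden locus at 1
    al <- cbind(c(1L,1L,1L,1L,1L), c(0L,0L,0L,0L,0L),
                c(1L,0L,1L,0L,1L), c(0L,1L,0L,1L,0L))
    colnames(al) <- paste0("h", 1:4)
    loci <- toyLoci(5, p = rowMeans(al))
    panel <- new("HaplotypePanel", alleles = al, loci = loci)
    g <- matrix(c(1, 1, NA, 1, 1), ncol = 1)
    filled <- imputeLD(toyCalls(g, loci), panel, K = 2)
    expect_equal(dosage(filled)[3, 1], 1)
    expect_identical(callSource(filled)[3, 1], "imputed-ld")

    # a panel of identical haplotypes imputes that haplotype everywhere
    alSame <- cbind(c(1L,0L,1L), c(1L,0L,1L))
    colnames(alSame) <- c("h1", "h2")
    lociS <- toyLoci(3, p = rowMeans(alSame))
    panelS <- new("HaplotypePanel", alleles = alSame, loci = lociS)
    gS <- matrix(c(NA, NA, NA), ncol = 1)
    expect_equal(unname(dosage(imputeLD(toyCalls(gS, lociS), panelS))[, 1]),
                 c(2, 0, 2))
})

test_that("individuals without any called locus fall back to the HWE dosage", {
    al <- cbind(c(1L, 0L), c(0L, 1L))
    colnames(al) <- c("h1", "h2")
    loci <- toyLoci(2, p = c(0.5, 0.5))
    panel <- new("HaplotypePanel", alleles = al, loci = loci)
    g <- matrix(NA_real_, 2, 1)
    filled <- imputeLD(toyCalls(g, loci), panel)
    expect_equal(unname(dosage(filled)[, 1]), c(1, 1))
    expect_true(all(callSource(filled) == "filled-af"))
    expect_equal(attr(filled, "afFallbackCells"), 2L)
})

test_that("no fill method alters called cells and all dosages stay in range", {
    cfg <- simConfig(nMarkers = 300, nIndividuals = 20, coverage = 1,
                     seed = 31)
    panel <- simulatePanel(cfg)
    truth <- sampleIndividuals(panel, 20, seed = 31)
    calls <- genotypeAll(simulatePileup(truth, cfg))
    called <- !is.na(dosage(calls))
    for (m in c("homref", "af", "ld")) {
        filled <- fillMissing(calls, m, panel = panel)
        expect_identical(dosage(filled)[called], dosage(calls)[called],
                         info = m)
        expect_false(anyNA(dosage(filled)), info = m)
        expect_true(all(dosage(filled) >= 0 & dosage(filled) <= 2),
                    info = m)
    }
})

test_that("panel imputation beats allele-frequency fill at 1x coverage", {
    accs <- sapply(1:5, function(s) {
        cfg <- simConfig(nMarkers = 600, nIndividuals = 25, coverage = 1,
                         seed = s)
        panel <- simulatePanel(cfg)
        truth <- sampleIndividuals(panel, 25, seed = s)
        calls <- genotypeAll(simulatePileup(truth, cfg))
        miss <- is.na(dosage(calls))
        tr <- dosage(truth)
        err <- function(f) mean(abs(dosage(f)[miss] - tr[miss]))
        c(ld = err(imputeLD(calls, panel)), af = err(fillAF(calls)))
    })
    expect_lt(mean(accs["ld", ]), mean(accs["af", ]))
})

test_that("the external Beagle adapter reports unavailability clearly", {
    calls <- missingPattern()
    expect_error(
        beagleImpute(calls, panelVcf = tempfile(), beagleJar = "",
                     javaBin = ""),
        "imputeLD")
})
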