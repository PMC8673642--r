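test_that("panel simulation is deterministic and respects the mosaic model", {
    cfg <- simConfig(nMarkers = 200, nPanelHaplotypes = 20,
                     nFounders = 5, seed = 42)
    p1 <- simulatePanel(cfg)
    p2 <- simulatePanel(cfg)
    expect_identical(panelAlleles(p1), panelAlleles(p2))
    expect_identical(as.data.frame(lociInfo(p1)), as.data.frame(lociInfo(p2)))
    expect_true(all(panelAlleles(p1) %in% c(0L, 1L)))
    expect_equal(lociInfo(p1)$alt_freq, rowMeans(panelAlleles(p1)))

    # switchRate = 0: every panel haplotype is an exact founder copy, so
    # there can be at most nFounders distinct haplotypes
    cfg0 <- simConfig(nMarkers = 200, nPanelHaplotypes = 20,
                      nFounders = 5, switchRate = 0, seed = 42)
    h <- panelAlleles(simulatePanel(cfg0))
    expect_lte(length(unique(apply(h, 2, paste, collapse = ""))), 5L)
})

test_that("adjacent-marker LD decreases with the switch rate", {
    r2adj <- function(panel) {
        h <- panelAlleles(panel)
        keep <- apply(h, 1, sd) > 0
        z <- h[keep, , drop = FALSE]
        r <- vapply(seq_len(nrow(z) - 1L), function(i)
            cor(z[i, ], z[i + 1L, ]), numeric(1))
        mean(r^2, na.rm = TRUE)
    }
    r2 <- sapply(1:10, function(s) {
        lo <- r2adj(simulatePanel(simConfig(nMarkers = 150,
            nPanelHaplotypes = 30, nFounders = 30, switchRate = 1,
            seed = s)))
        hi <- r2adj(simulatePanel(simConfig(nMarkers = 150,
            nPanelHaplotypes = 30, nFounders = 30, switchRate = 0,
            seed = s)))
        c(lo = lo, hi = hi)
    })
    # averaged over the 10 seeds, no-switch panels show strictly more
    # adjacent-marker LD than per-marker founder resampling
    expect_gt(mean(r2["hi", ]), mean(r2["lo", ]))
})

test_that("individuals are haplotype sums with panel-frequency dosage means", {
    cfg <- simConfig(nMarkers = 60, nPanelHaplotypes = 30, seed = 3)
    panel <- simulatePanel(cfg)
    truth <- sampleIndividuals(panel, 1000, seed = 3, switchRate = 0.05)
    d <- dosage(truth)
    expect_true(all(d %in% 0:2))
    expect_identical(d, assay(truth, "hap1") + assay(truth, "hap2"))
    # Monte Carlo: mean dosage ~ 2 * panel alt frequency, 3 SE tolerance
    p <- lociInfo(panel)$alt_freq
    se <- sqrt(2 * p * (1 - p) / 1000)   # per-locus binomial SE bound
    dev <- abs(rowMeans(d) - 2 * p)
    expect_true(mean(dev <= 3 * pmax(se, 1e-6)) > 0.95)

    expect_error(sampleIndividuals(panel, 0, seed = 1), "nIndividuals")

    # degenerate panels propagate to all individuals
    mono <- new("HaplotypePanel",
                alleles = matrix(1L, nrow = 5, ncol = 2,
                                 dimnames = list(NULL, c("h1", "h2"))),
                loci = toyLoci(5, p = rep(1, 5)))
    expect_true(all(dosage(sampleIndividuals(mono, 10, seed = 1)) == 2))
    mono0 <- new("HaplotypePanel",
                 alleles = matrix(0L, nrow = 5, ncol = 2,
                                  dimnames = list(NULL, c("h1", "h2"))),
                 loci = toyLoci(5, p = rep(0, 5)))
    expect_true(all(dosage(sampleIndividuals(mono0, 10, seed = 1)) == 0))
})

test_that("marker effects are polygenic, normalized, and scale with effectSd", {
    cfg <- simConfig(nMarkers = 5000, nTraits = 2,
                     effectSd = c(0.001, 0.0005), seed = 9)
    panel <- simulatePanel(simConfig(nMarkers = 5000, seed = 9))
    # shares sum to 1 in absolute value, for LD-projected and iid effects
    for (eff in list(simulateEffects(cfg, panel = panel),
                     simulateEffects(cfg))) {
        sh <- effectShare(eff)
        expect_equal(unname(colSums(abs(sh))), rep(1, 2))
        expect_equal(unname(apply(effectValues(eff), 2, sd)),
                     c(0.001, 0.0005), tolerance = 1e-10)
    }
    # highly polygenic: largest single-marker share is order 1/m
    maxShares <- sapply(1:10, function(s) {
        cfgS <- simConfig(nMarkers = 5000, nTraits = 1,
                          effectSd = 0.001, seed = s)
        max(abs(effectShare(simulateEffects(cfgS))))
    })
    expect_true(all(maxShares < 50 / 5000))
    # near-zero effectSd limit: predictions vanish
    cfg0 <- simConfig(nMarkers = 50, nTraits = 1, effectSd = 1e-30,
                      seed = 1)
    eff0 <- simulateEffects(cfg0)
    truth <- sampleIndividuals(simulatePanel(cfg0), 5, seed = 1)
    expect_equal(max(abs(gebvValues(predictGebv(truth, eff0)))), 0,
                 tolerance = 1e-25)
})

test_that("pileup depth, error rate and determinism match the read model", {
    cfg <- simConfig(nMarkers = 500, nIndividuals = 40, coverage = 2,
                     baseQuality = 20, seed = 5)
    panel <- simulatePanel(cfg)
    truth <- sampleIndividuals(panel, 40, seed = 5)
    ac1 <- simulatePileup(truth, cfg)
    ac2 <- simulatePileup(truth, cfg)
    expect_identical(assay(ac1, "ref"), assay(ac2, "ref"))
    expect_identical(assay(ac1, "alt"), assay(ac2, "alt"))

    depth <- assay(ac1, "ref") + assay(ac1, "alt")
    n <- length(depth)
    expect_lt(abs(mean(depth) - 2), 3 * sqrt(2 / n))

    # at hom loci, the error-read fraction estimates 10^(-Q/10) = 0.01
    g <- dosage(truth)
    errReads <- sum(assay(ac1, "alt")[g == 0]) +
                sum(assay(ac1, "ref")[g == 2])
    totReads <- sum(depth[g != 1])
    expect_gt(totReads, 1e4)
    ci <- qbinom(c(0.005, 0.995), totReads, 0.01)
    expect_gte(errReads, ci[1]); expect_lte(errReads, ci[2])

    # zero coverage: everything missing downstream
    cfg0 <- simConfig(nMarkers = 50, nIndividuals = 5, coverage = 0,
                      seed = 5)
    t0 <- sampleIndividuals(simulatePanel(cfg0), 5, seed = 5)
    ac0 <- simulatePileup(t0, cfg0)
    expect_true(all(assay(ac0, "ref") + assay(ac0, "alt") == 0))
    expect_true(all(is.na(dosage(genotypeAll(ac0)))))

    # error-free limit: hom-ref truth never shows alt reads
    cfgQ <- simConfig(nMarkers = 50, nIndividuals = 5, coverage = 10,
                      baseQuality = 1000, seed = 5)
    tQ <- sampleIndividuals(simulatePanel(cfgQ), 5, seed = 5)
    acQ <- simulatePileup(tQ, cfgQ)
    expect_true(all(assay(acQ, "alt")[dosage(tQ) == 0] == 0))

    # errorToOther routes errors to the third-base bucket
    cfgO <- simConfig(nMarkers = 200, nIndividuals = 10, coverage = 5,
                      baseQuality = 10, errorToOther = TRUE, seed = 5)
    tO <- sampleIndividuals(simulatePanel(cfgO), 10, seed = 5)
    acO <- simulatePileup(tO, cfgO)
    expect_gt(sum(assay(acO, "other")), 0)
    expect_true(all(assay(acO, "alt")[dosage(tO) == 0] == 0))
})

test_that("high-coverage error-free recovery matches the threshold rule's own limit", {
    # with negligible base error the only miscall channel left is a true
    # heterozygote failing the central condition t <= X <= d - t, whose
    # probability is fixed by the threshold table; observed miscalls must
    # match that exact binomial expectation, and every miscall must be a
    # het -> hom one-allele error
    cfg <- simConfig(nMarkers = 400, nIndividuals = 30, coverage = 20,
                     baseQuality = 1000, seed = 8)
    panel <- simulatePanel(cfg)
    truth <- sampleIndividuals(panel, 30, seed = 8)
    ac <- simulatePileup(truth, cfg)
    calls <- genotypeAll(ac)
    d <- dosage(calls)
    tr <- dosage(truth)
    wrong <- !is.na(d) & d != tr
    expect_true(all(abs(d[wrong] - tr[wrong]) == 1))
    expect_true(all(tr[wrong] == 1))
    depth <- assay(ac, "ref") + assay(ac, "alt")
    hets <- tr == 1 & depth >= 2
    tab <- minAlleleCountTable(max(depth))
    pMiss <- 1 - tab$p_both[depth[hets]]
    expected <- sum(pMiss)
    se <- sqrt(sum(pMiss * (1 - pMiss)))
    expect_lt(abs(sum(wrong) - expected), 3 * se + 1e-9)
    # homozygotes are recovered perfectly, so overall exact recovery
    # sits at 1 - hetShare * (1 - target) or better
    hetShare <- mean(tr == 1)
    expect_gte(mean(d == tr, na.rm = TRUE),
               1 - hetShare * 0.05 - 0.01)
})
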