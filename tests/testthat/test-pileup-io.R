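test_that("mpileup read-base strings decode per the format specification", {
    loci <- S4Vectors::DataFrame(
        chrom = "chr1", pos = 100L, ref = "A", alt = "G",
        alt_freq = 0.3, locus_id = "L1")
    parse1 <- function(line) {
        f <- tempfile()
        writeLines(line, f)
        ac <- readMpileup(f, loci)
        c(ref = assay(ac, "ref")[1, 1], alt = assay(ac, "alt")[1, 1],
          other = assay(ac, "other")[1, 1])
    }
    # all-reference line
    expect_equal(parse1("chr1\t100\tA\t4\t.,.,\tIIII"),
                 c(ref = 4, alt = 0, other = 0))
    # two alt matches among reference symbols
    expect_equal(parse1("chr1\t100\tA\t4\t.GG,\tIIII"),
                 c(ref = 2, alt = 2, other = 0))
    # ^I is a read-start marker (next char is mapping quality), T is a
    # third base -> other
    expect_equal(parse1("chr1\t100\tA\t3\t.T^I.\tIII"),
                 c(ref = 2, alt = 0, other = 1))
    # indels and end markers are stripped; lowercase matches too
    expect_equal(parse1("chr1\t100\tA\t5\t.+2AG,g$*N\tIIIII"),
                 c(ref = 2, alt = 1, other = 1))

    # loci absent from the stream yield zero counts
    loci2 <- rbind(loci, S4Vectors::DataFrame(
        chrom = "chr1", pos = 200L, ref = "C", alt = "T",
        alt_freq = 0.1, locus_id = "L2"))
    f <- tempfile()
    writeLines("chr1\t100\tA\t1\t.\tI", f)
    ac <- readMpileup(f, loci2)
    expect_equal(unname(assay(ac, "ref")[, 1]), c(1, 0))

    # ref-disagreement is flagged but still counted
    writeLines("chr1\t100\tC\t2\t..\tII", f)
    acFlag <- readMpileup(f, loci)
    expect_length(attr(acFlag, "flagged"), 1)
    expect_equal(assay(acFlag, "ref")[1, 1], 2)

    # malformed column counts are parse errors with a line number
    writeLines("chr1\t100\tA", f)
    expect_error(readMpileup(f, loci), "line 1")
})

test_that("allele-count TSVs round-trip exactly", {
    cfg <- simConfig(nMarkers = 40, nIndividuals = 6, coverage = 3,
                     seed = 21)
    truth <- sampleIndividuals(simulatePanel(cfg), 6, seed = 21)
    ac <- simulatePileup(truth, cfg)
    f1 <- tempfile(); f2 <- tempfile()
    writeAlleleCountsTsv(ac, f1)
    back <- readAlleleCountsTsv(f1, lociInfo(ac))
    writeAlleleCountsTsv(back, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(assay(back, "ref"), assay(ac, "ref"),
                 ignore_attr = TRUE)
    expect_equal(assay(back, "alt"), assay(ac, "alt"),
                 ignore_attr = TRUE)
})

test_that("binomial thinning halves counts on average and composes", {
    m <- 10000
    loci <- toyLoci(m)
    ref <- matrix(10L, nrow = m, ncol = 1,
                  dimnames = list(loci$locus_id, "s1"))
    alt <- matrix(2L, nrow = m, ncol = 1, dimnames = dimnames(ref))
    ac <- AlleleCounts(ref, alt, loci = loci)

    expect_identical(thinCounts(ac, 6, 6, seed = 1), ac)
    expect_error(thinCounts(ac, 6, 7, seed = 1), "targetCoverage")

    half <- thinCounts(ac, 6, 3, seed = 1)
    D <- sum(ref) + sum(alt)
    tot <- sum(assay(half, "ref")) + sum(assay(half, "alt"))
    se <- sqrt(D * 0.5 * 0.5)
    expect_lt(abs(tot - D / 2), 3 * se)

    # thinning full -> a -> b matches one-step full -> b in expectation
    twoStep <- thinCounts(thinCounts(ac, 6, 3, seed = 2), 3, 1, seed = 3)
    oneStep <- thinCounts(ac, 6, 1, seed = 4)
    m2 <- mean(assay(twoStep, "ref") + assay(twoStep, "alt"))
    m1 <- mean(assay(oneStep, "ref") + assay(oneStep, "alt"))
    seStep <- sqrt(2 * 2 / m)   # generous bound on either mean's SE
    expect_lt(abs(m2 - m1), 3 * seStep)

    zero <- AlleleCounts(ref * 0L, alt * 0L, loci = loci)
    thinZero <- thinCounts(zero, 6, 0.5, seed = 1)
    expect_true(all(assay(thinZero, "ref") == 0))
})

test_that("run summaries apply the effective-read formula and column means", {
    direct <- summarizeRun(data.frame(
        sample_id = c("a", "b"), total_reads = c(100, 100),
        mq0_reads = c(0, 5), unmapped_reads = c(0, 5)))
    expect_equal(direct$perSample$effective_pct, c(100, 90))
    expect_error(summarizeRun(data.frame(total_reads = 0, mq0_reads = 0,
                                         unmapped_reads = 0)),
                 "undefined")
    expect_error(summarizeRun(data.frame(sample_id = "a")), "effective_pct")

    stats <- utils::read.delim(
        system.file("extdata", "minion_run_stats.tsv",
                    package = "skimGEBV"))
    s <- summarizeRun(stats)
    expect_equal(nrow(s$perSample), 19)
    expect_equal(unname(round(s$means["read_length_bp"])), 1795)
})

test_that("Phred conversion is exact and strictly decreasing", {
    expect_equal(phredErrorRate(10), 0.1)
    expect_equal(phredErrorRate(20), 0.01)
    q <- seq(1, 60, by = 0.5)
    expect_true(all(diff(phredErrorRate(q)) < 0))
    expect_error(phredErrorRate(0), "> 0")
})
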