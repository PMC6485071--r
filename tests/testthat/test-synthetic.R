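test_that("genotype values, truth table and spike bookkeeping are sound", {
    sim <- simulateGenotypes(nGroups = 3, samplesPerGroup = 10,
                             nSites = 500, F = 0.1, missingRate = 0.1,
                             spike = spikeConfig(12, focalGroup = 2,
                                                 freqShift = 0.3),
                             seed = 11)
    d <- dosage(sim$genotypes)
    expect_true(all(d[!is.na(d)] %in% 0:2))
    expect_true(anyNA(d))
    expect_identical(sum(sim$truth$spiked), 12L)
    q <- as.matrix(sim$truth[, grep("^freqG", names(sim$truth))])
    expect_true(all(q >= 0 & q <= 1))
    ## spiked sites: focal frequency is shifted relative to other groups
    expect_gt(mean(q[sim$truth$spiked, 2]) - mean(q[sim$truth$spiked, 1]),
              0.15)
})

test_that("identical seeds reproduce genotypes, times and rates exactly", {
    a <- simulateGenotypes(nGroups = 2, samplesPerGroup = 5, nSites = 200,
                           missingRate = 0.1, seed = 42)
    b <- simulateGenotypes(nGroups = 2, samplesPerGroup = 5, nSites = 200,
                           missingRate = 0.1, seed = 42)
    expect_identical(dosage(a$genotypes), dosage(b$genotypes))
    expect_identical(a$truth, b$truth)
    t1 <- simulatePairCoalescence(1000, 5e3, 5e3, nPairs = 500, seed = 9)
    t2 <- simulatePairCoalescence(1000, 5e3, 5e3, nPairs = 500, seed = 9)
    expect_identical(t1, t2)
    bins <- splitTimeBins(t1)
    expect_identical(rates(ratesFromTimes(t1, bins)),
                     rates(ratesFromTimes(t2, bins)))
})

test_that("F near zero removes differentiation: sample frequencies track p", {
    sim <- simulateGenotypes(nGroups = 2, samplesPerGroup = 300,
                             nSites = 300, F = 1e-6, missingRate = 0,
                             seed = 3)
    dos <- dosage(sim$genotypes)
    grp <- sampleGroups(sim$genotypes)
    for (g in levels(grp)) {
        freq <- rowMeans(dos[, grp == g]) / 2
        ## binomial sampling sd at 600 alleles is < 0.021
        expect_lt(max(abs(freq - sim$truth$ancestralFreq)), 0.021 * 4)
        expect_lt(mean(abs(freq - sim$truth$ancestralFreq)), 0.02)
    }
})

test_that("degenerate generator configurations are rejected", {
    expect_error(simulateGenotypes(F = 1, nSites = 10), "F must")
    expect_error(simulateGenotypes(F = 0, nSites = 10), "F must")
    expect_error(simulateGenotypes(missingRate = 1, nSites = 10),
                 "missingRate")
    expect_error(simulateGenotypes(nSites = 10,
                                   ancestralRange = c(0, 0.9)),
                 "ancestralRange")
    expect_error(simulateGenotypes(nSites = 10,
                                   spike = spikeConfig(11, 1, 0.4)),
                 "spike")
    expect_error(spikeConfig(5, 1, 0))
})

test_that("mean estimated F_ST increases strictly with configured F", {
    means <- vapply(c(0.01, 0.05, 0.1, 0.2), function(F) {
        sim <- simulateGenotypes(nGroups = 2, samplesPerGroup = 25,
                                 nSites = 2e4, F = F, missingRate = 0,
                                 seed = 101)
        mean(fstValues(pairwiseFst(sim$genotypes)), na.rm = TRUE)
    }, numeric(1L))
    expect_true(all(diff(means) > 0))
})

test_that("clean-split coalescence times have the expected moments", {
    ## no split: within and cross identically distributed, mean ~ 2N
    t0 <- simulatePairCoalescence(0, 1e4, 1e4, nPairs = 5e4, seed = 5)
    expect_equal(mean(t0$within1), 2e4, tolerance = 0.03)
    expect_equal(mean(t0$cross), 2e4, tolerance = 0.03)
    expect_gt(suppressWarnings(
        ks.test(t0$within1, t0$cross)$p.value), 1e-4)
    ## split: cross mean ~ Tsplit + 2 Nanc
    ts <- simulatePairCoalescence(3000, 1e4, 2e4, nPairs = 5e4, seed = 6)
    expect_equal(mean(ts$cross), 3000 + 4e4, tolerance = 0.03)
    expect_true(all(ts$cross >= 3000))
})

test_that("binned hazards match their definition and a brute-force recount", {
    ## all samples coalesce in bin 1: rate = count / total exposure exactly
    tt <- list(within1 = c(1, 2, 3), within2 = c(2, 2, 2),
               cross = c(0.5, 1.5, 3.5))
    rc <- ratesFromTimes(tt, timeBins = c(0, 4, 8))
    expect_equal(unname(rates(rc)[1L, "lambda00"]), 3 / (1 + 2 + 3))
    expect_equal(unname(rates(rc)[1L, "lambda11"]), 3 / 6)
    expect_equal(unname(rates(rc)[1L, "lambda01"]), 3 / (0.5 + 1.5 + 3.5))
    expect_true(all(is.na(rates(rc)[2L, ])))  # no exposure left

    ## constant-size model: all three curves ~ 1/(2N) across bins
    tc <- simulatePairCoalescence(0, 8e3, 8e3, nPairs = 2e5, seed = 8)
    bins <- c(0, 4e3, 8e3, 16e3, 32e3, max(unlist(tc)) + 1)
    r <- rates(ratesFromTimes(tc, bins))
    expect_equal(unname(r[1:4, ]),
                 matrix(1 / 1.6e4, 4, 3), tolerance = 0.05)

    ## brute-force per-sample recount on 100 samples
    ts <- simulatePairCoalescence(500, 2e3, 2e3, nPairs = 100, seed = 12)
    bins <- splitTimeBins(ts, nBins = 10)
    r <- rates(ratesFromTimes(ts, bins))
    expect_equal(unname(r[, "lambda00"]),
                 bruteHazard(ts$within1, bins[-length(bins)], bins[-1]))
    expect_equal(unname(r[, "lambda01"]),
                 bruteHazard(ts$cross, bins[-length(bins)], bins[-1]))
})

test_that("rate estimation rejects unusable input", {
    tt <- list(within1 = 1, within2 = 1, cross = 1)
    expect_error(ratesFromTimes(tt, c(1, 2)), "from 0")
    expect_error(ratesFromTimes(tt, c(0, 0.5)), "cover")
    expect_error(ratesFromTimes(list(within1 = numeric(0), within2 = 1,
                                     cross = 1), c(0, 2)), "at least one")
})

test_that("closed-form expected rates agree with numeric quadrature", {
    bins <- c(0, exp(seq(log(100), log(2e5), length.out = 20)))
    rc <- expectedRateCurveCleanSplit(bins, Tsplit = 3000, Ndeme = 1e4,
                                      Nanc = 1e4)
    q <- quadCleanSplitRates(bins, 3000, 1e4, 1e4)
    expect_equal(unname(rates(rc)[, "lambda00"]), q$within,
                 tolerance = 1e-8)
    expect_equal(unname(rates(rc)[, "lambda01"]), q$cross,
                 tolerance = 1e-8)
})

test_that("block-copied variants carry the designed LD", {
    sim <- simulateGenotypes(nGroups = 2, samplesPerGroup = 30,
                             nSites = 50, missingRate = 0, seed = 21)
    bc <- blockCopyVariants(sim$genotypes, sites = c(10, 30), copies = 2,
                            flipProb = 0, seed = 1)
    dos <- dosage(bc$genotypes)
    for (k in seq_len(nrow(bc$blocks)))
        expect_equal(genotypeR2(dos[bc$blocks$site[k], ],
                                dos[bc$blocks$source[k], ]), 1)
    noisy <- blockCopyVariants(sim$genotypes, sites = 10, copies = 5,
                               flipProb = 0.4, seed = 2)
    nd <- dosage(noisy$genotypes)
    r2 <- vapply(noisy$blocks$site, function(s)
        genotypeR2(nd[s, ], nd["site10", ]), numeric(1L))
    expect_true(all(r2 < 1))
})
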