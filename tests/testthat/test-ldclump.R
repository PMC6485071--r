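test_that("dosage r-squared matches direct correlation", {
    x <- c(0L, 1L, 2L, 1L, 0L)
    expect_equal(genotypeR2(x, x), 1)
    expect_equal(genotypeR2(x, 2L - x), 1)   # repulsion is sign-blind
    expect_true(is.na(genotypeR2(x, rep(1L, 5))))
    expect_true(is.na(genotypeR2(c(0L, NA, NA, NA, 1L),
                                 c(NA, 1L, 2L, 0L, NA))))
    ## 50-sample fixture vs brute-force correlation
    set.seed(41)
    a <- sample(0:2, 50, TRUE); b <- sample(0:2, 50, TRUE)
    a[sample(50, 5)] <- NA
    ok <- !is.na(a)
    num <- sum((a[ok] - mean(a[ok])) * (b[ok] - mean(b[ok])))
    den <- sqrt(sum((a[ok] - mean(a[ok]))^2) * sum((b[ok] - mean(b[ok]))^2))
    expect_equal(genotypeR2(a, b), (num / den)^2, tolerance = 1e-12)
})

## shared fixture: block-copied LD among spiked outliers
clumpFixture <- function(seed = 61, nSites = 150) {
    sim <- simulateGenotypes(nGroups = 3, samplesPerGroup = 20,
                             nSites = nSites, missingRate = 0.02,
                             spike = spikeConfig(8, 1, 0.5), seed = seed)
    spiked <- which(sim$truth$spiked)
    bc <- blockCopyVariants(sim$genotypes, sites = spiked[1:4],
                            copies = 2, flipProb = 0.05, seed = seed)
    gd <- bc$genotypes
    ds <- suppressWarnings(suppressMessages(
        callOutliers(dStatistic(pairwiseFst(gd)), topFraction = 0.05)))
    list(gd = gd, ds = ds)
}

test_that("clumping matches the brute-force greedy rule on a fixture", {
    fx <- clumpFixture()
    cl <- clumpOutliers(fx$ds, "G1", fx$gd, p1 = 0.05, p2 = 0.2,
                        windowKb = 50, r2Thresh = 0.5)
    ## brute force from scratch on the same inputs
    f <- percentiles(fx$ds)[, "G1"] / 100
    rr <- rowRanges(fx$ds)
    pos <- start(rr); chrom <- as.character(seqnames(rr))
    dos <- dosage(fx$gd)[names(rr), ]
    n <- length(pos)
    r2m <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        r2m[i, j] <- genotypeR2(dos[i, ], dos[j, ])
    assigned <- bruteClump(f, pos, chrom, r2m, 0.05, 0.2, 5e4, 0.5)

    expTags <- names(rr)[sort(unique(assigned[!is.na(assigned)]))]
    gotTags <- sort(mcols(tags(cl))$site)
    expect_identical(gotTags, sort(expTags))
    m <- members(cl)
    gotAssign <- setNames(m$tagSite, m$site)
    expAssign <- setNames(names(rr)[assigned[!is.na(assigned)]],
                          names(rr)[!is.na(assigned)])
    expect_identical(gotAssign[sort(names(gotAssign))],
                     expAssign[sort(names(expAssign))])
})

test_that("clump structure follows the stated semantics", {
    fx <- clumpFixture(seed = 62)
    cl <- clumpOutliers(fx$ds, "G1", fx$gd, p1 = 0.05, p2 = 0.2,
                        windowKb = 50, r2Thresh = 0.5)
    m <- members(cl)
    f <- percentiles(fx$ds)[, "G1"] / 100
    names(f) <- names(rowRanges(fx$ds))
    ## every p1-passing variant is a tag or a member of exactly one clump
    p1Sites <- names(f)[!is.na(f) & f < 0.05]
    expect_true(all(p1Sites %in% m$site))
    expect_false(anyDuplicated(m$site) > 0)
    ## tag has the highest d of its clump, members within the horizon
    d <- dValues(fx$ds)[, "G1"]
    names(d) <- names(f)
    for (tg in mcols(tags(cl))$site) {
        clump <- m$site[m$tagSite == tg]
        expect_equal(max(d[clump]), unname(d[tg]))
    }
    expect_true(all(m$distanceBp <= 5e4))
    expect_true(all(m$r2[m$site != m$tagSite] > 0.5))
})

test_that("two correlated index variants form one clump tagged by higher d", {
    ## two p1 variants 10 kb apart with near-perfect LD
    set.seed(71)
    base <- sample(0:2, 60, TRUE, prob = c(.25, .5, .25))
    dos <- rbind(base, base,
                 sample(0:2, 60, TRUE, prob = c(.25, .5, .25)))
    rownames(dos) <- NULL
    gd <- GenotypeData(dos, pos = c(10000L, 20000L, 500000L),
                       groups = rep(c("A", "B"), each = 30))
    d <- matrix(c(5, 9, 0.1), ncol = 1, dimnames = list(NULL, "A"))
    ds <- suppressWarnings(callOutliers(makeDScan(
        d, pos = c(10000L, 20000L, 500000L)), topFraction = 0.5))
    cl <- clumpOutliers(ds, "A", gd, p1 = 0.5, p2 = 0.9, windowKb = 1000,
                        r2Thresh = 0.5)
    expect_identical(mcols(tags(cl))$site, "site2")   # the higher d
    expect_setequal(members(cl)$site, c("site1", "site2"))
    ## the uncorrelated distant variant stays unclaimed
    expect_false("site3" %in% members(cl)$site)
})

test_that("selection windows span strong-LD partners and merge", {
    fx <- clumpFixture(seed = 63)
    cl <- clumpOutliers(fx$ds, "G1", fx$gd, p1 = 0.05, p2 = 0.2,
                        windowKb = 50, r2Thresh = 0.5)
    win <- selectionWindows(cl, fx$gd, ldThresh = 0.8, horizonBp = 1e6)
    ## brute-force span + merge oracle
    rr <- rowRanges(fx$gd)
    pos <- start(rr); chrom <- as.character(seqnames(rr))
    dos <- dosage(fx$gd)
    n <- length(pos)
    r2m <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        r2m[i, j] <- genotypeR2(dos[i, ], dos[j, ])
    tagIdx <- match(mcols(tags(cl))$site, names(rr))
    exp <- bruteWindows(tagIdx, pos, chrom, r2m, 0.8, 1e6)
    expect_equal(cbind(start(win), end(win)), unname(exp),
                 ignore_attr = TRUE)
    ## raising the LD threshold never widens any window
    win9 <- selectionWindows(cl, fx$gd, ldThresh = 0.9, horizonBp = 1e6)
    expect_lte(sum(width(win9)), sum(width(win)))

    ## isolated tag -> 1 bp window at the tag position
    dos1 <- rbind(sample(0:2, 40, TRUE),
                  sample(0:2, 40, TRUE))
    rownames(dos1) <- NULL
    gd1 <- GenotypeData(dos1, pos = c(1000L, 900000L),
                        groups = rep(c("A", "B"), each = 20))
    d <- matrix(c(9, 0.1), ncol = 1, dimnames = list(NULL, "A"))
    ds1 <- suppressWarnings(callOutliers(makeDScan(d,
        pos = c(1000L, 900000L)), topFraction = 0.5))
    cl1 <- clumpOutliers(ds1, "A", gd1, p1 = 0.5, p2 = 0.5,
                         windowKb = 10, r2Thresh = 0.99)
    win1 <- selectionWindows(cl1, gd1, ldThresh = 0.99, horizonBp = 1e4)
    expect_identical(width(win1)[1], 1L)
    expect_identical(start(win1)[1], 1000L)
})

test_that("windows are invariant to input variant order", {
    fx <- clumpFixture(seed = 64, nSites = 80)
    cl <- clumpOutliers(fx$ds, "G1", fx$gd, p1 = 0.05, p2 = 0.2,
                        windowKb = 50, r2Thresh = 0.5)
    win <- selectionWindows(cl, fx$gd, 0.8, 1e6)
    ## shuffle genotype rows; scan results are row-aligned via names
    set.seed(1)
    perm <- sample(nrow(fx$gd))
    gdPerm <- fx$gd[perm, ]
    dsPerm <- suppressWarnings(suppressMessages(
        callOutliers(dStatistic(pairwiseFst(gdPerm)), topFraction = 0.05)))
    clPerm <- clumpOutliers(dsPerm, "G1", gdPerm, p1 = 0.05, p2 = 0.2,
                            windowKb = 50, r2Thresh = 0.5)
    expect_setequal(mcols(tags(clPerm))$site, mcols(tags(cl))$site)
    winPerm <- selectionWindows(clPerm, gdPerm, 0.8, 1e6)
    expect_identical(sort(start(winPerm)), sort(start(win)))
    expect_identical(sort(end(winPerm)), sort(end(win)))
})
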