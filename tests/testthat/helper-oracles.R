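## Independent oracles. Every routine here recomputes its quantity from the
## definitions with plain loops / quadrature, sharing no code path with the
## package implementation it checks.

## Monte-Carlo expectation of the per-site small-sample Hudson estimator
## under the Balding-Nichols + binomial-sampling generative model; the
## formula is evaluated inline on directly drawn allele counts (no genotype
## matrix, no package code).
oracleMeanHudsonFst <- function(F, nDiploid, nRep = 4e5,
                                ancestralRange = c(0.05, 0.95)) {
    p <- runif(nRep, ancestralRange[1L], ancestralRange[2L])
    a <- p * (1 - F) / F
    b <- (1 - p) * (1 - F) / F
    q1 <- rbeta(nRep, a, b)
    q2 <- rbeta(nRep, a, b)
    n <- 2 * nDiploid
    p1 <- rbinom(nRep, n, q1) / n
    p2 <- rbinom(nRep, n, q2) / n
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n - 1) - p2 * (1 - p2) / (n - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    mean((num / den)[den > 0])
}

## Greedy clump rule re-derived with explicit loops over all variant pairs.
## f: fraction of variants with a higher d (NA = undefined); r2mat: full
## precomputed r-squared matrix.
bruteClump <- function(f, pos, chrom, r2mat, p1, p2, winBp, r2th) {
    n <- length(f)
    assigned <- rep(NA_integer_, n)
    ord <- order(f, pos, na.last = TRUE)
    for (i in ord) {
        if (is.na(f[i]) || f[i] >= p1 || !is.na(assigned[i])) next
        assigned[i] <- i
        for (j in seq_len(n)) {
            if (j == i || !is.na(assigned[j])) next
            if (is.na(f[j]) || f[j] >= p2) next
            if (chrom[j] != chrom[i] || abs(pos[j] - pos[i]) > winBp) next
            if (!is.na(r2mat[i, j]) && r2mat[i, j] > r2th)
                assigned[j] <- i
        }
    }
    assigned
}

## Selection-window spans and merge, re-derived by hand
bruteWindows <- function(tagIdx, pos, chrom, r2mat, ldth, horizon) {
    spans <- t(vapply(tagIdx, function(i) {
        part <- i
        for (j in seq_along(pos))
            if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= horizon &&
                !is.na(r2mat[i, j]) && r2mat[i, j] > ldth)
                part <- c(part, j)
        c(min(pos[part]), max(pos[part]))
    }, numeric(2L)))
    spans <- spans[order(spans[, 1L]), , drop = FALSE]
    merged <- spans[1L, , drop = FALSE]
    for (k in seq_len(nrow(spans))[-1L]) {
        last <- nrow(merged)
        if (spans[k, 1L] <= merged[last, 2L] + 0)
            merged[last, 2L] <- max(merged[last, 2L], spans[k, 2L])
        else merged <- rbind(merged, spans[k, ])
    }
    merged
}

## Per-bin hazard from first principles: one sample at a time
bruteHazard <- function(t, left, right) {
    vapply(seq_along(left), function(b) {
        cnt <- 0; expo <- 0
        for (ti in t) {
            if (ti >= left[b] && ti < right[b]) cnt <- cnt + 1
            if (ti > left[b]) expo <- expo + min(ti, right[b]) - left[b]
        }
        if (expo == 0) NA_real_ else cnt / expo
    }, numeric(1L))
}

## Exact shift-permutation tail probability by enumerating the full offset
## grid. Each locus: list(W = span width, iv = matrix with columns rs, re
## (0-based half-open relative intervals), snp = relative SNP positions).
enumShiftExactP <- function(loci) {
    hitAt <- function(loc, off) {
        for (s in loc$snp) {
            x <- (s - off) %% loc$W
            for (r in seq_len(nrow(loc$iv)))
                if (x >= loc$iv[r, 1L] && x < loc$iv[r, 2L]) return(TRUE)
        }
        FALSE
    }
    grids <- lapply(loci, function(l) 0:(l$W - 1L))
    combos <- as.matrix(expand.grid(grids))
    scores <- apply(combos, 1L, function(off)
        sum(vapply(seq_along(loci), function(k) hitAt(loci[[k]], off[k]),
                   logical(1L))))
    obs <- sum(vapply(loci, function(l) hitAt(l, 0L), logical(1L)))
    list(observed = obs,
         p = max(mean(scores >= obs), 1 / length(scores)))
}

## Randomised permutation p-value: exactly Uniform(0,1) when the observed
## score is exchangeable with the permuted scores
randomisedP <- function(observed, perm) {
    (sum(perm > observed) + runif(1L) * (1 + sum(perm == observed))) /
        (length(perm) + 1L)
}

## Expected binned rates for the clean split by numeric quadrature of the
## pair survival functions (independent of the package's analytic form)
quadCleanSplitRates <- function(bins, Tsplit, Ndeme, Nanc) {
    Sw <- function(t) ifelse(t <= Tsplit, exp(-t / (2 * Ndeme)),
                             exp(-Tsplit / (2 * Ndeme) -
                                 (t - Tsplit) / (2 * Nanc)))
    Sc <- function(t) ifelse(t <= Tsplit, 1,
                             exp(-(t - Tsplit) / (2 * Nanc)))
    left <- bins[-length(bins)]; right <- bins[-1L]
    rate <- function(S) vapply(seq_along(left), function(b) {
        expo <- integrate(S, left[b], right[b], rel.tol = 1e-10,
                          subdivisions = 500L)$value
        (S(left[b]) - S(right[b])) / expo
    }, numeric(1L))
    list(left = left, right = right, within = rate(Sw), cross = rate(Sc))
}

## First present-to-past upcrossing by linear interpolation, re-derived
oracleUpcrossing <- function(tm, v, thr) {
    ok <- !is.na(v); tm <- tm[ok]; v <- v[ok]
    if (v[1L] >= thr) return(NA_real_)
    for (k in seq_len(length(v) - 1L))
        if (v[k] < thr && v[k + 1L] >= thr)
            return(tm[k] + (thr - v[k]) / (v[k + 1L] - v[k]) *
                   (tm[k + 1L] - tm[k]))
    NA_real_
}

## RCCR 0.5-crossing of the clean-split model under the estimator's binning
## and interpolation conventions, from the quadrature rates above
oracleRccrCrossing <- function(bins, Tsplit, Ndeme, Nanc, thr = 0.5) {
    q <- quadCleanSplitRates(bins, Tsplit, Ndeme, Nanc)
    rccr <- 2 * q$cross / (q$within + q$within)
    mid <- (q$left + q$right) / 2
    oracleUpcrossing(mid, rccr, thr)
}

## default log-spaced coalescent time bins used by the split-recovery tests
splitTimeBins <- function(times, nBins = 32L, tMin = 50) {
    tMax <- max(unlist(times)) + 1
    c(0, exp(seq(log(tMin), log(tMax), length.out = nBins)))
}
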