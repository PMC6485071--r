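#' Simulate pairwise coalescence times under a clean two-deme split
#'
#' Two demes of constant diploid size `Ndeme` split from a single ancestral
#' population of size `Nanc` at `Tsplit` generations before present. A
#' within-deme lineage pair coalesces with rate 1/(2 Ndeme) per generation;
#' if it has not coalesced by `Tsplit` the waiting time restarts from
#' `Tsplit` with rate 1/(2 Nanc). A cross-deme pair cannot coalesce before
#' `Tsplit` and then waits with rate 1/(2 Nanc).
#'
#' @param Tsplit split time, generations (>= 0).
#' @param Ndeme diploid size of each deme.
#' @param Nanc diploid ancestral size.
#' @param nPairs number of sampled lineage pairs per category.
#' @param seed integer seed.
#' @return list of numeric vectors `within1`, `within2`, `cross`
#'   (coalescence times in generations).
#' @examples
#' tt <- simulatePairCoalescence(3000, 1e4, 1e4, nPairs = 1000, seed = 1)
#' mean(tt$cross)  # about Tsplit + 2 * Nanc
#' @export
simulatePairCoalescence <- function(Tsplit, Ndeme, Nanc, nPairs = 1e5L,
                                    seed = 1L) {
    stopifnot(Tsplit >= 0, Ndeme > 0, Nanc > 0, nPairs >= 1L)
    set.seed(.stageSeed(seed, "coalescence"))
    within <- function(n) {
        t <- rexp(n, rate = 1 / (2 * Ndeme))
        late <- t > Tsplit
        t[late] <- Tsplit + rexp(sum(late), rate = 1 / (2 * Nanc))
        t
    }
    list(within1 = within(nPairs), within2 = within(nPairs),
         cross = Tsplit + rexp(nPairs, rate = 1 / (2 * Nanc)))
}

#' Binned hazard rates from coalescence-time samples
#'
#' Per bin and category, rate = (coalescences in bin) / (lineage-pair
#' exposure in bin), with exact within-bin survival accounting: a pair
#' coalescing mid-bin contributes exposure up to its coalescence time only.
#' Bins with zero exposure are flagged `NA`.
#'
#' @param times list with components `within1`, `within2`, `cross` (as
#'   returned by [simulatePairCoalescence()]).
#' @param timeBins strictly increasing bin edges starting at 0 and covering
#'   the sampled range.
#' @return A [RateCurve-class] with rates per generation.
#' @export
ratesFromTimes <- function(times, timeBins) {
    stopifnot(all(c("within1", "within2", "cross") %in% names(times)))
    if (any(lengths(times[c("within1", "within2", "cross")]) < 1L))
        stop("need at least one coalescence time per category")
    if (timeBins[1L] != 0 || any(diff(timeBins) <= 0))
        stop("timeBins must increase strictly from 0")
    tmax <- max(unlist(times))
    if (max(timeBins) < tmax)
        stop("timeBins must cover the sampled range (max time ",
             format(tmax), ")")
    left <- timeBins[-length(timeBins)]
    right <- timeBins[-1L]
    hazard <- function(t) {
        vapply(seq_along(left), function(b) {
            expo <- sum(pmax(0, pmin(t, right[b]) - left[b]))
            cnt <- sum(t >= left[b] & t < right[b])
            if (expo == 0) NA_real_ else cnt / expo
        }, numeric(1L))
    }
    rates <- cbind(lambda00 = hazard(times$within1),
                   lambda01 = hazard(times$cross),
                   lambda11 = hazard(times$within2))
    new("RateCurve", left = left, right = right, rates = rates)
}

#' Closed-form expected binned rates for the clean-split model
#'
#' Analytic counterpart of [simulatePairCoalescence()] +
#' [ratesFromTimes()]: for piecewise-constant pair-coalescence hazards (the
#' clean split), the expected binned rate is
#' (S(a) - S(b)) / integral_a^b S(t) dt with S the pair survival function,
#' evaluated exactly per bin. Useful as a model prediction to compare
#' Monte-Carlo estimates (and their downstream RCCR crossings) against.
#'
#' @inheritParams simulatePairCoalescence
#' @param timeBins strictly increasing bin edges starting at 0.
#' @return A [RateCurve-class] of expected rates per generation.
#' @export
expectedRateCurveCleanSplit <- function(timeBins, Tsplit, Ndeme, Nanc) {
    stopifnot(Tsplit >= 0, Ndeme > 0, Nanc > 0)
    if (timeBins[1L] != 0 || any(diff(timeBins) <= 0))
        stop("timeBins must increase strictly from 0")
    left <- timeBins[-length(timeBins)]
    right <- timeBins[-1L]
    ## survival and integrated survival for hazard h1 before Tsplit, h2 after
    binRate <- function(h1, h2) {
        S <- function(t) ifelse(t <= Tsplit, exp(-h1 * t),
                                exp(-h1 * Tsplit - h2 * (t - Tsplit)))
        segInt <- function(a, b, h) {    # integral of S over [a,b], constant h
            if (b <= a) return(0)
            if (h == 0) return(S(a) * (b - a))
            (S(a) - S(b)) / h
        }
        vapply(seq_along(left), function(bn) {
            a <- left[bn]; b <- right[bn]
            expo <- segInt(a, min(b, max(a, Tsplit)), h1) +
                    segInt(max(a, Tsplit), max(b, Tsplit), h2)
            coal <- S(a) - S(b)
            if (expo == 0) NA_real_ else coal / expo
        }, numeric(1L))
    }
    w <- binRate(1 / (2 * Ndeme), 1 / (2 * Nanc))
    x <- binRate(0, 1 / (2 * Nanc))
    new("RateCurve", left = left, right = right,
        rates = cbind(lambda00 = w, lambda01 = x, lambda11 = w))
}
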