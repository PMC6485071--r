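#' Read an MSMC-style final-rate table
#'
#' Whitespace-delimited text with columns `time_index`,
#' `left_time_boundary`, `right_time_boundary`, `lambda_00`, `lambda_01`,
#' `lambda_11` (a header line is accepted and skipped). Boundaries must be
#' strictly increasing and contiguous; malformed or shuffled files are
#' rejected. Rates and times stay in whatever units the producer used
#' (mutation-scaled for real MSMC output, per-generation for the synthetic
#' writer).
#'
#' @param path input path.
#' @return A [RateCurve-class].
#' @export
readRateTable <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("[A-Za-z]", first)
    tb <- read.table(path, header = hasHeader)
    if (ncol(tb) != 6L)
        stop("expected 6 columns (time_index, boundaries, three rates)")
    colnames(tb) <- c("time_index", "left", "right",
                      "lambda00", "lambda01", "lambda11")
    if (any(!is.finite(as.matrix(tb[, 1:3])) & !is.infinite(tb$right)))
        stop("malformed rate table")
    if (any(diff(tb$left) <= 0) || any(tb$right <= tb$left))
        stop("bin boundaries must be strictly increasing")
    if (nrow(tb) > 1L &&
        any(abs(tb$left[-1L] - tb$right[-nrow(tb)]) >
            1e-9 * pmax(1, abs(tb$right[-nrow(tb)]))))
        stop("bins must be contiguous")
    new("RateCurve", left = tb$left, right = tb$right,
        rates = as.matrix(tb[, c("lambda00", "lambda01", "lambda11")]))
}

#' Write a RateCurve in the MSMC-style final-rate layout
#'
#' Full-precision text so [readRateTable()] round-trips bit-identically.
#'
#' @param rc a [RateCurve-class].
#' @param path output path.
#' @export
writeRateTable <- function(rc, path) {
    fmt <- function(x) sprintf("%.17g", x)
    lines <- paste(seq_along(rc@left) - 1L, fmt(rc@left), fmt(rc@right),
                   fmt(rc@rates[, "lambda00"]), fmt(rc@rates[, "lambda01"]),
                   fmt(rc@rates[, "lambda11"]), sep = "\t")
    writeLines(c(paste("time_index", "left_time_boundary",
                       "right_time_boundary", "lambda_00", "lambda_01",
                       "lambda_11", sep = "\t"), lines), path)
    invisible(path)
}

#' @describeIn readRateTable the (bins x 3) rate matrix.
#' @param x a RateCurve.
#' @export
setMethod("rates", "RateCurve", function(x) x@rates)

setMethod("show", "RateCurve", function(object) {
    cat("RateCurve:", length(object@left), "time bins, [",
        format(object@left[1L]), ",", format(max(object@right)), "]\n")
})

#' Relative cross-coalescence rate per bin
#'
#' RCCR = 2 * lambda_cross / (lambda_within1 + lambda_within2). Bins where
#' the within-rate sum is zero or any rate is missing are flagged `NA`;
#' a curve with no defined bin is rejected. Values above 1 (estimation
#' noise) are retained, not clipped.
#'
#' @param x a [RateCurve-class].
#' @param timeUnit label recorded on the result.
#' @return An [RccrCurve-class]. The representative bin time is the
#'   arithmetic midpoint of the boundaries; an open-ended (infinite right
#'   boundary) last bin uses its left boundary.
#' @export
setMethod("computeRccr", "RateCurve", function(x, timeUnit = "input units") {
    r <- x@rates
    den <- r[, "lambda00"] + r[, "lambda11"]
    rccr <- 2 * r[, "lambda01"] / den
    rccr[!is.na(den) & den == 0] <- NA_real_
    if (all(is.na(rccr))) stop("RCCR undefined in every bin")
    mid <- (x@left + x@right) / 2
    open <- !is.finite(x@right)
    mid[open] <- x@left[open]
    new("RccrCurve", left = x@left, right = x@right, mid = mid,
        rccr = unname(rccr), timeUnit = timeUnit)
})

#' @describeIn computeRccr RCCR values per bin.
#' @export
setMethod("rccrValues", "RccrCurve", function(x) x@rccr)

setMethod("show", "RccrCurve", function(object) {
    cat("RccrCurve:", length(object@mid), "bins (", object@timeUnit, ")\n")
    ok <- !is.na(object@rccr)
    cat(sprintf("  RCCR range: [%.3f, %.3f]\n", min(object@rccr[ok]),
                max(object@rccr[ok])))
})

#' Mutation-rate scaling parameters
#'
#' @param nu per-site mutation rate per year (default 4.3e-10).
#' @param g generation time in years (default 29).
#' @return A [ScalingParams-class]; `mu(params)` gives the per-generation
#'   rate `nu * g` (1.25e-8 at the defaults, so `2 * mu` is 2.5e-8).
#' @examples
#' mu(scalingParams())          # 1.25e-8 to 3 significant figures
#' @export
scalingParams <- function(nu = 4.3e-10, g = 29) new("ScalingParams",
                                                    nu = nu, g = g)

#' @rdname scalingParams
#' @param params a ScalingParams object.
#' @export
mu <- function(params) params@nu * params@g

#' Convert mutation-scaled times to years
#'
#' Scaled times divide by the per-year mutation rate: years = t / nu
#' (equivalently t * g / mu). Linear, so it can be applied to boundaries,
#' midpoints or crossing times alike.
#'
#' @param scaledTime numeric vector of mutation-scaled times.
#' @param params a [ScalingParams-class].
#' @return years.
#' @export
scaleTime <- function(scaledTime, params) scaledTime / params@nu

#' Convert a scaled coalescence rate to a diploid effective size
#'
#' N_e = (1 / lambda) / (2 mu).
#'
#' @param lambda scaled coalescence rate(s), > 0.
#' @param params a [ScalingParams-class].
#' @return diploid effective population size(s).
#' @export
scaleNe <- function(lambda, params) {
    if (any(lambda <= 0)) stop("lambda must be positive")
    (1 / lambda) / (2 * mu(params))
}

#' Threshold-crossing divergence times from an RCCR curve
#'
#' Scanning from the present into the past, locates the first upcrossing of
#' each threshold by linear interpolation between bin representative times.
#' A threshold is reported only when the most recent defined bin lies below
#' it and some older bin lies at or above it; otherwise it is `NA`
#' (populations that never diverged have no crossing — nothing is
#' fabricated). Additional, later crossings of a non-monotone curve are
#' counted in a message but not reported.
#'
#' @param x an [RccrCurve-class].
#' @param thresholds RCCR levels, default `c(0.25, 0.5, 0.75)`; the 0.5
#'   crossing is the divergence-time definition, 0.25/0.75 bound the
#'   reported interval.
#' @return A [DivergenceEstimate-class] in the curve's time unit.
#' @export
setMethod("crossingTimes", "RccrCurve",
          function(x, thresholds = c(0.25, 0.5, 0.75)) {
    ok <- !is.na(x@rccr)
    t <- x@mid[ok]; v <- x@rccr[ok]
    if (length(v) < 2L) stop("need at least two defined bins")
    cross1 <- function(thr) {
        if (v[1L] >= thr) return(NA_real_)       # already above at present
        up <- which(v[-1L] >= thr & v[-length(v)] < thr)
        if (!length(up)) return(NA_real_)        # never crosses
        if (length(up) > 1L)
            message(length(up) - 1L, " additional upcrossing(s) of ",
                    thr, " ignored (non-monotone curve)")
        k <- up[1L]
        t[k] + (thr - v[k]) / (v[k + 1L] - v[k]) * (t[k + 1L] - t[k])
    }
    got <- vapply(sort(thresholds), cross1, numeric(1L))
    names(got) <- as.character(sort(thresholds))
    pick <- function(nm) if (nm %in% names(got)) got[[nm]] else NA_real_
    new("DivergenceEstimate", t25 = pick("0.25"), t50 = pick("0.5"),
        t75 = pick("0.75"), timeUnit = x@timeUnit)
})

#' Format a divergence estimate the way divergence tables report it
#'
#' `~t50 (t25-t75) kya`, times in thousands of years rounded to 2
#' significant figures by default; undefined crossings print as "n.d.".
#'
#' @param de a [DivergenceEstimate-class] whose times are in years.
#' @param digits significant figures.
#' @return character string.
#' @export
formatDivergence <- function(de, digits = 2L) {
    f <- function(t) if (is.na(t)) "n.d." else
        format(signif(t / 1000, digits))
    sprintf("~%s (%s-%s) kya", f(de@t50), f(de@t25), f(de@t75))
}

setMethod("show", "DivergenceEstimate", function(object) {
    cat("DivergenceEstimate (", object@timeUnit, "): t25 =",
        format(object@t25), ", t50 =", format(object@t50), ", t75 =",
        format(object@t75), "\n")
})
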