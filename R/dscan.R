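#' Per-site, per-group d statistic
#'
#' For focal group i at a site, sums over every other group j the squared
#' deviation of the site's pairwise F_ST from that pair's genome-wide mean,
#' divided by the pair's standard deviation:
#' \deqn{d_i = \sum_{j \ne i} \left(F_{ST}(i,j) - E[F_{ST}(i,j)]\right)^2 /
#'       \mathrm{sd}[F_{ST}(i,j)]}
#' Note the numerator is squared while the denominator is the (unsquared)
#' standard deviation. Large values flag sites unusually differentiated in
#' the focal group relative to genome-wide expectation. `squared = FALSE`
#' gives the classic signed standardised sum
#' \eqn{\sum_j (F_{ST}(i,j) - E[F_{ST}(i,j)]) / \mathrm{sd}[F_{ST}(i,j)]}
#' for comparison.
#'
#' A site's d for group i is `NA` when any required pair F_ST is undefined
#' there. If any pair involving a requested group has zero (or undefined)
#' F_ST standard deviation the scan aborts with a diagnostic naming the
#' pair, since the statistic is not defined for that group.
#'
#' @param pf a [PairFst-class] object.
#' @param summaries per-pair moments, default `pairSummaries(pf)`; supplying
#'   them explicitly allows standardising against moments computed on a
#'   different (e.g. larger) site set.
#' @param groups which focal groups to scan (default: all).
#' @param squared square the numerator (the default and canonical form).
#' @return A [DScanResult-class] with assay `"d"` (sites x groups);
#'   percentile and outlier assays are `NA` until [callOutliers()] runs.
#' @export
dStatistic <- function(pf, summaries = pairSummaries(pf), groups = NULL,
                       squared = TRUE) {
    f <- fstValues(pf)
    g1 <- colData(pf)$group1; g2 <- colData(pf)$group2
    allGroups <- sort(unique(c(g1, g2)))
    if (is.null(groups)) groups <- allGroups
    d <- matrix(NA_real_, nrow(f), length(groups),
                dimnames = list(rownames(f), groups))
    for (i in groups) {
        sel <- which(g1 == i | g2 == i)
        sdv <- summaries$sd[sel]
        if (anyNA(sdv) || any(sdv == 0)) {
            bad <- sel[which(is.na(sdv) | sdv == 0)][1L]
            stop("d scan for group '", i, "' aborted: pair ",
                 g1[bad], ":", g2[bad],
                 " has zero or undefined F_ST standard deviation")
        }
        dev <- sweep(f[, sel, drop = FALSE], 2L, summaries$mean[sel])
        contrib <- if (squared) dev^2 else dev
        d[, i] <- rowSums(sweep(contrib, 2L, sdv, `/`))
    }
    nDrop <- colSums(is.na(d))
    if (any(nDrop > 0))
        message("sites with undefined d per group: ",
                paste(names(nDrop), nDrop, sep = "=", collapse = ", "))
    blank <- matrix(NA_real_, nrow(f), length(groups),
                    dimnames = dimnames(d))
    se <- SummarizedExperiment(
        assays = list(d = d, percentile = blank,
                      outlier = array(NA, dim(d), dimnames(d))),
        rowRanges = rowRanges(pf),
        colData = DataFrame(group = groups, row.names = groups))
    metadata(se)$squared <- squared
    new("DScanResult", se)
}

#' Call empirical outliers on a d scan
#'
#' Per group, the percentile column records the percent of defined variants
#' with a strictly higher d; outliers are the sites whose d lies strictly
#' above the empirical (1 - `topFraction`) order statistic of that group's
#' defined d values, i.e. the top 0.1\% of the empirical distribution at the
#' default. Ties exactly at the threshold are excluded (conservative) and
#' counted in a message; groups with fewer than 1000 defined sites trigger a
#' degenerate-threshold warning.
#'
#' @param ds a [DScanResult-class].
#' @param topFraction outlier fraction (default 0.001).
#' @return the input with `"percentile"` and `"outlier"` assays filled and
#'   `metadata(ds)$topFraction` set.
#' @export
callOutliers <- function(ds, topFraction = 0.001) {
    stopifnot(topFraction > 0, topFraction < 1)
    d <- SummarizedExperiment::assay(ds, "d")
    pct <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
    out <- matrix(NA, nrow(d), ncol(d), dimnames = dimnames(d))
    for (g in colnames(d)) {
        ok <- !is.na(d[, g])
        n <- sum(ok)
        if (n == 0L) next
        if (n < 1000L)
            warning("group ", g, ": only ", n,
                    " defined sites; top-fraction threshold is degenerate")
        v <- d[ok, g]
        ## percent of defined variants with a strictly higher d
        pct[ok, g] <- 100 * (n - rank(v, ties.method = "max")) / n
        thr <- sort(v, partial = ceiling((1 - topFraction) * n))[
            ceiling((1 - topFraction) * n)]
        out[ok, g] <- v > thr
        nTies <- sum(v == thr)
        if (nTies > 1L)
            message("group ", g, ": ", nTies,
                    " sites tied at the outlier threshold, all excluded")
    }
    SummarizedExperiment::assays(ds)$percentile <- pct
    SummarizedExperiment::assays(ds)$outlier <- out
    metadata(ds)$topFraction <- topFraction
    ds
}

#' @describeIn dStatistic d matrix (sites x groups).
#' @param x a DScanResult.
#' @export
setMethod("dValues", "DScanResult", function(x)
    SummarizedExperiment::assay(x, "d"))

#' @describeIn dStatistic percentile matrix (percent of variants with a
#'   higher d).
#' @export
setMethod("percentiles", "DScanResult", function(x)
    SummarizedExperiment::assay(x, "percentile"))

#' @describeIn dStatistic logical outlier matrix.
#' @export
setMethod("outlierCalls", "DScanResult", function(x)
    SummarizedExperiment::assay(x, "outlier"))

setMethod("show", "DScanResult", function(object) {
    d <- dValues(object)
    cat("DScanResult:", nrow(d), "sites x", ncol(d), "groups\n")
    o <- outlierCalls(object)
    if (!all(is.na(o)))
        cat("  outliers per group:",
            paste(colnames(o), colSums(o, na.rm = TRUE), sep = "=",
                  collapse = ", "), "\n")
    else cat("  outliers not yet called (see callOutliers)\n")
})
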