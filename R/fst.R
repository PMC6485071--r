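#' Per-group missingness filter
#'
#' A site is retained only if, within \emph{every} group, the fraction of
#' missing genotype calls is at most `maxMissing` — one bad group drops the
#' site even when all other groups are complete.
#'
#' @param gd a [GenotypeData-class] object.
#' @param maxMissing per-group missing-call fraction tolerated (default 0.20).
#' @return logical vector over sites; attribute `"counts"` holds the
#'   input/retained/dropped accounting.
#' @export
missingnessFilter <- function(gd, maxMissing = 0.20) {
    groups <- sampleGroups(gd)
    if (any(table(groups) == 0L)) stop("empty group")
    dos <- dosage(gd)
    keep <- rep(TRUE, nrow(dos))
    for (g in levels(groups)) {
        sub <- dos[, groups == g, drop = FALSE]
        keep <- keep & rowMeans(is.na(sub)) <= maxMissing
    }
    attr(keep, "counts") <- c(input = nrow(dos), retained = sum(keep),
                              dropped = sum(!keep))
    keep
}

#' Per-site group allele counts
#'
#' Sufficient statistics for the per-site estimator: per site and group, the
#' number of called alleles (2 x non-missing diploids) and the alternate
#' allele count.
#'
#' @param gd a [GenotypeData-class] object.
#' @return list of two matrices (sites x groups): `called` and `alt`.
#' @export
alleleCounts <- function(gd) {
    groups <- sampleGroups(gd)
    dos <- dosage(gd)
    lev <- levels(groups)
    called <- alt <- matrix(0, nrow(dos), length(lev),
                            dimnames = list(rownames(dos), lev))
    for (g in lev) {
        sub <- dos[, groups == g, drop = FALSE]
        called[, g] <- 2 * rowSums(!is.na(sub))
        alt[, g] <- rowSums(sub, na.rm = TRUE)
    }
    list(called = called, alt = alt)
}

#' Hudson per-site F_ST with small-sample correction
#'
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}}
#' with allele frequencies \eqn{p_k} and called allele counts \eqn{n_k}. The
#' n-1 terms remove the sampling variance of the frequency estimates, so the
#' estimator is unbiased in the numerator at small sample sizes; values may
#' be negative (noise floor) and are deliberately not clipped. `NA` when the
#' denominator is zero (site monomorphic and identical in both groups).
#' Vectorised over sites.
#'
#' @param p1,p2 alternate-allele frequencies in the two groups.
#' @param n1,n2 called allele counts (>= 2).
#' @return numeric vector of F_ST values (may be negative, never above 1).
#' @examples
#' hudsonFst(0.8, 20, 0.2, 20)
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
    if (any(c(n1, n2) < 2)) stop("need at least 2 called alleles per group")
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    out <- num / den
    out[den == 0] <- NA_real_
    out
}

#' Pairwise per-site F_ST between all group pairs
#'
#' Applies [hudsonFst()] to every unordered group pair at every site.
#' Entries are `NA` (undefined) where a group has fewer than two called
#' alleles or the denominator vanishes.
#'
#' @param gd a [GenotypeData-class] object.
#' @param sites optional logical vector of sites to use (e.g. the output of
#'   [missingnessFilter()]); default all sites.
#' @return A [PairFst-class] object over the retained sites.
#' @export
pairwiseFst <- function(gd, sites = NULL) {
    if (!is.null(sites)) gd <- gd[sites, ]
    ac <- alleleCounts(gd)
    lev <- colnames(ac$called)
    if (length(lev) < 2L) stop("need at least two groups")
    prs <- combn(lev, 2L)
    fst <- matrix(NA_real_, nrow(gd), ncol(prs))
    for (k in seq_len(ncol(prs))) {
        g1 <- prs[1L, k]; g2 <- prs[2L, k]
        n1 <- ac$called[, g1]; n2 <- ac$called[, g2]
        ok <- n1 >= 2 & n2 >= 2
        if (any(ok)) {
            p1 <- ac$alt[ok, g1] / n1[ok]
            p2 <- ac$alt[ok, g2] / n2[ok]
            fst[ok, k] <- hudsonFst(p1, n1[ok], p2, n2[ok])
        }
    }
    colnames(fst) <- paste(prs[1L, ], prs[2L, ], sep = ":")
    rownames(fst) <- rownames(dosage(gd))
    se <- SummarizedExperiment(
        assays = list(fst = fst), rowRanges = rowRanges(gd),
        colData = DataFrame(group1 = prs[1L, ], group2 = prs[2L, ],
                            row.names = colnames(fst)))
    new("PairFst", se)
}

#' @describeIn pairwiseFst the per-site F_ST matrix (sites x pairs).
#' @param x a PairFst object.
#' @export
setMethod("fstValues", "PairFst", function(x)
    SummarizedExperiment::assay(x, "fst"))

#' @describeIn pairwiseFst per-pair mean, sample standard deviation (n-1
#'   denominator) and count over sites with a defined value; pairs with
#'   fewer than two defined sites are flagged unusable (`NA` moments).
#' @export
setMethod("pairSummaries", "PairFst", function(x) {
    f <- fstValues(x)
    n <- colSums(!is.na(f))
    mn <- colMeans(f, na.rm = TRUE)
    sdv <- apply(f, 2L, sd, na.rm = TRUE)
    usable <- n >= 2L
    mn[!usable] <- NA_real_; sdv[!usable] <- NA_real_
    DataFrame(group1 = colData(x)$group1, group2 = colData(x)$group2,
              mean = unname(mn), sd = unname(sdv),
              nSites = as.integer(unname(n)),
              usable = unname(usable), row.names = colnames(f))
})

setMethod("show", "PairFst", function(object) {
    cat("PairFst:", nrow(object), "sites x", ncol(object), "group pairs\n")
    s <- pairSummaries(object)
    cat(sprintf("  mean F_ST range over pairs: [%.4g, %.4g]\n",
                min(s$mean, na.rm = TRUE), max(s$mean, na.rm = TRUE)))
})
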