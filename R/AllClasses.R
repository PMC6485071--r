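#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowRanges
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom stats rbeta rbinom rexp runif cor sd quantile setNames
#' @importFrom utils combn read.table write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## Genotypes
## ---------------------------------------------------------------------------

#' GenotypeData: diploid dosages with site coordinates and group labels
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one assay, `"dosage"`:
#' an integer matrix (sites x samples) of alternate-allele dosages in
#' \{0, 1, 2\}, with `NA` marking missing calls. `rowRanges` carries the site
#' coordinates (1-based, width-1, VCF convention) with `ref`/`alt` alleles in
#' its metadata columns; `colData$group` assigns every sample to exactly one
#' group (the unit of the differentiation scan).
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        v <- d[!is.na(d)]
        if (length(v) && (any(v < 0L) || any(v > 2L)))
            msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
    }
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (anyNA(colData(object)$group))
        msg <- c(msg, "every sample must be assigned to a group")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Pairwise Fst
## ---------------------------------------------------------------------------

#' PairFst: per-site Hudson F_ST for every unordered group pair
#'
#' A \linkS4class{RangedSummarizedExperiment} with one assay `"fst"`
#' (sites x pairs); `NA` flags sites where the estimator is undefined for a
#' pair (fewer than two called alleles in a group, or the site monomorphic
#' and identical in both groups). `colData` names the two groups of each
#' pair. Negative values are retained: the downstream d statistic
#' standardises against each pair's own mean and standard deviation, so
#' clipping would bias those moments.
#'
#' @export
setClass("PairFst", contains = "RangedSummarizedExperiment")

setValidity("PairFst", function(object) {
    msg <- NULL
    if (!"fst" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'fst' is required")
    if (!all(c("group1", "group2") %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain 'group1' and 'group2'")
    f <- SummarizedExperiment::assay(object, "fst")
    if (any(f[!is.na(f)] > 1 + 1e-12))
        msg <- c(msg, "F_ST values cannot exceed 1")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## d scan
## ---------------------------------------------------------------------------

#' DScanResult: per-site, per-group d statistic with empirical percentiles
#'
#' A \linkS4class{RangedSummarizedExperiment} with assays `"d"` (sites x
#' groups; `NA` where any required pair F_ST is undefined at the site),
#' `"percentile"` (percent of defined variants in the same group with a
#' strictly higher d), and `"outlier"` (logical). Percentile and outlier
#' assays are populated by [callOutliers()].
#'
#' @export
setClass("DScanResult", contains = "RangedSummarizedExperiment")

setValidity("DScanResult", function(object) {
    msg <- NULL
    if (!"d" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'd' is required")
    else if (isTRUE(metadata(object)$squared)) {
        ## the canonical (squared-numerator) form is non-negative; the
        ## signed comparison variant is not
        d <- SummarizedExperiment::assay(object, "d")
        if (any(d[!is.na(d)] < 0))
            msg <- c(msg, "d values are non-negative by construction")
    }
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## LD clumping
## ---------------------------------------------------------------------------

#' ClumpResult: greedy LD clumps of outlier variants for one focal group
#'
#' @slot group focal group label.
#' @slot tags `GRanges` of index ("tag") variants, one per clump, with
#'   metadata columns `site`, `d` and `percentile` (fraction of variants
#'   with a higher d).
#' @slot members `DataFrame` mapping every claimed member to its tag:
#'   `site`, `tagSite`, `r2`, `distanceBp`. Tags are included as
#'   members of their own clump with `r2 = 1`, `distanceBp = 0`.
#' @slot params list of the clumping parameters used.
#'
#' @export
setClass("ClumpResult",
    representation(group = "character", tags = "GRanges",
                   members = "DataFrame", params = "list"))

setValidity("ClumpResult", function(object) {
    msg <- NULL
    m <- object@members
    if (nrow(m) && anyDuplicated(m$site))
        msg <- c(msg, "a variant cannot belong to more than one clump")
    if (nrow(m) && !all(m$tagSite %in% mcols(object@tags)$site))
        msg <- c(msg, "members must point at an existing tag")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Annotation-shift enrichment
## ---------------------------------------------------------------------------

#' LocusSet: tag variants with their LD proxies and padded local spans
#'
#' One locus per tag variant: the tag position, the positions of all LD
#' partners (r-squared above the proxy threshold within the distance
#' horizon), and a local span (partner range padded on both sides) inside
#' which annotation intervals are circularly shifted under the permutation
#' null.
#'
#' @slot spans `GRanges`, one padded span per locus (1-based inclusive).
#' @slot snps list of integer vectors: SNP positions (tag + proxies) per locus.
#' @slot tagPos integer vector of tag positions, one per locus.
#' @slot pad padding applied on each side of the partner span, in bp.
#'
#' @export
setClass("LocusSet",
    representation(spans = "GRanges", snps = "list", tagPos = "integer",
                   pad = "numeric"))

setValidity("LocusSet", function(object) {
    msg <- NULL
    n <- length(object@spans)
    if (length(object@snps) != n || length(object@tagPos) != n)
        msg <- c(msg, "spans, snps and tagPos must have one entry per locus")
    if (n) {
        inside <- object@tagPos >= start(object@spans) &
                  object@tagPos <= end(object@spans)
        if (!all(inside)) msg <- c(msg, "every tag must lie inside its span")
    }
    if (is.null(msg)) TRUE else msg
})

#' EnrichmentResult: one category's shift-permutation test
#'
#' @slot category annotation category label.
#' @slot observed observed score: number of loci with at least one SNP inside
#'   an annotation interval.
#' @slot permScores integer vector of permuted scores (length `nPerm`).
#' @slot p empirical P value, `max(#\{perm >= observed\}, 1) / nPerm`.
#' @slot nPerm number of permutations.
#' @slot nLoci number of loci tested.
#' @slot nInvariant number of loci whose local annotation footprint fills (or
#'   misses) the span entirely, so shifting cannot change their state.
#'
#' @export
setClass("EnrichmentResult",
    representation(category = "character", observed = "integer",
                   permScores = "integer", p = "numeric", nPerm = "integer",
                   nLoci = "integer", nInvariant = "integer"))

setValidity("EnrichmentResult", function(object) {
    msg <- NULL
    if (object@p <= 0 || object@p > 1)
        msg <- c(msg, "P must lie in (0, 1]")
    if (object@observed < 0L || object@observed > object@nLoci)
        msg <- c(msg, "observed score must lie in [0, nLoci]")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Coalescence rates / RCCR
## ---------------------------------------------------------------------------

#' RateCurve: binned coalescence rates for two demes and their cross pair
#'
#' Hazard-style coalescence rates per time bin for within-deme-1 (lambda00),
#' cross-deme (lambda01) and within-deme-2 (lambda11) lineage pairs, in the
#' layout MSMC writes its final rates. Time units are whatever the producer
#' used (generations for the clean-split simulator, mutation-scaled units for
#' MSMC output); `NA` rates flag bins with zero lineage-pair exposure.
#'
#' @slot left,right bin boundaries, strictly increasing, `left[1] >= 0`.
#' @slot rates numeric matrix (bins x 3), columns
#'   `lambda00`, `lambda01`, `lambda11`.
#'
#' @export
setClass("RateCurve",
    representation(left = "numeric", right = "numeric", rates = "matrix"))

setValidity("RateCurve", function(object) {
    msg <- NULL
    n <- length(object@left)
    if (length(object@right) != n || nrow(object@rates) != n)
        msg <- c(msg, "left, right and rates must agree in length")
    if (n) {
        if (any(diff(object@left) <= 0) ||
            any(diff(object@right[is.finite(object@right)]) <= 0))
            msg <- c(msg, "bin boundaries must be strictly increasing")
        if (any(object@right <= object@left))
            msg <- c(msg, "right boundary must exceed left boundary")
        if (object@left[1L] < 0)
            msg <- c(msg, "time starts at or after 0")
    }
    if (!identical(colnames(object@rates),
                   c("lambda00", "lambda01", "lambda11")))
        msg <- c(msg, "rate columns must be lambda00, lambda01, lambda11")
    r <- object@rates[!is.na(object@rates)]
    if (length(r) && any(r < 0)) msg <- c(msg, "rates must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' RccrCurve: relative cross-coalescence rate per time bin
#'
#' RCCR = 2 * lambda_cross / (lambda_within1 + lambda_within2); about 1 while
#' the two demes still behave as one ancestral population and tending to 0
#' after complete separation. Values above 1 (estimation noise) are retained.
#' `mid` is the representative bin time used for interpolation (arithmetic
#' midpoint; left boundary for an open-ended last bin).
#'
#' @slot left,right,mid bin boundaries and representative times.
#' @slot rccr RCCR per bin, `NA` where undefined.
#' @slot timeUnit free-text label for the time axis (e.g. "generations",
#'   "scaled", "years").
#'
#' @export
setClass("RccrCurve",
    representation(left = "numeric", right = "numeric", mid = "numeric",
                   rccr = "numeric", timeUnit = "character"))

setValidity("RccrCurve", function(object) {
    msg <- NULL
    if (any(object@rccr[!is.na(object@rccr)] < 0))
        msg <- c(msg, "RCCR must be non-negative")
    if (is.unsorted(object@mid, strictly = TRUE))
        msg <- c(msg, "bin representative times must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' ScalingParams: mutation-rate scaling between coalescent and clock time
#'
#' `nu` is the per-site mutation rate per year, `g` the generation time in
#' years, and `mu = nu * g` the per-site rate per generation. Scaled times
#' divide by `nu` to give years; scaled rates invert and divide by `2 * mu`
#' to give diploid effective sizes.
#'
#' @slot nu mutations per site per year.
#' @slot g generation time, years.
#'
#' @export
setClass("ScalingParams", representation(nu = "numeric", g = "numeric"))

setValidity("ScalingParams", function(object) {
    if (length(object@nu) != 1L || length(object@g) != 1L ||
        object@nu <= 0 || object@g <= 0)
        "nu and g must be positive scalars" else TRUE
})

#' DivergenceEstimate: RCCR threshold-crossing times
#'
#' Times (present to past) at which the RCCR first rises through 0.25, 0.5
#' and 0.75; the 0.5 crossing is the divergence-time definition, the
#' 0.25/0.75 crossings bound the reported interval. `NA` marks thresholds the
#' curve never crosses (e.g. populations that never diverged).
#'
#' @slot t25,t50,t75 crossing times (same unit as the input curve).
#' @slot timeUnit time unit label.
#'
#' @export
setClass("DivergenceEstimate",
    representation(t25 = "numeric", t50 = "numeric", t75 = "numeric",
                   timeUnit = "character"))

setValidity("DivergenceEstimate", function(object) {
    ts <- c(object@t25, object@t50, object@t75)
    ts <- ts[!is.na(ts)]
    if (length(ts) > 1L && is.unsorted(ts))
        "crossing times must be ordered t25 <= t50 <= t75" else TRUE
})
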