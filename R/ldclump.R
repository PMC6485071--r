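#' Squared genotype-dosage correlation (composite LD)
#'
#' r-squared between two dosage vectors over pairwise-complete samples.
#' This is composite LD on unphased genotypes, not haplotype-frequency
#' r-squared; the correlation is sign-blind, so perfect repulsion
#' (y = 2 - x) also gives 1. `NA` when fewer than two complete pairs remain
#' or either vector is constant.
#'
#' @param x,y integer dosage vectors of equal length (`NA` = missing).
#' @return squared Pearson correlation in [0, 1], or `NA`.
#' @export
genotypeR2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
}

#' Greedy LD clumping of outlier variants
#'
#' Mirrors the classic clump procedure on empirical d percentiles: candidate
#' index variants are those whose percentile (as a fraction: number of
#' variants with a higher d over all defined variants) is below `p1`,
#' visited in increasing percentile (decreasing d) order with genomic
#' position breaking ties. Each still-unclaimed index claims, as members,
#' every unclaimed variant below `p2` that lies within `windowKb` of the
#' index (tag-to-member distance, same chromosome) and has r-squared above
#' `r2Thresh` with it. Each clump's tag is its index variant — by
#' construction the member with the highest d.
#'
#' @param ds a [DScanResult-class] with outliers called.
#' @param group focal group label.
#' @param gd the [GenotypeData-class] the scan was computed from (r-squared
#'   source); sites are matched by name.
#' @param p1 index-variant percentile threshold (fraction; 0.001 = top 0.1\%).
#' @param p2 member percentile threshold (fraction).
#' @param windowKb maximum tag-to-member distance, kb.
#' @param r2Thresh r-squared above which a variant joins the clump.
#' @return A [ClumpResult-class].
#' @export
clumpOutliers <- function(ds, group, gd, p1 = 0.001, p2 = 0.01,
                          windowKb = 1000, r2Thresh = 0.5) {
    stopifnot(p1 > 0, p2 >= p1, windowKb > 0,
              r2Thresh >= 0, r2Thresh <= 1)
    d <- dValues(ds)[, group]
    f <- percentiles(ds)[, group] / 100       # fraction with higher d
    if (all(is.na(f))) stop("run callOutliers() before clumping")
    rr <- rowRanges(ds)
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    dos <- dosage(gd)
    site <- names(rowRanges(ds))
    if (!all(site %in% rownames(dos)))
        stop("scan sites missing from the genotype matrix")
    dos <- dos[site, , drop = FALSE]

    def <- !is.na(f)
    cand <- which(def & f < p1)
    pool <- def & f < p2
    cand <- cand[order(f[cand], pos[cand])]
    claimed <- logical(length(f))
    tagIdx <- integer(0)
    mem <- list()
    maxDist <- windowKb * 1000
    for (i in cand) {
        if (claimed[i]) next
        claimed[i] <- TRUE
        near <- which(pool & !claimed & chrom == chrom[i] &
                      abs(pos - pos[i]) <= maxDist)
        r2 <- vapply(near, function(j) genotypeR2(dos[i, ], dos[j, ]),
                     numeric(1L))
        take <- near[!is.na(r2) & r2 > r2Thresh]
        claimed[take] <- TRUE
        tagIdx <- c(tagIdx, i)
        mem[[length(mem) + 1L]] <- DataFrame(
            site = site[c(i, take)], tagSite = site[i],
            r2 = c(1, r2[match(take, near)]),
            distanceBp = abs(pos[c(i, take)] - pos[i]))
    }
    tags <- rr[tagIdx]
    mcols(tags) <- DataFrame(site = site[tagIdx], d = d[tagIdx],
                             percentile = f[tagIdx])
    members <- if (length(mem)) do.call(rbind, mem) else
        DataFrame(site = character(0), tagSite = character(0),
                  r2 = numeric(0), distanceBp = numeric(0))
    new("ClumpResult", group = group, tags = tags, members = members,
        params = list(p1 = p1, p2 = p2, windowKb = windowKb,
                      r2Thresh = r2Thresh))
}

#' @describeIn clumpOutliers tag (index) variants as a `GRanges`.
#' @param x a ClumpResult.
#' @export
setMethod("tags", "ClumpResult", function(x) x@tags)

#' @describeIn clumpOutliers member-to-tag assignment table.
#' @param i unused (required by the generic's signature).
#' @export
setMethod("members", "ClumpResult", function(x, i) x@members)

setMethod("show", "ClumpResult", function(object) {
    cat("ClumpResult for group", object@group, "\n")
    cat("  ", length(object@tags), "clumps,", nrow(object@members),
        "member variants\n")
})

#' Merged selection windows around tag variants
#'
#' For each tag, the interval spanning the minimum to maximum position of
#' all variants within `horizonBp` of the tag and with r-squared above
#' `ldThresh` with it (the tag itself included; an isolated tag yields a
#' 1-bp window at its own position). Overlapping intervals are merged.
#'
#' @param clump a [ClumpResult-class].
#' @param gd the [GenotypeData-class] supplying candidate variants and the
#'   r-squared source.
#' @param ldThresh strong-LD r-squared threshold (default 0.8).
#' @param horizonBp search distance around the tag, bp (default 1 Mb).
#' @return `GRanges` of merged windows (1-based inclusive internally; use
#'   [writeWindowsBed()] for 0-based half-open BED); metadata column
#'   `nTags` counts tags per merged window.
#' @export
selectionWindows <- function(clump, gd, ldThresh = 0.8, horizonBp = 1e6) {
    tg <- tags(clump)
    if (!length(tg)) return(GRanges())
    rr <- rowRanges(gd)
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    dos <- dosage(gd)
    spans <- lapply(seq_along(tg), function(k) {
        i <- match(mcols(tg)$site[k], names(rr))
        near <- which(chrom == chrom[i] & abs(pos - pos[i]) <= horizonBp)
        r2 <- vapply(near, function(j) genotypeR2(dos[i, ], dos[j, ]),
                     numeric(1L))
        take <- near[!is.na(r2) & r2 > ldThresh]
        take <- union(take, i)
        GRanges(chrom[i], IRanges(min(pos[take]), max(pos[take])))
    })
    win <- reduce(do.call(c, spans))
    hit <- findOverlaps(tg, win)
    mcols(win)$nTags <- tabulate(S4Vectors::subjectHits(hit), length(win))
    win
}
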