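#' Build loci (tag + LD proxies + padded span) for enrichment testing
#'
#' One locus per clump tag: the tag, every variant within `horizonBp` and
#' r-squared above `proxyR2` with it, and a span covering the proxy range
#' padded by `pad` on each side (floored at position 1) so the shift null
#' has local background to move annotations within.
#'
#' @param clump a [ClumpResult-class].
#' @param gd the [GenotypeData-class] supplying proxies and r-squared.
#' @param proxyR2 r-squared threshold for LD proxies (default 0.8).
#' @param horizonBp proxy search distance, bp.
#' @param pad span padding per side, bp (default 50 kb).
#' @return A [LocusSet-class].
#' @export
tagLoci <- function(clump, gd, proxyR2 = 0.8, horizonBp = 1e6, pad = 5e4) {
    tg <- tags(clump)
    rr <- rowRanges(gd)
    chrom <- as.character(seqnames(rr))
    pos <- start(rr)
    dos <- dosage(gd)
    snps <- vector("list", length(tg))
    spanStart <- spanEnd <- tagPos <- integer(length(tg))
    spanChrom <- character(length(tg))
    for (k in seq_along(tg)) {
        i <- match(mcols(tg)$site[k], names(rr))
        near <- which(chrom == chrom[i] & abs(pos - pos[i]) <= horizonBp)
        r2 <- vapply(near, function(j) genotypeR2(dos[i, ], dos[j, ]),
                     numeric(1L))
        take <- union(near[!is.na(r2) & r2 > proxyR2], i)
        snps[[k]] <- sort(pos[take])
        spanChrom[k] <- chrom[i]
        spanStart[k] <- max(1L, min(pos[take]) - as.integer(pad))
        spanEnd[k] <- max(pos[take]) + as.integer(pad)
        tagPos[k] <- pos[i]
    }
    new("LocusSet",
        spans = GRanges(spanChrom, IRanges(spanStart, spanEnd)),
        snps = snps, tagPos = tagPos, pad = pad)
}

#' @describeIn tagLoci locus spans as `GRanges`.
#' @param x a LocusSet.
#' @export
setMethod("spans", "LocusSet", function(x) x@spans)

setMethod("show", "LocusSet", function(object) {
    cat("LocusSet:", length(object@spans), "loci,",
        sum(lengths(object@snps)), "SNPs, pad", object@pad, "bp\n")
})

#' Observed annotation-overlap score
#'
#' Number of loci in which at least one SNP (tag or LD proxy) falls inside
#' any interval of the annotation track.
#'
#' @param loci a [LocusSet-class].
#' @param track annotation intervals as a `GRanges` (one category).
#' @return integer score in [0, number of loci].
#' @export
observedOverlap <- function(loci, track) {
    if (!length(track) || !length(loci@spans)) return(0L)
    n <- lengths(loci@snps)
    snpGr <- GRanges(rep(as.character(seqnames(loci@spans)), n),
                     IRanges(unlist(loci@snps), width = 1L))
    hit <- unique(rep.int(seq_along(n), n)[
        S4Vectors::queryHits(findOverlaps(snpGr, track))])
    length(hit)
}

#' Locus-local annotation-shift permutation test
#'
#' Keeps SNP positions fixed and, per permutation, circularly shifts each
#' locus's local annotation intervals by an independent uniform offset
#' (wrapping within the locus span), then recomputes the overlap score. The
#' empirical P value is `max(#\{permuted >= observed\}, 1) / nPerm`: the
#' observed configuration is never impossible under the null, so P is
#' floored at 1/nPerm rather than reported as 0. Loci whose local annotation
#' footprint is empty or fills the whole span cannot change state under any
#' shift; they contribute their observed state to every permutation and are
#' counted in `nInvariant`.
#'
#' @param loci a [LocusSet-class].
#' @param track annotation `GRanges` for one category.
#' @param nPerm number of permutations (>= 1; default 10000).
#' @param seed integer seed.
#' @param category label stored on the result.
#' @return An [EnrichmentResult-class].
#' @export
shiftPermutation <- function(loci, track, nPerm = 10000L, seed = 1L,
                             category = "annotation") {
    stopifnot(nPerm >= 1L)
    set.seed(.stageSeed(seed, "permutation"))
    nLoci <- length(loci@spans)
    scores <- integer(nPerm)
    observed <- 0L
    nInv <- 0L
    spanChrom <- as.character(seqnames(loci@spans))
    trkChrom <- as.character(seqnames(track))
    for (k in seq_len(nLoci)) {
        L <- start(loci@spans)[k]; R <- end(loci@spans)[k]
        W <- R - L + 1L
        sel <- trkChrom == spanChrom[k] & start(track) <= R & end(track) >= L
        ## clipped local intervals, 0-based half-open relative to the span
        iv <- reduce(IRanges(pmax(start(track)[sel], L),
                             pmin(end(track)[sel], R)))
        rs <- start(iv) - L
        re <- end(iv) - L + 1L
        foot <- sum(re - rs)
        snpRel <- loci@snps[[k]] - L
        bnds <- as.vector(rbind(rs, re))     # sorted by construction
        inside <- function(x) findInterval(x, bnds) %% 2L == 1L
        obsK <- any(inside(snpRel))
        observed <- observed + obsK
        if (foot == 0L || foot >= W) {       # shift cannot change the state
            nInv <- nInv + 1L
            scores <- scores + obsK
            next
        }
        offsets <- sample.int(W, nPerm, replace = TRUE) - 1L
        ## shifting annotations by +o equals shifting SNPs by -o (mod W)
        shifted <- outer(snpRel, offsets, function(s, o) (s - o) %% W)
        scores <- scores + (colSums(matrix(inside(shifted),
                                           nrow = length(snpRel))) > 0L)
    }
    if (nInv)
        message(nInv, " locus/loci shift-invariant ",
                "(annotation footprint empty or covering the span)")
    p <- max(sum(scores >= observed), 1L) / nPerm
    new("EnrichmentResult", category = category,
        observed = as.integer(observed), permScores = scores, p = p,
        nPerm = as.integer(nPerm), nLoci = as.integer(nLoci),
        nInvariant = as.integer(nInv))
}

#' @describeIn shiftPermutation permuted scores (length `nPerm`).
#' @param x an EnrichmentResult.
#' @export
setMethod("permScores", "EnrichmentResult", function(x) x@permScores)

#' @describeIn shiftPermutation empirical P value.
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@p)

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult '%s': observed %d/%d loci, P = %.4g (%d permutations)\n",
                object@category, object@observed, object@nLoci, object@p,
                object@nPerm))
})

#' Bonferroni family-wise error threshold
#'
#' @param nCategories number of annotation categories tested (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return per-test P threshold `alpha / nCategories`.
#' @examples
#' bonferroniThreshold(9)   # 0.00556 at 3 significant figures
#' @export
bonferroniThreshold <- function(nCategories, alpha = 0.05) {
    if (nCategories < 1L) stop("need at least one category")
    alpha / nCategories
}

#' Run the shift-permutation test over several annotation categories
#'
#' @param loci a [LocusSet-class].
#' @param tracks named list of annotation `GRanges` (names = category
#'   labels), e.g. from [readAnnotationBed()].
#' @param nPerm permutations per category.
#' @param seed integer seed (a distinct substream per category).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return `DataFrame` with one row per category: observed score, P and the
#'   significance flag at the Bonferroni-corrected threshold.
#' @export
annotationEnrichment <- function(loci, tracks, nPerm = 10000L, seed = 1L,
                                 alpha = 0.05) {
    stopifnot(length(tracks) >= 1L, !is.null(names(tracks)))
    thr <- bonferroniThreshold(length(tracks), alpha)
    res <- lapply(seq_along(tracks), function(k)
        shiftPermutation(loci, tracks[[k]], nPerm = nPerm,
                         seed = seed + k, category = names(tracks)[k]))
    DataFrame(category = names(tracks),
              observed = vapply(res, function(r) r@observed, integer(1L)),
              nLoci = length(loci@spans),
              p = vapply(res, pValue, numeric(1L)),
              significant = vapply(res, pValue, numeric(1L)) < thr,
              row.names = names(tracks))
}

#' Read annotation BED files, one category per file
#'
#' @param paths character vector of BED paths; category labels default to
#'   the file stems.
#' @return named list of `GRanges` (1-based inclusive internally;
#'   `rtracklayer` performs the BED 0-based half-open conversion).
#' @export
readAnnotationBed <- function(paths) {
    labels <- sub("\\.bed$", "", basename(paths))
    setNames(lapply(paths, rtracklayer::import, format = "bed"), labels)
}

#' Write genomic windows as BED (0-based half-open)
#'
#' @param gr a `GRanges` (1-based inclusive, the in-memory convention).
#' @param path output path; a `track` line states the coordinate convention.
#' @export
writeWindowsBed <- function(gr, path) {
    lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   sep = "\t")
    writeLines(c(paste0("track name=selectionWindows ",
                        "description=\"0-based half-open BED\""), lines),
               path)
    invisible(path)
}
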