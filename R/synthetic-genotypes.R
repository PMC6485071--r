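#' Spike-in configuration for the Balding-Nichols generator
#'
#' Describes planted high-differentiation loci: at `nSpiked` randomly chosen
#' sites the focal group's allele frequency is shifted additively by
#' `freqShift` (then clamped to [0, 1]) before genotypes are drawn, mimicking
#' a locally adapted allele. The generator's truth table records which sites
#' were spiked and the realised group frequencies.
#'
#' @param nSpiked number of spiked sites.
#' @param focalGroup index (1-based) of the group receiving the shift.
#' @param freqShift additive frequency shift in (0, 1].
#' @export
spikeConfig <- function(nSpiked, focalGroup = 1L, freqShift = 0.4) {
    stopifnot(nSpiked >= 1L, focalGroup >= 1L,
              freqShift > 0, freqShift <= 1)
    list(nSpiked = as.integer(nSpiked), focalGroup = as.integer(focalGroup),
         freqShift = freqShift)
}

#' Simulate multi-group genotypes under the Balding-Nichols model
#'
#' Each site draws an ancestral frequency p uniformly from `ancestralRange`;
#' each group's frequency comes from a Beta distribution with mean p and
#' variance p(1-p)F (shape parameters p(1-F)/F and (1-p)(1-F)/F), so F
#' controls the expected differentiation between groups. Diploid genotypes
#' are Binomial(2, group frequency); missing calls are dropped independently
#' per call. Sites are independent (no linkage) — use [blockCopyVariants()]
#' to graft LD structure on top.
#'
#' Defaults emulate a small-cohort multi-ancestry scan: six groups of 25
#' diploid individuals, typical genome-wide background differentiation
#' (F = 0.02), ancestral frequencies kept off the boundaries to stabilise
#' per-site F_ST moments.
#'
#' @param nGroups number of groups.
#' @param samplesPerGroup diploid individuals per group.
#' @param nSites number of biallelic sites.
#' @param F drift parameter per group in (0, 1); recycled to `nGroups`.
#' @param ancestralRange interval within (0, 1) for the ancestral frequency.
#' @param missingRate per-call missingness probability in [0, 1).
#' @param spike optional [spikeConfig()].
#' @param positions site positions (default 1 kb spacing on chromosome "1").
#' @param chrom chromosome label.
#' @param seed integer seed; identical seeds reproduce output bit-identically.
#' @return list with `genotypes` ([GenotypeData-class]) and `truth`, a
#'   data.frame of per-site ancestral and realised group frequencies plus a
#'   `spiked` flag.
#' @examples
#' sim <- simulateGenotypes(nGroups = 2, samplesPerGroup = 10, nSites = 100,
#'                          F = 0.1, seed = 1)
#' sim$genotypes
#' @export
simulateGenotypes <- function(nGroups = 6L, samplesPerGroup = 25L,
                              nSites = 1e5L, F = 0.02,
                              ancestralRange = c(0.05, 0.95),
                              missingRate = 0.05, spike = NULL,
                              positions = NULL, chrom = "1", seed = 1L) {
    F <- rep_len(F, nGroups)
    if (any(F <= 0 | F >= 1)) stop("F must lie in (0, 1) for every group")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    if (nSites < 1L) stop("need at least one site")
    if (length(ancestralRange) != 2L || ancestralRange[1L] <= 0 ||
        ancestralRange[2L] >= 1 || diff(ancestralRange) <= 0)
        stop("ancestralRange must be an increasing interval within (0, 1)")
    if (!is.null(spike) && spike$nSpiked > nSites)
        stop("cannot spike more sites than exist")
    if (!is.null(spike) && spike$focalGroup > nGroups)
        stop("focal group does not exist")

    set.seed(.stageSeed(seed, "genotypes"))
    p <- runif(nSites, ancestralRange[1L], ancestralRange[2L])
    q <- matrix(0, nSites, nGroups)
    for (g in seq_len(nGroups))
        q[, g] <- rbeta(nSites, p * (1 - F[g]) / F[g],
                        (1 - p) * (1 - F[g]) / F[g])

    spiked <- logical(nSites)
    if (!is.null(spike)) {
        idx <- sample.int(nSites, spike$nSpiked)
        spiked[idx] <- TRUE
        q[idx, spike$focalGroup] <-
            pmin(1, pmax(0, q[idx, spike$focalGroup] + spike$freqShift))
    }

    nTot <- nGroups * samplesPerGroup
    dos <- matrix(NA_integer_, nSites, nTot)
    for (g in seq_len(nGroups)) {
        cols <- (g - 1L) * samplesPerGroup + seq_len(samplesPerGroup)
        dos[, cols] <- rbinom(nSites * samplesPerGroup, 2L, q[, g])
    }
    if (missingRate > 0)
        dos[runif(length(dos)) < missingRate] <- NA_integer_

    if (is.null(positions)) positions <- seq_len(nSites) * 1000L
    groups <- rep(paste0("G", seq_len(nGroups)), each = samplesPerGroup)
    colnames(dos) <- paste0(groups, "_s",
                            rep(seq_len(samplesPerGroup), nGroups))
    rownames(dos) <- paste0("site", seq_len(nSites))
    gd <- GenotypeData(dos, chrom = chrom, pos = positions, groups = groups)
    truth <- data.frame(site = rownames(dos), chrom = chrom, pos = positions,
                        ancestralFreq = p, spiked = spiked)
    truth[paste0("freqG", seq_len(nGroups))] <- q
    list(genotypes = gd, truth = truth)
}

#' Graft LD blocks onto independent sites by block-copying genotypes
#'
#' The Balding-Nichols generator draws sites independently, so it carries no
#' linkage. This helper inserts, after each selected source site, `copies`
#' new sites whose genotype vectors are copies of the source with each call
#' reflected (x -> 2 - x) independently with probability `flipProb`,
#' producing blocks of known, tunable r-squared. New sites are placed at
#' `spacingBp` intervals after the source.
#'
#' @param gd a [GenotypeData-class] object.
#' @param sites integer indices of source sites.
#' @param copies number of LD partners to create per source site.
#' @param flipProb per-call reflection probability (0 gives r-squared 1).
#' @param spacingBp spacing between inserted sites, bp.
#' @param seed integer seed.
#' @return list with `genotypes` (new [GenotypeData-class], sites sorted by
#'   position) and `blocks`, a data.frame mapping each inserted site id to
#'   its source site id.
#' @export
blockCopyVariants <- function(gd, sites, copies = 3L, flipProb = 0,
                              spacingBp = 2000L, seed = 1L) {
    set.seed(.stageSeed(seed, "ldblocks"))
    dos <- dosage(gd)
    rr <- rowRanges(gd)
    newDos <- list(); newPos <- c(); newChrom <- c(); src <- c()
    for (s in sites) {
        for (k in seq_len(copies)) {
            x <- dos[s, ]
            flip <- !is.na(x) & runif(length(x)) < flipProb
            x[flip] <- 2L - x[flip]
            newDos[[length(newDos) + 1L]] <- x
            newPos <- c(newPos, start(rr)[s] + k * spacingBp)
            newChrom <- c(newChrom, as.character(seqnames(rr)[s]))
            src <- c(src, rownames(dos)[s])
        }
    }
    add <- do.call(rbind, newDos)
    rownames(add) <- paste0(src, "_ld", sequence(rep(copies, length(sites))))
    allDos <- rbind(dos, add)
    allChrom <- c(as.character(seqnames(rr)), newChrom)
    allPos <- c(start(rr), newPos)
    ord <- order(allChrom, allPos)
    out <- GenotypeData(allDos[ord, , drop = FALSE], chrom = allChrom[ord],
                        pos = allPos[ord], groups = sampleGroups(gd))
    list(genotypes = out,
         blocks = data.frame(site = rownames(add), source = src))
}

## deterministic per-stage substreams from one user-facing seed, so stages
## can be rerun independently without sharing an RNG stream
.stageSeed <- function(seed, stage) {
    offsets <- c(genotypes = 101L, ldblocks = 211L, coalescence = 307L,
                 permutation = 401L, pipeline = 503L, annotation = 601L)
    off <- offsets[[stage]]
    as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}
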