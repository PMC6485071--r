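#' Pipeline configuration with the scan's canonical defaults
#'
#' Defaults are the study-convention values carried by every stage: 20\%
#' per-group missingness tolerance, top 0.1\% outliers, clump thresholds
#' 0.001 / 0.01 with a 1000 kb window and r-squared 0.5, selection windows
#' at r-squared 0.8 within 1 Mb, 10,000 permutations with family-wise error
#' 0.05, and mutation-rate scaling nu = 4.3e-10 per year with a 29-year
#' generation time.
#'
#' @param maxMissing per-group missingness tolerance.
#' @param topFraction outlier fraction.
#' @param clumpP1,clumpP2,clumpKb,clumpR2 clumping parameters.
#' @param windowR2,windowBp selection-window LD threshold and horizon.
#' @param lociPad locus span padding for enrichment, bp.
#' @param nPerm permutations per annotation category.
#' @param alpha family-wise error rate.
#' @param nu,g mutation rate per year and generation time.
#' @param seed global seed fanned out to per-stage substreams.
#' @return a validated config list of class `popdiffConfig`.
#' @export
pipelineConfig <- function(maxMissing = 0.20, topFraction = 0.001,
                           clumpP1 = 0.001, clumpP2 = 0.01, clumpKb = 1000,
                           clumpR2 = 0.5, windowR2 = 0.8, windowBp = 1e6,
                           lociPad = 5e4, nPerm = 10000L, alpha = 0.05,
                           nu = 4.3e-10, g = 29, seed = 1L) {
    cfg <- list(maxMissing = maxMissing, topFraction = topFraction,
                clumpP1 = clumpP1, clumpP2 = clumpP2, clumpKb = clumpKb,
                clumpR2 = clumpR2, windowR2 = windowR2, windowBp = windowBp,
                lociPad = lociPad, nPerm = as.integer(nPerm), alpha = alpha,
                nu = nu, g = g, seed = as.integer(seed))
    with(cfg, stopifnot(maxMissing >= 0, maxMissing < 1,
                        topFraction > 0, topFraction < 1,
                        clumpP1 > 0, clumpP2 >= clumpP1, clumpKb > 0,
                        clumpR2 >= 0, clumpR2 <= 1,
                        windowR2 >= 0, windowR2 <= 1, windowBp > 0,
                        nPerm >= 1L, alpha > 0, alpha < 1, nu > 0, g > 0))
    structure(cfg, class = "popdiffConfig")
}

#' Run the differentiation scan end to end
#'
#' filter -> pairwise F_ST -> d statistic -> outliers -> clump -> selection
#' windows (-> annotation enrichment when tracks are supplied), writing
#' every stage table under `outdir` together with the serialized config and
#' a run manifest (inputs, checksums, seed, stage log). Variant tables are
#' 1-based (VCF convention), interval outputs 0-based half-open BED; each
#' file header states its convention. A stage failure aborts with the
#' failing stage named. Identical inputs and seed reproduce identical stage
#' outputs.
#'
#' @param genotypes a [GenotypeData-class], or `NULL` to read from paths.
#' @param vcfPath,groupPath input paths (used when `genotypes` is `NULL`).
#' @param annotationBeds optional character vector of BED paths (one
#'   category per file) for the enrichment stage.
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(genotypes = NULL, vcfPath = NULL, groupPath = NULL,
                        annotationBeds = NULL, config = pipelineConfig(),
                        outdir = "popdiff_out") {
    stopifnot(inherits(config, "popdiffConfig"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    hdr1 <- "# coordinates: 1-based positions (VCF convention)"
    writeTsv <- function(df, file, header = hdr1) {
        con <- file.path(outdir, file)
        writeLines(header, con)
        suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                     row.names = FALSE, append = TRUE))
    }

    gd <- stage("input", {
        if (is.null(genotypes)) {
            if (is.null(vcfPath) || is.null(groupPath))
                stop("need either genotypes or vcfPath + groupPath")
            readVcfGenotypes(vcfPath, groupPath)
        } else genotypes
    })

    keep <- stage("missingness_filter",
                  missingnessFilter(gd, config$maxMissing))
    log$missingness <- as.list(attr(keep, "counts"))

    pf <- stage("fst", pairwiseFst(gd, sites = keep))
    ps <- pairSummaries(pf)
    writeTsv(as.data.frame(ps), "pair_fst_summary.tsv",
             header = "# per-pair F_ST moments over retained sites")

    ds <- stage("dscan", callOutliers(dStatistic(pf),
                                      topFraction = config$topFraction))
    rr <- rowRanges(ds)
    groups <- colnames(dValues(ds))
    clumps <- list(); windows <- list(); loci <- list()
    for (grp in groups) {
        tab <- data.frame(chrom = as.character(seqnames(rr)),
                          pos = start(rr), site = names(rr),
                          d = dValues(ds)[, grp],
                          percentile = percentiles(ds)[, grp],
                          outlier = outlierCalls(ds)[, grp])
        writeTsv(tab, paste0("dscan_", grp, ".tsv"))
        cl <- stage(paste0("clump_", grp),
                    clumpOutliers(ds, grp, gd, p1 = config$clumpP1,
                                  p2 = config$clumpP2,
                                  windowKb = config$clumpKb,
                                  r2Thresh = config$clumpR2))
        clumps[[grp]] <- cl
        writeTsv(as.data.frame(members(cl)), paste0("clumps_", grp, ".tsv"))
        win <- stage(paste0("windows_", grp),
                     selectionWindows(cl, gd, ldThresh = config$windowR2,
                                      horizonBp = config$windowBp))
        windows[[grp]] <- win
        writeWindowsBed(win, file.path(outdir,
                                       paste0("windows_", grp, ".bed")))
        loci[[grp]] <- tagLoci(cl, gd, proxyR2 = config$windowR2,
                               horizonBp = config$windowBp,
                               pad = config$lociPad)
        log[[paste0("clumps_", grp)]] <- length(tags(cl))
    }

    enrich <- NULL
    if (!is.null(annotationBeds) && length(annotationBeds)) {
        tracks <- stage("annotation_input", readAnnotationBed(annotationBeds))
        enrich <- lapply(groups, function(grp)
            stage(paste0("enrich_", grp),
                  annotationEnrichment(loci[[grp]], tracks,
                                       nPerm = config$nPerm,
                                       seed = config$seed,
                                       alpha = config$alpha)))
        names(enrich) <- groups
        for (grp in groups)
            writeTsv(as.data.frame(enrich[[grp]]),
                     paste0("enrichment_", grp, ".tsv"),
                     header = paste0("# FWER threshold (Bonferroni): ",
                                     format(bonferroniThreshold(
                                         length(annotationBeds),
                                         config$alpha))))
    }

    manifest <- list(
        package = as.character(packageVersion("popdiff")),
        seed = config$seed,
        config = unclass(config),
        inputs = if (is.null(vcfPath)) "in-memory GenotypeData" else
            as.list(tools::md5sum(c(vcfPath, groupPath))),
        stages = log,
        timestamp = format(Sys.time(), tz = "UTC"))
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
    invisible(list(genotypes = gd, retained = keep, fst = pf, scan = ds,
                   clumps = clumps, windows = windows, loci = loci,
                   enrichment = enrich, manifest = manifest))
}

#' Divergence-time analysis from a rate table
#'
#' Reads an MSMC-style rate table, forms the RCCR curve, optionally rescales
#' times to years, and reports the 0.25/0.5/0.75 threshold crossings.
#'
#' @param ratePath path to a rate table ([readRateTable()] layout).
#' @param scaled `TRUE` when the table is in mutation-scaled units (real
#'   MSMC output): times are converted to years via `nu`. `FALSE` (e.g. the
#'   synthetic writer) converts generations to years via `g`.
#' @param nu,g scaling parameters (see [scalingParams()]).
#' @return list with the `RccrCurve` (years) and the `DivergenceEstimate`.
#' @export
runRccr <- function(ratePath, scaled = TRUE, nu = 4.3e-10, g = 29) {
    rc <- readRateTable(ratePath)
    pars <- scalingParams(nu = nu, g = g)
    rccr <- computeRccr(rc, timeUnit = "years")
    fac <- if (scaled) 1 / pars@nu else pars@g
    rccr@left <- rccr@left * fac
    rccr@right <- rccr@right * fac
    rccr@mid <- rccr@mid * fac
    est <- crossingTimes(rccr)
    list(rccr = rccr, estimate = est, report = formatDivergence(est))
}
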