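#' Construct a GenotypeData object
#'
#' @param dosage integer matrix, sites x samples, alternate-allele dosage in
#'   \{0, 1, 2\} with `NA` for missing calls. Row names are site ids, column
#'   names sample ids.
#' @param chrom chromosome per site (recycled). Names are passed through
#'   verbatim; no "chr" normalisation is applied.
#' @param pos 1-based position per site (VCF convention).
#' @param groups group label per sample (character or factor), every sample
#'   assigned to exactly one group.
#' @param ref,alt alleles per site (defaults "A"/"G" for synthetic data).
#' @return A [GenotypeData-class] object.
#' @examples
#' gd <- GenotypeData(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                    chrom = "1", pos = c(100L, 200L),
#'                    groups = c("G1", "G2"))
#' dosage(gd)
#' @export
GenotypeData <- function(dosage, chrom = "1", pos = seq_len(nrow(dosage)),
                         groups, ref = "A", alt = "G") {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("site", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("sample", seq_len(ncol(dosage)))
    if (length(groups) != ncol(dosage))
        stop("need one group label per sample")
    rr <- GRanges(rep_len(chrom, nrow(dosage)),
                  IRanges(start = pos, width = 1L),
                  ref = rep_len(ref, nrow(dosage)),
                  alt = rep_len(alt, nrow(dosage)))
    names(rr) <- rownames(dosage)
    se <- SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr,
        colData = DataFrame(group = factor(groups),
                            row.names = colnames(dosage)))
    new("GenotypeData", se)
}

#' @describeIn GenotypeData the dosage matrix (sites x samples).
#' @param x a GenotypeData object.
#' @export
setMethod("dosage", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeData factor of group labels, one per sample.
#' @export
setMethod("sampleGroups", "GenotypeData", function(x) colData(x)$group)

setMethod("show", "GenotypeData", function(object) {
    g <- table(sampleGroups(object))
    cat("GenotypeData:", nrow(object), "sites x", ncol(object), "samples\n")
    cat("  groups:", paste0(names(g), " (", g, ")", collapse = ", "), "\n")
    miss <- mean(is.na(dosage(object)))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

## ---------------------------------------------------------------------------
## VCF / group-table I/O
## ---------------------------------------------------------------------------

#' Read genotypes from a VCF plus a sample-to-group table
#'
#' Keeps biallelic SNP records with a GT field; multiallelic and non-SNP
#' records are skipped and counted (see attribute `"skipped"` and the
#' message). Every VCF sample must appear in the group table.
#'
#' @param vcfPath path to a VCF (plain text or bgzipped).
#' @param groupPath path to a two-column TSV (header `sample`, `group`).
#' @return [GenotypeData-class]; positions are 1-based as in the VCF.
#' @export
readVcfGenotypes <- function(vcfPath, groupPath) {
    groups <- readGroupTable(groupPath)
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
        fix[, "REF"] %in% c("A", "C", "G", "T") &
        fix[, "ALT"] %in% c("A", "C", "G", "T")
    nSkip <- sum(!keep)
    if (nSkip)
        message(nSkip, " multiallelic/non-SNP record(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
    samp <- colnames(gt)
    missing <- setdiff(samp, names(groups))
    if (length(missing))
        stop("samples absent from the group table: ",
             paste(missing, collapse = ", "))
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    dos[clean == "0/0"] <- 0L
    dos[clean %in% c("0/1", "1/0")] <- 1L
    dos[clean == "1/1"] <- 2L
    gd <- GenotypeData(dos, chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       groups = groups[samp],
                       ref = fix[, "REF"], alt = fix[, "ALT"])
    attr(gd, "skipped") <- nSkip
    gd
}

#' @rdname readVcfGenotypes
#' @param path output/input path.
#' @return `readGroupTable` returns a named character vector (sample -> group).
#' @export
readGroupTable <- function(path) {
    tb <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("sample", "group") %in% colnames(tb)))
        stop("group table needs 'sample' and 'group' columns")
    setNames(as.character(tb$group), tb$sample)
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Emits biallelic SNP records with a single GT FORMAT field, `./.` for
#' missing calls — the layout [readVcfGenotypes()] round-trips exactly.
#'
#' @param gd a [GenotypeData-class] object.
#' @param path output VCF path.
#' @export
writeGenotypeVcf <- function(gd, path) {
    rr <- rowRanges(gd)
    dos <- dosage(gd)
    gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(dos), ncol(dos))
    ok <- !is.na(dos)
    gt[ok] <- gtmap[as.character(dos[ok])]
    hdr <- c("##fileformat=VCFv4.2",
             "##source=popdiff",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
    body <- paste(as.character(seqnames(rr)), start(rr), names(rr),
                  mcols(rr)$ref, mcols(rr)$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname writeGenotypeVcf
#' @export
writeGroupTable <- function(gd, path) {
    tb <- data.frame(sample = colnames(gd),
                     group = as.character(sampleGroups(gd)))
    writeLines(c("sample\tgroup",
                 paste(tb$sample, tb$group, sep = "\t")), path)
    invisible(path)
}
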