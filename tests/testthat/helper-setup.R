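suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## PairFst built directly from a per-site x per-pair matrix, for hand examples
makePairFst <- function(fst, group1, group2, pos = seq_len(nrow(fst)) * 1000L) {
    colnames(fst) <- paste(group1, group2, sep = ":")
    rownames(fst) <- paste0("site", seq_len(nrow(fst)))
    rr <- GRanges("1", IRanges(pos, width = 1L), ref = "A", alt = "G")
    names(rr) <- rownames(fst)
    new("PairFst", SummarizedExperiment(
        assays = list(fst = fst), rowRanges = rr,
        colData = DataFrame(group1 = group1, group2 = group2,
                            row.names = colnames(fst))))
}

## DScanResult built directly from a d matrix, for outlier-calling tests
makeDScan <- function(d, pos = seq_len(nrow(d)) * 1000L) {
    if (is.null(colnames(d))) colnames(d) <- paste0("G", seq_len(ncol(d)))
    rownames(d) <- paste0("site", seq_len(nrow(d)))
    rr <- GRanges("1", IRanges(pos, width = 1L))
    names(rr) <- rownames(d)
    blank <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
    new("DScanResult", SummarizedExperiment(
        assays = list(d = d, percentile = blank,
                      outlier = array(NA, dim(d), dimnames(d))),
        rowRanges = rr,
        colData = DataFrame(group = colnames(d), row.names = colnames(d))))
}
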