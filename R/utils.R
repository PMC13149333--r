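#' @import methods
#' @importFrom stats cor hclust cutree median rbinom rnorm rpois runif setNames
#' @importFrom utils head read.table write.table
#' @importFrom data.table := .N data.table as.data.table setorder setcolorder rbindlist uniqueN
#' @importFrom S4Vectors mcols queryHits subjectHits
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomicRanges GRanges findOverlaps reduce width seqnames
NULL

#' Chromosome lengths of the mouse reference genome (GRCm38/mm10)
#'
#' Canonical chromosome lengths used as the default genome model throughout
#' the package: 19 autosomes plus X and Y.
#'
#' @param autosomesOnly logical; return only chr1-chr19.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
#' @examples
#' mouseChromLengths()[c("chr1", "chrY")]
mouseChromLengths <- function(autosomesOnly = FALSE) {
    len <- c(
        chr1 = 195471971, chr2 = 182113224, chr3 = 160039680,
        chr4 = 156508116, chr5 = 151834684, chr6 = 149736546,
        chr7 = 145441459, chr8 = 129401213, chr9 = 124595110,
        chr10 = 130694993, chr11 = 122082543, chr12 = 120129022,
        chr13 = 120421639, chr14 = 124902244, chr15 = 104043685,
        chr16 = 98207768, chr17 = 94987271, chr18 = 90702639,
        chr19 = 61431566, chrX = 171031299, chrY = 91744698
    )
    if (autosomesOnly) len[paste0("chr", 1:19)] else len
}

#' Autosome names for a genome build
#'
#' @param genome build label, one of \code{"mm10"} (chr1-19) or
#'   \code{"GRCh38"} (chr1-22).
#' @return Character vector of autosome names.
#' @export
autosomeNames <- function(genome = "mm10") {
    switch(genome,
        mm10 = paste0("chr", 1:19),
        GRCm38 = paste0("chr", 1:19),
        GRCh38 = paste0("chr", 1:22),
        hg38 = paste0("chr", 1:22),
        stop("unknown genome build: ", genome)
    )
}

## Harmonize "1"/"MT" style names to "chr1"/"chrM".
harmonizeChrom <- function(x) {
    x <- as.character(x)
    x[x == "MT"] <- "M"
    bare <- !grepl("^chr", x)
    x[bare] <- paste0("chr", x[bare])
    x
}

## site key used for joins on (chrom, pos, alt)
siteKey <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

## clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## length-weighted median
weightedMedian <- function(x, w) {
    ok <- is.finite(x) & is.finite(w) & w > 0
    x <- x[ok]; w <- w[ok]
    if (!length(x)) return(NA_real_)
    o <- order(x)
    x <- x[o]; w <- w[o]
    cw <- cumsum(w) / sum(w)
    x[which(cw >= 0.5)[1]]
}

## running median, centered, edge-truncated, NA-skipping
runningMedian <- function(x, window) {
    stopifnot(window %% 2 == 1)
    h <- (window - 1) / 2
    n <- length(x)
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        v <- x[max(1, i - h):min(n, i + h)]
        v <- v[!is.na(v)]
        if (length(v)) out[i] <- median(v)
    }
    out
}

## internal: coerce a data.frame of sites to canonical form
normalizeSites <- function(df, required = c("chrom", "pos", "alt")) {
    stopifnot(all(required %in% names(df)))
    df$chrom <- harmonizeChrom(df$chrom)
    df$pos <- as.integer(df$pos)
    if (any(is.na(df$pos)) || any(df$pos < 1))
        stop("positions must be positive integers")
    df
}
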