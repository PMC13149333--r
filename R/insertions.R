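#' Normalize transposon insertion read counts to library size
#'
#' Expresses each insertion's read count as counts per hundred reads
#' (raw / sample total x 100) and removes insertions with normalized
#' counts below 0.02 (background noise). Normalization is invariant under
#' uniform scaling of a sample's read counts.
#'
#' @param insertions data.frame with columns \code{sample}, \code{chrom},
#'   \code{pos}, \code{reads} (strand optional).
#' @param minNormalized exclusion threshold on counts per hundred reads
#'   (default 0.02; exclusion is strict \code{<}).
#' @param totals optional named vector of per-sample total read counts;
#'   defaults to the per-sample sum of \code{reads}.
#' @return The table with a \code{normalized} column, filtered.
#' @export
normalizeInsertions <- function(insertions, minNormalized = 0.02,
                                totals = NULL) {
    ins <- as.data.frame(insertions)
    stopifnot(all(c("sample", "chrom", "pos", "reads") %in% names(ins)))
    if (is.null(totals))
        totals <- tapply(ins$reads, ins$sample, sum)
    if (any(totals <= 0)) stop("sample total read counts must be positive")
    ins$normalized <- as.numeric(
        ins$reads / unname(totals[as.character(ins$sample)]) * 100)
    ins[ins$normalized >= minNormalized, , drop = FALSE]
}

#' Rank insertion sites by normalized read support
#'
#' Drops sites with fewer than \code{minReads} supporting reads or
#' normalized counts below \code{minNormalized}, then ranks the remaining
#' sites per sample by normalized count (descending); ties are broken by
#' raw reads (descending), then chromosome and position. Rank 1 is the
#' most strongly selected insertion of the sample.
#'
#' @param insertions normalized insertion table
#'   (\code{\link{normalizeInsertions}}).
#' @param minReads minimum raw supporting reads (default 10, inclusive).
#' @param minNormalized minimum counts per hundred reads (default 0.02).
#' @return The filtered table with a per-sample \code{rank} column
#'   (empty when nothing survives filtering).
#' @export
rankInsertions <- function(insertions, minReads = 10, minNormalized = 0.02) {
    ins <- as.data.frame(insertions)
    if (!"normalized" %in% names(ins))
        stop("run normalizeInsertions() first")
    ins <- ins[ins$reads >= minReads & ins$normalized >= minNormalized, ,
        drop = FALSE]
    if (!nrow(ins)) { ins$rank <- integer(); return(ins) }
    dt <- data.table::as.data.table(ins)
    data.table::setorder(dt, sample, -normalized, -reads, chrom, pos)
    dt[, rank := seq_len(.N), by = sample]
    as.data.frame(dt)
}

#' Classify target-region insertions as high- or low-ranked
#'
#' Flags each insertion overlapping a target region (e.g. the Cdkn2a locus
#' or WNT pathway genes) as high-ranked when its within-sample rank is at
#' most \code{topK} (default top 10), and reports the cohort fraction of
#' high-ranked target insertions across samples -- a direct read-out of
#' the selective advantage conferred by insertions in those genes.
#'
#' @param ranked ranked insertion table (\code{\link{rankInsertions}}).
#' @param targets \code{GRanges} of target regions (e.g. read from BED).
#' @param topK high-rank cutoff (default 10).
#' @return List of class \code{"targetRanking"}: \code{perInsertion}
#'   (target insertions with a \code{high} flag) and \code{fraction}
#'   (cohort fraction of high-ranked target insertions; \code{NA} when no
#'   target insertion exists).
#' @export
classifyTargetRank <- function(ranked, targets, topK = 10) {
    ranked <- as.data.frame(ranked)
    if (!nrow(ranked)) {
        return(structure(list(perInsertion = ranked, fraction = NA_real_),
            class = "targetRanking"))
    }
    gr <- GenomicRanges::GRanges(harmonizeChrom(ranked$chrom),
        IRanges::IRanges(ranked$pos, ranked$pos))
    hit <- IRanges::overlapsAny(gr, targets)
    per <- ranked[hit, , drop = FALSE]
    if (!nrow(per)) {
        return(structure(list(perInsertion = per, fraction = NA_real_),
            class = "targetRanking"))
    }
    per$high <- per$rank <= topK
    structure(list(perInsertion = per,
        fraction = mean(per$high)), class = "targetRanking")
}

#' @export
print.targetRanking <- function(x, ...) {
    if (is.na(x$fraction))
        cat("no target-region insertions\n")
    else cat(sprintf(
        "%d target insertions, %.1f%% high-ranked (top-k)\n",
        nrow(x$perInsertion), x$fraction * 100))
    invisible(x)
}
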