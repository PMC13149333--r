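#' CNV load: percent of the autosomal genome altered
#'
#' Segments with an absolute log2 copy ratio above the cutoff are defined
#' as altered; their total autosomal length is divided by the total
#' autosomal genome length and multiplied by 100. Segments extending
#' beyond the chromosome end are clipped with a warning.
#'
#' @param profile a \linkS4class{SegmentProfile}.
#' @param autosomeLengths named vector of autosome lengths (defaults to the
#'   mouse autosomes for an mm10 profile, human chr1-22 for GRCh38).
#' @param cutoff absolute log2 threshold (default 0.2; alteration means
#'   strictly greater).
#' @return Percent of the autosomal genome altered.
#' @export
cnvLoad <- function(profile, autosomeLengths = NULL, cutoff = 0.2) {
    stopifnot(is(profile, "SegmentProfile"))
    if (is.null(autosomeLengths)) {
        if (genomeBuild(profile) %in% c("mm10", "GRCm38"))
            autosomeLengths <- mouseChromLengths(autosomesOnly = TRUE)
        else stop("autosomeLengths required for build ", genomeBuild(profile))
    }
    seg <- profileSegments(profile)
    seg <- seg[as.character(GenomicRanges::seqnames(seg)) %in%
        names(autosomeLengths)]
    if (!length(seg)) return(0)
    chrEnd <- autosomeLengths[as.character(GenomicRanges::seqnames(seg))]
    over <- GenomicRanges::end(seg) > chrEnd
    if (any(over)) {
        warning(sum(over), " segment(s) beyond chromosome ends clipped")
        GenomicRanges::end(seg)[over] <- chrEnd[over]
    }
    altered <- abs(S4Vectors::mcols(seg)$log2) > cutoff
    sum(as.numeric(GenomicRanges::width(seg[altered]))) /
        sum(as.numeric(autosomeLengths)) * 100
}

#' Weighted genome instability index (wGII)
#'
#' Estimates copy-number instability as the proportion of the genome with
#' aberrant copy number relative to the sample median copy state, weighted
#' per chromosome: the median log2 state is the length-weighted median over
#' autosomal segments; each autosome contributes the fraction of its
#' covered length deviating from that median by more than the tolerance;
#' wGII is the mean of those per-chromosome fractions. Autosomes without
#' segments are excluded with a warning.
#'
#' @param profile a \linkS4class{SegmentProfile}.
#' @param tolerance absolute log2 deviation from the median that counts as
#'   aberrant (default 0.2, configurable).
#' @param autosomes autosome names (derived from the build by default).
#' @return wGII score in [0, 1].
#' @export
wgii <- function(profile, tolerance = 0.2, autosomes = NULL) {
    stopifnot(is(profile, "SegmentProfile"))
    if (is.null(autosomes))
        autosomes <- autosomeNames(genomeBuild(profile))
    seg <- profileSegments(profile)
    seg <- seg[as.character(GenomicRanges::seqnames(seg)) %in% autosomes]
    if (!length(seg)) stop("no autosomal segments")
    w <- as.numeric(GenomicRanges::width(seg))
    l2 <- S4Vectors::mcols(seg)$log2
    med <- weightedMedian(l2, w)
    chrom <- as.character(GenomicRanges::seqnames(seg))
    empty <- setdiff(autosomes, unique(chrom))
    if (length(empty))
        warning("autosomes without segments excluded: ",
            paste(empty, collapse = ", "))
    frac <- vapply(unique(chrom), function(ch) {
        i <- chrom == ch
        sum(w[i][abs(l2[i] - med) > tolerance]) / sum(w[i])
    }, numeric(1))
    mean(frac)
}

#' Bin a segment profile into fixed-width bins
#'
#' Assigns a single log2 value per bin: the overlap-length-weighted mean of
#' the segments covering the bin. Bins without coverage are missing (NA)
#' and propagate (no imputation).
#'
#' @param profile a \linkS4class{SegmentProfile}.
#' @param binSize bin width in bp (default 1 Mb).
#' @param genome named chromosome lengths (defaults to the mouse table for
#'   mm10 builds; otherwise inferred from the segment extent).
#' @return A \linkS4class{BinnedProfile}.
#' @export
binProfile <- function(profile, binSize = 1e6, genome = NULL) {
    stopifnot(is(profile, "SegmentProfile"))
    seg <- profileSegments(profile)
    chroms <- unique(as.character(GenomicRanges::seqnames(seg)))
    if (is.null(genome)) {
        genome <- if (genomeBuild(profile) %in% c("mm10", "GRCm38"))
            mouseChromLengths()
        else setNames(vapply(chroms, function(ch)
            max(GenomicRanges::end(seg[
                as.character(GenomicRanges::seqnames(seg)) == ch])),
            numeric(1)), chroms)
    }
    bins <- do.call(rbind, lapply(chroms, function(ch) {
        len <- genome[ch]
        if (is.na(len)) len <- max(GenomicRanges::end(
            seg[as.character(GenomicRanges::seqnames(seg)) == ch]))
        n <- ceiling(len / binSize)
        data.frame(chrom = ch, start = (seq_len(n) - 1) * binSize + 1,
            end = pmin(seq_len(n) * binSize, len))
    }))
    binGr <- GenomicRanges::GRanges(bins$chrom,
        IRanges::IRanges(bins$start, bins$end))
    hits <- GenomicRanges::findOverlaps(binGr, seg)
    bins$log2 <- NA_real_
    if (length(hits)) {
        ov <- GenomicRanges::pintersect(binGr[S4Vectors::queryHits(hits)],
            seg[S4Vectors::subjectHits(hits)])
        dt <- data.table::data.table(
            bin = S4Vectors::queryHits(hits),
            w = as.numeric(GenomicRanges::width(ov)),
            l2 = S4Vectors::mcols(seg)$log2[S4Vectors::subjectHits(hits)])
        agg <- dt[, .(log2 = sum(l2 * w) / sum(w)), by = bin]
        bins$log2[agg$bin] <- agg$log2
    }
    rownames(bins) <- NULL
    new("BinnedProfile", bins = bins, binSize = binSize,
        excluded = excludedChroms(profile))
}

#' Smooth a binned profile and recentre it
#'
#' Per chromosome, applies a centered, edge-truncated running median
#' (window of 5 bins by default), skipping the excluded chromosomes (e.g.
#' those flagged for chromothripsis or other complex rearrangements, which
#' keep their raw values). Then, if the genome-wide median of the smoothed
#' non-excluded bins is positive, that median is subtracted from every bin
#' to recentre the profile.
#'
#' @param binned a \linkS4class{BinnedProfile}.
#' @param window odd smoothing window in bins (default 5).
#' @return The smoothed, recentred \linkS4class{BinnedProfile}.
#' @export
smoothRecenter <- function(binned, window = 5) {
    stopifnot(is(binned, "BinnedProfile"))
    if (window %% 2 != 1) stop("window must be odd")
    bins <- profileBins(binned)
    excl <- excludedChroms(binned)
    for (ch in unique(bins$chrom)) {
        if (ch %in% excl) next
        i <- bins$chrom == ch
        bins$log2[i] <- runningMedian(bins$log2[i], window)
    }
    med <- median(bins$log2[!bins$chrom %in% excl], na.rm = TRUE)
    if (is.finite(med) && med > 0)
        bins$log2 <- bins$log2 - med
    new("BinnedProfile", bins = bins, binSize = binSize(binned),
        excluded = excl)
}

#' Genome-stability distance between two binned copy-number profiles
#'
#' For two (smoothed, recentred) profiles of the same sample on the same
#' bin grid, the per-bin distance is the absolute difference of log2
#' values; per chromosome the mean over bins present in both profiles is
#' reported, and the genome summary is the mean of the chromosome means.
#' Excluded chromosomes (union of both profiles' exclusion sets) and
#' chromosomes without shared bins are omitted.
#'
#' @param a,b \linkS4class{BinnedProfile}s on the same bin grid.
#' @return List of class \code{"stabilityDistance"}: \code{perChromosome}
#'   (data.frame chrom, nBins, meanDistance) and \code{genome} (scalar).
#' @export
stabilityDistance <- function(a, b) {
    stopifnot(is(a, "BinnedProfile"), is(b, "BinnedProfile"))
    if (binSize(a) != binSize(b))
        stop("profiles are on different bin grids")
    excl <- union(excludedChroms(a), excludedChroms(b))
    da <- profileBins(a); db <- profileBins(b)
    m <- merge(da, db, by = c("chrom", "start", "end"),
        suffixes = c(".a", ".b"))
    m <- m[!m$chrom %in% excl & !is.na(m$log2.a) & !is.na(m$log2.b), ,
        drop = FALSE]
    if (!nrow(m))
        return(structure(list(perChromosome = data.frame(
            chrom = character(), nBins = integer(),
            meanDistance = numeric()), genome = NA_real_),
            class = "stabilityDistance"))
    m$d <- abs(m$log2.a - m$log2.b)
    per <- data.table::as.data.table(m)[,
        .(nBins = .N, meanDistance = mean(d)), by = chrom]
    structure(list(perChromosome = as.data.frame(per),
        genome = mean(per$meanDistance)), class = "stabilityDistance")
}

#' @export
print.stabilityDistance <- function(x, ...) {
    cat(sprintf("genome-stability distance: %.4f over %d chromosomes\n",
        x$genome, nrow(x$perChromosome)))
    invisible(x)
}
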