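#' Per-bin signature-SNP enrichment of a sample
#'
#' The genome is tiled into consecutive bins (10 Mb by default for the
#' genome-wide analysis, 1 Mb for the MHC clusters). For every bin and
#' strain group, \code{expected} is the number of library signature SNPs in
#' the bin, \code{matched} is the subset of those also detected in the
#' sample, and the enrichment score is \code{matched / expected}. Bins
#' without signature SNPs for a group carry no row for that group.
#'
#' @param calls data.frame of sample SNP calls with columns \code{chrom},
#'   \code{pos}, \code{alt}.
#' @param library a \linkS4class{SignatureLibrary}.
#' @param binSize bin width in bp (default 10 Mb).
#' @param genome named vector of chromosome lengths used to truncate the
#'   terminal bin of each chromosome.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{group}, \code{expected}, \code{matched}, \code{score}.
#' @export
binEnrichment <- function(calls, library, binSize = 1e7,
                          genome = mouseChromLengths()) {
    stopifnot(is(library, "SignatureLibrary"), binSize > 0)
    lib <- data.table::as.data.table(signatureSites(library))
    if (!nrow(lib)) stop("signature library is empty")
    calls <- as.data.frame(calls)
    if (!nrow(calls)) {
        warning("sample has no SNP calls; all enrichment scores are 0")
        calls <- data.frame(chrom = character(), pos = integer(),
            alt = character())
    } else {
        calls <- normalizeSites(calls)
    }
    callKeys <- unique(siteKey(calls$chrom, calls$pos, calls$alt))
    lib[, bin := (pos - 1) %/% binSize]
    lib[, matchedSite := siteKey(chrom, pos, alt) %in% callKeys]
    tab <- lib[, .(expected = .N, matched = sum(matchedSite)),
        by = .(chrom, bin, group)]
    tab[, start := bin * binSize + 1]
    tab[, end := (bin + 1) * binSize]
    known <- tab$chrom %in% names(genome)
    tab$end[known] <- pmin(tab$end[known], genome[tab$chrom[known]])
    tab[, score := matched / expected]
    tab[, bin := NULL]
    data.table::setorder(tab, chrom, start, group)
    data.table::setcolorder(tab,
        c("chrom", "start", "end", "group", "expected", "matched", "score"))
    as.data.frame(tab)
}

#' Genome-wide strain composition from binned enrichment scores
#'
#' For every strain group, the lengths of all bins with a sufficient
#' enrichment score (and a minimum number of expected signature SNPs, to
#' guard sparse bins) are summed; percentages are those summed lengths
#' normalized across groups, so a pure inbred line reads 100\% and an F1
#' hybrid about 50/50.
#'
#' @param table enrichment table from \code{\link{binEnrichment}}.
#' @param minScore minimum per-bin enrichment score (default 0.3).
#' @param minExpected minimum expected signature SNPs for a bin to score.
#' @param weightByScore weight each passing bin's length by its enrichment
#'   score (default TRUE). A linkage block covering only part of a bin
#'   scores proportionally, so score weighting removes the upward bias
#'   that counting whole bins would give to small residual blocks; pure
#'   inbred (100\%) and F1 (50/50) reads are unaffected.
#' @return data.frame of class \code{"strainComposition"} with one row per
#'   detected group: \code{group}, \code{length} (bp of passing bins,
#'   score-weighted by default), \code{percent}; sorted by descending
#'   percent, ties broken by group name. The ordered top three rows are
#'   attached as attribute \code{"top3"}.
#' @export
strainComposition <- function(table, minScore = 0.3, minExpected = 5,
                              weightByScore = TRUE) {
    tab <- data.table::as.data.table(table)
    pass <- tab[expected >= minExpected & score >= minScore]
    if (!nrow(pass))
        stop("insufficient signal: no bin passes the enrichment threshold")
    comp <- if (weightByScore)
        pass[, .(length = sum((end - start + 1) * score)), by = group]
    else pass[, .(length = sum(end - start + 1)), by = group]
    comp[, percent := length / sum(length) * 100]
    data.table::setorder(comp, -percent, group)
    comp <- as.data.frame(comp)
    attr(comp, "top3") <- head(comp, 3)
    class(comp) <- c("strainComposition", "data.frame")
    comp
}

#' Top-scoring strain groups of a composition
#'
#' @param composition result of \code{\link{strainComposition}}.
#' @param n how many groups to report (default 3).
#' @return Head of the composition table, ordered by descending percent.
#' @export
topStrains <- function(composition, n = 3) head(as.data.frame(composition), n)

#' Infer sample sex from per-chromosome read counts
#'
#' Sex is called from the ratio of Y-chromosome uniquely mapped reads over
#' the sum of all autosomal reads; samples at or above the 0.05 cutoff are
#' called male, below it female. The call is invariant under uniform
#' scaling of all read counts.
#'
#' @param readCounts named numeric vector of uniquely mapped read counts per
#'   chromosome (names like \code{chr1..chr19, chrX, chrY}).
#' @param cutoff male/female decision boundary on the Y/autosome ratio;
#'   the boundary itself is called male.
#' @param autosomes autosome names (default mouse chr1-19).
#' @return List of class \code{"sexCall"} with elements \code{ratio} and
#'   \code{call} (\code{"male"} or \code{"female"}).
#' @export
inferSex <- function(readCounts, cutoff = 0.05,
                     autosomes = autosomeNames("mm10")) {
    names(readCounts) <- harmonizeChrom(names(readCounts))
    auto <- readCounts[names(readCounts) %in% autosomes]
    if (!length(auto) || sum(auto) <= 0)
        stop("autosome read counts must be positive")
    y <- readCounts["chrY"]
    if (is.na(y)) {
        warning("no chrY read count; treating as 0")
        y <- 0
    }
    ratio <- unname(y) / sum(auto)
    structure(list(ratio = ratio,
        call = if (ratio >= cutoff) "male" else "female"),
        class = "sexCall")
}

#' @export
print.sexCall <- function(x, ...) {
    cat("sex call:", x$call,
        sprintf("(Y/autosome read ratio %.4f)\n", x$ratio))
    invisible(x)
}

#' Computational backcross status (cBS)
#'
#' Estimates the number of backcross generations of a line from its strain
#' composition as \code{cBS = log2(2 x 100\% / (sum(FS\%) - sum(AS\%)))},
#' where FS\% is the foreign (non-recipient) strain contribution and AS\%
#' is the part of it attributable to linkage with engineered alleles.
#' Signature SNPs of an allele's origin group within +/- 25 Mb of its
#' integration site are removed and the composition recomputed; the
#' resulting drop in foreign contribution (measured on the unadjusted
#' denominator so the drop reflects removed bins only) is AS\%. Alleles
#' with unknown integration site subtract a flat 1\% from their origin
#' background instead. When the adjusted foreign contribution falls to (or
#' below) 0.1\%, the line is reported as fully backcrossed (cBS >= cap).
#'
#' @param calls sample SNP calls (chrom, pos, alt).
#' @param library genome-wide \linkS4class{SignatureLibrary}.
#' @param alleles data.frame of engineered-allele annotations with columns
#'   \code{allele}, \code{originGroup}, \code{chrom}, \code{pos}
#'   (\code{chrom}/\code{pos} \code{NA} for unknown integration sites);
#'   may be \code{NULL}/empty.
#' @param recipientGroup name of the recipient (dominant) background group.
#' @param window linkage window half-width around an integration site
#'   (default 25 Mb, applied symmetrically).
#' @param cap reporting cap for fully backcrossed lines (default 10).
#' @param sentinelFloor adjusted foreign percentages at or below this value
#'   trigger the fully-backcrossed sentinel (default 0.1).
#' @param binSize,minScore,minExpected,genome passed to
#'   \code{\link{binEnrichment}}/\code{\link{strainComposition}}.
#' @return List of class \code{"backcrossEstimate"}: \code{fsPercent},
#'   \code{asPercent}, \code{cbs} (finite value or \code{Inf}),
#'   \code{fullyBackcrossed}, \code{cap}.
#' @export
estimateBackcross <- function(calls, library, alleles = NULL, recipientGroup,
                              window = 2.5e7, cap = 10, sentinelFloor = 0.1,
                              binSize = 1e7, minScore = 0.3, minExpected = 5,
                              genome = mouseChromLengths()) {
    stopifnot(is(library, "SignatureLibrary"))
    tab0 <- binEnrichment(calls, library, binSize, genome)
    comp0 <- strainComposition(tab0, minScore, minExpected)
    total0 <- sum(comp0$length)
    foreign0 <- comp0[comp0$group != recipientGroup, , drop = FALSE]
    fsPercent <- sum(foreign0$length) / total0 * 100

    alleles <- normalizeAlleles(alleles)
    known <- alleles[!is.na(alleles$pos), , drop = FALSE]
    unknown <- alleles[is.na(alleles$pos), , drop = FALSE]

    adjForeignPct <- fsPercent
    if (nrow(known)) {
        sites <- data.table::as.data.table(signatureSites(library))
        dropMask <- rep(FALSE, nrow(sites))
        for (i in seq_len(nrow(known))) {
            dropMask <- dropMask |
                (sites$group == known$originGroup[i] &
                 sites$chrom == known$chrom[i] &
                 abs(sites$pos - known$pos[i]) <= window)
        }
        filtered <- new("SignatureLibrary",
            sites = as.data.frame(sites[!dropMask]),
            groups = libraryGroups(library), scope = libraryScope(library))
        tab1 <- binEnrichment(calls, filtered, binSize, genome)
        pass1 <- tab1[tab1$expected >= minExpected & tab1$score >= minScore, ]
        lens1 <- tapply((pass1$end - pass1$start + 1) * pass1$score,
            pass1$group, sum)
        foreignLen1 <- sum(lens1[setdiff(names(lens1), recipientGroup)],
            na.rm = TRUE)
        ## same denominator as the unadjusted composition, so the reduction
        ## is purely the removed linkage bins
        adjForeignPct <- foreignLen1 / total0 * 100
    }
    ## 1% flat subtraction per unknown-site allele, bounded by what the
    ## origin background actually contributes
    if (nrow(unknown)) {
        perGroup <- setNames(
            comp0$length / total0 * 100, comp0$group)
        for (i in seq_len(nrow(unknown))) {
            g <- unknown$originGroup[i]
            if (g == recipientGroup || is.na(perGroup[g])) next
            take <- min(1, max(perGroup[g], 0))
            perGroup[g] <- perGroup[g] - take
            adjForeignPct <- adjForeignPct - take
        }
    }
    adjForeignPct <- max(adjForeignPct, 0)
    asPercent <- fsPercent - adjForeignPct
    if (asPercent < 0) {
        warning("negative allele-clustered adjustment clamped at 0")
        asPercent <- 0
    }
    backcrossStatus(fsPercent, asPercent, cap = cap,
        sentinelFloor = sentinelFloor)
}

#' Backcross status from foreign and allele-clustered contributions
#'
#' The printed equation, applied to already-computed contributions:
#' \code{cBS = log2(2 x 100 / (fsPercent - asPercent))}. A denominator at
#' or below \code{sentinelFloor} (or a cBS at or above \code{cap}) reports
#' the fully-backcrossed sentinel.
#'
#' @param fsPercent sum of foreign strain contribution (percent).
#' @param asPercent sum of allele-clustered SNP contribution (percent).
#' @param cap,sentinelFloor see \code{\link{estimateBackcross}}.
#' @return List of class \code{"backcrossEstimate"}.
#' @export
#' @examples
#' backcrossStatus(50, 0)$cbs    # log2(200/50) = 2
#' backcrossStatus(6.25, 0)$cbs  # 5
backcrossStatus <- function(fsPercent, asPercent = 0, cap = 10,
                            sentinelFloor = 0.1) {
    stopifnot(fsPercent >= 0, asPercent >= 0)
    denom <- fsPercent - asPercent
    fully <- denom <= sentinelFloor
    cbs <- if (fully) Inf else log2(2 * 100 / denom)
    if (is.finite(cbs) && cbs >= cap) fully <- TRUE
    structure(list(fsPercent = fsPercent, asPercent = asPercent,
        cbs = cbs, fullyBackcrossed = fully, cap = cap),
        class = "backcrossEstimate")
}

normalizeAlleles <- function(alleles) {
    if (is.null(alleles) || !nrow(as.data.frame(alleles)))
        return(data.frame(allele = character(), originGroup = character(),
            chrom = character(), pos = integer()))
    alleles <- as.data.frame(alleles)
    stopifnot(all(c("allele", "originGroup") %in% names(alleles)))
    if (!"chrom" %in% names(alleles)) alleles$chrom <- NA_character_
    if (!"pos" %in% names(alleles)) alleles$pos <- NA_integer_
    alleles$pos <- suppressWarnings(as.integer(alleles$pos))
    ok <- !is.na(alleles$chrom)
    alleles$chrom[ok] <- harmonizeChrom(alleles$chrom[ok])
    alleles
}

#' @export
print.backcrossEstimate <- function(x, ...) {
    cat(sprintf("foreign strain contribution: %.2f%%\n", x$fsPercent))
    cat(sprintf("allele-clustered contribution: %.2f%%\n", x$asPercent))
    if (x$fullyBackcrossed)
        cat(sprintf("cBS >= %g (fully backcrossed)\n", x$cap))
    else cat(sprintf("cBS = %.2f\n", x$cbs))
    invisible(x)
}

#' Call the MHC (H2) haplotype of a sample per gene cluster
#'
#' For each of the six MHC gene clusters, signature SNPs of the
#' cluster-scoped library are binned (1 Mb) and matched against the sample
#' calls; haplotype groups whose aggregate score (total matched over total
#' expected, over bins with enough expected SNPs) reaches \code{minScore}
#' are called, at most two per cluster (the two alleles of a diploid
#' genome). The combined haplotype concatenates the cluster calls in locus
#' order; the mosaic flag is set when resolved clusters disagree on the
#' called haplotype pattern (the hallmark of a recombinant MHC locus).
#'
#' @param calls sample SNP calls (chrom, pos, alt).
#' @param mhc result of \code{\link{buildMhcHaplotypeGroups}}.
#' @param binSize bin width inside clusters (default 1 Mb).
#' @param minScore minimum aggregate enrichment score for a haplotype call.
#' @param minExpected minimum expected SNPs per bin for the bin to count.
#' @return List of class \code{"mhcCall"}: \code{perCluster} (named list of
#'   called haplotype group vectors, \code{NA} when unresolved),
#'   \code{combined} label, \code{mosaic} flag.
#' @export
callMhc <- function(calls, mhc, binSize = 1e6, minScore = 0.3,
                    minExpected = 5) {
    perCluster <- setNames(vector("list", length(mhc$perCluster)),
        names(mhc$perCluster))
    for (cl in names(mhc$perCluster)) {
        entry <- mhc$perCluster[[cl]]
        if (is.null(entry) || !nrow(signatureSites(entry$library))) {
            perCluster[[cl]] <- NA_character_
            next
        }
        tab <- binEnrichment(calls, entry$library, binSize)
        tab <- tab[tab$expected >= minExpected, , drop = FALSE]
        if (!nrow(tab)) { perCluster[[cl]] <- NA_character_; next }
        agg <- data.table::as.data.table(tab)[,
            .(score = sum(matched) / sum(expected)), by = group]
        hit <- agg[score >= minScore]
        if (!nrow(hit)) { perCluster[[cl]] <- NA_character_; next }
        data.table::setorder(hit, -score, group)
        perCluster[[cl]] <- head(hit$group, 2)
    }
    resolved <- perCluster[!vapply(perCluster,
        function(x) length(x) == 1 && is.na(x), logical(1))]
    patterns <- unique(vapply(resolved,
        function(x) paste(sort(x), collapse = "/"), character(1)))
    mosaic <- length(patterns) > 1
    combined <- paste(vapply(names(perCluster), function(cl) {
        x <- perCluster[[cl]]
        lab <- if (length(x) == 1 && is.na(x)) "?" else
            paste(sort(x), collapse = "/")
        paste0(sub("^H2-", "", cl), ":", lab)
    }, character(1)), collapse = "|")
    structure(list(perCluster = perCluster, combined = combined,
        mosaic = mosaic), class = "mhcCall")
}

#' @export
print.mhcCall <- function(x, ...) {
    cat("MHC haplotype:", x$combined, "\n")
    cat("mosaic:", x$mosaic, "\n")
    invisible(x)
}
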