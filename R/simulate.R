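#' Simulate an inbred-strain variant catalog with group structure
#'
#' Generates group-private SNP pools placed uniformly on a mouse-like
#' genome. Each pool site is carried by one designated strain of its group
#' and shared with every other group member with probability
#' \code{withinGroupSharing}; no site is ever carried outside its group, so
#' the planted pools are exactly the group-private signature truth.
#'
#' @param nGroups number of strain groups.
#' @param strainsPerGroup strains per group.
#' @param snpsPerGroup pool sites per group.
#' @param withinGroupSharing probability that a non-designated group member
#'   also carries a pool site (1 makes all group members identical).
#' @param genome named chromosome lengths (default mouse).
#' @param region optional \code{GRanges}; place all sites inside it.
#' @param groupNames optional group names (default \code{G1..Gn}).
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return List: \code{catalog} (\linkS4class{StrainVariantCatalog}),
#'   \code{groups} (truth \linkS4class{StrainGroupSet}), \code{truth}
#'   (data.frame of planted sites with owning group).
#' @export
simulateStrainCatalog <- function(nGroups = 4, strainsPerGroup = 2,
                                  snpsPerGroup = 2000,
                                  withinGroupSharing = 0.9,
                                  genome = mouseChromLengths(),
                                  region = NULL, groupNames = NULL,
                                  seed = 1) {
    stopifnot(nGroups > 0, strainsPerGroup > 0, snpsPerGroup > 0)
    set.seed(seed)
    if (is.null(groupNames)) groupNames <- paste0("G", seq_len(nGroups))
    stopifnot(length(groupNames) == nGroups)
    groups <- setNames(lapply(groupNames, function(g)
        paste0(g, "_S", seq_len(strainsPerGroup))), groupNames)
    placeSites <- function(n) {
        if (is.null(region)) {
            chrom <- sample(names(genome), n, replace = TRUE,
                prob = genome / sum(genome))
            pos <- floor(runif(n, 1, genome[chrom] + 1))
        } else {
            w <- as.numeric(GenomicRanges::width(region))
            i <- sample(length(region), n, replace = TRUE, prob = w / sum(w))
            chrom <- as.character(GenomicRanges::seqnames(region))[i]
            pos <- floor(runif(n, GenomicRanges::start(region)[i],
                GenomicRanges::end(region)[i] + 1))
        }
        data.frame(chrom = chrom, pos = as.integer(pos),
            alt = sample(c("A", "C", "G", "T"), n, replace = TRUE))
    }
    truth <- NULL
    rows <- list()
    for (g in groupNames) {
        pool <- unique(placeSites(snpsPerGroup))
        pool$group <- g
        truth <- rbind(truth, pool)
        members <- groups[[g]]
        primary <- sample(members, nrow(pool), replace = TRUE)
        for (s in members) {
            carry <- primary == s |
                runif(nrow(pool)) < withinGroupSharing
            if (any(carry))
                rows[[paste(g, s)]] <- data.frame(
                    chrom = pool$chrom[carry], pos = pool$pos[carry],
                    alt = pool$alt[carry], strain = s)
        }
    }
    ## a site duplicated across groups (rare collision) would violate the
    ## planted-truth contract; drop such collisions everywhere
    key <- siteKey(truth$chrom, truth$pos, truth$alt)
    dupKeys <- key[duplicated(key)]
    if (length(dupKeys)) {
        truth <- truth[!key %in% dupKeys, ]
        rows <- lapply(rows, function(df)
            df[!siteKey(df$chrom, df$pos, df$alt) %in% dupKeys, ])
    }
    sites <- do.call(rbind, rows)
    rownames(sites) <- rownames(truth) <- NULL
    list(catalog = strainVariantCatalog(sites,
            strains = unlist(groups, use.names = FALSE)),
        groups = strainGroupSet(groups), truth = truth)
}

## segments of a haplotype overlapping [a, b] on one chromosome, clipped
extractHapSegments <- function(hap, chrom, a, b) {
    h <- hap[hap$chrom == chrom & hap$end >= a & hap$start <= b, ,
        drop = FALSE]
    if (!nrow(h)) return(h)
    h$start <- pmax(h$start, a)
    h$end <- pmin(h$end, b)
    h
}

## one meiosis: recombine two haplotypes into a gamete
drawGamete <- function(hap1, hap2, genome, rate) {
    out <- list()
    for (ch in names(genome)) {
        len <- genome[ch]
        k <- rpois(1, rate)
        cuts <- sort(floor(runif(k, 1, len)))
        bounds <- unique(c(1, cuts + 1, len + 1))
        current <- sample(1:2, 1)
        for (j in seq_len(length(bounds) - 1)) {
            a <- bounds[j]; b <- bounds[j + 1] - 1
            hp <- if (current == 1) hap1 else hap2
            out[[length(out) + 1]] <- extractHapSegments(hp, ch, a, b)
            current <- 3 - current
        }
    }
    do.call(rbind, out)
}

## strain carried by a haplotype at a position (NA if outside)
hapStrainAt <- function(hap, chrom, pos) {
    h <- hap[hap$chrom == chrom & hap$start <= pos & hap$end >= pos, ]
    if (nrow(h)) h$strain[1] else NA_character_
}

pureHaplotype <- function(strain, genome) {
    data.frame(chrom = names(genome), start = 1,
        end = as.numeric(genome), strain = strain, row.names = NULL)
}

#' Simulate a diploid mosaic genome from a cross schedule
#'
#' Models F1 hybrids, repeated backcrosses to a recipient strain, and
#' single-crossover MHC recombinants. Crossovers per chromosome per
#' meiosis are Poisson with the given rate (uniform positions). Engineered
#' alleles model breeder selection: every selected offspring retains the
#' origin-strain haplotype block containing the allele's integration site,
#' which is what makes linkage blocks "withstand" backcrossing. The
#' emitted SNP calls are the union of catalog sites carried by either
#' haplotype. Because SNP-pattern analysis is presence-based and cannot
#' distinguish heterozygous from homozygous carriage, realized per-group
#' fractions are reported on the same presence basis (fraction of genome
#' length where the group is present on at least one haplotype, normalized
#' across groups); raw diploid fractions are returned alongside.
#'
#' @param sim result of \code{\link{simulateStrainCatalog}} (or a list with
#'   \code{catalog} and \code{groups}).
#' @param founderA,founderB founder strain names (founderA is the recipient
#'   of backcrosses).
#' @param schedule \code{"F1"}, \code{"backcross"} or
#'   \code{"mhcRecombinant"}.
#' @param nBackcross number of backcross generations after the F1.
#' @param alleles optional engineered-allele annotation (data.frame with
#'   \code{allele}, \code{originStrain}, \code{chrom}, \code{pos}); alleles
#'   whose origin is not the recipient force retention of the origin block.
#' @param recombRate expected crossovers per chromosome per meiosis
#'   (default 0.5).
#' @param genome named chromosome lengths.
#' @param clusters MHC cluster intervals (for \code{"mhcRecombinant"}).
#' @param switchCluster cluster at whose 5' boundary the recombinant
#'   switches strain (default \code{"H2-T"}).
#' @param seed RNG seed.
#' @return List: \code{haplotypes} (two segment data.frames), \code{calls}
#'   (chrom/pos/alt), \code{presencePercent} (named, sums to 100),
#'   \code{diploidFraction} (named), \code{foreignPercent} (presence-based
#'   non-recipient percent).
#' @export
simulateCross <- function(sim, founderA, founderB,
                          schedule = c("F1", "backcross", "mhcRecombinant"),
                          nBackcross = 0, alleles = NULL, recombRate = 0.5,
                          genome = mouseChromLengths(),
                          clusters = mhcClusterSpec(),
                          switchCluster = "H2-T", seed = 1) {
    schedule <- match.arg(schedule)
    set.seed(seed)
    catalog <- sim$catalog
    groups <- sim$groups
    stopifnot(all(c(founderA, founderB) %in% strainNames(catalog)))
    hapA <- pureHaplotype(founderA, genome)
    hapB <- pureHaplotype(founderB, genome)
    forced <- NULL
    if (!is.null(alleles) && nrow(as.data.frame(alleles))) {
        alleles <- as.data.frame(alleles)
        alleles$chrom <- harmonizeChrom(alleles$chrom)
        forced <- alleles[alleles$originStrain != founderA, , drop = FALSE]
    }
    if (schedule == "F1") {
        h1 <- hapA; h2 <- hapB
    } else if (schedule == "backcross") {
        h1 <- hapA; h2 <- hapB   # the F1
        for (gen in seq_len(nBackcross)) {
            gam <- NULL
            for (try in seq_len(1000)) {
                cand <- drawGamete(h1, h2, genome, recombRate)
                ok <- TRUE
                if (!is.null(forced) && nrow(forced)) {
                    for (i in seq_len(nrow(forced))) {
                        if (!identical(hapStrainAt(cand, forced$chrom[i],
                                forced$pos[i]), forced$originStrain[i])) {
                            ok <- FALSE; break
                        }
                    }
                }
                if (ok) { gam <- cand; break }
            }
            if (is.null(gam))
                stop("could not satisfy engineered-allele retention; ",
                    "alleles may sit on incompatible haplotypes")
            h1 <- hapA
            h2 <- gam
        }
    } else {  # mhcRecombinant: homozygous single-crossover switch
        stopifnot(switchCluster %in% names(clusters))
        cut <- GenomicRanges::start(clusters[switchCluster])
        ch17 <- as.character(GenomicRanges::seqnames(clusters[switchCluster]))
        mk <- function() {
            h <- pureHaplotype(founderA, genome)
            i <- h$chrom == ch17
            len <- h$end[i]
            h <- h[!i, ]
            rbind(h,
                data.frame(chrom = ch17, start = 1, end = cut - 1,
                    strain = founderA),
                data.frame(chrom = ch17, start = cut, end = len,
                    strain = founderB))
        }
        h1 <- mk(); h2 <- mk()
    }
    calls <- callsFromHaplotypes(catalog, h1, h2)
    ## presence-based truth
    g2s <- groupOf(groups)
    presence <- list()
    for (s in unique(c(h1$strain, h2$strain))) {
        gr <- unionStrainCover(h1, h2, s)
        g <- unname(g2s[s])
        presence[[g]] <- sum(c(presence[[g]], gr))
    }
    presLen <- unlist(presence)
    presencePercent <- presLen / sum(presLen) * 100
    dipLen <- tapply(c(h1$end - h1$start + 1, h2$end - h2$start + 1),
        unname(g2s[c(h1$strain, h2$strain)]), sum)
    diploidFraction <- c(dipLen / (2 * sum(as.numeric(genome))))
    recipientGroup <- unname(g2s[founderA])
    foreignPercent <- sum(presencePercent[
        setdiff(names(presencePercent), recipientGroup)])
    list(haplotypes = list(h1 = h1, h2 = h2), calls = calls,
        presencePercent = presencePercent,
        diploidFraction = diploidFraction,
        foreignPercent = foreignPercent,
        recipientGroup = recipientGroup)
}

## total genome length where strain s is present on >= 1 haplotype
unionStrainCover <- function(h1, h2, s) {
    seg <- rbind(h1[h1$strain == s, ], h2[h2$strain == s, ])
    if (!nrow(seg)) return(0)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(seg$chrom,
        IRanges::IRanges(seg$start, seg$end)))
    sum(as.numeric(GenomicRanges::width(gr)))
}

## catalog sites carried by either haplotype
callsFromHaplotypes <- function(catalog, h1, h2) {
    sites <- data.table::as.data.table(catalogSites(catalog))
    haps <- rbind(h1, h2)
    out <- list()
    for (i in seq_len(nrow(haps))) {
        hit <- sites[strain == haps$strain[i] & chrom == haps$chrom[i] &
            pos >= haps$start[i] & pos <= haps$end[i],
            .(chrom, pos, alt)]
        if (nrow(hit)) out[[length(out) + 1]] <- hit
    }
    if (!length(out))
        return(data.frame(chrom = character(), pos = integer(),
            alt = character()))
    as.data.frame(unique(data.table::rbindlist(out)))
}

#' Simulate a tumor/normal variant table with known truth
#'
#' Somatic variants are present in the tumor only; germline variants are
#' drawn from catalog sites of the requested strain groups and present in
#' tumor and normal. Read depths follow a binomial model around the
#' expected allele fraction (set \code{noise = FALSE} for deterministic
#' depths). Impact classes are assigned so that the requested
#' protein-altering counts are exact.
#'
#' @param sim result of \code{\link{simulateStrainCatalog}}.
#' @param nSomatic protein-altering somatic mutations.
#' @param nSomaticSilent additional non-protein-altering (MODIFIER) somatic
#'   mutations.
#' @param germlineCounts named integer vector: protein-altering germline
#'   variants to draw per strain group.
#' @param nGermlineSilent additional non-protein-altering germline variants
#'   (drawn across all groups).
#' @param depth sequencing depth per site.
#' @param vaf expected somatic/germline allele fraction (default 0.5).
#' @param noise draw alt reads from a binomial (default TRUE).
#' @param genome named chromosome lengths (for somatic placement).
#' @param seed RNG seed.
#' @return List: \code{records} (variant data.frame with truth columns
#'   \code{trueOrigin}, \code{trueGroup}) and \code{truth} (summary
#'   counts).
#' @export
simulateVariantTable <- function(sim, nSomatic = 26, nSomaticSilent = 0,
                                 germlineCounts = c(),
                                 nGermlineSilent = 0, depth = 60,
                                 vaf = 0.5, noise = TRUE,
                                 genome = mouseChromLengths(), seed = 1) {
    set.seed(seed)
    catalog <- sim$catalog
    groups <- sim$groups
    g2s <- groupOf(groups)
    altReads <- function(n, p) {
        if (noise) rbinom(n, depth, p) else round(rep(depth * p, n))
    }
    impacts <- function(n) sample(c("MODERATE", "HIGH"), n, replace = TRUE)
    recs <- list()
    nSom <- nSomatic + nSomaticSilent
    if (nSom > 0) {
        chrom <- sample(names(genome), nSom, replace = TRUE,
            prob = genome / sum(genome))
        recs$somatic <- data.frame(
            chrom = chrom,
            pos = as.integer(floor(runif(nSom, 1, genome[chrom] + 1))),
            ref = "N",
            alt = sample(c("A", "C", "G", "T"), nSom, replace = TRUE),
            tumorDepth = depth, normalDepth = depth,
            tumorAlt = altReads(nSom, vaf), normalAlt = 0L,
            impact = c(impacts(nSomatic), rep("MODIFIER", nSomaticSilent)),
            trueOrigin = "somatic", trueGroup = NA_character_)
    }
    drawGermline <- function(n, grp, impact) {
        members <- groupMembers(groups)[[grp]]
        pool <- unique(catalogSites(catalog)[
            catalogSites(catalog)$strain %in% members,
            c("chrom", "pos", "alt")])
        if (nrow(pool) < n)
            stop("catalog has too few sites in group ", grp)
        pick <- pool[sample(nrow(pool), n), ]
        data.frame(chrom = pick$chrom, pos = pick$pos, ref = "N",
            alt = pick$alt, tumorDepth = depth, normalDepth = depth,
            tumorAlt = pmax(altReads(n, vaf), 1L),
            normalAlt = pmax(altReads(n, vaf), 1L),
            impact = impact, trueOrigin = "germline", trueGroup = grp)
    }
    for (grp in names(germlineCounts)) {
        n <- germlineCounts[[grp]]
        if (n > 0)
            recs[[paste0("germ_", grp)]] <-
                drawGermline(n, grp, impacts(n))
    }
    if (nGermlineSilent > 0) {
        grp <- sample(groupNames(groups), 1)
        recs$germSilent <- drawGermline(nGermlineSilent, grp, "MODIFIER")
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    records$vaf <- records$tumorAlt / records$tumorDepth
    list(records = records,
        truth = list(nSomaticProteinAltering = nSomatic,
            germlineProteinAltering = germlineCounts))
}

#' Simulate a pair of segmented copy-number profiles
#'
#' Builds a baseline log2 = 0 profile with planted events (one or more per
#' chromosome, each spanning a fraction of it) and a replicate of the same
#' segmentation with per-segment Gaussian noise and an optional global
#' offset (emulating two platforms profiling the same sample).
#'
#' @param events data.frame with columns \code{chrom}, \code{spanFraction}
#'   (0-1), \code{log2}; events are placed from the chromosome start.
#' @param noiseSd per-segment Gaussian noise of the replicate profile.
#' @param offset global log2 offset of the replicate profile.
#' @param genome named chromosome lengths.
#' @param excluded chromosomes to flag as excluded in both profiles.
#' @param seed RNG seed.
#' @return List: \code{a}, \code{b} (\linkS4class{SegmentProfile}s) and
#'   \code{truth} (data.frame of realized event intervals).
#' @export
simulateSegments <- function(events = NULL, noiseSd = 0, offset = 0,
                             genome = mouseChromLengths(),
                             excluded = character(), seed = 1) {
    set.seed(seed)
    events <- if (is.null(events))
        data.frame(chrom = character(), spanFraction = numeric(),
            log2 = numeric())
        else as.data.frame(events)
    stopifnot(all(events$spanFraction <= 1))
    events$chrom <- if (nrow(events)) harmonizeChrom(events$chrom)
        else character()
    segs <- list(); truth <- list()
    for (ch in names(genome)) {
        len <- genome[ch]
        ev <- events[events$chrom == ch, , drop = FALSE]
        cursor <- 1
        for (i in seq_len(nrow(ev))) {
            span <- round(ev$spanFraction[i] * len)
            if (span < 1) next
            if (cursor + span - 1 > len)
                stop("events exceed chromosome ", ch)
            segs[[length(segs) + 1]] <- data.frame(chrom = ch,
                start = cursor, end = cursor + span - 1,
                log2 = ev$log2[i])
            truth[[length(truth) + 1]] <- data.frame(chrom = ch,
                start = cursor, end = cursor + span - 1,
                log2 = ev$log2[i])
            cursor <- cursor + span
        }
        if (cursor <= len)
            segs[[length(segs) + 1]] <- data.frame(chrom = ch,
                start = cursor, end = as.numeric(len), log2 = 0)
    }
    a <- do.call(rbind, segs)
    b <- a
    b$log2 <- b$log2 + rnorm(nrow(b), 0, noiseSd) + offset
    mk <- function(df) {
        gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(df$start, df$end))
        S4Vectors::mcols(gr)$log2 <- df$log2
        new("SegmentProfile", segments = GenomicRanges::sort(gr),
            genome = "mm10", excluded = harmonizeChrom(excluded))
    }
    list(a = mk(a), b = mk(b),
        truth = if (length(truth)) do.call(rbind, truth) else
            data.frame(chrom = character(), start = numeric(),
                end = numeric(), log2 = numeric()))
}
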