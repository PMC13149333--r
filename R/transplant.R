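#' Collapse protein-coding exons into a non-redundant exome model
#'
#' Keeps exons of protein-coding transcripts and merges overlapping or
#' bookended intervals per chromosome (union over strands) into a
#' non-redundant, non-overlapping interval set whose total length defines
#' the per-Mb denominator of mutational-burden values.
#'
#' @param annotation a \code{GRanges} (e.g. from \code{\link{readGtf}}) with
#'   metadata columns \code{type} and a biotype column
#'   (\code{transcript_biotype}, \code{transcript_type} or
#'   \code{gene_biotype}), or a data.frame with \code{chrom}, \code{start},
#'   \code{end} (1-based, closed), \code{type}, \code{biotype}.
#' @return List of class \code{"exomeModel"}: \code{intervals} (reduced
#'   \code{GRanges}) and \code{totalMb}.
#' @export
collapseExome <- function(annotation) {
    if (is.data.frame(annotation)) {
        gr <- GenomicRanges::GRanges(harmonizeChrom(annotation$chrom),
            IRanges::IRanges(annotation$start, annotation$end))
        S4Vectors::mcols(gr)$type <- annotation$type
        S4Vectors::mcols(gr)$transcript_biotype <- annotation$biotype
        annotation <- gr
    }
    if (!length(annotation)) stop("empty annotation")
    mc <- S4Vectors::mcols(annotation)
    biocol <- intersect(c("transcript_biotype", "transcript_type",
        "gene_biotype", "gene_type"), names(mc))
    if (!"type" %in% names(mc) || !length(biocol))
        stop("annotation needs 'type' and a biotype column")
    keep <- mc$type == "exon" & mc[[biocol[1]]] == "protein_coding"
    exons <- annotation[keep & !is.na(keep)]
    if (!length(exons)) stop("no protein-coding exons in annotation")
    GenomicRanges::strand(exons) <- "*"
    merged <- GenomicRanges::reduce(exons)
    structure(list(intervals = merged,
        totalMb = sum(as.numeric(GenomicRanges::width(merged))) / 1e6),
        class = "exomeModel")
}

#' @export
print.exomeModel <- function(x, ...) {
    cat("exome model:", length(x$intervals), "intervals,",
        sprintf("%.2f Mb\n", x$totalMb))
    invisible(x)
}

#' Filter variant records for mutational-burden analysis
#'
#' Retains records meeting, inclusively: read coverage >= \code{minDepth}
#' at the variant site in the tumor (and the matched normal, when one is
#' available); VAF >= \code{minVaf}; >= \code{minAltReads}
#' variant-supporting reads in the tumor; and, with a matched normal, no
#' variant-supporting reads in the normal. Without a matched normal only
#' the tumor-side criteria apply (the cell-line-panel variant of the
#' filter). The filter is idempotent.
#'
#' @param records data.frame of variant records with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{tumorDepth},
#'   \code{tumorAlt}, and (when \code{matchedNormal}) \code{normalDepth},
#'   \code{normalAlt}; \code{vaf} is computed as tumorAlt/tumorDepth when
#'   absent.
#' @param matchedNormal is a matched normal sample available?
#' @param minDepth,minVaf,minAltReads filter thresholds.
#' @return The retained records.
#' @export
filterTmbVariants <- function(records, matchedNormal = TRUE, minDepth = 10,
                              minVaf = 0.1, minAltReads = 3) {
    records <- as.data.frame(records)
    if (!nrow(records)) return(records)
    if (!"vaf" %in% names(records))
        records$vaf <- records$tumorAlt / records$tumorDepth
    keep <- records$tumorDepth >= minDepth &
        records$vaf >= minVaf &
        records$tumorAlt >= minAltReads
    if (matchedNormal) {
        keep <- keep & records$normalDepth >= minDepth &
            records$normalAlt == 0
    }
    records[keep & !is.na(keep), , drop = FALSE]
}

#' Tumor mutational burden per megabase
#'
#' Counts retained variant records inside the collapsed protein-coding
#' exome and divides by the exome length in Mb; mutations outside the
#' exome model are excluded.
#'
#' @param records filtered variant records (chrom, pos).
#' @param exome an \code{"exomeModel"} from \code{\link{collapseExome}}.
#' @return Mutations per Mb (numeric scalar).
#' @export
computeTmb <- function(records, exome) {
    stopifnot(inherits(exome, "exomeModel"))
    if (exome$totalMb <= 0) stop("zero-length exome model")
    records <- as.data.frame(records)
    if (!nrow(records)) return(0)
    gr <- GenomicRanges::GRanges(harmonizeChrom(records$chrom),
        IRanges::IRanges(records$pos, records$pos))
    sum(IRanges::overlapsAny(gr, exome$intervals)) / exome$totalMb
}

#' Is a variant protein-altering?
#'
#' Variants with a predicted impact of MODERATE or HIGH are treated as
#' protein-altering (potentially immunogenic); LOW and MODIFIER are not.
#' Missing impacts yield \code{NA} with a warning, and such records are
#' excluded by downstream counts.
#'
#' @param impact character vector of impact classes.
#' @return Logical vector (NA where the impact is missing).
#' @export
isProteinAltering <- function(impact) {
    impact <- toupper(as.character(impact))
    out <- impact %in% c("MODERATE", "HIGH")
    missing <- is.na(impact) | impact == "" | impact == "NA"
    if (any(missing)) {
        warning(sum(missing), " record(s) without impact annotation excluded")
        out[missing] <- NA
    }
    out
}

#' SNP-dense region mask from a strain catalog
#'
#' Tiles the genome into fixed windows and masks windows whose catalog SNP
#' count exceeds \code{factor} times the median count over covered windows.
#' Such regions are indicative of assembly errors and disqualify germline
#' strain-variant evidence.
#'
#' @param catalog a \linkS4class{StrainVariantCatalog}.
#' @param window window size in bp (default 10 kb).
#' @param factor density multiple over the median that triggers masking.
#' @return \code{GRanges} of masked windows (possibly empty).
#' @export
denseRegionMask <- function(catalog, window = 1e4, factor = 5) {
    sites <- unique(catalogSites(catalog)[, c("chrom", "pos")])
    if (!nrow(sites)) return(GenomicRanges::GRanges())
    dt <- data.table::as.data.table(sites)
    dt[, win := (pos - 1) %/% window]
    counts <- dt[, .N, by = .(chrom, win)]
    med <- median(counts$N)
    hot <- counts[N > factor * med]
    if (!nrow(hot)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(hot$chrom,
        IRanges::IRanges(start = hot$win * window + 1,
            end = (hot$win + 1) * window))
}

#' Tag germline variants with their strain group of origin
#'
#' A record is tagged as a strain germline variant when it is present in
#' both tumor and normal (variant-supporting reads in both), is reported in
#' the strain catalog for a strain whose group is among the line's
#' annotated backgrounds, and lies outside the SNP-dense region mask.
#' Other records keep an \code{NA} tag. The returned records carry an
#' \code{origin} column (\code{"somatic"} for tumor-only records,
#' \code{"germline"} for tumor+normal records) and a \code{strainGroup}
#' column with the tag.
#'
#' @param records variant records with \code{chrom}, \code{pos}, \code{alt},
#'   \code{tumorAlt}, \code{normalAlt}.
#' @param catalog a \linkS4class{StrainVariantCatalog}.
#' @param groups the \linkS4class{StrainGroupSet} of the catalog strains.
#' @param lineBackgrounds character vector of strain groups annotated as
#'   the line's genetic backgrounds.
#' @param mask optional \code{GRanges} dense-region mask
#'   (\code{\link{denseRegionMask}}).
#' @return The records with \code{origin} and \code{strainGroup} columns.
#' @export
annotateStrainGermline <- function(records, catalog, groups, lineBackgrounds,
                                   mask = NULL) {
    records <- normalizeSites(as.data.frame(records))
    records$origin <- ifelse(records$normalAlt > 0 & records$tumorAlt > 0,
        "germline", ifelse(records$tumorAlt > 0, "somatic", "unassigned"))
    records$strainGroup <- NA_character_
    germIdx <- which(records$origin == "germline")
    if (!length(germIdx)) return(records)
    g2s <- groupOf(groups)
    sites <- catalogSites(catalog)
    siteGroups <- split(unname(g2s[sites$strain]),
        siteKey(sites$chrom, sites$pos, sites$alt))
    keys <- siteKey(records$chrom[germIdx], records$pos[germIdx],
        records$alt[germIdx])
    tags <- vapply(keys, function(k) {
        gs <- unique(siteGroups[[k]])
        gs <- gs[!is.na(gs)]
        hit <- sort(intersect(gs, lineBackgrounds))
        if (length(hit)) hit[1] else NA_character_
    }, character(1), USE.NAMES = FALSE)
    if (!is.null(mask) && length(mask)) {
        gr <- GenomicRanges::GRanges(records$chrom[germIdx],
            IRanges::IRanges(records$pos[germIdx], records$pos[germIdx]))
        tags[IRanges::overlapsAny(gr, mask)] <- NA_character_
    }
    records$strainGroup[germIdx] <- tags
    records
}

#' Recipient-dependent effective protein-altering TMB
#'
#' The effective protein-altering mutation set of a donor line for a given
#' recipient is its somatic protein-altering mutations plus those tagged
#' germline protein-altering variants whose strain group does not match any
#' of the recipient's backgrounds (an F1 hybrid recipient contributes both
#' parental groups). Germline variants matching the recipient are
#' self-antigens there and drop out.
#'
#' @param records annotated variant records (see
#'   \code{\link{annotateStrainGermline}}) with an \code{impact} column;
#'   records should already have passed \code{\link{filterTmbVariants}}.
#' @param recipientGroups character vector of the recipient's strain
#'   groups.
#' @param exome optional \code{"exomeModel"}; when given, the effective
#'   count is also expressed per Mb.
#' @return List of class \code{"ptmbResult"}: \code{somaticCount},
#'   \code{germlineMismatchedCount}, \code{effectiveCount},
#'   \code{effectivePerMb} (NA without an exome), \code{recipient}.
#' @export
effectivePtmb <- function(records, recipientGroups, exome = NULL) {
    records <- as.data.frame(records)
    pa <- isProteinAltering(records$impact)
    records <- records[!is.na(pa) & pa, , drop = FALSE]
    somatic <- sum(records$origin == "somatic")
    germ <- records[records$origin == "germline" &
        !is.na(records$strainGroup), , drop = FALSE]
    mismatched <- sum(!germ$strainGroup %in% recipientGroups)
    eff <- somatic + mismatched
    perMb <- if (!is.null(exome)) eff / exome$totalMb else NA_real_
    structure(list(somaticCount = somatic,
        germlineMismatchedCount = mismatched,
        effectiveCount = eff, effectivePerMb = perMb,
        recipient = paste(sort(recipientGroups), collapse = ";")),
        class = "ptmbResult")
}

#' @export
print.ptmbResult <- function(x, ...) {
    cat(sprintf(
        "effective pTMB for recipient %s: %d mutations (%d somatic + %d mismatched germline)%s\n",
        x$recipient, x$effectiveCount, x$somaticCount,
        x$germlineMismatchedCount,
        if (is.na(x$effectivePerMb)) "" else
            sprintf(" = %.2f per Mb", x$effectivePerMb)))
    invisible(x)
}

#' Recommend transplantation recipients for a donor line
#'
#' Ranks the line's genetic backgrounds by percent contribution and
#' classifies transplantability: lines with one or two backgrounds (a
#' third, if any, contributing < 1\%) are prioritized; a third background
#' contributing 1-9\% makes the line feasible; three dominant backgrounds
#' (third >= 10\%) are not recommended. Candidate recipients are the top
#' background strain and, when a second background contributes >= 1\%, the
#' matched F1 hybrid of the top two. Candidates incompatible with the
#' line's resolved MHC cluster calls are dropped, and male lines carry a
#' male-recipient constraint (male-specific antigens mismatch into
#' females).
#'
#' @param composition a \code{\link{strainComposition}} result.
#' @param mhc optional \code{\link{callMhc}} result.
#' @param sex optional \code{\link{inferSex}} result.
#' @return List of class \code{"recommendation"}: \code{category},
#'   \code{candidates} (data.frame of recipient labels and their group
#'   sets), \code{sexConstraint}, \code{rationale}.
#' @export
recommendRecipients <- function(composition, mhc = NULL, sex = NULL) {
    comp <- as.data.frame(composition)
    if (!nrow(comp)) stop("composition undefined; no recommendation")
    third <- if (nrow(comp) >= 3) comp$percent[3] else 0
    category <- if (third < 1) "prioritized"
        else if (third < 10) "feasible"
        else "not recommended"
    top <- comp$group[1]
    cands <- data.frame(recipient = top, groups = top,
        stringsAsFactors = FALSE)
    if (nrow(comp) >= 2 && comp$percent[2] >= 1) {
        pair <- sort(comp$group[1:2])
        cands <- rbind(cands, data.frame(
            recipient = paste0(pair[1], ";", pair[2], "-F1"),
            groups = paste(pair, collapse = ";")))
    }
    if (!is.null(mhc)) {
        resolved <- mhc$perCluster[!vapply(mhc$perCluster,
            function(x) length(x) == 1 && is.na(x), logical(1))]
        need <- unique(unlist(resolved))
        ok <- vapply(strsplit(cands$groups, ";"),
            function(g) all(need %in% g) || !length(need), logical(1))
        if (any(ok)) cands <- cands[ok, , drop = FALSE]
        else warning("no candidate recipient covers the line's MHC calls")
    }
    sexConstraint <- if (!is.null(sex) && sex$call == "male")
        "male recipients (male-specific antigens mismatch into females)"
        else "any sex"
    rationale <- sprintf(
        "third-ranked background at %.2f%% -> %s; top backgrounds: %s",
        third, category,
        paste(sprintf("%s (%.1f%%)", head(comp$group, 3),
            head(comp$percent, 3)), collapse = ", "))
    structure(list(category = category, candidates = cands,
        sexConstraint = sexConstraint, rationale = rationale),
        class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
    cat("transplantation category:", x$category, "\n")
    cat("candidate recipients:",
        paste(x$candidates$recipient, collapse = ", "), "\n")
    cat("sex constraint:", x$sexConstraint, "\n")
    cat(x$rationale, "\n")
    invisible(x)
}
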