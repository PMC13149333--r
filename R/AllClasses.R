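#' StrainVariantCatalog: per-strain SNP sites of an inbred strain panel
#'
#' Container for a strain variant catalog in the style of the Mouse Genomes
#' Project: for each inbred strain, the set of SNP sites (chromosome,
#' 1-based position, alternate base) that distinguish it from the reference.
#' A site is keyed by (chrom, pos, alt), so different alternate bases at one
#' position are distinct sites. Inbred strains are essentially homozygous,
#' so carriage is recorded as presence/absence only.
#'
#' @slot sites data.frame with columns \code{chrom}, \code{pos}, \code{alt},
#'   \code{strain}; one row per (strain, site) pair.
#' @slot strains character vector of unique strain names.
#' @name StrainVariantCatalog-class
#' @aliases StrainVariantCatalog-class
#' @exportClass StrainVariantCatalog
setClass("StrainVariantCatalog",
    representation(sites = "data.frame", strains = "character"))

setValidity("StrainVariantCatalog", function(object) {
    msg <- character()
    req <- c("chrom", "pos", "alt", "strain")
    if (!all(req %in% names(object@sites)))
        msg <- c(msg, paste("sites must have columns", paste(req, collapse = ", ")))
    if (anyDuplicated(object@strains))
        msg <- c(msg, "strain names must be unique")
    if (length(msg)) return(msg)
    if (nrow(object@sites)) {
        if (any(object@sites$pos < 1)) msg <- c(msg, "positions must be >= 1")
        if (!all(object@sites$strain %in% object@strains))
            msg <- c(msg, "sites refer to strains absent from the strain list")
        key <- paste(object@sites$strain,
            siteKey(object@sites$chrom, object@sites$pos, object@sites$alt))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (strain, site) pairs")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a StrainVariantCatalog
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos}, \code{alt},
#'   \code{strain} (one row per strain carrying the site). Chromosome names
#'   are harmonized to the \code{chr*} convention.
#' @param strains optional character vector of strain names; defaults to the
#'   strains observed in \code{sites}. Strains without any site are legal but
#'   are excluded from correlation with a warning.
#' @return A \linkS4class{StrainVariantCatalog}.
#' @export
#' @examples
#' cat <- strainVariantCatalog(data.frame(
#'     chrom = "chr1", pos = c(100, 200, 100), alt = "A",
#'     strain = c("B6", "B6", "129S1")))
#' strainNames(cat)
strainVariantCatalog <- function(sites, strains = NULL) {
    sites <- normalizeSites(as.data.frame(sites))
    sites$strain <- as.character(sites$strain)
    sites <- unique(sites[, c("chrom", "pos", "alt", "strain")])
    if (is.null(strains)) strains <- sort(unique(sites$strain))
    new("StrainVariantCatalog", sites = sites, strains = as.character(strains))
}

#' StrainGroupSet: a partition of strains into genealogically related groups
#'
#' @slot groups named list; each element a character vector of strain names.
#' @name StrainGroupSet-class
#' @exportClass StrainGroupSet
setClass("StrainGroupSet", representation(groups = "list"))

setValidity("StrainGroupSet", function(object) {
    g <- object@groups
    msg <- character()
    if (is.null(names(g)) || any(names(g) == "") || anyDuplicated(names(g)))
        msg <- c(msg, "groups must be uniquely named")
    if (any(lengths(g) == 0)) msg <- c(msg, "empty groups are not allowed")
    all <- unlist(g, use.names = FALSE)
    if (anyDuplicated(all)) msg <- c(msg, "a strain may belong to only one group")
    if (length(msg)) msg else TRUE
})

#' Construct a StrainGroupSet
#'
#' @param groups named list of character vectors (group name -> member
#'   strains), or a named character vector (strain -> group name).
#' @return A \linkS4class{StrainGroupSet}.
#' @export
strainGroupSet <- function(groups) {
    if (is.character(groups) && !is.null(names(groups)))
        groups <- split(names(groups), unname(groups))
    new("StrainGroupSet", groups = lapply(groups, as.character))
}

#' SignatureLibrary: signature SNPs owned by strain groups
#'
#' A signature SNP is carried by at least one strain of its owning group and
#' by no strain outside that group; within-group sharing is allowed. The
#' scope is either \code{"genome"} or the name of one MHC gene cluster.
#'
#' @slot sites data.frame with columns \code{chrom}, \code{pos}, \code{alt},
#'   \code{group}; each site maps to exactly one group.
#' @slot groups a \linkS4class{StrainGroupSet} the owning groups belong to.
#' @slot scope character scalar.
#' @name SignatureLibrary-class
#' @exportClass SignatureLibrary
setClass("SignatureLibrary",
    representation(sites = "data.frame", groups = "StrainGroupSet",
        scope = "character"))

setValidity("SignatureLibrary", function(object) {
    msg <- character()
    req <- c("chrom", "pos", "alt", "group")
    if (!all(req %in% names(object@sites)))
        msg <- c(msg, paste("sites must have columns", paste(req, collapse = ", ")))
    if (length(object@scope) != 1) msg <- c(msg, "scope must be a scalar")
    if (length(msg)) return(msg)
    if (nrow(object@sites)) {
        if (anyDuplicated(siteKey(object@sites$chrom, object@sites$pos,
                object@sites$alt)))
            msg <- c(msg, "each site must map to exactly one group")
        if (!all(object@sites$group %in% names(object@groups@groups)))
            msg <- c(msg, "owning groups must exist in the StrainGroupSet")
    }
    if (length(msg)) msg else TRUE
})

#' SegmentProfile: a segmented log2 copy-ratio track
#'
#' @slot segments \link[GenomicRanges]{GRanges} with a numeric metadata
#'   column \code{log2}; per chromosome non-overlapping and sorted.
#' @slot genome genome build label (e.g. \code{"mm10"}).
#' @slot excluded chromosomes excluded from smoothing/distance analyses
#'   (e.g. chromothriptic chromosomes, flagged by the user).
#' @name SegmentProfile-class
#' @exportClass SegmentProfile
setClass("SegmentProfile",
    representation(segments = "GRanges", genome = "character",
        excluded = "character"))

setValidity("SegmentProfile", function(object) {
    msg <- character()
    if (!"log2" %in% names(S4Vectors::mcols(object@segments)))
        msg <- c(msg, "segments need a 'log2' metadata column")
    else if (!all(is.finite(S4Vectors::mcols(object@segments)$log2)))
        msg <- c(msg, "log2 values must be finite")
    if (length(object@segments) &&
        !GenomicRanges::isDisjoint(object@segments))
        msg <- c(msg, "segments must be non-overlapping within chromosomes")
    if (length(msg)) msg else TRUE
})

#' Construct a SegmentProfile
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{log2} (half-open, BED-like start coordinates) or a
#'   \code{GRanges} with a \code{log2} column (1-based, closed).
#' @param genome genome build label.
#' @param excluded character vector of chromosomes to exclude from
#'   smoothing/stability analyses.
#' @return A \linkS4class{SegmentProfile}.
#' @export
segmentProfile <- function(segments, genome = "mm10", excluded = character()) {
    if (is.data.frame(segments)) {
        segments$chrom <- harmonizeChrom(segments$chrom)
        gr <- GenomicRanges::GRanges(segments$chrom,
            IRanges::IRanges(start = as.numeric(segments$start) + 1,
                end = as.numeric(segments$end)))
        S4Vectors::mcols(gr)$log2 <- as.numeric(segments$log2)
        segments <- gr
    }
    segments <- GenomicRanges::sort(segments)
    new("SegmentProfile", segments = segments, genome = genome,
        excluded = harmonizeChrom(excluded))
}

#' BinnedProfile: fixed-width binned log2 copy-ratio values
#'
#' @slot bins data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{log2} (1-based closed bin coordinates aligned to the bin grid;
#'   \code{log2} is \code{NA} where a bin has no segment coverage).
#' @slot binSize bin width in bp.
#' @slot excluded chromosomes excluded from smoothing/distance analyses.
#' @name BinnedProfile-class
#' @exportClass BinnedProfile
setClass("BinnedProfile",
    representation(bins = "data.frame", binSize = "numeric",
        excluded = "character"))

setValidity("BinnedProfile", function(object) {
    b <- object@bins
    msg <- character()
    if (!all(c("chrom", "start", "end", "log2") %in% names(b)))
        msg <- c(msg, "bins must have chrom/start/end/log2")
    else if (any((b$start - 1) %% object@binSize != 0))
        msg <- c(msg, "bin starts must align to the bin grid")
    if (length(msg)) msg else TRUE
})

## ---- accessors -------------------------------------------------------------

#' @rdname StrainVariantCatalog-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname StrainVariantCatalog-class
#' @export
setMethod("strainNames", "StrainVariantCatalog", function(x) x@strains)
#' @rdname StrainGroupSet-class
#' @export
setMethod("strainNames", "StrainGroupSet",
    function(x) unlist(x@groups, use.names = FALSE))

#' @rdname StrainVariantCatalog-class
#' @export
setGeneric("catalogSites", function(x) standardGeneric("catalogSites"))
#' @rdname StrainVariantCatalog-class
#' @export
setMethod("catalogSites", "StrainVariantCatalog", function(x) x@sites)

#' @rdname StrainGroupSet-class
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))
#' @rdname StrainGroupSet-class
#' @export
setMethod("groupNames", "StrainGroupSet", function(x) names(x@groups))
#' @rdname SignatureLibrary-class
#' @export
setMethod("groupNames", "SignatureLibrary", function(x) names(x@groups@groups))

#' @rdname StrainGroupSet-class
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))
#' @rdname StrainGroupSet-class
#' @export
setMethod("groupMembers", "StrainGroupSet", function(x) x@groups)

#' @rdname StrainGroupSet-class
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))
#' @rdname StrainGroupSet-class
#' @export
setMethod("groupOf", "StrainGroupSet", function(x) {
    setNames(rep(names(x@groups), lengths(x@groups)),
        unlist(x@groups, use.names = FALSE))
})

#' @rdname SignatureLibrary-class
#' @export
setGeneric("signatureSites", function(x) standardGeneric("signatureSites"))
#' @rdname SignatureLibrary-class
#' @export
setMethod("signatureSites", "SignatureLibrary", function(x) x@sites)

#' @rdname SignatureLibrary-class
#' @export
setGeneric("libraryScope", function(x) standardGeneric("libraryScope"))
#' @rdname SignatureLibrary-class
#' @export
setMethod("libraryScope", "SignatureLibrary", function(x) x@scope)

#' @rdname SignatureLibrary-class
#' @export
setGeneric("libraryGroups", function(x) standardGeneric("libraryGroups"))
#' @rdname SignatureLibrary-class
#' @export
setMethod("libraryGroups", "SignatureLibrary", function(x) x@groups)

#' @rdname SegmentProfile-class
#' @export
setGeneric("profileSegments", function(x) standardGeneric("profileSegments"))
#' @rdname SegmentProfile-class
#' @export
setMethod("profileSegments", "SegmentProfile", function(x) x@segments)

#' @rdname SegmentProfile-class
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))
#' @rdname SegmentProfile-class
#' @export
setMethod("genomeBuild", "SegmentProfile", function(x) x@genome)

#' @rdname SegmentProfile-class
#' @export
setGeneric("excludedChroms", function(x) standardGeneric("excludedChroms"))
#' @rdname SegmentProfile-class
#' @export
setMethod("excludedChroms", "SegmentProfile", function(x) x@excluded)
#' @rdname BinnedProfile-class
#' @export
setMethod("excludedChroms", "BinnedProfile", function(x) x@excluded)

#' @rdname BinnedProfile-class
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))
#' @rdname BinnedProfile-class
#' @export
setMethod("profileBins", "BinnedProfile", function(x) x@bins)

#' @rdname BinnedProfile-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname BinnedProfile-class
#' @export
setMethod("binSize", "BinnedProfile", function(x) x@binSize)

## ---- show ------------------------------------------------------------------

setMethod("show", "StrainVariantCatalog", function(object) {
    cat("StrainVariantCatalog with", length(object@strains), "strains and",
        length(unique(siteKey(object@sites$chrom, object@sites$pos,
            object@sites$alt))), "distinct sites\n")
})

setMethod("show", "StrainGroupSet", function(object) {
    cat("StrainGroupSet:", length(object@groups), "groups,",
        length(unlist(object@groups)), "strains\n")
    for (g in names(object@groups))
        cat("  ", g, ": ", paste(object@groups[[g]], collapse = ", "),
            "\n", sep = "")
})

setMethod("show", "SignatureLibrary", function(object) {
    cat("SignatureLibrary [scope: ", object@scope, "] ",
        nrow(object@sites), " signature SNPs across ",
        length(unique(object@sites$group)), " groups\n", sep = "")
})

setMethod("show", "SegmentProfile", function(object) {
    cat("SegmentProfile (", object@genome, "): ",
        length(object@segments), " segments",
        if (length(object@excluded))
            paste0("; excluded: ", paste(object@excluded, collapse = ",")),
        "\n", sep = "")
})

setMethod("show", "BinnedProfile", function(object) {
    cat("BinnedProfile: ", nrow(object@bins), " bins of ",
        object@binSize / 1e6, " Mb\n", sep = "")
})
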