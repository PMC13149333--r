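#' Read variant records from VCF or a site TSV
#'
#' VCF parsing is delegated to \pkg{vcfR}; per-sample allelic depths (AD)
#' are used for tumor/normal read counts when two genotype columns are
#' present (tumor assumed first unless named), and a SnpEff/VEP-style
#' \code{ANN}/\code{CSQ} INFO field is scanned for the impact class. The
#' TSV dialect expects the columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt} and optionally \code{tumorDepth}, \code{normalDepth},
#' \code{tumorAlt}, \code{normalAlt}, \code{impact}. Malformed TSV rows
#' are skipped with a counted warning; more than 1\% malformed rows is an
#' error.
#'
#' @param path input file.
#' @param dialect \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"tsv"}.
#' @param tumorSample,normalSample genotype column names in the VCF
#'   (defaults: first and second column).
#' @return data.frame of variant records.
#' @export
readVariants <- function(path, dialect = c("auto", "vcf", "tsv"),
                         tumorSample = NULL, normalSample = NULL) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (dialect == "vcf")
        return(readVariantsVcf(path, tumorSample, normalSample))
    raw <- read.table(path, header = TRUE, sep = "\t",
        colClasses = "character", comment.char = "#")
    need <- c("chrom", "pos", "alt")
    if (!all(need %in% names(raw)))
        stop("TSV needs at least columns chrom, pos, alt")
    pos <- suppressWarnings(as.integer(raw$pos))
    bad <- is.na(pos) | raw$chrom == "" | raw$alt == ""
    if (any(bad)) {
        if (mean(bad) > 0.01)
            stop("more than 1% malformed records in ", path)
        warning(sum(bad), " malformed record(s) skipped")
        raw <- raw[!bad, , drop = FALSE]
        pos <- pos[!bad]
    }
    out <- data.frame(chrom = harmonizeChrom(raw$chrom), pos = pos,
        ref = if ("ref" %in% names(raw)) raw$ref else "N",
        alt = raw$alt)
    for (col in c("tumorDepth", "normalDepth", "tumorAlt", "normalAlt"))
        if (col %in% names(raw)) out[[col]] <- as.numeric(raw[[col]])
    if ("impact" %in% names(raw)) out$impact <- raw$impact
    if ("vaf" %in% names(raw)) out$vaf <- as.numeric(raw$vaf)
    out
}

readVariantsVcf <- function(path, tumorSample = NULL, normalSample = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    out <- data.frame(chrom = harmonizeChrom(fix$CHROM),
        pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT)
    info <- vcfR::getINFO(v)
    imp <- regmatches(info,
        regexpr("(HIGH|MODERATE|LOW|MODIFIER)", info))
    out$impact <- NA_character_
    has <- grepl("(HIGH|MODERATE|LOW|MODIFIER)", info)
    out$impact[has] <- imp
    gtSamples <- colnames(v@gt)[-1]
    if (length(gtSamples)) {
        if (is.null(tumorSample)) tumorSample <- gtSamples[1]
        ad <- vcfR::extract.gt(v, "AD")
        parseAD <- function(x) {
            parts <- strsplit(x, ",")
            alt <- vapply(parts, function(p)
                suppressWarnings(as.numeric(p[2])), numeric(1))
            tot <- vapply(parts, function(p)
                sum(suppressWarnings(as.numeric(p)), na.rm = TRUE),
                numeric(1))
            list(alt = alt, depth = tot)
        }
        if (tumorSample %in% colnames(ad)) {
            t <- parseAD(ad[, tumorSample])
            out$tumorDepth <- t$depth
            out$tumorAlt <- t$alt
            out$vaf <- t$alt / t$depth
        }
        if (is.null(normalSample) && length(gtSamples) >= 2)
            normalSample <- gtSamples[2]
        if (!is.null(normalSample) && normalSample %in% colnames(ad)) {
            n <- parseAD(ad[, normalSample])
            out$normalDepth <- n$depth
            out$normalAlt <- n$alt
        }
    }
    out
}

#' Read sample SNP calls (chrom, pos, alt)
#'
#' Thin wrapper over \code{\link{readVariants}} returning only the site
#' columns used by the signature-SNP machinery.
#'
#' @inheritParams readVariants
#' @return data.frame with \code{chrom}, \code{pos}, \code{alt}.
#' @export
readSampleCalls <- function(path, dialect = c("auto", "vcf", "tsv")) {
    unique(readVariants(path, dialect)[, c("chrom", "pos", "alt")])
}

#' Read a strain variant catalog
#'
#' Accepts the 4-column TSV dialect (\code{chrom}, \code{pos}, \code{alt},
#' \code{strain}) or a multi-sample VCF whose genotype columns are strains:
#' a strain carries a site when its genotype contains a non-reference
#' allele (heterozygous catalog entries count as presence).
#'
#' @inheritParams readVariants
#' @return A \linkS4class{StrainVariantCatalog}.
#' @export
readCatalog <- function(path, dialect = c("auto", "vcf", "tsv")) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (dialect == "tsv") {
        df <- read.table(path, header = TRUE, sep = "\t",
            colClasses = c(chrom = "character", alt = "character",
                strain = "character"))
        return(strainVariantCatalog(df))
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, "GT")
    carrier <- !is.na(gt) & grepl("[1-9]", gt)
    idx <- which(carrier, arr.ind = TRUE)
    sites <- data.frame(chrom = fix$CHROM[idx[, 1]],
        pos = as.integer(fix$POS[idx[, 1]]),
        alt = fix$ALT[idx[, 1]],
        strain = colnames(gt)[idx[, 2]])
    strainVariantCatalog(sites)
}

#' Read a copy-number segment table
#'
#' Expects the common segmentation-output dialect: a TSV with columns
#' \code{chrom}(osome), \code{start}, \code{end}, \code{log2} (BED-like
#' half-open starts). Unsorted input is sorted; overlapping segments are an
#' error.
#'
#' @param path TSV file.
#' @param genome genome build label stored on the profile.
#' @param excluded chromosomes to flag as excluded.
#' @return A \linkS4class{SegmentProfile}.
#' @export
readSegments <- function(path, genome = "mm10", excluded = character()) {
    df <- read.table(path, header = TRUE, sep = "\t")
    names(df) <- sub("^chromosome$", "chrom", names(df))
    stopifnot(all(c("chrom", "start", "end", "log2") %in% names(df)))
    segmentProfile(df, genome = genome, excluded = excluded)
}

#' Read interval sets (BED) and gene annotation (GTF)
#'
#' Delegates to \pkg{rtracklayer}; BED half-open coordinates and GTF
#' 1-based closed coordinates are converted to the internal GRanges
#' convention by the importer.
#'
#' @param path BED or GTF file.
#' @return \code{GRanges}.
#' @export
readIntervals <- function(path) {
    gr <- rtracklayer::import(path)
    GenomeInfoDb::seqlevels(gr) <- harmonizeChrom(
        GenomeInfoDb::seqlevels(gr))
    gr
}

#' @rdname readIntervals
#' @export
readGtf <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    GenomeInfoDb::seqlevels(gr) <- harmonizeChrom(
        GenomeInfoDb::seqlevels(gr))
    gr
}

#' Default run configuration
#'
#' Central bundle of the tunable thresholds with their documented defaults;
#' round-trips losslessly through JSON.
#'
#' @param ... overrides of individual defaults.
#' @return Named list of class \code{"runConfig"}.
#' @export
runConfig <- function(...) {
    cfg <- list(
        genome = "mm10",
        binSizeGenome = 1e7,
        binSizeMhc = 1e6,
        minScore = 0.3,
        minExpected = 5,
        sexRatioCutoff = 0.05,
        linkageWindow = 2.5e7,
        cbsCap = 10,
        purityFloor = 0.2,
        cnvLoadCutoff = 0.2,
        wgiiTolerance = 0.2,
        smoothWindow = 5,
        insertionMinReads = 10,
        insertionMinNormalized = 0.02,
        topK = 10,
        seed = 1)
    over <- list(...)
    stopifnot(all(names(over) %in% names(cfg)))
    cfg[names(over)] <- over
    structure(cfg, class = "runConfig")
}

#' @rdname runConfig
#' @param config a \code{runConfig}.
#' @param path JSON file.
#' @export
writeRunConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(runConfig, cfg)
}
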