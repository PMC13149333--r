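#' Pairwise Pearson correlation of strain SNP patterns
#'
#' Encodes every strain as a presence/absence vector over the union of all
#' catalog sites and computes the Pearson correlation (the phi coefficient
#' on binary vectors) for each pairwise strain combination. Strains without
#' any site in the requested scope are excluded with a warning, as their
#' correlation is undefined.
#'
#' @param catalog a \linkS4class{StrainVariantCatalog}.
#' @param scopeInterval optional \code{GRanges} restricting the site universe
#'   (used for per-MHC-cluster correlation).
#' @return Symmetric correlation matrix with unit diagonal, one row/column
#'   per retained strain.
#' @export
#' @examples
#' cat <- strainVariantCatalog(data.frame(
#'     chrom = "chr1", pos = rep(1:4, 2), alt = "A",
#'     strain = rep(c("s1", "s2"), each = 4)))
#' correlateStrains(cat)
correlateStrains <- function(catalog, scopeInterval = NULL) {
    stopifnot(is(catalog, "StrainVariantCatalog"))
    sites <- catalogSites(catalog)
    if (!is.null(scopeInterval))
        sites <- restrictSites(sites, scopeInterval)
    strains <- strainNames(catalog)
    if (length(strains) < 2)
        stop("need at least two strains to correlate")
    universe <- unique(siteKey(sites$chrom, sites$pos, sites$alt))
    if (!length(universe))
        stop("catalog has no sites in the requested scope")
    m <- matrix(0L, nrow = length(universe), ncol = length(strains),
        dimnames = list(universe, strains))
    m[cbind(siteKey(sites$chrom, sites$pos, sites$alt), sites$strain)] <- 1L
    empty <- colSums(m) == 0L
    constant <- colSums(m) == nrow(m)
    drop <- empty | constant
    if (any(drop)) {
        warning("excluding strains with undefined correlation (no sites or ",
            "all sites): ", paste(strains[drop], collapse = ", "))
        m <- m[, !drop, drop = FALSE]
    }
    if (ncol(m) < 2)
        stop("fewer than two strains with defined correlation")
    r <- cor(m)
    diag(r) <- 1
    r
}

restrictSites <- function(sites, interval) {
    if (!nrow(sites)) return(sites)
    gr <- GenomicRanges::GRanges(sites$chrom,
        IRanges::IRanges(sites$pos, sites$pos))
    sites[IRanges::overlapsAny(gr, interval), , drop = FALSE]
}

#' Cluster strains into genealogically related groups
#'
#' Agglomerative hierarchical clustering on the distance 1 - r, where r is
#' the pairwise SNP-pattern correlation, cut at a fixed height. Groups are
#' named after their alphabetically first member strain so that identical
#' inputs always yield identical group labels.
#'
#' @param corr symmetric correlation matrix from \code{\link{correlateStrains}}.
#' @param linkageMethod agglomeration method passed to \code{\link[stats]{hclust}}.
#' @param cutHeight tree cut height on the 1 - r scale; must lie in (0, 2).
#' @return A \linkS4class{StrainGroupSet}.
#' @export
clusterStrainGroups <- function(corr, linkageMethod = "average",
                                cutHeight = 0.5) {
    if (!is.matrix(corr) || nrow(corr) != ncol(corr) ||
        !isTRUE(all.equal(unname(corr), unname(t(corr)), tolerance = 1e-8)))
        stop("corr must be a symmetric correlation matrix")
    if (cutHeight <= 0 || cutHeight >= 2)
        stop("cutHeight must lie in (0, 2)")
    if (nrow(corr) == 1)
        return(strainGroupSet(setNames(list(rownames(corr)), rownames(corr))))
    d <- stats::as.dist(1 - corr)
    hc <- hclust(d, method = linkageMethod)
    cl <- cutree(hc, h = cutHeight)
    groups <- split(names(cl), cl)
    names(groups) <- vapply(groups, function(s) sort(s)[1], character(1))
    strainGroupSet(groups[order(names(groups))])
}

#' Select group-specific signature SNPs
#'
#' A site is a signature SNP of group G when it is carried by at least one
#' strain of G and by no strain outside G; carriage may be shared freely
#' within the group. Strains that were excluded from clustering (e.g. no
#' sites) still count as "outside every group" carriers and therefore veto
#' signatures.
#'
#' @param catalog a \linkS4class{StrainVariantCatalog}.
#' @param groups a \linkS4class{StrainGroupSet} covering the catalog strains.
#' @param scopeInterval optional \code{GRanges}; restrict selection to sites
#'   inside it.
#' @param scope scope label stored in the library (default \code{"genome"}).
#' @return A \linkS4class{SignatureLibrary} (possibly empty).
#' @export
selectSignatureSnps <- function(catalog, groups, scopeInterval = NULL,
                                scope = "genome") {
    stopifnot(is(catalog, "StrainVariantCatalog"), is(groups, "StrainGroupSet"))
    sites <- catalogSites(catalog)
    if (!is.null(scopeInterval))
        sites <- restrictSites(sites, scopeInterval)
    g2s <- groupOf(groups)
    dt <- data.table::as.data.table(sites)
    ## strains not assigned to any group get a sentinel group that always
    ## disqualifies a shared site
    dt[, grp := ifelse(is.na(g2s[strain]), ".unassigned", g2s[strain])]
    sig <- dt[, .(ngroup = data.table::uniqueN(grp), group = grp[1]),
        by = .(chrom, pos, alt)]
    sig <- sig[ngroup == 1L & group != ".unassigned",
        .(chrom, pos, alt, group)]
    data.table::setorder(sig, chrom, pos, alt)
    new("SignatureLibrary", sites = as.data.frame(sig), groups = groups,
        scope = scope)
}

#' MHC (H2) gene cluster intervals
#'
#' The mouse MHC locus on chromosome 17 divided into six gene clusters
#' (H2-K, -A, -E, -D, -Q, -T) by MHC subclass. Shipped as an editable,
#' versioned configuration with approximate GRCm38 coordinates; the
#' intervals are non-overlapping and ordered along the chromosome.
#'
#' @param genome build label (only \code{"GRCm38"}/\code{"mm10"} shipped).
#' @return \code{GRanges} of six named cluster intervals.
#' @export
#' @examples
#' mhcClusterSpec()
mhcClusterSpec <- function(genome = "GRCm38") {
    if (!genome %in% c("GRCm38", "mm10"))
        stop("no MHC cluster configuration for build ", genome)
    gr <- GenomicRanges::GRanges("chr17", IRanges::IRanges(
        start = c(33600000, 34200001, 34350001, 34600001, 35400001, 35600001),
        end   = c(34200000, 34350000, 34600000, 35400000, 35600000, 36400000)))
    names(gr) <- c("H2-K", "H2-A", "H2-E", "H2-D", "H2-Q", "H2-T")
    S4Vectors::mcols(gr)$cluster <- names(gr)
    gr
}

#' Build per-cluster MHC haplotype groups and signature libraries
#'
#' Runs the strain-group workflow independently for each of the six MHC gene
#' clusters: correlate SNP patterns restricted to the cluster interval,
#' cluster into haplotype groups, and select cluster-scoped signature SNPs.
#' A cluster with no catalog sites (or fewer than two informative strains)
#' is marked unresolvable (\code{NULL} entry).
#'
#' @param catalog a \linkS4class{StrainVariantCatalog} covering chr17.
#' @param clusters \code{GRanges} of cluster intervals, see
#'   \code{\link{mhcClusterSpec}}.
#' @param linkageMethod,cutHeight clustering parameters, see
#'   \code{\link{clusterStrainGroups}}.
#' @return List with elements \code{clusters} (the interval spec) and
#'   \code{perCluster}: for each cluster either \code{NULL} or a list with
#'   \code{groups} (haplotype \linkS4class{StrainGroupSet}) and
#'   \code{library} (cluster-scoped \linkS4class{SignatureLibrary}).
#' @export
buildMhcHaplotypeGroups <- function(catalog, clusters = mhcClusterSpec(),
                                    linkageMethod = "average",
                                    cutHeight = 0.5) {
    stopifnot(is(catalog, "StrainVariantCatalog"))
    if (length(clusters) != 6)
        stop("expected exactly six MHC gene clusters")
    perCluster <- setNames(vector("list", length(clusters)), names(clusters))
    for (cl in names(clusters)) {
        iv <- clusters[cl]
        inCluster <- restrictSites(catalogSites(catalog), iv)
        if (!nrow(inCluster)) next  # unresolvable
        patterns <- vapply(split(
            siteKey(inCluster$chrom, inCluster$pos, inCluster$alt),
            inCluster$strain),
            function(k) paste(sort(k), collapse = ";"), character(1))
        if (length(unique(patterns)) == 1) {
            ## every site-carrying strain shows the same pattern: a single
            ## haplotype group; no site discriminates, so the cluster
            ## library is empty (uninformative)
            hap <- strainGroupSet(setNames(list(names(patterns)), cl))
            lib <- new("SignatureLibrary", sites = data.frame(
                chrom = character(), pos = integer(), alt = character(),
                group = character()), groups = hap, scope = cl)
            perCluster[[cl]] <- list(groups = hap, library = lib)
            next
        }
        res <- tryCatch({
            r <- suppressWarnings(correlateStrains(catalog, scopeInterval = iv))
            hap <- clusterStrainGroups(r, linkageMethod, cutHeight)
            lib <- if (length(groupNames(hap)) < 2)
                new("SignatureLibrary", sites = data.frame(
                    chrom = character(), pos = integer(),
                    alt = character(), group = character()),
                    groups = hap, scope = cl)
            else selectSignatureSnps(catalog, hap, scopeInterval = iv,
                scope = cl)
            list(groups = hap, library = lib)
        }, error = function(e) NULL)
        perCluster[[cl]] <- res
    }
    unresolved <- names(perCluster)[vapply(perCluster, is.null, logical(1))]
    if (length(unresolved))
        warning("unresolvable MHC clusters (no informative sites): ",
            paste(unresolved, collapse = ", "))
    list(clusters = clusters, perCluster = perCluster)
}

#' Write / read a signature library as TSV plus a JSON manifest
#'
#' The TSV carries one signature site per row (chrom, pos, alt, group,
#' scope); the manifest records group membership and the scope label.
#'
#' @param library a \linkS4class{SignatureLibrary}.
#' @param path output TSV path; the manifest is written next to it with a
#'   \code{.json} extension.
#' @return \code{path}, invisibly.
#' @export
writeSignatureLibrary <- function(library, path) {
    stopifnot(is(library, "SignatureLibrary"))
    df <- signatureSites(library)
    df$scope <- libraryScope(library)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(scope = libraryScope(library),
        groups = groupMembers(libraryGroups(library)),
        n_sites = nrow(df))
    jsonlite::write_json(manifest, sub("\\.tsv$", ".json", paste0(path)),
        auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeSignatureLibrary
#' @export
readSignatureLibrary <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
        colClasses = c(chrom = "character", alt = "character",
            group = "character"))
    manifest <- jsonlite::read_json(sub("\\.tsv$", ".json", paste0(path)),
        simplifyVector = TRUE)
    groups <- strainGroupSet(lapply(manifest$groups, as.character))
    new("SignatureLibrary",
        sites = df[, c("chrom", "pos", "alt", "group")],
        groups = groups, scope = manifest$scope)
}
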