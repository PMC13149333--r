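#' Purity correction of a locus observation
#'
#' Adjusts an observed VAF and copy ratio to the values that would be
#' detected in pure cancer cells, under the standard diploid-normal
#' admixture model: a sample with tumor cell fraction \code{purity} (rho)
#' and tumor ploidy \code{ploidy} (psi) averages
#' \code{D = rho * psi + 2 * (1 - rho)} copies per cell, so the tumor local
#' total copy number is \code{nT = (CR * D - 2 * (1 - rho)) / rho}, the
#' pure copy ratio \code{nT / psi}, and the pure VAF
#' \code{VAF * (rho * nT + 2 * (1 - rho)) / (rho * nT)} (the variant is
#' assumed absent from normal cells), clamped to [0, 1].
#'
#' @param vaf observed variant allele frequency in [0, 1].
#' @param cr observed copy ratio (>= 0, linear scale).
#' @param purity tumor cell fraction rho in (0, 1].
#' @param ploidy tumor ploidy psi (> 0; default 2).
#' @return data.frame with columns \code{nT} (inferred tumor local total
#'   copy number), \code{crPure} and \code{vafPure}. In the
#'   homozygous-deletion regime (nT <= 0) the VAF correction is undefined
#'   and \code{vafPure} is \code{NA}.
#' @export
#' @examples
#' purityCorrect(vaf = 0.25, cr = 1.0, purity = 0.5)  # recovers 0.5 / 1.0
purityCorrect <- function(vaf, cr, purity, ploidy = 2) {
    stopifnot(all(purity > 0 & purity <= 1), all(ploidy > 0))
    D <- purity * ploidy + 2 * (1 - purity)
    nT <- (cr * D - 2 * (1 - purity)) / purity
    crPure <- nT / ploidy
    vafPure <- ifelse(nT > 0,
        clamp(vaf * (purity * nT + 2 * (1 - purity)) / (purity * nT), 0, 1),
        NA_real_)
    data.frame(nT = nT, crPure = crPure, vafPure = vafPure)
}

#' Classify the allelic state of a mutant KRAS locus
#'
#' Applies fixed VAF/CR thresholds to purity-adjusted values: absent
#' (VAF < 0.05), dGD (0.05 <= VAF < 0.4), HET (0.4 <= VAF < 0.61), and for
#' VAF >= 0.61 either LOH (CR < 1.3), gain (1.3 <= CR < 2.8) or amp
#' (CR >= 2.8). The dosage category collapses gain/amp/LOH into iGD
#' (increased mutant gene dosage), keeps HET, and maps dGD to itself.
#'
#' @param vaf,cr purity-adjusted VAF and linear copy ratio (finite, >= 0);
#'   vectorized.
#' @return data.frame with columns \code{state} and \code{dosage}.
#' @export
#' @examples
#' classifyKrasState(c(0.5, 0.7, 0.7, 0.2), c(1.0, 3.0, 1.0, 1.0))
classifyKrasState <- function(vaf, cr) {
    stopifnot(all(is.finite(vaf)), all(is.finite(cr)),
        all(vaf >= 0), all(cr >= 0))
    state <- ifelse(vaf < 0.05, "absent",
        ifelse(vaf < 0.4, "dGD",
        ifelse(vaf < 0.61, "HET",
        ifelse(cr < 1.3, "LOH", ifelse(cr < 2.8, "gain", "amp")))))
    dosage <- ifelse(state %in% c("gain", "amp", "LOH"), "iGD",
        ifelse(state == "HET", "HET",
        ifelse(state == "dGD", "dGD", NA_character_)))
    data.frame(state = state, dosage = dosage)
}

#' Classify the allelic state of CDKN2A
#'
#' Integrates the (maximum) VAF of detected inactivating mutations (0 when
#' none) with the linear copy ratio. Precedence resolves the overlapping
#' printed clauses: HOM first (VAF >= 0.85 or CR <= 0.19), then HET
#' (0 < VAF < 0.85 or 0.19 < CR < 0.87), else WT (VAF = 0 and CR >= 0.87).
#'
#' @param vaf,cr purity-adjusted VAF and linear copy ratio; vectorized.
#' @return Character vector of states (\code{"WT"}, \code{"HET"},
#'   \code{"HOM"}).
#' @export
classifyCdkn2aState <- function(vaf, cr) {
    stopifnot(all(is.finite(vaf)), all(is.finite(cr)),
        all(vaf >= 0), all(cr >= 0))
    ifelse(vaf >= 0.85 | cr <= 0.19, "HOM",
        ifelse((vaf > 0 & vaf < 0.85) | (cr > 0.19 & cr < 0.87), "HET",
        "WT"))
}

#' qPCR-based purity of microdissected tissue
#'
#' For tissues carrying a conditional Lox-Stop-Lox Kras allele, the
#' quantity of non-recombined LSL alleles normalized to the total Kras
#' locus copy quantity reflects the stroma contribution directly: tumor
#' cells have recombined the cassette away, stroma cells are heterozygous
#' for it. The measured LSL/copy ratio is calibrated against a
#' known-heterozygous normal control, giving the stroma copy fraction
#' \code{s} and purity \code{1 - s} (in copy space).
#'
#' @param lslQuantity qPCR quantity of the LSL allele.
#' @param copyQuantity qPCR quantity of the total locus copy assay (> 0).
#' @param calibrationRatio LSL/copy ratio measured in a heterozygous
#'   normal control (> 0).
#' @return List of class \code{"qpcrPurity"}: \code{ratio} (normalized),
#'   \code{stromaFraction}, \code{purity}.
#' @export
qpcrPurity <- function(lslQuantity, copyQuantity, calibrationRatio) {
    if (any(copyQuantity == 0)) stop("copy quantity must be non-zero")
    stopifnot(all(calibrationRatio > 0))
    r <- (lslQuantity / copyQuantity) / calibrationRatio
    s <- clamp(r, 0, 1)
    structure(list(ratio = r, stromaFraction = s, purity = 1 - s),
        class = "qpcrPurity")
}

#' @export
print.qpcrPurity <- function(x, ...) {
    cat(sprintf("stroma copy fraction %.3f -> purity %.3f\n",
        x$stromaFraction, x$purity))
    invisible(x)
}

#' Subtract stroma reads from an observed VAF
#'
#' Inverts the read mixture at an amplicon: with stroma copy fraction
#' \code{s} and stroma mutant-read fraction \code{fMut} (0.5 by default,
#' because heterozygous stroma carrying the non-recombined LSL allele
#' still reads the mutant base at the genomic amplicon), the pure tumor
#' VAF is \code{(VAF - s * fMut) / (1 - s)}, clamped to [0, 1]. Assumes
#' equal per-copy amplification of tumor and stroma alleles.
#'
#' @param vafObs observed VAF.
#' @param s stroma copy fraction in [0, 1).
#' @param fMut mutant-read fraction of stroma reads (default 0.5).
#' @return Purity-adjusted VAF.
#' @export
subtractStromaReads <- function(vafObs, s, fMut = 0.5) {
    stopifnot(all(s >= 0), all(fMut >= 0 & fMut <= 1))
    if (any(s >= 1)) stop("stroma fraction 1: no tumor signal")
    clamp((vafObs - s * fMut) / (1 - s), 0, 1)
}

#' Length-weighted copy ratio of a gene locus
#'
#' The linear copy ratio of a gene is computed as 2 to the power of the
#' overlap-length-weighted mean log2 ratio of the segments covering the
#' gene interval.
#'
#' @param profile a \linkS4class{SegmentProfile}.
#' @param geneInterval \code{GRanges} of length 1.
#' @return Linear copy ratio (NA when no segment overlaps).
#' @export
geneCopyRatio <- function(profile, geneInterval) {
    stopifnot(is(profile, "SegmentProfile"), length(geneInterval) == 1)
    seg <- profileSegments(profile)
    hits <- GenomicRanges::findOverlaps(seg, geneInterval)
    if (!length(hits)) return(NA_real_)
    ov <- GenomicRanges::pintersect(seg[S4Vectors::queryHits(hits)],
        rep(geneInterval, length(hits)))
    w <- GenomicRanges::width(ov)
    l2 <- S4Vectors::mcols(seg)$log2[S4Vectors::queryHits(hits)]
    2^(sum(l2 * w) / sum(w))
}

#' Call KRAS and CDKN2A allele states for a sample table
#'
#' Convenience wrapper: purity-corrects each locus observation and applies
#' the gene-specific classifier. Samples below the purity floor are
#' excluded (allelic-imbalance calls are unreliable at low tumor content).
#'
#' @param observations data.frame with columns \code{sample}, \code{gene}
#'   (\code{"Kras"} or \code{"Cdkn2a"}), \code{vaf}, \code{cr}.
#' @param purity data.frame with columns \code{sample}, \code{purity},
#'   \code{ploidy} (curated purity/ploidy solutions, consumed as input).
#' @param minPurity exclusion floor (default 0.2).
#' @param correct purity-correct before classification (default TRUE; set
#'   FALSE for cell-line data that are already pure).
#' @return data.frame with the corrected values and the per-gene state
#'   call; excluded samples carry \code{state = NA} and
#'   \code{excluded = TRUE}.
#' @export
callAlleleStates <- function(observations, purity, minPurity = 0.2,
                             correct = TRUE) {
    obs <- merge(as.data.frame(observations), as.data.frame(purity),
        by = "sample", all.x = TRUE)
    obs$excluded <- !is.na(obs$purity) & obs$purity < minPurity
    if (correct) {
        pc <- purityCorrect(obs$vaf, obs$cr, pmax(obs$purity, 1e-6),
            obs$ploidy)
        obs$vafPure <- pc$vafPure
        obs$crPure <- pmax(pc$crPure, 0)
    } else {
        obs$vafPure <- obs$vaf
        obs$crPure <- obs$cr
    }
    obs$state <- NA_character_
    idx <- which(!obs$excluded & is.finite(obs$vafPure) &
        is.finite(obs$crPure))
    for (i in idx) {
        obs$state[i] <- if (toupper(obs$gene[i]) == "KRAS")
            classifyKrasState(obs$vafPure[i], obs$crPure[i])$state
        else classifyCdkn2aState(obs$vafPure[i], obs$crPure[i])
    }
    obs
}
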