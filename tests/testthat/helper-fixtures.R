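## Shared fixture builders; everything is generated in code at test time.

## tiny hand-checkable catalog on a 10-site universe
tinyCatalog <- function() {
    sites <- rbind(
        data.frame(chrom = "chr1", pos = 1:6, alt = "A", strain = "s1"),
        data.frame(chrom = "chr1", pos = c(1:3, 7:8), alt = "A", strain = "s2"),
        data.frame(chrom = "chr1", pos = c(9, 10), alt = "A", strain = "s3"))
    strainVariantCatalog(sites)
}

## independent phi-coefficient oracle by direct summation over the union
phiOracle <- function(catalog) {
    sites <- catalogSites(catalog)
    strains <- strainNames(catalog)
    keys <- unique(paste(sites$chrom, sites$pos, sites$alt))
    vecs <- sapply(strains, function(s) {
        k <- paste(sites$chrom, sites$pos, sites$alt)[sites$strain == s]
        as.numeric(keys %in% k)
    })
    n <- length(keys)
    out <- matrix(NA_real_, length(strains), length(strains),
        dimnames = list(strains, strains))
    for (i in seq_along(strains)) for (j in seq_along(strains)) {
        x <- vecs[, i]; y <- vecs[, j]
        sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
        out[i, j] <- sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
    }
    out
}

## two-group catalog with genome-wide and MHC-cluster sites sharing one
## strain layout, for immunophenotyping / MHC tests
twoGroupSim <- function(seed = 3, snpsGenome = 20000, snpsMhc = 1500,
                        groupNames = c("C57BL/6", "129")) {
    simG <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
        snpsPerGroup = snpsGenome, withinGroupSharing = 0.9, seed = seed,
        groupNames = groupNames)
    mhcSites <- if (snpsMhc > 0) {
        simM <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
            snpsPerGroup = snpsMhc, withinGroupSharing = 0.9,
            seed = seed + 1, region = mhcClusterSpec(),
            groupNames = groupNames)
        catalogSites(simM$catalog)
    } else NULL
    sites <- unique(rbind(catalogSites(simG$catalog), mhcSites))
    list(catalog = strainVariantCatalog(sites), groups = simG$groups,
        truth = simG$truth)
}

## donor-line worked-example fixture: 26 somatic protein-altering mutations
## plus 77 129-group germline protein-altering variants (and noise records)
donorLineFixture <- function(seed = 349) {
    sim <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
        snpsPerGroup = 20000, withinGroupSharing = 0.9, seed = seed,
        groupNames = c("C57BL/6", "129"))
    vt <- simulateVariantTable(sim, nSomatic = 26, nSomaticSilent = 10,
        germlineCounts = c("129" = 77, "C57BL/6" = 40),
        nGermlineSilent = 15, depth = 60, seed = seed + 1)
    list(sim = sim, records = vt$records, truth = vt$truth)
}

## run the effective-pTMB pipeline of a fixture for one recipient set
effectiveCountFor <- function(fx, recipientGroups) {
    rec <- filterTmbVariants(fx$records, matchedNormal = FALSE)
    mask <- denseRegionMask(fx$sim$catalog)
    ann <- annotateStrainGermline(rec, fx$sim$catalog, fx$sim$groups,
        lineBackgrounds = c("C57BL/6", "129"), mask = mask)
    effectivePtmb(ann, recipientGroups)
}

## small genome for brute-force interval oracles
toyGenome <- function() c(chrA = 100000, chrB = 80000)
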