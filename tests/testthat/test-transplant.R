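test_that("exome collapse merges protein-coding exons only", {
    annot <- data.frame(
        chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
        start = c(101, 151, 501, 11, 1000),
        end   = c(200, 250, 600, 110, 1500),
        type = "exon",
        biotype = c("protein_coding", "protein_coding", "protein_coding",
            "protein_coding", "lincRNA"))
    ex <- collapseExome(annot)
    ## [101,200] + [151,250] merge to [101,250]: 150 bp; two disjoint
    ## protein-coding exons add their own lengths; lincRNA is dropped
    expect_equal(sum(GenomicRanges::width(ex$intervals)), 150 + 100 + 100)
    expect_equal(length(ex$intervals), 3)
    expect_error(collapseExome(annot[0, ]), "empty")
})

test_that("exome collapse equals a sweep-line union oracle", {
    set.seed(1234)
    for (rep in 1:200) {
        n <- sample(1:20, 1)
        start <- sample(1:5000, n, replace = TRUE)
        width <- sample(1:500, n, replace = TRUE)
        annot <- data.frame(chrom = "chrA", start = start,
            end = start + width - 1, type = "exon",
            biotype = "protein_coding")
        ex <- collapseExome(annot)
        ## sweep-line oracle: mark covered bases
        cov <- logical(6000)
        for (i in seq_len(n)) cov[start[i]:(start[i] + width[i] - 1)] <- TRUE
        expect_equal(sum(GenomicRanges::width(ex$intervals)), sum(cov))
        expect_true(GenomicRanges::isDisjoint(ex$intervals))
    }
})

test_that("burden filters apply the printed criteria inclusively", {
    mk <- function(tumorDepth = 50, normalDepth = 50, tumorAlt = 6,
                   normalAlt = 0, vaf = tumorAlt / tumorDepth)
        data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "T",
            tumorDepth = tumorDepth, normalDepth = normalDepth,
            tumorAlt = tumorAlt, normalAlt = normalAlt, vaf = vaf)
    expect_equal(nrow(filterTmbVariants(mk())), 1)
    expect_equal(nrow(filterTmbVariants(mk(tumorDepth = 9))), 0)
    expect_equal(nrow(filterTmbVariants(mk(tumorDepth = 10))), 1)
    expect_equal(nrow(filterTmbVariants(mk(vaf = 0.09))), 0)
    expect_equal(nrow(filterTmbVariants(mk(vaf = 0.10))), 1)
    expect_equal(nrow(filterTmbVariants(mk(tumorAlt = 2, vaf = 0.2))), 0)
    expect_equal(nrow(filterTmbVariants(mk(tumorAlt = 3, vaf = 0.2))), 1)
    expect_equal(nrow(filterTmbVariants(mk(normalAlt = 1))), 0)
    ## tumor-only mode ignores the normal-side criteria
    expect_equal(nrow(filterTmbVariants(mk(normalAlt = 1),
        matchedNormal = FALSE)), 1)
    expect_equal(nrow(filterTmbVariants(mk(normalDepth = 0),
        matchedNormal = FALSE)), 1)
})

test_that("burden filtering is idempotent", {
    fx <- donorLineFixture()
    once <- filterTmbVariants(fx$records, matchedNormal = FALSE)
    twice <- filterTmbVariants(once, matchedNormal = FALSE)
    expect_identical(once, twice)
})

test_that("TMB divides exonic mutation counts by exome megabases", {
    exome <- collapseExome(data.frame(chrom = "chr1", start = 1,
        end = 25e6, type = "exon", biotype = "protein_coding"))
    recs <- data.frame(chrom = "chr1", pos = seq(1, 25e6, length.out = 50))
    expect_equal(computeTmb(recs, exome), 2.0)
    expect_equal(computeTmb(recs[0, ], exome), 0.0)
    ## mutations outside the exome are excluded
    out <- data.frame(chrom = "chr2", pos = 100)
    expect_equal(computeTmb(rbind(recs, out), exome), 2.0)
})

test_that("protein-altering means MODERATE or HIGH impact", {
    expect_true(isProteinAltering("HIGH"))
    expect_true(isProteinAltering("MODERATE"))
    expect_false(isProteinAltering("LOW"))
    expect_false(isProteinAltering("MODIFIER"))
    expect_warning(res <- isProteinAltering(c("HIGH", NA)), "impact")
    expect_true(is.na(res[2]))
})

test_that("germline strain tagging requires catalog, background and mask", {
    sim <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
        snpsPerGroup = 300, seed = 17, groupNames = c("C57BL/6", "129"))
    site129 <- catalogSites(sim$catalog)
    site129 <- site129[site129$strain == "129_S1", ][1, ]
    recs <- data.frame(
        chrom = c(site129$chrom, site129$chrom, "chr3"),
        pos = c(site129$pos, site129$pos + 1, 500),
        ref = "N",
        alt = c(site129$alt, "A", "C"),
        tumorDepth = 60, normalDepth = 60,
        tumorAlt = c(30, 30, 30), normalAlt = c(28, 28, 0),
        impact = "MODERATE")
    ann <- annotateStrainGermline(recs, sim$catalog, sim$groups,
        lineBackgrounds = c("C57BL/6", "129"))
    expect_equal(ann$strainGroup[1], "129")       # catalog + background
    expect_true(is.na(ann$strainGroup[2]))        # absent from catalog
    expect_equal(ann$origin[3], "somatic")        # tumor-only record

    ## background mismatch: line does not carry 129
    ann2 <- annotateStrainGermline(recs, sim$catalog, sim$groups,
        lineBackgrounds = "C57BL/6")
    expect_true(is.na(ann2$strainGroup[1]))

    ## inside a dense-region mask the tag is withheld
    mask <- GenomicRanges::GRanges(site129$chrom,
        IRanges::IRanges(site129$pos - 10, site129$pos + 10))
    ann3 <- annotateStrainGermline(recs, sim$catalog, sim$groups,
        lineBackgrounds = c("C57BL/6", "129"), mask = mask)
    expect_true(is.na(ann3$strainGroup[1]))
})

test_that("dense-region mask flags windows above the median density", {
    dense <- data.frame(chrom = "chr1", pos = 1:80, alt = "A",
        strain = "X")  # 80 sites in one 10 kb window
    sparse <- data.frame(chrom = "chr2", pos = (1:40) * 1e6, alt = "A",
        strain = "X")
    cat <- strainVariantCatalog(rbind(dense, sparse))
    mask <- denseRegionMask(cat, window = 1e4, factor = 5)
    expect_true(IRanges::overlapsAny(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 50)), mask))
    expect_false(any(suppressWarnings(IRanges::overlapsAny(
        GenomicRanges::GRanges("chr2", IRanges::IRanges(1e6, 1e6)), mask))))
})

test_that("effective pTMB adds only recipient-mismatched germline variants", {
    fx <- donorLineFixture()
    ## additivity: one extra mismatched germline variant adds exactly 1
    r1 <- effectiveCountFor(fx, c("C57BL/6", "129"))
    r2 <- effectiveCountFor(fx, "C57BL/6")
    expect_equal(r2$effectiveCount,
        r1$effectiveCount + r2$germlineMismatchedCount)
    ## scenario ordering: germline sets are nested
    expect_gte(r2$effectiveCount, r1$effectiveCount)

    ## zero germline -> effective equals somatic for every recipient
    sim <- fx$sim
    vt <- simulateVariantTable(sim, nSomatic = 12, germlineCounts = c(),
        seed = 5)
    ann <- annotateStrainGermline(filterTmbVariants(vt$records,
        matchedNormal = FALSE), sim$catalog, sim$groups,
        lineBackgrounds = c("C57BL/6", "129"))
    for (rec in list("C57BL/6", "129", c("C57BL/6", "129")))
        expect_equal(effectivePtmb(ann, rec)$effectiveCount, 12)
})

test_that("adding one germline variant shifts the count by its match", {
    sim <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
        snpsPerGroup = 500, seed = 23, groupNames = c("B6", "FVB"))
    vt <- simulateVariantTable(sim, nSomatic = 5,
        germlineCounts = c(FVB = 10, B6 = 4), seed = 11)
    ann <- annotateStrainGermline(filterTmbVariants(vt$records,
        matchedNormal = FALSE), sim$catalog, sim$groups,
        lineBackgrounds = c("B6", "FVB"))
    resB6 <- effectivePtmb(ann, "B6")
    expect_equal(resB6$somaticCount, 5)
    expect_equal(resB6$germlineMismatchedCount, 10)   # FVB-tagged mismatch
    resF1 <- effectivePtmb(ann, c("B6", "FVB"))
    expect_equal(resF1$effectiveCount, 5)
})

test_that("recipient recommendation follows the background-count rules", {
    mkComp <- function(groups, percents) {
        df <- data.frame(group = groups, length = percents * 1e7,
            percent = percents)
        class(df) <- c("strainComposition", "data.frame")
        df
    }
    ## two backgrounds -> prioritized, F1 hybrid among candidates
    r1 <- recommendRecipients(mkComp(c("B6", "129"), c(96, 4)))
    expect_equal(r1$category, "prioritized")
    expect_true("129;B6-F1" %in% r1$candidates$recipient)
    ## third background at 8% -> feasible
    r2 <- recommendRecipients(mkComp(c("A", "B", "C"), c(60, 32, 8)))
    expect_equal(r2$category, "feasible")
    ## three dominant backgrounds -> not recommended
    r3 <- recommendRecipients(mkComp(c("A", "B", "C"), c(50, 30, 20)))
    expect_equal(r3$category, "not recommended")
    ## third background under 1% still prioritized
    r4 <- recommendRecipients(mkComp(c("A", "B", "C"), c(70, 29.5, 0.5)))
    expect_equal(r4$category, "prioritized")
    ## male lines carry a male-recipient constraint
    sexM <- structure(list(ratio = 0.08, call = "male"), class = "sexCall")
    r5 <- recommendRecipients(mkComp("B6", 100), sex = sexM)
    expect_match(r5$sexConstraint, "male")
})
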