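## small two-chromosome genome so per-base oracles stay cheap
toyProfile <- function(df, excluded = character()) {
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$log2 <- df$log2
    methods::new("SegmentProfile", segments = GenomicRanges::sort(gr),
        genome = "toy", excluded = excluded)
}

test_that("CNV load is the altered fraction of the autosomal genome", {
    lens <- mouseChromLengths(autosomesOnly = TRUE)
    flat <- toyProfile(data.frame(chrom = names(lens), start = 1,
        end = as.numeric(lens), log2 = 0))
    flat@genome <- "mm10"
    expect_equal(cnvLoad(flat), 0)

    ## segments covering exactly 10% of the autosomes at log2 0.5
    ## (split over two chromosomes)
    span <- round(0.05 * sum(as.numeric(lens)))
    prof <- toyProfile(data.frame(
        chrom = c("chr1", "chr2", "chr3"),
        start = c(1, 1, 1), end = c(span, span, 1000),
        log2 = c(0.5, -0.5, 0.1)))
    prof@genome <- "mm10"
    expect_true(span <= lens["chr2"])
    expect_equal(cnvLoad(prof), 2 * span / sum(as.numeric(lens)) * 100)
    expect_equal(cnvLoad(prof), 10.0, tolerance = 1e-6)

    ## |log2| must exceed the cutoff strictly
    at <- toyProfile(data.frame(chrom = "chr1", start = 1, end = 1e6,
        log2 = 0.2))
    at@genome <- "mm10"
    expect_equal(cnvLoad(at), 0)
})

test_that("CNV load equals a direct-summation oracle and splits freely", {
    set.seed(5)
    lens <- c(chr1 = 1e6, chr2 = 8e5)
    segs <- do.call(rbind, lapply(names(lens), function(ch) {
        bounds <- sort(sample(2:(lens[ch] - 1), 9))
        data.frame(chrom = ch, start = c(1, bounds + 1),
            end = c(bounds, lens[ch]),
            log2 = round(runif(10, -1, 1), 2))
    }))
    prof <- toyProfile(segs)
    got <- cnvLoad(prof, autosomeLengths = lens)
    oracle <- sum((segs$end - segs$start + 1)[abs(segs$log2) > 0.2]) /
        sum(lens) * 100
    expect_equal(got, oracle, tolerance = 1e-12)

    ## splitting a segment in half changes nothing
    first <- segs[1, ]
    mid <- floor((first$start + first$end) / 2)
    split <- rbind(
        data.frame(chrom = first$chrom, start = first$start, end = mid,
            log2 = first$log2),
        data.frame(chrom = first$chrom, start = mid + 1, end = first$end,
            log2 = first$log2),
        segs[-1, ])
    expect_equal(cnvLoad(toyProfile(split), autosomeLengths = lens), got)

    ## segments beyond chromosome ends are clipped with a warning
    long <- toyProfile(data.frame(chrom = "chr1", start = 1, end = 2e6,
        log2 = 0.5))
    expect_warning(cl <- cnvLoad(long, autosomeLengths = lens), "clipped")
    expect_equal(cl, lens[["chr1"]] / sum(lens) * 100)
})

test_that("wGII averages per-chromosome aberrant fractions", {
    lens <- mouseChromLengths(autosomesOnly = TRUE)
    flat <- toyProfile(data.frame(chrom = names(lens), start = 1,
        end = as.numeric(lens), log2 = 0))
    flat@genome <- "mm10"
    expect_equal(wgii(flat), 0)

    ## one of 19 autosomes fully aberrant
    one <- data.frame(chrom = names(lens), start = 1,
        end = as.numeric(lens), log2 = 0)
    one$log2[one$chrom == "chr7"] <- 1
    p1 <- toyProfile(one); p1@genome <- "mm10"
    expect_equal(wgii(p1), 1 / 19, tolerance = 1e-12)

    ## hand-computed toy: chr1 half aberrant, chr2 quarter aberrant
    toy <- toyProfile(data.frame(
        chrom = c("chr1", "chr1", "chr2", "chr2"),
        start = c(1, 5e5 + 1, 1, 2e5 + 1),
        end = c(5e5, 1e6, 2e5, 8e5),
        log2 = c(0.6, 0, 0.6, 0)))
    expect_equal(wgii(toy, autosomes = c("chr1", "chr2")),
        mean(c(0.5, 0.25)), tolerance = 1e-12)

    ## autosomes without segments are excluded with a warning
    expect_warning(w <- wgii(p1, autosomes = c(names(lens), "chr99")),
        "chr99")
    expect_equal(w, 1 / 19, tolerance = 1e-12)
})

test_that("binning takes overlap-weighted means and leaves gaps missing", {
    genome <- c(chr1 = 3e6)
    ## bin fully inside one segment
    p <- toyProfile(data.frame(chrom = "chr1", start = 1, end = 3e6,
        log2 = 0.4))
    b <- binProfile(p, binSize = 1e6, genome = genome)
    expect_equal(profileBins(b)$log2, rep(0.4, 3))

    ## bin split 50/50 between log2 0 and log2 1
    p2 <- toyProfile(data.frame(chrom = "chr1",
        start = c(1, 5e5 + 1), end = c(5e5, 1e6), log2 = c(0, 1)))
    b2 <- binProfile(p2, binSize = 1e6, genome = c(chr1 = 1e6))
    expect_equal(profileBins(b2)$log2, 0.5)

    ## uncovered bins are NA
    p3 <- toyProfile(data.frame(chrom = "chr1", start = 1, end = 1e6,
        log2 = 0.3))
    b3 <- binProfile(p3, binSize = 1e6, genome = genome)
    expect_equal(is.na(profileBins(b3)$log2), c(FALSE, TRUE, TRUE))

    ## random segmentation vs brute-force per-base mean
    set.seed(31)
    lens <- c(chrA = 50000)
    bounds <- sort(sample(2:49999, 7))
    segs <- data.frame(chrom = "chrA", start = c(1, bounds + 1),
        end = c(bounds, 50000), log2 = round(runif(8, -1, 1), 3))
    bp <- binProfile(toyProfile(segs), binSize = 1e4, genome = lens)
    base <- rep(NA_real_, 50000)
    for (i in seq_len(nrow(segs)))
        base[segs$start[i]:segs$end[i]] <- segs$log2[i]
    for (k in 1:5) {
        idx <- ((k - 1) * 1e4 + 1):(k * 1e4)
        expect_equal(profileBins(bp)$log2[k], mean(base[idx]),
            tolerance = 1e-9)
    }

    ## length-weighted genome mean is conserved over covered bases
    covered <- sum(segs$end - segs$start + 1)
    expect_equal(mean(profileBins(bp)$log2) * 1,
        sum(segs$log2 * (segs$end - segs$start + 1)) / covered,
        tolerance = 1e-9)
})

test_that("smoothing removes spikes and recentres positive medians", {
    genome <- c(chr1 = 1e7)
    mkBinned <- function(vals, excluded = character())
        methods::new("BinnedProfile", bins = data.frame(chrom = "chr1",
            start = (seq_along(vals) - 1) * 1e6 + 1,
            end = seq_along(vals) * 1e6, log2 = vals),
            binSize = 1e6, excluded = excluded)

    ## constant positive profile recentres to 0
    sm <- smoothRecenter(mkBinned(rep(0.3, 10)))
    expect_equal(profileBins(sm)$log2, rep(0, 10))
    ## constant non-positive profile is unchanged
    sm0 <- smoothRecenter(mkBinned(rep(-0.1, 10)))
    expect_equal(profileBins(sm0)$log2, rep(-0.1, 10))

    ## a single-bin spike in a flat background is removed
    vals <- rep(0, 10); vals[5] <- 2
    expect_equal(profileBins(smoothRecenter(mkBinned(vals)))$log2,
        rep(0, 10))

    ## matches a direct running-median oracle (edge-truncated, window 5)
    set.seed(77)
    noisy <- round(rnorm(30, 0, 0.5), 3)
    got <- profileBins(smoothRecenter(mkBinned(noisy)))$log2
    oracle <- vapply(seq_along(noisy), function(i)
        median(noisy[max(1, i - 2):min(30, i + 2)]), numeric(1))
    med <- median(oracle)
    if (med > 0) oracle <- oracle - med
    expect_equal(got, oracle)

    ## excluded chromosomes keep raw values
    exBins <- methods::new("BinnedProfile", bins = rbind(
        data.frame(chrom = "chr1", start = (0:9) * 1e6 + 1,
            end = (1:10) * 1e6, log2 = rep(c(0, 1), 5)),
        data.frame(chrom = "chr2", start = (0:9) * 1e6 + 1,
            end = (1:10) * 1e6, log2 = 0)),
        binSize = 1e6, excluded = "chr1")
    smEx <- smoothRecenter(exBins)
    raw <- profileBins(smEx)$log2[profileBins(smEx)$chrom == "chr1"]
    expect_equal(raw, rep(c(0, 1), 5))
    expect_error(smoothRecenter(exBins, window = 4), "odd")
})

test_that("stability distance is a pseudometric on recentred profiles", {
    sims <- simulateSegments(events = data.frame(chrom = "chr3",
        spanFraction = 0.4, log2 = 0.8), noiseSd = 0, offset = 0, seed = 9)
    ba <- smoothRecenter(binProfile(sims$a))
    bb <- smoothRecenter(binProfile(sims$b))
    d <- stabilityDistance(ba, bb)
    expect_equal(d$genome, 0)

    ## a global offset vanishes after recentring when the base median is 0
    simOff <- simulateSegments(events = data.frame(chrom = "chr3",
        spanFraction = 0.4, log2 = 0.8), noiseSd = 0, offset = 0.3,
        seed = 9)
    dOff <- stabilityDistance(smoothRecenter(binProfile(simOff$a)),
        smoothRecenter(binProfile(simOff$b)))
    expect_equal(dOff$genome, 0, tolerance = 1e-12)

    ## toy pair vs brute force, symmetry, triangle inequality
    mkBinned <- function(vals) methods::new("BinnedProfile",
        bins = data.frame(chrom = "chr1", start = (seq_along(vals) - 1) *
            1e6 + 1, end = seq_along(vals) * 1e6, log2 = vals),
        binSize = 1e6, excluded = character())
    x <- c(0, 0.5, -0.2, NA, 1)
    y <- c(0.1, 0.4, 0.3, 0.2, NA)
    z <- c(0, 0, 0, 0, 0)
    dxy <- stabilityDistance(mkBinned(x), mkBinned(y))
    shared <- !is.na(x) & !is.na(y)
    expect_equal(dxy$genome, mean(abs(x - y)[shared]))
    expect_equal(dxy$genome,
        stabilityDistance(mkBinned(y), mkBinned(x))$genome)
    dxz <- stabilityDistance(mkBinned(x), mkBinned(z))$genome
    dzy <- stabilityDistance(mkBinned(z), mkBinned(y))$genome
    expect_lte(stabilityDistance(mkBinned(x[1:3]), mkBinned(y[1:3]))$genome,
        stabilityDistance(mkBinned(x[1:3]), mkBinned(z[1:3]))$genome +
        stabilityDistance(mkBinned(z[1:3]), mkBinned(y[1:3]))$genome)

    ## different bin grids are rejected
    bigBin <- methods::new("BinnedProfile", bins = data.frame(
        chrom = "chr1", start = c(1, 2e6 + 1), end = c(2e6, 4e6),
        log2 = c(0, 0)), binSize = 2e6, excluded = character())
    expect_error(stabilityDistance(mkBinned(x), bigBin), "grid")
})
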