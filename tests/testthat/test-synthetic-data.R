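test_that("generation is reproducible: same seed, identical output", {
    gn <- SyntheticGenome(c(chr1 = 2e6, chr2 = 1e6))
    p1 <- simulatePromoters(300, gn, seed = 5)
    p2 <- simulatePromoters(300, gn, seed = 5)
    expect_identical(promoterTss(p1), promoterTss(p2))
    expect_identical(as.character(GenomicRanges::strand(p1)),
                     as.character(GenomicRanges::strand(p2)))
    em <- EffectModel(seed = 6)
    f1 <- simulateFragments(p1, em, 20000, 7000)
    f2 <- simulateFragments(p2, em, 20000, 7000)
    expect_identical(GenomicRanges::start(fragments(f1)),
                     GenomicRanges::start(fragments(f2)))
    e1 <- simulateExpression(p1, seed = 7)
    e2 <- simulateExpression(p1, seed = 7)
    expect_identical(e1, e2)
    t1 <- simulateTorsionTrack(p1, 4, seed = 8)
    t2 <- simulateTorsionTrack(p1, 4, seed = 8)
    expect_identical(trackAsVectors(t1), trackAsVectors(t2))
    # and a different seed actually changes the draw
    expect_false(identical(promoterTss(p1),
                           promoterTss(simulatePromoters(300, gn, seed = 9))))
})

test_that("a fully divergent 2-promoter table is forced head-to-head", {
    gn <- SyntheticGenome(c(chr1 = 10000))
    pr <- simulatePromoters(2, gn,
                            spacingLaw = list(dist = "fixed", gap = 500),
                            divergentFraction = 1, seed = 7)
    expect_equal(diff(promoterTss(pr)), 500, ignore_attr = TRUE)
    expect_equal(as.character(GenomicRanges::strand(pr)), c("-", "+"))
    ann <- annotateSpacing(pr)
    expect_equal(ann$orientation, c("divergent", "divergent"))
    expect_equal(ann$distance, c(500, 500))
})

test_that("promoter counts, ID uniqueness and over-full genomes", {
    gn <- SyntheticGenome(c(chr1 = 4e7))
    pr <- simulatePromoters(16972, gn, seed = 1)
    expect_length(pr, 16972)
    expect_false(anyDuplicated(S4Vectors::mcols(pr)$id) > 0)
    expect_error(simulatePromoters(1000, SyntheticGenome(c(chr1 = 5000)),
                                   seed = 1),
                 "too short")
})

test_that("a bimodal spacing law produces a bimodal gap histogram", {
    gn <- SyntheticGenome(c(chr1 = 8e6))
    pr <- simulatePromoters(1000, gn,
        spacingLaw = list(dist = "mixture", modes = c(300, 10000),
                          weights = c(0.5, 0.5), sdlog = 0.2),
        seed = 2)
    gaps <- diff(sort(promoterTss(pr)))
    nearLow <- mean(gaps > 150 & gaps < 600)
    nearHigh <- mean(gaps > 5000 & gaps < 20000)
    expect_gt(nearLow, 0.35)
    expect_gt(nearHigh, 0.35)
    expect_gt(nearLow + nearHigh, 0.9)
    expect_lt(mean(gaps > 1000 & gaps < 4000), 0.05)
})

test_that("null effect model leaves divergent and tandem exchangeable", {
    gn <- SyntheticGenome(c(chr1 = 4e6))
    pr <- simulatePromoters(500, gn, seed = 21)
    em <- EffectModel(divergentCloseBoost = 1, seed = 22)
    fs <- simulateFragments(pr, em, 40000, 10000)
    s <- regionSum(calibrateSpike(fragmentPileup(fs), spikeScaleFactor(fs)),
                   pr)
    ann <- annotateSpacing(pr)
    div <- ann$promoter_id[ann$orientation == "divergent"]
    tan <- ann$promoter_id[ann$orientation == "tandem"]
    expect_gt(wilcox.test(s[div], s[tan])$p.value, 0.01)
})

test_that("planted boosts are recovered within three standard errors", {
    gn <- SyntheticGenome(c(chr1 = 4e6))
    pr <- simulatePromoters(500, gn, seed = 31)
    ann <- annotateSpacing(pr)
    closeDiv <- ann$promoter_id[!is.na(ann$distance) & ann$distance < 1000 &
                                ann$orientation == "divergent"]
    far <- ann$promoter_id[!is.na(ann$distance) & ann$distance >= 1000]
    for (b in c(1, 2, 4)) {
        em <- EffectModel(divergentCloseBoost = b, distanceCutoff = 1000,
                          seed = 32 + b)
        fs <- simulateFragments(pr, em, 50000, 10000)
        s <- regionSum(fragmentPileup(fs), pr)
        mC <- mean(s[closeDiv]); mF <- mean(s[far])
        ratio <- mC / mF
        se <- ratio * sqrt((sd(s[closeDiv]) / sqrt(length(closeDiv)) / mC)^2 +
                           (sd(s[far]) / sqrt(length(far)) / mF)^2)
        expect_lt(abs(ratio - b), 3 * se)
    }
})

test_that("spike counts are conserved verbatim and drive the factor", {
    gn <- SyntheticGenome(c(chr1 = 1e6))
    pr <- simulatePromoters(50, gn, seed = 41)
    fs <- simulateFragments(pr, EffectModel(seed = 42), 5000, 5000)
    expect_identical(spikeCount(fs), 5000)
    expect_equal(spikeScaleFactor(fs), 2)
    expect_error(simulateFragments(pr[0], EffectModel(seed = 1), 10, 10),
                 "empty promoter")
})

test_that("expression generator hits group medians and degenerate cases", {
    gn <- SyntheticGenome(c(chr1 = 1.5e7))
    pr <- simulatePromoters(2000, gn, seed = 51)
    ann <- annotateSpacing(pr)
    ex <- simulateExpression(pr, divergentMedian = 210.3,
                             tandemMedian = 34.5, dispersion = 1, seed = 52)
    v <- setNames(ex$value, ex$promoter_id)
    mdDiv <- median(v[ann$promoter_id[ann$orientation == "divergent"]])
    mdTan <- median(v[ann$promoter_id[ann$orientation == "tandem"]])
    expect_lt(abs(mdDiv - 210.3) / 210.3, 0.1)
    expect_lt(abs(mdTan - 34.5) / 34.5, 0.1)
    # dispersion 0: exact group medians
    ex0 <- simulateExpression(pr, 210.3, 34.5, dispersion = 0, seed = 53)
    v0 <- setNames(ex0$value, ex0$promoter_id)
    expect_true(all(v0[ann$promoter_id[ann$orientation == "divergent"]] ==
                    210.3))
    # equal medians: orientation groups exchangeable
    exE <- simulateExpression(pr, 50, 50, dispersion = 1, seed = 54)
    vE <- setNames(exE$value, exE$promoter_id)
    expect_gt(wilcox.test(
        vE[ann$promoter_id[ann$orientation == "divergent"]],
        vE[ann$promoter_id[ann$orientation == "tandem"]])$p.value, 0.01)
    expect_error(simulateExpression(pr, -1, 10), "nonnegative")
})

test_that("torsion track plants upstream enrichment at close promoters", {
    gn <- SyntheticGenome(c(chr1 = 8e6))
    pr <- simulatePromoters(1000, gn, seed = 61)
    ann <- annotateSpacing(pr)
    d <- setNames(ann$distance, ann$promoter_id)
    # enrichment 1: upstream sums uncorrelated with distance among promoters
    # whose upstream windows cannot overlap a neighbor's read cloud
    t0 <- simulateTorsionTrack(pr, closePairEnrichment = 1, seed = 62)
    s0 <- upstreamSum(t0, pr)
    ok <- names(d)[!is.na(d)]
    sep <- ok[d[ok] > 400]
    expect_gt(cor.test(s0[sep], d[sep], method = "spearman",
                       exact = FALSE)$p.value, 0.01)
    # enrichment 4 below 1 kb: decile mean curve decreases with distance
    t4 <- simulateTorsionTrack(pr, closePairEnrichment = 4, seed = 63)
    s4 <- upstreamSum(t4, pr)
    cv <- movingMedianCurve(s4, d, decileWindow(length(ok)),
                            statistic = "mean")
    third <- floor(nrow(cv) / 3)
    expect_gt(mean(cv$median_signal[(nrow(cv) - third):nrow(cv)]),
              2 * mean(cv$median_signal[1:third]))
    # a value 64.7 SDs above the track's mean is flagged by the 64-SD filter
    m <- mean(s4); sdev <- sd(s4)
    s4[["injected"]] <- m + 64.7 * sdev
    res <- filterOutliers(s4, thresholdSds = 64, center = m, scale = sdev)
    expect_identical(res$report$promoter_id, "injected")
    expect_error(simulateTorsionTrack(pr, 0.5, seed = 1), ">= 1")
})
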