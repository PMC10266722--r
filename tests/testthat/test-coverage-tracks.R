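test_that("spike scale factor is the spike constant over the spike count", {
    expect_equal(spikeScaleFactor(10000), 1)
    expect_equal(spikeScaleFactor(5000), 2)
    expect_equal(spikeScaleFactor(4000, spikeConstant = 8000), 2)
    expect_error(spikeScaleFactor(0), "calibration impossible")
    gn <- SyntheticGenome(c(chr1 = 1000))
    fs <- FragmentSet(data.frame(chrom = "chr1", start = 0, end = 10),
                      spikeCount = 0, sampleId = "bad_sample", genome = gn)
    expect_error(spikeScaleFactor(fs), "bad_sample")
})

test_that("pileup counts fragment membership per base", {
    gn <- SyntheticGenome(c(chr1 = 20))
    fs <- FragmentSet(data.frame(chrom = "chr1", start = 10, end = 13),
                      spikeCount = 1, genome = gn)
    v <- trackAsVectors(fragmentPileup(fs))$chr1
    expect_equal(v, c(rep(0, 10), 1, 1, 1, rep(0, 7)))

    fs2 <- FragmentSet(data.frame(chrom = "chr1", start = c(0, 3),
                                  end = c(5, 8)),
                       spikeCount = 1, genome = gn)
    v2 <- trackAsVectors(fragmentPileup(fs2))$chr1
    expect_equal(v2[4:5], c(2, 2))
    expect_equal(v2, c(1, 1, 1, 2, 2, 1, 1, 1, rep(0, 12)))
})

test_that("pileup matches the per-base brute-force count and conserves mass", {
    set.seed(42)
    for (rep in 1:20) {
        cl <- randomGenomeDf(nChrom = sample(1:3, 1), maxLen = 3000)
        frags <- randomFragmentsDf(cl, n = sample(20:150, 1))
        fs <- FragmentSet(frags, spikeCount = 1,
                          genome = SyntheticGenome(cl))
        got <- trackAsVectors(fragmentPileup(fs))
        want <- bruteForcePileup(frags, cl)
        expect_equal(got[names(cl)], want[names(cl)])
        expect_equal(sum(unlist(got)), sum(frags$end - frags$start))
    }
})

test_that("off-chromosome fragments are rejected naming the record", {
    gn <- SyntheticGenome(c(chr1 = 100))
    expect_error(
        FragmentSet(data.frame(chrom = "chr1", start = 90, end = 120),
                    spikeCount = 1, genome = gn),
        "record 1")
})

test_that("spike calibration scales values and is linear", {
    gn <- SyntheticGenome(c(chr1 = 500))
    fs <- FragmentSet(data.frame(chrom = "chr1", start = c(0, 100),
                                 end = c(50, 400)),
                      spikeCount = 10000, genome = gn)
    raw <- fragmentPileup(fs)
    expect_equal(trackAsVectors(calibrateSpike(raw, 1)), trackAsVectors(raw))
    expect_equal(unlist(trackAsVectors(calibrateSpike(raw, 2))),
                 2 * unlist(trackAsVectors(raw)))
    # equal pileups, spike counts 10,000 vs 20,000 -> calibrated ratio 2:1
    a <- calibrateSpike(raw, spikeScaleFactor(10000))
    b <- calibrateSpike(raw, spikeScaleFactor(20000))
    expect_equal(unlist(trackAsVectors(a)), 2 * unlist(trackAsVectors(b)))
    expect_equal(scaleUsed(a), 1)
    expect_error(calibrateSpike(a, 2), "raw track")
})

test_that("normcount calibration gives 1 under uniform coverage", {
    v <- vectorsAsTrack(list(chr1 = rep(3, 1000)))
    nc <- calibrateNormcount(v)
    expect_equal(unique(unlist(trackAsVectors(nc))), 1)
    expect_equal(calibration(nc), "normcount")
})

test_that("normcount calibration: half-covered genome, total, idempotence", {
    v <- vectorsAsTrack(list(chr1 = c(rep(4, 500), rep(0, 500))))
    nc <- trackAsVectors(calibrateNormcount(v))$chr1
    expect_equal(nc, c(rep(2, 500), rep(0, 500)))

    set.seed(7)
    rnd <- vectorsAsTrack(list(chr1 = runif(800, 0, 3),
                               chr2 = runif(200, 0, 3)))
    out <- calibrateNormcount(rnd, referenceLength = 12345)
    expect_equal(sum(unlist(trackAsVectors(out))), 12345)
    twice <- calibrateNormcount(out)
    expect_equal(trackAsVectors(twice), trackAsVectors(calibrateNormcount(rnd)))
    zero <- vectorsAsTrack(list(chr1 = rep(0, 10)))
    expect_error(calibrateNormcount(zero), "all-zero")
})

test_that("bedGraph round-trips are value-exact and runs are merged", {
    set.seed(11)
    vecs <- list(chr1 = rep(round(runif(40), 3), each = 25),
                 chr2 = c(rep(0, 100), runif(300), rep(0, 100)))
    tr <- vectorsAsTrack(vecs, calibration = "spike", scaleUsed = 2)
    path <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraph(tr, path)
    back <- readBedGraph(path, SyntheticGenome(lengths(vecs)),
                         calibration = "spike", scaleUsed = 2)
    expect_equal(trackAsVectors(back), lapply(vecs, as.numeric))
    # merged equal-valued runs: line count is below the base count
    expect_lt(length(readLines(path)), sum(lengths(vecs)))
})

test_that("bedGraph reading agrees with rtracklayer on well-formed files", {
    set.seed(13)
    vecs <- list(chr1 = sample(0:4, 500, replace = TRUE))
    path <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraph(vectorsAsTrack(vecs), path)
    gr <- rtracklayer::import(path, format = "bedGraph")
    ref <- numeric(500)
    for (i in seq_along(gr))
        ref[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
            gr$score[i]
    got <- trackAsVectors(readBedGraph(path,
        SyntheticGenome(c(chr1 = 500))))$chr1
    expect_equal(got, ref)
})

test_that("malformed, unsorted or overlapping bedGraph lines are rejected", {
    path <- withr::local_tempfile(fileext = ".bedGraph")
    writeLines(c("chr1\t0\t10\t1.5", "chr1\t10\t20"), path)
    expect_error(readBedGraph(path), "line 2")
    writeLines(c("chr1\t50\t60\t1", "chr1\t0\t10\t2"), path)
    expect_error(readBedGraph(path), "unsorted.*line 2")
    writeLines(c("chr1\t0\t10\t1", "chr1\t5\t20\t2"), path)
    expect_error(readBedGraph(path), "overlapping.*line 2")
})
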