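# Coverage tracks: fragment pileup and the two calibration conventions.
#
# "spike" calibration multiplies raw pileup by spikeConstant / spike fragment
# count (default constant 10,000), making signal comparable across samples
# profiled with the same spike-in. "normcount" calibration rescales the
# per-base fraction of total counts by the reference length, so that a
# uniformly distributed library would read exactly 1 at every position.

#' Spike-in scaling factor
#'
#' @param spikeCount fragments mapped to the spike genome, or a
#'   [FragmentSet-class].
#' @param spikeConstant numerator of the scaling factor; 10,000 by default.
#' @return `spikeConstant / spikeCount`.
#' @examples
#' spikeScaleFactor(5000) # 2
#' @export
spikeScaleFactor <- function(spikeCount, spikeConstant = 10000) {
    sample <- "sample"
    if (is(spikeCount, "FragmentSet")) {
        sample <- sampleId(spikeCount)
        spikeCount <- spikeCount(spikeCount)
    }
    if (length(spikeCount) != 1L || is.na(spikeCount) || spikeCount < 0)
        stop("spikeCount must be a single nonnegative number")
    if (spikeCount == 0)
        stop("spike-in calibration impossible for sample '", sample,
             "': zero fragments mapped to the spike genome")
    spikeConstant / spikeCount
}

#' Per-base fragment pileup
#'
#' The value at base x is the number of fragments whose interval contains x
#' (whole-fragment coverage, as produced by genome-coverage tools run on
#' fragment BED files). The pileup sums to the total fragment length.
#'
#' @param frags a [FragmentSet-class] (its seqinfo defines the genome).
#' @param genome optional chromosome-size override.
#' @return A raw [CoverageTrack-class].
#' @export
fragmentPileup <- function(frags, genome = NULL) {
    gr <- fragments(frags)
    if (!is.null(genome)) {
        si <- asSeqinfo(genome)
        bad <- !(as.character(seqnames(gr)) %in% seqlevels(si))
        if (any(bad))
            stop("fragment on undeclared chromosome: record ", which(bad)[1L])
        gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), seqinfo = si)
        over <- which(end(gr) > seqlengths(si)[as.character(seqnames(gr))])
        if (length(over))
            stop("fragment beyond chromosome end: record ", over[1L])
    }
    cov <- coverage(gr)
    CoverageTrack(cov, calibration = "raw", scaleUsed = 1)
}

#' Spike-in calibration of a raw track
#'
#' @param raw a raw [CoverageTrack-class].
#' @param factor the multiplicative factor, usually [spikeScaleFactor()].
#' @return A spike-calibrated [CoverageTrack-class] with `scaleUsed` recorded.
#' @export
calibrateSpike <- function(raw, factor) {
    if (!identical(calibration(raw), "raw"))
        stop("calibrateSpike expects a raw track")
    if (factor <= 0) stop("scaling factor must be positive")
    CoverageTrack(trackValues(raw) * factor, calibration = "spike",
                  scaleUsed = factor)
}

#' Normalized-count calibration of a track
#'
#' Rescales each base's fraction of total counts by the reference length:
#' `value(x) = raw(x) / sum(raw) * referenceLength`. When `referenceLength`
#' equals the genome length, uniformly distributed counts give exactly 1 at
#' every position. Applying the calibration twice is a no-op.
#'
#' @param raw a [CoverageTrack-class] with positive total signal.
#' @param referenceLength reference size in bp; defaults to the track's own
#'   genome length.
#' @return A normcount [CoverageTrack-class].
#' @export
calibrateNormcount <- function(raw, referenceLength = NULL) {
    total <- sum(vapply(trackValues(raw), function(r) sum(as.numeric(r)),
                        numeric(1)))
    if (total <= 0)
        stop("cannot normalize an all-zero track")
    if (is.null(referenceLength)) referenceLength <- totalLength(raw)
    factor <- referenceLength / total
    CoverageTrack(trackValues(raw) * factor, calibration = "normcount",
                  scaleUsed = factor)
}

#' Read a bedGraph file into a CoverageTrack
#'
#' Intervals must be 0-based half-open, sorted, and non-overlapping within
#' each chromosome; violations are rejected with the offending line number.
#' Bases not covered by any interval are 0.
#'
#' @param path bedGraph file.
#' @param genome chromosome sizes; when `NULL`, each chromosome's length is
#'   taken as the largest end coordinate seen.
#' @param calibration calibration tag to record on the track.
#' @param scaleUsed scale factor to record.
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(path, genome = NULL, calibration = "raw",
                         scaleUsed = 1) {
    lines <- readLines(path)
    keep <- !grepl("^(track|#|browser)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    if (!length(lineno)) stop("no data lines in ", path)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 4L))
        stop("malformed bedGraph line ", lineno[which(nf != 4L)[1L]],
             " in ", path, ": expected 4 tab-separated fields")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    val <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
    bad <- which(is.na(start) | is.na(end) | is.na(val) | start < 0 |
                 end <= start)
    if (length(bad))
        stop("malformed bedGraph line ", lineno[bad[1L]], " in ", path)
    rl <- list()
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        if (is.unsorted(start[i], strictly = FALSE))
            stop("unsorted bedGraph intervals at line ",
                 lineno[i][which(diff(start[i]) < 0)[1L] + 1L], " in ", path)
        ov <- which(start[i][-1L] < end[i][-length(i)])
        if (length(ov))
            stop("overlapping bedGraph intervals at line ",
                 lineno[i][ov[1L] + 1L], " in ", path)
        len <- if (!is.null(genome)) {
            cl <- chromLengths(if (is(genome, "SyntheticGenome")) genome
                               else SyntheticGenome(genome))
            if (!ch %in% names(cl))
                stop("bedGraph chromosome ", ch, " not in genome")
            cl[[ch]]
        } else max(end[i])
        if (max(end[i]) > len)
            stop("bedGraph interval beyond chromosome end at line ",
                 lineno[i][which.max(end[i])], " in ", path)
        # runs: gaps are zero
        s <- start[i]; e <- end[i]; v <- val[i]
        starts <- c(rbind(c(0, e[-length(e)]), s))
        ends <- c(rbind(s, e))
        vals <- c(rbind(0, v))
        if (ends[length(ends)] < len) {
            starts <- c(starts, ends[length(ends)])
            ends <- c(ends, len)
            vals <- c(vals, 0)
        }
        w <- ends - starts
        keepruns <- w > 0
        rl[[ch]] <- Rle(vals[keepruns], w[keepruns])
    }
    if (!is.null(genome)) {
        cl <- chromLengths(if (is(genome, "SyntheticGenome")) genome
                           else SyntheticGenome(genome))
        for (ch in setdiff(names(cl), names(rl)))
            rl[[ch]] <- Rle(0, cl[[ch]])
        rl <- rl[names(cl)]
    }
    CoverageTrack(as(rl, "RleList"), calibration = calibration,
                  scaleUsed = scaleUsed)
}

#' Write a CoverageTrack as bedGraph
#'
#' Adjacent equal-valued runs are merged; zero runs are omitted. Values are
#' written with enough digits (`%.17g`) that reading the file back
#' reconstructs the per-base values exactly.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeBedGraph <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    rl <- trackValues(track)
    for (ch in names(rl)) {
        r <- rl[[ch]]
        ends <- cumsum(as.numeric(runLength(r)))
        starts <- c(0, ends[-length(ends)])
        v <- runValue(r)
        nz <- v != 0
        if (!any(nz)) next
        writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, as.integer(starts[nz]),
                           as.integer(ends[nz]), v[nz]), con)
    }
    invisible(path)
}

#' Optional BigWig export
#'
#' Thin wrapper over `rtracklayer::export.bw`; provided for interoperability
#' with genome browsers, not used by the analysis itself.
#'
#' @param track a [CoverageTrack-class].
#' @param path output `.bw` path.
#' @return The path, invisibly.
#' @export
exportBigWig <- function(track, path) {
    rl <- trackValues(track)
    gr <- as(rl, "GRanges")
    GenomeInfoDb::seqlengths(gr) <- chromLengths(track)[seqlevels(gr)]
    rtracklayer::export.bw(gr, path)
    invisible(path)
}
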