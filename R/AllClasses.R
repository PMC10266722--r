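#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- Rle runValue runLength
#' @importFrom IRanges IRanges Views RleList viewMeans viewSums restrict
#' @importFrom GenomicRanges GRanges granges coverage seqnames start end width strand
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqlevels
NULL

#' SyntheticGenome: a minimal chromosome-size table
#'
#' Holds chromosome names and lengths for a (usually synthetic) reference.
#' All coordinates in text files produced or consumed by this package are
#' 0-based half-open; internally ranges follow the Bioconductor 1-based
#' closed convention.
#'
#' @slot chromNames character vector of chromosome labels.
#' @slot chromLengths numeric vector of chromosome lengths in bp.
#' @export
setClass("SyntheticGenome",
    representation(chromNames = "character", chromLengths = "numeric"))

setValidity("SyntheticGenome", function(object) {
    msg <- NULL
    if (length(object@chromNames) != length(object@chromLengths))
        msg <- c(msg, "chromNames and chromLengths must have equal length")
    if (anyDuplicated(object@chromNames))
        msg <- c(msg, "chromosome names must be unique")
    if (length(object@chromLengths) == 0L || any(object@chromLengths <= 0) ||
        any(object@chromLengths != round(object@chromLengths)))
        msg <- c(msg, "chromosome lengths must be positive integers")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SyntheticGenome
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp), or an
#'   unnamed vector together with `chromNames`.
#' @param chromNames optional character vector of chromosome names.
#' @return A [SyntheticGenome-class] object.
#' @examples
#' gn <- SyntheticGenome(c(chr1 = 1e6, chr2 = 5e5))
#' totalLength(gn)
#' @export
SyntheticGenome <- function(chromLengths, chromNames = names(chromLengths)) {
    if (is.null(chromNames))
        chromNames <- paste0("chr", seq_along(chromLengths))
    new("SyntheticGenome", chromNames = as.character(chromNames),
        chromLengths = as.numeric(chromLengths))
}

#' FragmentSet: one sample's fragment intervals plus its spike-in count
#'
#' Wraps a `GRanges` of sequenced fragments (with seqlengths set, so
#' off-chromosome records are impossible) together with the number of
#' fragments that mapped to the spike-in genome, which drives spike
#' calibration of coverage.
#'
#' @slot fragments GRanges of fragment intervals (1-based closed internally).
#' @slot sampleId single sample label.
#' @slot spikeCount number of fragments mapped to the spike genome.
#' @export
setClass("FragmentSet",
    representation(fragments = "GRanges", sampleId = "character",
                   spikeCount = "numeric"))

setValidity("FragmentSet", function(object) {
    msg <- NULL
    gr <- object@fragments
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (length(object@spikeCount) != 1L || is.na(object@spikeCount) ||
        object@spikeCount < 0)
        msg <- c(msg, "spikeCount must be a single nonnegative number")
    sl <- seqlengths(gr)
    if (length(gr)) {
        if (any(is.na(sl)))
            msg <- c(msg, "fragment seqinfo must declare all chromosome lengths")
        else {
            bad <- which(start(gr) < 1L | end(gr) > sl[as.character(seqnames(gr))])
            if (length(bad))
                msg <- c(msg, sprintf(
                    "fragment(s) outside chromosome bounds, e.g. record %d (%s:%d-%d)",
                    bad[1L], as.character(seqnames(gr))[bad[1L]],
                    start(gr)[bad[1L]] - 1L, end(gr)[bad[1L]]))
        }
        if (any(width(gr) < 1L))
            msg <- c(msg, "all fragments must have width >= 1 (start < end)")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a FragmentSet
#'
#' @param fragments `GRanges` of fragment intervals, or a data.frame with
#'   columns chrom, start, end in 0-based half-open coordinates.
#' @param spikeCount fragments mapped to the spike-in genome.
#' @param sampleId sample label.
#' @param genome a [SyntheticGenome-class] (required when `fragments` is a
#'   data.frame, or when the GRanges lacks seqlengths).
#' @return A [FragmentSet-class].
#' @export
FragmentSet <- function(fragments, spikeCount, sampleId = "sample",
                        genome = NULL) {
    if (is.data.frame(fragments)) {
        if (is.null(genome))
            stop("a genome is required to build a FragmentSet from a data.frame")
        # out-of-bound ranges are reported by the validity method instead
        fragments <- suppressWarnings(GRanges(fragments$chrom,
            IRanges(start = fragments$start + 1L, end = fragments$end),
            seqinfo = asSeqinfo(genome)))
    } else if (is.null(genome) && any(is.na(seqlengths(fragments)))) {
        stop("fragment GRanges must carry seqlengths (or pass a genome)")
    } else if (!is.null(genome)) {
        fragments <- GRanges(seqnames(fragments),
            IRanges(start(fragments), end(fragments)),
            seqinfo = asSeqinfo(genome))
    }
    new("FragmentSet", fragments = fragments, sampleId = sampleId,
        spikeCount = as.numeric(spikeCount))
}

#' CoverageTrack: per-base signal over a reference
#'
#' Per-base coverage stored as a run-length encoded list (one `Rle` per
#' chromosome, full chromosome length), with a record of how it was
#' calibrated: `"raw"` (fragment pileup), `"spike"` (multiplied by
#' 10,000 / spike fragments) or `"normcount"` (fraction of counts per base
#' scaled by the reference length, so uniform coverage reads 1 everywhere).
#'
#' @slot values `RleList`, one run-length encoded vector per chromosome.
#' @slot calibration one of `"raw"`, `"spike"`, `"normcount"`.
#' @slot scaleUsed the multiplicative factor that was applied (1 for raw).
#' @export
setClass("CoverageTrack",
    representation(values = "RleList", calibration = "character",
                   scaleUsed = "numeric"))

setValidity("CoverageTrack", function(object) {
    msg <- NULL
    if (!(length(object@calibration) == 1L &&
          object@calibration %in% c("raw", "spike", "normcount")))
        msg <- c(msg, "calibration must be one of raw, spike, normcount")
    if (length(object@scaleUsed) != 1L || is.na(object@scaleUsed))
        msg <- c(msg, "scaleUsed must be a single number")
    else if (identical(object@calibration, "raw") && object@scaleUsed != 1)
        msg <- c(msg, "raw tracks must have scaleUsed == 1")
    if (length(object@values)) {
        mins <- vapply(object@values, function(r) {
            rv <- runValue(r)
            if (length(rv)) min(rv) else 0
        }, numeric(1))
        if (any(mins < 0))
            msg <- c(msg, "track values must be nonnegative everywhere")
    }
    if (is.null(msg)) TRUE else msg
})

CoverageTrack <- function(values, calibration = "raw", scaleUsed = 1) {
    new("CoverageTrack", values = values, calibration = calibration,
        scaleUsed = as.numeric(scaleUsed))
}

#' CoverageMatrix: promoters x bins of track signal, strand-oriented
#'
#' Rows are promoters (rownames carry promoter IDs), columns are fixed-width
#' bins running upstream to downstream in the transcriptional sense:
#' minus-strand rows are reversed at construction so bin 1 is always the most
#' upstream bin. Bins that fall entirely off a chromosome end are `NA`;
#' partially covered bins average over the covered bases only.
#'
#' @slot values numeric matrix of per-bin signal (mean or sum per bin).
#' @slot binSize bin width in bp.
#' @slot upstream bp upstream of the TSS covered by the matrix.
#' @slot downstream bp downstream of the TSS covered.
#' @slot binStat `"mean"` or `"sum"` per bin.
#' @export
setClass("CoverageMatrix",
    representation(values = "matrix", binSize = "integer",
                   upstream = "integer", downstream = "integer",
                   binStat = "character"))

setValidity("CoverageMatrix", function(object) {
    msg <- NULL
    nb <- (object@upstream + object@downstream) / object@binSize
    if (ncol(object@values) != nb)
        msg <- c(msg, "ncol(values) must equal (upstream + downstream)/binSize")
    if (is.null(rownames(object@values)) ||
        anyDuplicated(rownames(object@values)))
        msg <- c(msg, "rows must carry unique promoter IDs")
    if (!(object@binStat %in% c("mean", "sum")))
        msg <- c(msg, "binStat must be mean or sum")
    v <- object@values
    if (any(!is.na(v) & (v < 0 | is.infinite(v))))
        msg <- c(msg, "matrix values must be finite and >= 0 (or NA off-edge)")
    if (is.null(msg)) TRUE else msg
})

#' ClusterAssignment: k-means promoter clusters, relabeled by signal
#'
#' A named factor mapping promoter IDs to cluster labels `I`, `II`, ...,
#' relabeled after fitting so that cluster `I` always has the highest mean
#' matrix signal; this makes cluster names comparable across seeds and runs.
#'
#' @slot clusters named factor, names are promoter IDs, levels `I..k`.
#' @slot k number of clusters requested.
#' @slot seed RNG seed used for the k-means restarts.
#' @export
setClass("ClusterAssignment",
    representation(clusters = "factor", k = "integer", seed = "integer"))

setValidity("ClusterAssignment", function(object) {
    msg <- NULL
    if (is.null(names(object@clusters)) || anyDuplicated(names(object@clusters)))
        msg <- c(msg, "clusters must be named by unique promoter IDs")
    if (nlevels(object@clusters) > object@k)
        msg <- c(msg, "more cluster levels than k")
    if (is.null(msg)) TRUE else msg
})

#' EffectModel: planted-effect parameters for the fragment generator
#'
#' Encodes what the synthetic fragment generator plants: a baseline fragment
#' rate per promoter, a multiplicative accessibility boost at divergent
#' promoters whose nearest upstream neighbor is closer than `distanceCutoff`,
#' three class-rate multipliers for planted cluster structure, a downstream
#' placement shift, negative-binomial overdispersion, a uniform background
#' fraction, and the seed.
#'
#' @slot baselineRate baseline fragments per promoter (relative weight).
#' @slot divergentCloseBoost multiplicative factor (>= 1) for close
#'   divergent promoters.
#' @slot distanceCutoff bp; "close" means nearest-upstream distance below this.
#' @slot classRates three rate multipliers for planted cluster classes.
#' @slot downstreamShift bp offset of fragment midpoints from the TSS,
#'   in the transcriptional direction.
#' @slot noiseDispersion negative-binomial dispersion (0 = Poisson).
#' @slot backgroundFraction fraction of fragments placed uniformly.
#' @slot footprintSd sd (bp) of fragment midpoint placement around the TSS.
#' @slot seed RNG seed.
#' @export
setClass("EffectModel",
    representation(baselineRate = "numeric", divergentCloseBoost = "numeric",
                   distanceCutoff = "numeric", classRates = "numeric",
                   downstreamShift = "numeric", noiseDispersion = "numeric",
                   backgroundFraction = "numeric", footprintSd = "numeric",
                   seed = "integer"))

setValidity("EffectModel", function(object) {
    msg <- NULL
    if (object@baselineRate < 0 || any(object@classRates < 0))
        msg <- c(msg, "rates must be nonnegative")
    if (object@divergentCloseBoost < 1)
        msg <- c(msg, "divergentCloseBoost must be >= 1")
    if (object@distanceCutoff <= 0)
        msg <- c(msg, "distanceCutoff must be > 0")
    if (length(object@classRates) != 3L)
        msg <- c(msg, "classRates must have length 3")
    if (object@noiseDispersion < 0)
        msg <- c(msg, "noiseDispersion must be >= 0")
    if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
        msg <- c(msg, "backgroundFraction must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Construct an EffectModel
#'
#' @param baselineRate baseline fragments-per-promoter weight.
#' @param divergentCloseBoost accessibility boost (>= 1) planted at divergent
#'   promoters closer than `distanceCutoff` to their upstream neighbor.
#' @param distanceCutoff bp cutoff defining "close".
#' @param classRates three rate multipliers for planted cluster classes.
#' @param downstreamShift bp shift of fragment mass downstream of the TSS.
#' @param noiseDispersion negative-binomial dispersion; 0 gives Poisson counts.
#' @param backgroundFraction fraction of fragments placed uniformly over the
#'   genome rather than at promoters.
#' @param footprintSd sd in bp of fragment midpoints around the (shifted) TSS.
#' @param seed integer RNG seed.
#' @return An [EffectModel-class].
#' @export
EffectModel <- function(baselineRate = 40, divergentCloseBoost = 1,
                        distanceCutoff = 1000, classRates = c(1, 1, 1),
                        downstreamShift = 150, noiseDispersion = 0.2,
                        backgroundFraction = 0.05, footprintSd = 150,
                        seed = 1L) {
    new("EffectModel", baselineRate = baselineRate,
        divergentCloseBoost = divergentCloseBoost,
        distanceCutoff = distanceCutoff, classRates = classRates,
        downstreamShift = downstreamShift, noiseDispersion = noiseDispersion,
        backgroundFraction = backgroundFraction, footprintSd = footprintSd,
        seed = as.integer(seed))
}
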