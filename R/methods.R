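# Accessors and show methods for the core classes.

#' @rdname SyntheticGenome-class
#' @export
setMethod("chromLengths", "SyntheticGenome", function(x) {
    stats::setNames(x@chromLengths, x@chromNames)
})

#' @rdname SyntheticGenome-class
#' @export
setMethod("totalLength", "SyntheticGenome", function(x) sum(x@chromLengths))

#' @rdname CoverageTrack-class
#' @export
setMethod("chromLengths", "CoverageTrack", function(x) {
    vapply(x@values, length, numeric(1))
})

#' @rdname CoverageTrack-class
#' @export
setMethod("totalLength", "CoverageTrack", function(x) sum(chromLengths(x)))

#' @rdname FragmentSet-class
#' @export
setMethod("chromLengths", "FragmentSet", function(x) {
    sl <- seqlengths(x@fragments)
    stats::setNames(as.numeric(sl), names(sl))
})

#' Coerce a chromosome-size source to a Seqinfo
#'
#' @param genome a [SyntheticGenome-class], named numeric vector, or `Seqinfo`.
#' @return a `GenomeInfoDb::Seqinfo`.
#' @export
asSeqinfo <- function(genome) {
    if (is(genome, "Seqinfo")) return(genome)
    if (is(genome, "SyntheticGenome"))
        return(Seqinfo(seqnames = genome@chromNames,
                       seqlengths = as.integer(genome@chromLengths)))
    if (is.numeric(genome) && !is.null(names(genome)))
        return(Seqinfo(seqnames = names(genome),
                       seqlengths = as.integer(genome)))
    stop("cannot interpret 'genome' as a chromosome-size table")
}

#' @rdname FragmentSet-class
#' @export
setMethod("spikeCount", "FragmentSet", function(x) x@spikeCount)

#' @rdname FragmentSet-class
#' @export
setMethod("sampleId", "FragmentSet", function(x) x@sampleId)

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname CoverageTrack-class
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @rdname CoverageTrack-class
#' @export
setMethod("calibration", "CoverageTrack", function(x) x@calibration)

#' @rdname CoverageTrack-class
#' @export
setMethod("scaleUsed", "CoverageTrack", function(x) x@scaleUsed)

#' @rdname CoverageMatrix-class
#' @export
setMethod("matrixValues", "CoverageMatrix", function(x) x@values)

#' @rdname CoverageMatrix-class
#' @export
setMethod("binSize", "CoverageMatrix", function(x) x@binSize)

#' @rdname CoverageMatrix-class
#' @export
setMethod("binCenters", "CoverageMatrix", function(x) {
    -x@upstream + (seq_len(ncol(x@values)) - 0.5) * x@binSize
})

#' @rdname ClusterAssignment-class
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@clusters)

setMethod("show", "SyntheticGenome", function(object) {
    cat("SyntheticGenome with", length(object@chromNames),
        "chromosome(s),", format(sum(object@chromLengths), big.mark = ","),
        "bp total\n")
})

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet '", object@sampleId, "': ",
        format(length(object@fragments), big.mark = ","),
        " fragments, spike count ",
        format(object@spikeCount, big.mark = ","), "\n", sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack (", object@calibration, ", scale ",
        signif(object@scaleUsed, 6), ") over ",
        length(object@values), " chromosome(s), ",
        format(sum(chromLengths(object)), big.mark = ","), " bp\n", sep = "")
})

setMethod("show", "CoverageMatrix", function(object) {
    cat("CoverageMatrix: ", nrow(object@values), " promoters x ",
        ncol(object@values), " bins of ", object@binSize, " bp (",
        object@upstream, " bp upstream to ", object@downstream,
        " bp downstream, per-bin ", object@binStat, ")\n", sep = "")
})

setMethod("show", "ClusterAssignment", function(object) {
    tab <- table(object@clusters)
    cat("ClusterAssignment: k = ", object@k, " (",
        paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        ")\n", sep = "")
})
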