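#' @rdname SyntheticGenome-class
#' @param x an object with chromosome sizes.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname FragmentSet-class
#' @param x a FragmentSet.
#' @export
setGeneric("spikeCount", function(x) standardGeneric("spikeCount"))

#' @rdname FragmentSet-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname CoverageTrack-class
#' @param x a CoverageTrack.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("scaleUsed", function(x) standardGeneric("scaleUsed"))

#' @rdname CoverageMatrix-class
#' @param x a CoverageMatrix or ClusterAssignment.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' @rdname CoverageMatrix-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname CoverageMatrix-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname ClusterAssignment-class
#' @param x a ClusterAssignment.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
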