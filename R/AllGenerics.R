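#' @rdname ITSAlignment-class
#' @param x,object an object.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname ITSAlignment-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname ITSAlignment-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname ITSAlignment-class
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))

#' @rdname ITSAlignment-class
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname ITSAlignment-class
#' @export
setGeneric("sequenceStrings", function(x) standardGeneric("sequenceStrings"))

#' @rdname DistanceMatrix-class
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname DistanceMatrix-class
#' @export
setGeneric("comparedSites", function(x) standardGeneric("comparedSites"))

#' @rdname ThresholdSweep-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ThresholdSweep-class
#' @export
setGeneric("clusterCounts", function(x) standardGeneric("clusterCounts"))

#' @rdname ThresholdSweep-class
#' @param t a grid threshold (percent distance).
#' @export
setGeneric("partitionAt", function(x, t) standardGeneric("partitionAt"))

#' @rdname SpeciesTreeModel-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname SpeciesTreeModel-class
#' @export
setGeneric("nodeTimes", function(x) standardGeneric("nodeTimes"))

#' @rdname SpeciesTreeModel-class
#' @export
setGeneric("thetaValues", function(x) standardGeneric("thetaValues"))

#' @rdname DiagnosticTable-class
#' @export
setGeneric("diagnosticPositions", function(x) standardGeneric("diagnosticPositions"))
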