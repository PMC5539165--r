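#' @include AllClasses.R
NULL

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakIds", function(x) standardGeneric("peakIds"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakScores", function(x) standardGeneric("peakScores"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("tagRanges", function(x) standardGeneric("tagRanges"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("tagTotal", function(x) standardGeneric("tagTotal"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))

#' @rdname GenomeModel-accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname GenomeModel-accessors
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))

#' @rdname GenomeModel-accessors
#' @export
setGeneric("enhancers", function(x) standardGeneric("enhancers"))

#' @rdname FuzzyClusterResult-accessors
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname FuzzyClusterResult-accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname FuzzyClusterResult-accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname MetaProfile-accessors
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' @rdname MetaProfile-accessors
#' @export
setGeneric("profileDensity", function(x) standardGeneric("profileDensity"))

#' @rdname DensityMatrix-accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname DensityMatrix-accessors
#' @export
setGeneric("rowClusters", function(x) standardGeneric("rowClusters"))
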