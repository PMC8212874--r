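#' @include AllClasses.R
NULL

#' @export
setGeneric("peakCoverage", function(x, ...) standardGeneric("peakCoverage"))

#' @export
setGeneric("peakCV", function(x, ...) standardGeneric("peakCV"))

#' @export
setGeneric("normalizedCV", function(x, ...) standardGeneric("normalizedCV"))

#' @export
setGeneric("specificityLabel", function(x, ...) standardGeneric("specificityLabel"))

#' @export
setGeneric("shapeCluster", function(x, ...) standardGeneric("shapeCluster"))

#' @export
setGeneric("embeddingCoords", function(x, ...) standardGeneric("embeddingCoords"))

#' @export
setGeneric("sharpPeaks", function(x, ...) standardGeneric("sharpPeaks"))

#' @export
setGeneric("kSelection", function(x, ...) standardGeneric("kSelection"))
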