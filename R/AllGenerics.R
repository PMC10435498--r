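#' @rdname ContactMatrix-class
#' @param object,x an object.
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))

#' @rdname HicWindows-class
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

#' @rdname HicWindows-class
#' @export
setGeneric("windowBins", function(x) standardGeneric("windowBins"))

#' @rdname HicWindows-class
#' @export
setGeneric("windowData", function(x) standardGeneric("windowData"))

#' @rdname HicWindows-class
#' @export
setGeneric("isCleaned", function(x) standardGeneric("isCleaned"))

#' @rdname WindowPairs-class
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname WindowPairs-class
#' @export
setGeneric("pairSplits", function(x) standardGeneric("pairSplits"))

#' @rdname SiameseModel-class
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname SiameseModel-class
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname SeparationReport-class
#' @export
setGeneric("separationIndexOf", function(x) standardGeneric("separationIndexOf"))

#' @rdname SeparationReport-class
#' @export
setGeneric("meanPerformanceOf", function(x) standardGeneric("meanPerformanceOf"))
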