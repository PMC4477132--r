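#' @rdname emd
#' @export
setGeneric("emd", function(x, config = siftConfig(), ...) standardGeneric("emd"))

#' @rdname accessors
#' @export
setGeneric("imfs", function(x) standardGeneric("imfs"))

#' @rdname accessors
#' @export
setGeneric("residualSignal", function(x) standardGeneric("residualSignal"))

#' @rdname accessors
#' @export
setGeneric("nIMF", function(x) standardGeneric("nIMF"))

#' @rdname accessors
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))

#' @rdname accessors
#' @export
setGeneric("pulseSamples", function(x) standardGeneric("pulseSamples"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname normalizedEnergy
#' @export
setGeneric("normalizedEnergy", function(x, ...) standardGeneric("normalizedEnergy"))

#' @rdname sampenVector
#' @export
setGeneric("sampenVector", function(x, ...) standardGeneric("sampenVector"))

#' @rdname hilbertSpectrum
#' @export
setGeneric("hilbertSpectrum", function(x, ...) standardGeneric("hilbertSpectrum"))

#' @rdname featureTable
#' @export
setGeneric("featureTable", function(x, ...) standardGeneric("featureTable"))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x, family = c("combined", "energy", "sampen"), ...)
  standardGeneric("featureMatrix"))
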