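#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the signal and result classes: complex
#' sample vectors, time axes, echo times, fitted parameters.
#'
#' @param x,object an object of one of the classes defined in this package
#' @param ... passed to methods
#' @return the slot value (see the class documentation)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("dwellTime", function(x) standardGeneric("dwellTime"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x, ...) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("baselineValue", function(x) standardGeneric("baselineValue"))

#' @rdname accessors
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname accessors
#' @export
setGeneric("fastFraction", function(x) standardGeneric("fastFraction"))

#' @rdname accessors
#' @export
setGeneric("totalAmplitude", function(x) standardGeneric("totalAmplitude"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("ffMap", function(x) standardGeneric("ffMap"))

#' @rdname accessors
#' @export
setGeneric("frequencyAxis", function(x) standardGeneric("frequencyAxis"))
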