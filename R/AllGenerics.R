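#' @rdname OffsetGrid-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname ZSpectrumStack-class
#' @export
setGeneric("sSat", function(x) standardGeneric("sSat"))

#' @rdname ZSpectrumStack-class
#' @export
setGeneric("s0", function(x) standardGeneric("s0"))

#' @rdname ZSpectrumStack-class
#' @export
setGeneric("offsetGrid", function(x) standardGeneric("offsetGrid"))

#' @rdname B0Map-class
#' @export
setGeneric("b0Shift", function(x) standardGeneric("b0Shift"))

#' @rdname B0Map-class
#' @export
setGeneric("validVoxels", function(x) standardGeneric("validVoxels"))

#' @rdname B0Map-class
#' @export
setGeneric("fitResidual", function(x) standardGeneric("fitResidual"))

#' @rdname APTwMap-class
#' @export
setGeneric("aptwPercent", function(x) standardGeneric("aptwPercent"))
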