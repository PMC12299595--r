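#' @rdname OffsetGrid-class
#' @export
setMethod("offsets", "OffsetGrid", function(x) x@offsets)

#' @rdname OffsetGrid-class
#' @export
setMethod("length", "OffsetGrid", function(x) length(x@offsets))

setMethod("show", "OffsetGrid", function(object) {
  o <- object@offsets
  cat(sprintf("OffsetGrid: %d offsets, %.3g to %.3g ppm\n",
              length(o), min(o), max(o)))
})

#' @rdname ZSpectrumStack-class
#' @export
setMethod("sSat", "ZSpectrumStack", function(x) x@sSat)

#' @rdname ZSpectrumStack-class
#' @export
setMethod("s0", "ZSpectrumStack", function(x) x@s0)

#' @rdname ZSpectrumStack-class
#' @export
setMethod("offsetGrid", "ZSpectrumStack", function(x) x@grid)

#' @rdname ZSpectrumStack-class
#' @export
setMethod("offsets", "ZSpectrumStack", function(x) x@grid@offsets)

#' @rdname ZSpectrumStack-class
#' @export
setMethod("dim", "ZSpectrumStack", function(x) dim(x@sSat))

setMethod("show", "ZSpectrumStack", function(object) {
  d <- dim(object@sSat)
  cat(sprintf("ZSpectrumStack: %d x %d voxels, %d offsets (%.3g to %.3g ppm)\n",
              d[1], d[2], d[3],
              min(object@grid@offsets), max(object@grid@offsets)))
  if (length(object@provenance)) {
    cat("provenance:", paste(object@provenance, collapse = "; "), "\n")
  }
})

#' @rdname B0Map-class
#' @export
setMethod("b0Shift", "B0Map", function(x) x@shift)

#' @rdname B0Map-class
#' @export
setMethod("validVoxels", "B0Map", function(x) x@valid)

#' @rdname B0Map-class
#' @export
setMethod("fitResidual", "B0Map", function(x) x@residual)

#' @rdname B0Map-class
#' @export
setMethod("dim", "B0Map", function(x) dim(x@shift))

setMethod("show", "B0Map", function(object) {
  v <- object@valid
  cat(sprintf("B0Map: %d x %d, %.1f%% valid", nrow(v), ncol(v),
              100 * mean(v)))
  if (any(v)) {
    cat(sprintf(", shift range [%.3f, %.3f] ppm",
                min(object@shift[v]), max(object@shift[v])))
  }
  cat("\n")
})

#' @rdname APTwMap-class
#' @export
setMethod("aptwPercent", "APTwMap", function(x) x@aptw)

#' @rdname APTwMap-class
#' @export
setMethod("validVoxels", "APTwMap", function(x) x@valid)

#' @rdname APTwMap-class
#' @export
setMethod("dim", "APTwMap", function(x) dim(x@aptw))

setMethod("show", "APTwMap", function(object) {
  v <- object@valid
  cat(sprintf("APTwMap: %d x %d, %.1f%% valid", nrow(v), ncol(v),
              100 * mean(v)))
  if (any(v)) {
    cat(sprintf(", APTw range [%.2f, %.2f]%%",
                min(object@aptw[v]), max(object@aptw[v])))
  }
  cat("\n")
})
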