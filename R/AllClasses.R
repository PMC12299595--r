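#' @import methods
NULL

#' OffsetGrid: an ordered set of saturation frequency offsets
#'
#' Container for the saturation frequency offsets (in ppm from water) shared
#' by all voxels of a z-spectrum stack. Offsets are stored strictly
#' ascending, finite, without duplicates.
#'
#' @slot offsets numeric vector of offsets in ppm, strictly ascending.
#'
#' @seealso [makeOffsetGrid()] for the constructor used throughout the
#'   package, [aptwOffsetGrid()] and [wassrOffsetGrid()] for the two
#'   acquisition grids.
#' @export
setClass("OffsetGrid", representation(offsets = "numeric"))

setValidity("OffsetGrid", function(object) {
  o <- object@offsets
  if (length(o) < 1L) return("grid must contain at least one offset")
  if (any(!is.finite(o))) return("offsets must be finite")
  if (is.unsorted(o, strictly = TRUE)) {
    return("offsets must be strictly ascending (no duplicates)")
  }
  TRUE
})

#' ZSpectrumStack: per-voxel saturated signal plus unsaturated reference
#'
#' Holds the saturated signal S_sat for every voxel at every offset of an
#' [OffsetGrid-class], together with the unsaturated reference image S0 used
#' for normalization. Signal units are arbitrary but shared between S_sat
#' and S0.
#'
#' @slot sSat numeric array (rows x cols x n_offsets) of saturated signal.
#' @slot s0 numeric matrix (rows x cols) of unsaturated signal.
#' @slot grid [OffsetGrid-class] with one entry per S_sat plane.
#' @slot provenance character log of transformations applied on read
#'   (e.g. reordering of planes to ascending offset order).
#' @export
setClass("ZSpectrumStack",
  representation(sSat = "array", s0 = "matrix", grid = "OffsetGrid",
                 provenance = "character"),
  prototype(provenance = character(0)))

setValidity("ZSpectrumStack", function(object) {
  d <- dim(object@sSat)
  if (length(d) != 3L) return("sSat must be a 3D array (rows x cols x offsets)")
  if (d[3L] != length(object@grid@offsets)) {
    return(sprintf("sSat has %d planes but grid has %d offsets",
                   d[3L], length(object@grid@offsets)))
  }
  if (!identical(dim(object@s0), d[1:2])) {
    return("s0 shape does not match sSat rows x cols")
  }
  TRUE
})

#' B0Map: per-voxel water frequency shift
#'
#' Result of the WASSR stage: the estimated water resonance shift (ppm) per
#' voxel, a validity flag, and the RMS residual of the polynomial fit in
#' normalized signal units. A voxel is invalid where the fit failed, the
#' fitted minimum sat on the boundary of the acquired range, or the shift
#' exceeded the configured bound.
#'
#' @slot shift numeric matrix of shifts in ppm (NA where invalid).
#' @slot valid logical matrix.
#' @slot residual numeric matrix, RMS fit residual.
#' @export
setClass("B0Map",
  representation(shift = "matrix", valid = "matrix", residual = "matrix"))

setValidity("B0Map", function(object) {
  if (!identical(dim(object@shift), dim(object@valid)) ||
      !identical(dim(object@shift), dim(object@residual))) {
    return("shift, valid and residual must share one shape")
  }
  if (!is.logical(object@valid)) return("valid must be logical")
  TRUE
})

#' APTwMap: per-voxel MTRasym at the analysis offset, in percent
#'
#' @slot aptw numeric matrix of MTRasym(analysis offset) in percent
#'   (NA where invalid).
#' @slot valid logical matrix; FALSE where the B0 estimate was invalid, S0
#'   was non-positive, or the shift correction required samples outside the
#'   acquired offset range.
#' @export
setClass("APTwMap", representation(aptw = "matrix", valid = "matrix"))

setValidity("APTwMap", function(object) {
  if (!identical(dim(object@aptw), dim(object@valid))) {
    return("aptw and valid must share one shape")
  }
  if (!is.logical(object@valid)) return("valid must be logical")
  if (any(!is.finite(object@aptw[object@valid]))) {
    return("aptw must be finite wherever valid")
  }
  TRUE
})
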