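#' Normalize a stack to its unsaturated reference
#'
#' Divides each voxel's saturated series by its S0 value. Voxels with
#' non-positive or non-finite S0 are not an error: they are flagged in the
#' returned validity matrix and excluded downstream.
#'
#' @param stack a [ZSpectrumStack-class].
#' @return list with `z` (rows x cols x offsets array) and `valid`
#'   (logical matrix, TRUE where S0 > 0).
#' @export
normalizeToS0 <- function(stack) {
  stopifnot(is(stack, "ZSpectrumStack"))
  d <- dim(stack@sSat)
  valid <- is.finite(stack@s0) & stack@s0 > 0
  z <- stack@sSat / array(stack@s0, d)  # s0 recycled across offset planes
  z[array(!valid, d)] <- NA_real_
  list(z = z, valid = valid)
}

#' B0-correct one voxel's z-spectrum
#'
#' Interpolates the sampled spectrum with a natural cubic spline and
#' translates the frequency axis by the voxel's water shift so that water
#' sits at 0 ppm, then resamples at the original offsets: the corrected
#' value at offset x is the spline evaluated at x + shift. Offsets whose
#' shifted sampling point falls outside the acquired range are returned as
#' NA rather than extrapolated (order-12/spline extrapolation is
#' unreliable); a voxel only becomes unusable for APTw if the analysis
#' offsets themselves are lost.
#'
#' @param grid [OffsetGrid-class] (or numeric offsets).
#' @param z numeric z-values, one per offset.
#' @param shift_ppm the voxel's water frequency shift (finite).
#' @param resolution_ppm retained for interface symmetry with the WASSR
#'   stage; the spline is evaluated exactly at the shifted offsets, which
#'   is the 0-step-size limit of fine-grid resampling.
#' @return numeric vector of corrected z on the original grid, NA where
#'   the required sample lies outside the acquired range.
#' @export
correctVoxel <- function(grid, z, shift_ppm, resolution_ppm = 0.01) {
  x <- .asOffsets(grid)
  if (length(z) != length(x)) stop("z length does not match the grid")
  if (!is.finite(shift_ppm)) stop("non-finite shift")
  if (shift_ppm == 0) return(z)
  sf <- stats::splinefun(x, z, method = "natural")
  xq <- x + shift_ppm
  out <- sf(xq)
  out[xq < min(x) - 1e-9 | xq > max(x) + 1e-9] <- NA_real_
  out
}

#' MTR asymmetry of a (corrected) z-spectrum
#'
#' `MTRasym(at) = MTR(+at) - MTR(-at) = 100 * (z(-at) - z(+at))` percent,
#' with `MTR = 1 - S_sat/S0`. Both `+at` and `-at` must be grid offsets.
#'
#' @param z numeric z-values on `grid`.
#' @param grid [OffsetGrid-class] (or numeric offsets).
#' @param at_ppm analysis offset (default 3.5 ppm).
#' @return MTRasym in percent (NA if either required sample is NA).
#' @export
mtrAsym <- function(z, grid, at_ppm = 3.5) {
  x <- .asOffsets(grid)
  if (length(z) != length(x)) stop("z length does not match the grid")
  ip <- which(abs(x - at_ppm) < 1e-6)
  im <- which(abs(x + at_ppm) < 1e-6)
  if (length(ip) != 1L || length(im) != 1L) {
    stop(sprintf("offsets +/-%g ppm are not on the grid", at_ppm))
  }
  100 * (z[im] - z[ip])
}

#' Per-voxel APTw map
#'
#' Runs the normalize / B0-correct / MTRasym chain on every in-mask voxel:
#' z = S_sat/S0, cubic-spline shift correction by the voxel's [b0Map()]
#' estimate, then MTRasym at the analysis offset. Voxels with invalid B0,
#' non-positive S0, or analysis samples pushed outside the acquired range
#' are marked invalid.
#'
#' @param aptw_stack [ZSpectrumStack-class]; its grid must contain
#'   +/- the analysis offset.
#' @param b0map [B0Map-class] from the WASSR stage.
#' @param mask logical matrix of voxels to process.
#' @param config a `cest_config`.
#' @param correct set FALSE to skip the B0 correction (ablation /
#'   comparison runs).
#' @return an [APTwMap-class].
#' @export
aptwMap <- function(aptw_stack, b0map, mask, config = pipelineConfig(),
                    correct = TRUE) {
  stopifnot(is(aptw_stack, "ZSpectrumStack"), is(b0map, "B0Map"),
            is.logical(mask))
  d <- dim(aptw_stack@sSat)
  stopifnot(identical(dim(mask), d[1:2]), identical(dim(b0map@shift), d[1:2]))
  x <- aptw_stack@grid@offsets
  at <- config$analysis_offset_ppm
  if (!any(abs(x - at) < 1e-6) || !any(abs(x + at) < 1e-6)) {
    stop(sprintf("APTw grid does not contain +/-%g ppm", at))
  }
  nz <- normalizeToS0(aptw_stack)
  aptw <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  zmat <- matrix(nz$z, d[1] * d[2], d[3])
  for (i in which(mask & nz$valid & (b0map@valid | !correct))) {
    zi <- zmat[i, ]
    if (correct) zi <- correctVoxel(x, zi, b0map@shift[i])
    v <- mtrAsym(zi, x, at)
    if (is.finite(v)) {
      aptw[i] <- v
      valid[i] <- TRUE
    }
  }
  new("APTwMap", aptw = aptw, valid = valid)
}

#' ROI-mean MTRasym curve
#'
#' The per-voxel corrected MTRasym evaluated at every positive grid offset
#' whose negative counterpart is also on the grid, averaged over the valid
#' voxels of an ROI — the curve a z-spectrum figure plots against offset.
#'
#' @param aptw_stack [ZSpectrumStack-class].
#' @param b0map [B0Map-class].
#' @param roi_mask logical matrix; must contain at least one valid voxel.
#' @param config a `cest_config`.
#' @return data.frame with columns `offset_ppm`, `mean`, `sem`, `n`
#'   (voxels contributing at that offset).
#' @export
meanMtrAsymCurve <- function(aptw_stack, b0map, roi_mask,
                             config = pipelineConfig()) {
  stopifnot(is(aptw_stack, "ZSpectrumStack"), is(b0map, "B0Map"))
  d <- dim(aptw_stack@sSat)
  x <- aptw_stack@grid@offsets
  pos <- sort(x[x > 0])
  pos <- pos[vapply(pos, function(p) any(abs(x + p) < 1e-6), logical(1))]
  if (!length(pos)) stop("grid has no +/- offset pairs")
  nz <- normalizeToS0(aptw_stack)
  zmat <- matrix(nz$z, d[1] * d[2], d[3])
  use <- which(roi_mask & nz$valid & b0map@valid)
  if (!length(use)) stop("no valid voxels in the ROI")
  vals <- matrix(NA_real_, length(use), length(pos))
  for (k in seq_along(use)) {
    i <- use[k]
    zi <- correctVoxel(x, zmat[i, ], b0map@shift[i])
    for (j in seq_along(pos)) {
      ip <- which(abs(x - pos[j]) < 1e-6)
      im <- which(abs(x + pos[j]) < 1e-6)
      vals[k, j] <- 100 * (zi[im] - zi[ip])
    }
  }
  n <- colSums(is.finite(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  sem <- apply(vals, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  data.frame(offset_ppm = pos, mean = mu, sem = sem, n = n)
}
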