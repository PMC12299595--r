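# Least-squares polynomial machinery for the WASSR stage. The fit is a
# linear projection of the sampled z-values, so for a fixed grid, order and
# resolution we precompute two matrices: Ffine (fine-grid evaluations of the
# fitted polynomial) and H (hat matrix, fitted values at the sample nodes,
# for residuals). Offsets are rescaled to [-1, 1] before building the
# Vandermonde basis; an order-12 basis on raw ppm values is severely
# ill-conditioned.
.wassrProjection <- function(offsets, order, resolution_ppm) {
  rng <- range(offsets)
  xs <- 2 * (offsets - rng[1]) / diff(rng) - 1
  fine <- seq(rng[1], rng[2], by = resolution_ppm)
  xf <- 2 * (fine - rng[1]) / diff(rng) - 1
  V <- outer(xs, 0:order, `^`)
  Vf <- outer(xf, 0:order, `^`)
  qrV <- qr(V)
  # coefficient solve folded into the projections
  P <- qr.solve(qrV, diag(length(offsets)))   # (order+1) x n
  list(fine = fine, Ffine = Vf %*% P, H = V %*% P)
}

# locate the minimum of a fitted fine curve with the stage's conventions:
# ties broken toward the smallest |offset|; boundary or flat minima invalid
.locateMinimum <- function(fine, zf) {
  if (any(!is.finite(zf))) return(list(shift = NA_real_, valid = FALSE))
  rngz <- max(zf) - min(zf)
  if (rngz < 1e-10) return(list(shift = NA_real_, valid = FALSE))
  cand <- which(zf <= min(zf) + 1e-12 * max(1, rngz))
  i <- cand[which.min(abs(fine[cand]))]
  if (i == 1L || i == length(zf)) {
    return(list(shift = fine[i], valid = FALSE))
  }
  list(shift = fine[i], valid = TRUE)
}

#' Fit one voxel's WASSR spectrum and locate the water minimum
#'
#' Fits the sampled z-values with a least-squares polynomial of the given
#' order (on offsets rescaled to `[-1, 1]` for conditioning), evaluates the
#' fitted curve on a fine grid at `resolution_ppm` spanning the acquired
#' range, and returns the fine-grid location of the curve minimum as the
#' voxel's water frequency shift. Ties are broken toward the smallest
#' absolute offset; a minimum on the boundary of the acquired range, or a
#' flat fitted curve, is flagged invalid.
#'
#' @param grid [OffsetGrid-class] (or numeric offsets) of the WASSR
#'   acquisition.
#' @param z numeric z-values (S_sat/S0), one per offset.
#' @param order polynomial order (default 12); needs at least `order + 1`
#'   samples.
#' @param resolution_ppm fine-grid spacing (default 0.01 ppm).
#' @return list with `shift_ppm`, `residual` (RMS of fit at the sample
#'   nodes), `valid`, and `fine_curve` (data.frame `offset_ppm`, `z_fit`).
#' @export
fitWassrVoxel <- function(grid, z, order = 12, resolution_ppm = 0.01) {
  x <- .asOffsets(grid)
  if (length(z) != length(x)) stop("z length does not match the grid")
  if (any(!is.finite(z))) stop("non-finite z-values")
  if (length(x) < order + 1) {
    stop(sprintf("need at least %d samples for an order-%d fit; got %d",
                 order + 1, order, length(x)))
  }
  proj <- .wassrProjection(x, order, resolution_ppm)
  zf <- drop(proj$Ffine %*% z)
  res <- sqrt(mean((drop(proj$H %*% z) - z)^2))
  loc <- .locateMinimum(proj$fine, zf)
  list(shift_ppm = loc$shift, residual = res, valid = loc$valid,
       fine_curve = data.frame(offset_ppm = proj$fine, z_fit = zf))
}

#' Per-voxel B0 map from a WASSR stack
#'
#' Applies [fitWassrVoxel()] to the S0-normalized spectrum of every in-mask
#' voxel (the fit is batched: one matrix product for all voxels). Voxels
#' outside the mask, with non-positive S0, with boundary/degenerate minima,
#' or with |shift| beyond `max_shift_ppm` are marked invalid.
#'
#' @param wassr_stack [ZSpectrumStack-class] from the WASSR acquisition;
#'   its grid must span at least +/- `max_shift_ppm`.
#' @param mask logical matrix of voxels to process (non-empty).
#' @param config a `cest_config` from [pipelineConfig()].
#' @return a [B0Map-class].
#' @export
b0Map <- function(wassr_stack, mask, config = pipelineConfig()) {
  stopifnot(is(wassr_stack, "ZSpectrumStack"), is.logical(mask))
  d <- dim(wassr_stack@sSat)
  if (!identical(dim(mask), d[1:2])) stop("mask shape does not match stack")
  if (!any(mask)) stop("analysis mask is empty")
  off <- wassr_stack@grid@offsets
  if (min(off) > -config$max_shift_ppm || max(off) < config$max_shift_ppm) {
    stop("WASSR grid does not span +/- max_shift_ppm")
  }
  idx <- which(mask)
  nvox <- length(idx)
  sat <- matrix(wassr_stack@sSat, d[1] * d[2], d[3])[idx, , drop = FALSE]
  s0v <- wassr_stack@s0[idx]
  ok_s0 <- is.finite(s0v) & s0v > 0
  Z <- sat / s0v  # recycles s0 down columns: rows are voxels
  proj <- .wassrProjection(off, config$polynomial_order,
                           config$interpolation_resolution_ppm)
  shift <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  resid <- matrix(NA_real_, d[1], d[2])
  if (any(ok_s0)) {
    Zo <- t(Z[ok_s0, , drop = FALSE])          # offsets x voxels
    ZF <- proj$Ffine %*% Zo                    # fine x voxels
    R <- proj$H %*% Zo - Zo
    rms <- sqrt(colMeans(R^2))
    sh <- numeric(ncol(ZF)); vl <- logical(ncol(ZF))
    for (j in seq_len(ncol(ZF))) {
      loc <- .locateMinimum(proj$fine, ZF[, j])
      sh[j] <- loc$shift; vl[j] <- loc$valid
    }
    vl <- vl & is.finite(sh) & abs(sh) <= config$max_shift_ppm
    ii <- idx[ok_s0]
    shift[ii] <- sh
    shift[ii[!vl]] <- NA_real_
    valid[ii] <- vl
    resid[ii] <- rms
  }
  new("B0Map", shift = shift, valid = valid, residual = resid)
}
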