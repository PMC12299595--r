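#' Tissue class for the synthetic phantom
#'
#' Bundles the saturation pool set and unsaturated signal level of one
#' tissue type. Every tissue must contain exactly one water pool at
#' 0 ppm; the WASSR acquisition of that tissue is simulated with a separate
#' low-power water line (`wassr_water`), since the weak WASSR saturation
#' pulse produces a narrower, shallower direct-saturation line and does not
#' excite the solute pools appreciably.
#'
#' @param name tissue label.
#' @param pools data.frame of [poolSpec()] rows (APTw acquisition pools).
#' @param s0_mean unsaturated signal level, arbitrary units (> 0).
#' @param wassr_water single [poolSpec()] row for the WASSR water line.
#' @return a validated list of class `tissue_class`.
#' @export
tissueClass <- function(name, pools, s0_mean = 1,
                        wassr_water = poolSpec(0, 0.6, 0.6)) {
  pools <- .validatePools(pools)
  nw <- sum(pools$center_ppm == 0)
  if (nw != 1L) stop("tissue '", name, "' must have exactly one water pool at 0 ppm")
  if (s0_mean <= 0) stop("s0_mean must be > 0")
  stopifnot(nrow(wassr_water) == 1L, wassr_water$center_ppm == 0)
  structure(list(name = name, pools = pools, s0_mean = s0_mean,
                 wassr_water = wassr_water),
            class = "tissue_class")
}

# Hippocampal amide saturation depths per experimental group, calibrated so
# that the noiseless model MTRasym(3.5 ppm) of hippocampal tissue is about
# -1.94% (CTRL-like) and -0.47% / -0.49% (endotoxemia-like): the NOE/MT
# background at -3.5 ppm outweighs the amide pool, so healthy tissue is net
# negative, and the inflamed groups move toward zero. Defaults only; tests
# never treat them as truth.
.groupAmide <- c(CTRL = 0.05030, LPS05 = 0.06513, LPS10 = 0.06494)

#' Default phantom tissue set
#'
#' Three tissue classes: `background` (outside the brain, near-zero signal),
#' `cortex` (brain parenchyma), and `hippocampus` (the analysis target whose
#' amide amplitude carries the group effect). Pool parameters: water
#' A = 0.85, FWHM 1.5 ppm; amide A per group at +3.5 ppm, FWHM 1.4 ppm
#' (continuous-wave saturation at APTw power broadens the amide line well
#' beyond its low-power width); NOE/MT background A = 0.07 at -3.5 ppm,
#' FWHM 1.5 ppm.
#'
#' @param amide_amplitude hippocampal amide saturation depth; defaults to
#'   the CTRL-like calibration.
#' @return named list of `tissue_class` objects.
#' @export
defaultTissues <- function(amide_amplitude = .groupAmide[["CTRL"]]) {
  water <- poolSpec(0, 0.85, 1.5)
  noe <- poolSpec(-3.5, 0.07, 1.5)
  list(
    background = tissueClass("background", poolSpec(0, 0.02, 1.0),
                             s0_mean = 0.05),
    cortex = tissueClass("cortex",
                         rbind(water, poolSpec(3.5, 0.045, 1.4), noe)),
    hippocampus = tissueClass("hippocampus",
                              rbind(water,
                                    poolSpec(3.5, amide_amplitude, 1.4),
                                    noe))
  )
}

#' Region layout for the phantom
#'
#' Assigns each voxel a tissue class and ROI membership: a centred
#' elliptical "brain" of cortex tissue containing two circular hippocampal
#' ROIs (left and right), on a background of near-zero signal. Geometry is
#' specified in fractions of the grid so the same layout scales from the
#' 16 x 16 test grid to the full 96 x 96 acquisition matrix.
#'
#' @param shape integer vector (rows, cols).
#' @return list with `class_map` (character matrix of tissue names),
#'   `brain_mask` (logical), and `roi_masks` (named list of logical masks
#'   `left_hippocampus`, `right_hippocampus`).
#' @export
regionLayout <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  R <- row(matrix(0, nr, nc)); C <- col(matrix(0, nr, nc))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  brain <- ((R - cy) / (0.42 * nr))^2 + ((C - cx) / (0.42 * nc))^2 <= 1
  rad <- max(1.9, 0.12 * min(nr, nc))
  hy <- cy + 0.08 * nr
  left <- ((R - hy)^2 + (C - 0.32 * nc)^2 <= rad^2) & brain
  right <- ((R - hy)^2 + (C - 0.68 * nc)^2 <= rad^2) & brain
  class_map <- matrix("background", nr, nc)
  class_map[brain] <- "cortex"
  class_map[left | right] <- "hippocampus"
  list(class_map = class_map, brain_mask = brain,
       roi_masks = list(left_hippocampus = left, right_hippocampus = right))
}

#' Phantom specification
#'
#' Everything needed to generate one subject's synthetic acquisition pair:
#' grid shape, tissue classes, region layout, B0 field amplitude, and noise
#' level. The B0 inhomogeneity is a smooth random low-order 2D polynomial
#' field scaled so its maximum absolute value equals `b0_amplitude_ppm`
#' (shimming residuals are spatially smooth); it must stay within reach of
#' the WASSR grid, i.e. at most 0.5 ppm in magnitude.
#'
#' @param shape grid shape (rows, cols); default 32 x 32. The full
#'   acquisition matrix (96 x 96) is available by passing `c(96, 96)`.
#' @param group one of `"CTRL"`, `"LPS05"`, `"LPS10"` selecting the
#'   calibrated hippocampal amide amplitude, or NULL if
#'   `amide_amplitude` is given directly.
#' @param amide_amplitude hippocampal amide saturation depth override.
#' @param b0_amplitude_ppm maximum absolute B0 shift of the smooth field,
#'   in ppm (|value| <= 0.5).
#' @param noise_sd additive Gaussian noise SD as a fraction of the tissue
#'   `s0_mean` (applied to S_sat and S0). Default 0.005 (0.5% of S0,
#'   i.e. SNR 200, typical of averaged preclinical CEST at 7 T).
#' @param tissues named list of `tissue_class` objects; the hippocampal
#'   amide amplitude is taken from `group`/`amide_amplitude`.
#' @param layout region layout as returned by [regionLayout()]; computed
#'   from `shape` when NULL.
#' @return validated list of class `phantom_spec`.
#' @export
phantomSpec <- function(shape = c(32, 32), group = "CTRL",
                        amide_amplitude = NULL,
                        b0_amplitude_ppm = 0.15, noise_sd = 0.005,
                        tissues = NULL, layout = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 4), all(shape == round(shape)))
  if (abs(b0_amplitude_ppm) > 0.5) {
    stop("|b0_amplitude_ppm| must be <= 0.5 ppm (WASSR grid reach)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(amide_amplitude)) {
    group <- match.arg(group, names(.groupAmide))
    amide_amplitude <- .groupAmide[[group]]
  }
  if (is.null(tissues)) tissues <- defaultTissues(amide_amplitude)
  if (is.null(layout)) layout <- regionLayout(shape)
  stopifnot(identical(dim(layout$class_map), as.integer(shape)))
  if (!all(layout$class_map %in% names(tissues))) {
    stop("layout assigns a tissue class with no tissue_class definition")
  }
  structure(list(shape = as.integer(shape), group = group,
                 amide_amplitude = amide_amplitude,
                 b0_amplitude_ppm = b0_amplitude_ppm, noise_sd = noise_sd,
                 tissues = tissues, layout = layout),
            class = "phantom_spec")
}

# smooth random low-order 2D polynomial field, max|.| scaled to `amplitude`
.makeB0Field <- function(shape, amplitude) {
  nr <- shape[1]; nc <- shape[2]
  if (amplitude == 0) return(matrix(0, nr, nc))
  X <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  cf <- stats::rnorm(6)
  f <- cf[1] * X + cf[2] * Y + cf[3] * X * Y +
    cf[4] * X^2 + cf[5] * Y^2 + 0.5 * cf[6] * (X^2 - Y^2)
  f <- f - mean(f)
  m <- max(abs(f))
  if (m == 0) return(matrix(0, nr, nc))
  f * amplitude / m
}

# evaluate the pool model for every voxel given a per-voxel b0 vector,
# vectorized over voxels: returns nvox x noffsets matrix
.modelMatrix <- function(b0_vec, offsets, pools) {
  z <- matrix(1, length(b0_vec), length(offsets))
  for (i in seq_len(nrow(pools))) {
    g2 <- pools$linewidth_ppm[i]^2 / 4
    d <- outer(-b0_vec, offsets, `+`) - pools$center_ppm[i]
    z <- z - pools$amplitude[i] * g2 / (d^2 + g2)
  }
  z
}

#' Generate one subject's synthetic acquisition pair
#'
#' Builds the APTw z-spectrum stack (full pool model), the WASSR stack
#' (low-power water line only, identical B0 field), and the ground truth:
#' the true B0 map, the analytic noiseless MTRasym map in percent, and the
#' ROI masks. Noise is additive Gaussian on S_sat and S0, independent per
#' voxel and offset. Identical `(spec, seed)` gives identical output.
#'
#' @param spec a [phantomSpec()].
#' @param aptw_grid,wassr_grid the two acquisition [OffsetGrid-class]s.
#' @param seed integer RNG seed.
#' @param analysis_ppm offset at which the ground-truth MTRasym map is
#'   evaluated (default 3.5).
#' @return list of class `cest_phantom` with elements `aptw`, `wassr`
#'   ([ZSpectrumStack-class]s), and `truth` (list: `b0_ppm`,
#'   `aptw_percent`, `roi_masks`, `brain_mask`, `class_map`).
#' @export
buildPhantom <- function(spec, aptw_grid = aptwOffsetGrid(),
                         wassr_grid = wassrOffsetGrid(), seed = 1L,
                         analysis_ppm = 3.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  nvox <- nr * nc
  class_vec <- as.vector(spec$layout$class_map)

  b0 <- .makeB0Field(spec$shape, spec$b0_amplitude_ppm)
  b0_vec <- as.vector(b0)

  ap_off <- aptw_grid@offsets
  wa_off <- wassr_grid@offsets
  sat_ap <- matrix(NA_real_, nvox, length(ap_off))
  sat_wa <- matrix(NA_real_, nvox, length(wa_off))
  s0_mean <- numeric(nvox)
  true_aptw <- numeric(nvox)

  for (nm in unique(class_vec)) {
    ti <- spec$tissues[[nm]]
    idx <- which(class_vec == nm)
    sat_ap[idx, ] <- ti$s0_mean *
      .modelMatrix(b0_vec[idx], ap_off, ti$pools)
    sat_wa[idx, ] <- ti$s0_mean *
      .modelMatrix(b0_vec[idx], wa_off, ti$wassr_water)
    s0_mean[idx] <- ti$s0_mean
    true_aptw[idx] <- trueMtrAsym(ti$pools, analysis_ppm)
  }

  if (spec$noise_sd > 0) {
    sd_vec <- spec$noise_sd * s0_mean
    sat_ap <- sat_ap + stats::rnorm(length(sat_ap)) * sd_vec
    sat_wa <- sat_wa + stats::rnorm(length(sat_wa)) * sd_vec
    s0_ap <- s0_mean + stats::rnorm(nvox) * sd_vec
    s0_wa <- s0_mean + stats::rnorm(nvox) * sd_vec
  } else {
    s0_ap <- s0_mean
    s0_wa <- s0_mean
  }

  aptw <- new("ZSpectrumStack",
              sSat = array(sat_ap, c(nr, nc, length(ap_off))),
              s0 = matrix(s0_ap, nr, nc), grid = aptw_grid)
  wassr <- new("ZSpectrumStack",
               sSat = array(sat_wa, c(nr, nc, length(wa_off))),
               s0 = matrix(s0_wa, nr, nc), grid = wassr_grid)
  structure(list(
    aptw = aptw, wassr = wassr,
    truth = list(b0_ppm = b0,
                 aptw_percent = matrix(true_aptw, nr, nc),
                 roi_masks = spec$layout$roi_masks,
                 brain_mask = spec$layout$brain_mask,
                 class_map = spec$layout$class_map),
    spec = spec, seed = as.integer(seed)),
    class = "cest_phantom")
}
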