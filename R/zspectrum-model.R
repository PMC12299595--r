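#' Saturation pool specification
#'
#' A single saturable proton pool in the multi-pool Lorentzian forward model.
#' `amplitude` is the peak saturation depth (fraction of normalized signal
#' removed on resonance), `linewidth_ppm` the full width at half maximum of
#' the Lorentzian line, and `center_ppm` its resonance offset from water.
#'
#' @param center_ppm resonance offset from water, in ppm.
#' @param amplitude peak saturation depth, in `[0, 1)`.
#' @param linewidth_ppm full width at half maximum, in ppm (> 0).
#' @return one-row data.frame; combine pools with `rbind()`.
#'
#' @examples
#' pools <- rbind(
#'   poolSpec(0, 0.9, 1.5),      # direct water saturation
#'   poolSpec(3.5, 0.05, 0.8),   # amide
#'   poolSpec(-3.5, 0.07, 1.5))  # NOE / MT background
#' zspectrumModel(c(-3.5, 0, 3.5), pools)
#' @export
poolSpec <- function(center_ppm, amplitude, linewidth_ppm) {
  stopifnot(is.finite(center_ppm), is.finite(amplitude),
            is.finite(linewidth_ppm))
  if (amplitude < 0) stop("pool amplitude must be >= 0")
  if (linewidth_ppm <= 0) stop("pool linewidth_ppm must be > 0")
  data.frame(center_ppm = center_ppm, amplitude = amplitude,
             linewidth_ppm = linewidth_ppm)
}

.validatePools <- function(pools) {
  stopifnot(is.data.frame(pools),
            all(c("center_ppm", "amplitude", "linewidth_ppm") %in%
                  names(pools)))
  if (any(pools$amplitude < 0)) stop("pool amplitudes must be >= 0")
  if (any(pools$linewidth_ppm <= 0)) stop("pool linewidths must be > 0")
  if (sum(pools$amplitude) >= 1) {
    stop("pool amplitudes must sum to < 1 (normalized signal must stay positive)")
  }
  pools
}

#' Multi-pool Lorentzian z-spectrum forward model
#'
#' Evaluates the normalized saturated signal
#' \deqn{Z(\Delta\omega) = 1 - \sum_i A_i \frac{\Gamma_i^2/4}
#'   {(\Delta\omega - \delta_i - b_0)^2 + \Gamma_i^2/4}}
#' at each requested offset, where pool i has depth \eqn{A_i}, FWHM
#' \eqn{\Gamma_i} and center \eqn{\delta_i}, and \eqn{b_0} is the voxel's
#' water frequency shift. This is the steady-state line-shape model the
#' whole synthetic phantom is built from; because it is closed-form it also
#' yields an analytic MTRasym oracle ([trueMtrAsym()]).
#'
#' @param offsets an [OffsetGrid-class] or numeric vector of offsets (ppm).
#' @param pools data.frame of pools from [poolSpec()]; amplitudes must sum
#'   to < 1.
#' @param b0_shift water frequency shift in ppm (default 0).
#' @return numeric vector of Z values in (0, 1], one per offset.
#' @export
zspectrumModel <- function(offsets, pools, b0_shift = 0) {
  x <- .asOffsets(offsets)
  pools <- .validatePools(pools)
  stopifnot(is.finite(b0_shift))
  z <- rep(1, length(x))
  for (i in seq_len(nrow(pools))) {
    g2 <- pools$linewidth_ppm[i]^2 / 4
    z <- z - pools$amplitude[i] * g2 /
      ((x - pools$center_ppm[i] - b0_shift)^2 + g2)
  }
  z
}

#' Analytic MTR asymmetry of a pool model
#'
#' Closed-form MTRasym of the noiseless, unshifted forward model:
#' `100 * (Z(-at_ppm) - Z(+at_ppm))` in percent. Used as the ground-truth
#' oracle against which the full normalize / B0-correct / MTRasym pipeline
#' is checked.
#'
#' @param pools data.frame of pools from [poolSpec()].
#' @param at_ppm analysis offset in ppm (default 3.5, the amide resonance).
#' @return MTRasym in percent.
#' @export
trueMtrAsym <- function(pools, at_ppm = 3.5) {
  z <- zspectrumModel(c(-at_ppm, at_ppm), pools, b0_shift = 0)
  100 * (z[1] - z[2])
}
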