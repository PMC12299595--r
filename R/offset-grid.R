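#' Build an evenly spaced offset grid
#'
#' Constructs the inclusive, ascending grid of saturation frequency offsets
#' used by an acquisition. The span must be an integer multiple of the step
#' (to within 1e-9 ppm), so that both endpoints land exactly on the grid.
#'
#' @param start_ppm,stop_ppm first and last offset in ppm (start <= stop).
#' @param step_ppm positive grid spacing in ppm.
#' @return an [OffsetGrid-class] with `round((stop-start)/step) + 1` offsets.
#'
#' @examples
#' length(makeOffsetGrid(-6, 6, 0.5))      # 25-point APTw grid
#' length(makeOffsetGrid(-0.8, 0.8, 0.05)) # 33-point WASSR grid
#' @export
makeOffsetGrid <- function(start_ppm, stop_ppm, step_ppm) {
  stopifnot(is.numeric(start_ppm), is.numeric(stop_ppm), is.numeric(step_ppm))
  if (step_ppm <= 0) stop("step_ppm must be > 0")
  if (stop_ppm < start_ppm) stop("stop_ppm must be >= start_ppm")
  span <- stop_ppm - start_ppm
  n_steps <- span / step_ppm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop(sprintf(
      "grid span (%g ppm) is not an integer multiple of step (%g ppm)",
      span, step_ppm))
  }
  n_steps <- round(n_steps)
  o <- start_ppm + step_ppm * seq.int(0L, n_steps)
  # pin the endpoint exactly despite floating-point accumulation
  o[length(o)] <- stop_ppm
  new("OffsetGrid", offsets = o)
}

#' @describeIn makeOffsetGrid the 25-point APTw acquisition grid,
#'   -6 to +6 ppm in 0.5 ppm steps.
#' @export
aptwOffsetGrid <- function() makeOffsetGrid(-6, 6, 0.5)

#' @describeIn makeOffsetGrid the 33-point WASSR acquisition grid,
#'   -0.8 to +0.8 ppm in 0.05 ppm steps.
#' @export
wassrOffsetGrid <- function() makeOffsetGrid(-0.8, 0.8, 0.05)

# accept either an OffsetGrid or a bare numeric vector of offsets
.asOffsets <- function(x) {
  if (is(x, "OffsetGrid")) x@offsets
  else if (is(x, "ZSpectrumStack")) x@grid@offsets
  else as.numeric(x)
}
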