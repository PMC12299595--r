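#' Render an APTw overlay image
#'
#' Draws the APTw map over the grayscale S0 image with a diverging
#' blue-white-red palette windowed to `window` (percent); invalid voxels
#' show the underlying anatomy only. Writes a PNG when `file` is given,
#' otherwise draws on the current device.
#'
#' @param map an [APTwMap-class].
#' @param s0_image numeric matrix for the anatomical underlay.
#' @param file optional PNG output path.
#' @param window APTw display window in percent, default `c(-5, 5)`.
#' @param mask optional logical matrix limiting the overlay.
#' @return invisibly, `file` (or NULL).
#' @export
plotAPTwOverlay <- function(map, s0_image, file = NULL, window = c(-5, 5),
                            mask = NULL) {
  stopifnot(is(map, "APTwMap"), is.matrix(s0_image))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(2, 2, 3, 6))
  on.exit(graphics::par(op), add = TRUE)
  img <- function(m, ...) {
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                    t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, xlab = "", ylab = "", ...)
  }
  img(s0_image, col = grDevices::gray.colors(128, 0, 1))
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  a <- map@aptw
  show <- map@valid
  if (!is.null(mask)) show <- show & mask
  a[!show] <- NA
  ac <- pmin(pmax(a, window[1]), window[2])
  graphics::par(new = TRUE)
  img(ac, col = pal, zlim = window)
  graphics::title(main = sprintf("APTw (MTRasym at 3.5 ppm), window [%g, %g]%%",
                                 window[1], window[2]))
  # simple colorbar in the right margin
  usr <- graphics::par("usr")
  xb <- usr[2] + 0.02 * diff(usr[1:2])
  graphics::par(xpd = TRUE)
  yy <- seq(usr[3], usr[4], length.out = 102)
  graphics::rect(xb, yy[-102], xb + 0.03 * diff(usr[1:2]), yy[-1],
                 col = pal, border = NA)
  graphics::text(xb + 0.05 * diff(usr[1:2]),
                 c(usr[3], mean(usr[3:4]), usr[4]),
                 labels = sprintf("%g%%", c(window[1], 0, window[2])),
                 adj = 0, cex = 0.9)
  invisible(file)
}
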