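#' Render a bullseye polar map to PNG
#'
#' Draws the polar raster as filled annular sectors (apex at the centre, base
#' at the rim), overlays the AHA segment boundaries, and adds an MBF colour
#' bar annotated with a green dashed line at the abnormal-flow threshold.
#' Unsampled (NaN) bins render neutral gray. Output is deterministic for a
#' fixed map and style.
#'
#' @param polar a `polar_map`.
#' @param threshold MBF threshold annotated on the colour bar.
#' @param path output PNG file.
#' @param width,height device size in pixels.
#' @param zlim colour range; defaults to c(0, 400) mL·min^-1·(100 g)^-1.
#' @return invisibly, `path`.
#' @export
render_polar_png <- function(polar, threshold = 200, path = "polar.png",
                             width = 640L, height = 560L, zlim = c(0, 400)) {
  stopifnot(inherits(polar, "polar_map"))
  nr <- nrow(polar$raster); na <- ncol(polar$raster)
  pal <- grDevices::hcl.colors(128, "Spectral", rev = TRUE)
  col_of <- function(v) {
    if (!is.finite(v)) return("gray70")
    i <- 1L + round((min(max(v, zlim[1]), zlim[2]) - zlim[1]) /
                      diff(zlim) * 127)
    pal[i]
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 2, 6), pty = "s")
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), axes = FALSE,
                 xlab = "", ylab = "", asp = 1,
                 main = "Stress MBF polar map (mL/min/100g)")
  for (ri in seq_len(nr)) {
    r0 <- (ri - 1) / nr; r1 <- ri / nr
    for (ai in seq_len(na)) {
      a0 <- (ai - 1) / na * 2 * pi; a1 <- ai / na * 2 * pi
      th <- seq(a0, a1, length.out = 6)
      graphics::polygon(c(r0 * cos(th), r1 * cos(rev(th))),
                        c(r0 * sin(th), r1 * sin(rev(th))),
                        col = col_of(polar$raster[ri, ai]), border = NA)
    }
  }
  # ring and segment boundaries
  thf <- seq(0, 2 * pi, length.out = 181)
  for (r in c(1 / 3, 2 / 3, 1))
    graphics::lines(r * cos(thf), r * sin(thf), col = "black")
  for (a in seq(0, 300, by = 60) * pi / 180) {
    graphics::segments(cos(a) / 3, sin(a) / 3, cos(a), sin(a))
  }
  for (a in (45 + seq(0, 270, by = 90)) * pi / 180) {
    graphics::segments(0, 0, cos(a) / 3, sin(a) / 3)
  }
  # colour bar with threshold annotation
  usr <- graphics::par("usr")
  xl <- usr[2] + 0.02 * diff(usr[1:2])
  graphics::par(xpd = NA)
  ny <- 128
  ys <- seq(-0.9, 0.9, length.out = ny + 1)
  for (i in seq_len(ny)) {
    graphics::rect(1.15, ys[i], 1.25, ys[i + 1], col = pal[i], border = NA)
  }
  graphics::rect(1.15, -0.9, 1.25, 0.9, border = "black")
  ticks <- pretty(zlim, 5)
  ticks <- ticks[ticks >= zlim[1] & ticks <= zlim[2]]
  ty <- -0.9 + (ticks - zlim[1]) / diff(zlim) * 1.8
  graphics::text(1.3, ty, labels = ticks, adj = 0, cex = 0.8)
  thr_y <- -0.9 + (min(max(threshold, zlim[1]), zlim[2]) - zlim[1]) /
    diff(zlim) * 1.8
  graphics::segments(1.12, thr_y, 1.28, thr_y, col = "green3", lty = 2, lwd = 2)
  graphics::text(1.3, thr_y, sprintf("thr %.0f", threshold), adj = 0,
                 cex = 0.8, col = "green4")
  invisible(path)
}
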