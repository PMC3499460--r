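# Base-graphics views of the main results.

#' Plot a turning-angle rose histogram
#'
#' Wedge length encodes the normalized frequency of travel in each 10-degree
#' sector; wedge color encodes the mean speed of the contributing steps.
#'
#' @param x a `rose_histogram` from [turning_angles()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.rose_histogram <- function(x, ...) {
  w <- x$wedges
  rmax <- max(w$frequency, 1e-9)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("turning angles (%s)", x$mode))
  spd <- w$mean_speed_um_s
  spd[!is.finite(spd)] <- 0
  pal <- grDevices::hcl.colors(32, "viridis")
  col_idx <- 1 + round(31 * (spd - min(spd)) / max(diff(range(spd)), 1e-9))
  for (i in seq_len(nrow(w))) {
    th <- seq(w$wedge_start_deg[i], w$wedge_end_deg[i],
              length.out = 8) * pi / 180
    graphics::polygon(c(0, w$frequency[i] * cos(th)),
                      c(0, w$frequency[i] * sin(th)),
                      col = pal[col_idx[i]], border = "grey30")
  }
  invisible(x)
}

#' Plot track-density or speed contour maps
#'
#' @param x a `contour_maps` object.
#' @param which `"density"` or `"speed"`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.contour_maps <- function(x, which = c("density", "speed"), ...) {
  which <- match.arg(which)
  z <- x[[which]]
  xs <- x$origin_nm[1] + x$box_nm * (seq_len(ncol(z)) - 0.5)
  ys <- x$origin_nm[2] + x$box_nm * (seq_len(nrow(z)) - 0.5)
  graphics::image(xs, ys, t(z), col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (nm)", ylab = "y (nm)",
                  main = sprintf("%s map (%.0f nm boxes)", which, x$box_nm),
                  ...)
  invisible(x)
}
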