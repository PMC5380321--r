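# Minimal base-graphics renderers used by the analysis drivers.

#' Render a concentration field
#'
#' Grey-to-black palette: black marks high concentration, light grey low.
#'
#' @param field Numeric matrix.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot_field <- function(field, main = "", ...) {
  stopifnot(is.matrix(field))
  pal <- grDevices::gray(seq(0.85, 0, length.out = 64))
  graphics::image(t(field), col = pal, axes = FALSE, main = main,
                  useRaster = TRUE, asp = nrow(field) / ncol(field), ...)
  invisible(field)
}

#' Render a Turing region, optionally with a trajectory overlay
#'
#' @param region A `turing_region_map`.
#' @param traj Optional `differentiation_trajectory` to overlay.
#' @param points Optional 2-column matrix of (S, Y) points to mark.
#' @param main Plot title.
#' @export
plot_region <- function(region, traj = NULL, points = NULL,
                        main = sprintf("Turing region (rho_H = %g)",
                                       region$rho_H)) {
  stopifnot(inherits(region, "turing_region_map"))
  graphics::image(region$S_axis, region$Y_axis, t(region$mask * 1),
                  col = c("white", "grey70"), xlab = "S", ylab = "Y",
                  main = main, useRaster = TRUE)
  graphics::box()
  if (!is.null(traj)) {
    graphics::lines(traj$S_values, traj$Y_values, col = "darkgreen", lwd = 2)
  }
  if (!is.null(points)) {
    graphics::points(points[, 1], points[, 2], pch = 19, col = "red")
  }
  invisible(region)
}
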