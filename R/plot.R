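# Base-graphics views of fields, meshes and traces.

#' Image plot of an Eulerian field
#'
#' @param field an [eulerian_field()] or matrix (then `grid` required).
#' @param grid grid for a plain matrix.
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @export
plot_field <- function(field, grid = NULL, main = "", ...) {
  if (inherits(field, "eulerian_field")) { grid <- field$grid; V <- field$values }
  else V <- field
  cc <- cell_centers(grid)
  graphics::image(cc$x, cc$y, V, asp = 1, xlab = "x", ylab = "y",
                  main = main, useRaster = TRUE, ...)
  invisible(NULL)
}

#' Outline plot of a Lagrangian mesh (current configuration)
#'
#' Draws a subsample of element edges; intended as a quick sanity view, not
#' a rendering tool.
#'
#' @param mesh a `lagrangian_mesh`.
#' @param max_elements at most this many elements are drawn.
#' @param add add to an existing plot.
#' @param ... passed to [graphics::segments()].
#' @export
plot_mesh <- function(mesh, max_elements = 5000, add = FALSE, ...) {
  el <- mesh$elements
  if (nrow(el) > max_elements)
    el <- el[round(seq(1, nrow(el), length.out = max_elements)), , drop = FALSE]
  p <- mesh$current
  if (!add)
    plot(NA, xlim = range(p[, 1]), ylim = range(p[, 2]), asp = 1,
         xlab = "x", ylab = "y")
  for (k in 1:3) {
    a <- el[, k]; b <- el[, k %% 3 + 1]
    graphics::segments(p[a, 1], p[a, 2], p[b, 1], p[b, 2], ...)
  }
  invisible(NULL)
}

#' Plot probe traces of a run
#'
#' @param run a `gs_run` with probes.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_probes <- function(run, ...) {
  pr <- run$probes
  graphics::matplot(pr$time, as.matrix(pr[, -1, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time", ylab = "V", ...)
  invisible(NULL)
}
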