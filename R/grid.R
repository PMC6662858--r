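# Regular Cartesian ghost-box grid and the staggered-grid anisotropic
# diffusion operator.

#' Build a regular Cartesian ghost-box grid
#'
#' The ghost box \eqn{\Omega} is discretized by an \eqn{N_1 \times N_2} grid of
#' cells; all fields live at cell centers, with the center of cell
#' \eqn{(i, j)} at \eqn{\mathrm{lo} + ((i + 1/2)\Delta x_1, (j + 1/2)\Delta
#' x_2)}, \eqn{i = 0, \ldots, N_1 - 1}.
#'
#' @param extent numeric length-4 vector `c(x_lo, x_hi, y_lo, y_hi)`, or a
#'   2x2 matrix with columns `(lo, hi)` per axis.
#' @param n1,n2 cell counts per axis (at least 4).
#' @return An object of class `cartesian_grid` with fields `lo`, `hi`,
#'   `n1`, `n2`, `dx1`, `dx2`.
#' @examples
#' g <- build_grid(c(-0.1, 2.6, -0.1, 2.6), 275, 275)
#' g$dx1  # 2.7 / 275
#' @export
build_grid <- function(extent, n1, n2) {
  if (is.matrix(extent)) extent <- c(extent[1, ], extent[2, ])
  stopifnot(length(extent) == 4)
  lo <- c(extent[1], extent[3])
  hi <- c(extent[2], extent[4])
  if (!all(is.finite(c(lo, hi))) || any(hi <= lo))
    stop("build_grid: extent must be finite and non-degenerate (hi > lo)")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 4L || n2 < 4L)
    stop("build_grid: n1 and n2 must be integers >= 4")
  structure(
    list(lo = lo, hi = hi, n1 = n1, n2 = n2,
         dx1 = (hi[1] - lo[1]) / n1, dx2 = (hi[2] - lo[2]) / n2),
    class = "cartesian_grid")
}

#' @export
print.cartesian_grid <- function(x, ...) {
  cat(sprintf("<cartesian_grid> [%g, %g] x [%g, %g], %d x %d cells, dx = (%g, %g)\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$n1, x$n2, x$dx1, x$dx2))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [build_grid()] object.
#' @return list with vectors `x` (length `n1`) and `y` (length `n2`).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "cartesian_grid"))
  list(x = grid$lo[1] + (seq_len(grid$n1) - 0.5) * grid$dx1,
       y = grid$lo[2] + (seq_len(grid$n2) - 0.5) * grid$dx2)
}

#' Scalar field at the cell centers of a grid
#'
#' @param grid a [build_grid()] object.
#' @param values an `n1 x n2` numeric matrix (`values[i, j]` is cell
#'   `(i - 1, j - 1)`), or a single number to fill with.
#' @return An object of class `eulerian_field` (list with `grid`, `values`).
#' @export
eulerian_field <- function(grid, values = 0) {
  stopifnot(inherits(grid, "cartesian_grid"))
  if (length(values) == 1L) values <- matrix(values, grid$n1, grid$n2)
  if (!is.matrix(values) || nrow(values) != grid$n1 || ncol(values) != grid$n2)
    stop("eulerian_field: values must be an n1 x n2 matrix matching the grid")
  if (!all(is.finite(values)))
    stop("eulerian_field: values must be finite")
  structure(list(grid = grid, values = values), class = "eulerian_field")
}

field_values <- function(field) {
  if (inherits(field, "eulerian_field")) field$values else field
}

#' Conductivity tensor of the tissue
#'
#' Axis-aligned diagonal conductivities: `sigma_l` acts along axis 1
#' (longitudinal), `sigma_t` along axis 2 (transversal).  The extracellular
#' conductivities may be given either through the equal-anisotropy ratio
#' `lambda` (\eqn{\sigma_e = \lambda \sigma_i}) or per direction.
#'
#' @param sigma_l,sigma_t intracellular conductivities (S/m, or the
#'   dimensionless diffusion coefficients of a normalized model).
#' @param lambda extracellular/intracellular anisotropy ratio, or `NULL` when
#'   per-direction extracellular values are given.
#' @param sigma_e_l,sigma_e_t per-direction extracellular conductivities.
#' @return object of class `conductivity_tensor`.
#' @export
conductivity_tensor <- function(sigma_l, sigma_t, lambda = NULL,
                                sigma_e_l = NULL, sigma_e_t = NULL) {
  if (is.null(lambda) && (is.null(sigma_e_l) || is.null(sigma_e_t)))
    stop("conductivity_tensor: give either lambda or both extracellular values")
  if (!is.null(lambda)) {
    sigma_e_l <- lambda * sigma_l
    sigma_e_t <- lambda * sigma_t
  }
  vals <- c(sigma_l, sigma_t, sigma_e_l, sigma_e_t)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("conductivity_tensor: all conductivities must be positive")
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t,
                 sigma_e_l = sigma_e_l, sigma_e_t = sigma_e_t,
                 lambda = if (is.null(lambda)) NA_real_ else lambda),
            class = "conductivity_tensor")
}

#' Effective monodomain conductivities
#'
#' Per-direction harmonic combination \eqn{\sigma = \sigma_i \sigma_e /
#' (\sigma_i + \sigma_e)}, which reduces exactly to \eqn{\lambda/(1+\lambda)
#' \, \sigma_i} under equal anisotropy \eqn{\sigma_e = \lambda \sigma_i}.
#' Measured human ventricular conductivities violate equal anisotropy, so the
#' per-direction form is what makes them usable in a monodomain solver.
#'
#' @param cond a [conductivity_tensor()].
#' @return named numeric vector `c(l = ..., t = ...)`.
#' @export
monodomain_conductivity <- function(cond) {
  stopifnot(inherits(cond, "conductivity_tensor"))
  c(l = cond$sigma_l * cond$sigma_e_l / (cond$sigma_l + cond$sigma_e_l),
    t = cond$sigma_t * cond$sigma_e_t / (cond$sigma_t + cond$sigma_e_t))
}

#' Staggered-grid anisotropic Laplacian
#'
#' Applies \eqn{\sigma_l \partial^2_{x_1} + \sigma_t \partial^2_{x_2}} with
#' standard second differences at cell centers.  Cells on the edge of the box
#' see a one-cell ghost ring held at the homogeneous Dirichlet value `vrest`.
#'
#' @param field an [eulerian_field()] or a plain `n1 x n2` matrix (then
#'   `grid` is required).
#' @param cond a [conductivity_tensor()] (its intracellular values are used
#'   directly), or a numeric length-2 vector `c(sigma_l, sigma_t)`.
#' @param grid grid for a plain-matrix `field`.
#' @param vrest Dirichlet ring value (resting potential), default 0.
#' @return object of the same kind as `field` holding the operator values.
#' @export
anisotropic_laplacian <- function(field, cond, grid = NULL, vrest = 0) {
  wrap <- inherits(field, "eulerian_field")
  if (wrap) {
    grid <- field$grid
    V <- field$values
  } else {
    if (is.null(grid)) stop("anisotropic_laplacian: grid required for a plain matrix")
    V <- field
  }
  if (nrow(V) != grid$n1 || ncol(V) != grid$n2)
    stop("anisotropic_laplacian: field shape does not match the grid")
  s <- if (inherits(cond, "conductivity_tensor")) c(cond$sigma_l, cond$sigma_t) else cond
  out <- .laplacian_cpp(V, s[1], s[2], grid$dx1, grid$dx2, vrest)
  if (wrap) eulerian_field(grid, out) else out
}
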