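# Delta-kernel coupling between the Lagrangian structure and the Eulerian
# ghost grid: kernel evaluation, spreading, interpolation, and the L2
# projection of quadrature values back to mesh nodes.

#' The one-dimensional four-point smoothed delta kernel
#'
#' Piecewise cubic with support `|r| < 2`:
#' \deqn{\Psi(r) = \tfrac12 (|r|+1)(|r|-1)(|r|-2), \quad |r| \le 1}
#' \deqn{\Psi(r) = -\tfrac16 (|r|-1)(|r|-2)(|r|-3), \quad 1 < |r| < 2}
#' and zero otherwise.  It satisfies the partition of unity
#' \eqn{\sum_{j \in Z} \Psi(r - j) = 1} and reproduces linear functions, so
#' the induced spreading/interpolation pair is conservative and second-order
#' accurate.  The two-dimensional kernel is the tensor product
#' \eqn{\delta_h(x) = \Psi(x_1/\Delta x_1)\Psi(x_2/\Delta x_2) /
#' (\Delta x_1 \Delta x_2)}; the normalization makes spreading and
#' interpolation mutually adjoint and exact on constants.
#'
#' @param r numeric vector of signed distances in grid units.
#' @return kernel values, same length as `r`.
#' @examples
#' psi(0)            # 1
#' psi(c(0.5, 1.5))  # 0.5625, -0.0625
#' @export
psi <- function(r) .psi_cpp(as.numeric(r))

#' Spread Lagrangian quadrature values to the Eulerian grid
#'
#' Each quadrature point \eqn{X_Q} contributes
#' \eqn{q_Q \, \omega_Q \, \delta_h(x - \chi(X_Q))} to the (at most) 16 cell
#' centers within two cells of it.  Spreading a density that is constant over
#' the structure therefore conserves its integral exactly (partition of
#' unity).
#'
#' @param values numeric vector of quadrature-point values \eqn{q_Q}.
#' @param mesh a `lagrangian_mesh` (current positions and weights are used).
#' @param grid host [build_grid()].
#' @return an [eulerian_field()].
#' @export
spread <- function(values, mesh, grid) {
  stopifnot(inherits(mesh, "lagrangian_mesh"), inherits(grid, "cartesian_grid"))
  if (length(values) == 1L) values <- rep(values, nrow(mesh$quad_current))
  stopifnot(length(values) == nrow(mesh$quad_current))
  vals <- .spread_cpp(mesh$quad_current[, 1], mesh$quad_current[, 2],
                      as.numeric(values) * mesh$quad_w,
                      grid$n1, grid$n2, grid$lo[1], grid$lo[2],
                      grid$dx1, grid$dx2)
  eulerian_field(grid, vals)
}

#' Interpolate an Eulerian field to arbitrary positions
#'
#' \eqn{\tilde V(X) = \sum_{i,j} V(x_{i,j}) \, \delta_h(x_{i,j} - X)\,
#' \Delta x_1 \Delta x_2}, a 4x4-cell tensor-product stencil.  Constants are
#' reproduced exactly and (by the kernel's moment condition) so are linear
#' fields.
#'
#' @param field an [eulerian_field()] or a plain matrix (then `grid` is
#'   required).
#' @param positions `n x 2` matrix of physical positions, or a
#'   `lagrangian_mesh` (its current quadrature positions are used).
#' @param grid grid for a plain-matrix `field`.
#' @return numeric vector of interpolated values.
#' @export
interpolate <- function(field, positions, grid = NULL) {
  if (inherits(field, "eulerian_field")) {
    grid <- field$grid; V <- field$values
  } else {
    if (is.null(grid)) stop("interpolate: grid required for a plain matrix")
    V <- field
  }
  if (inherits(positions, "lagrangian_mesh")) positions <- positions$quad_current
  positions <- matrix(as.numeric(positions), ncol = 2)
  .interp_cpp(positions[, 1], positions[, 2], V,
              grid$lo[1], grid$lo[2], grid$dx1, grid$dx2)
}

#' Finite-element mass matrix of the Lagrangian mesh
#'
#' \eqn{M_{lm} = \sum_Q \varphi_l(X_Q)\varphi_m(X_Q)\,\omega_Q}, assembled
#' with the same quadrature rule as spreading (consistent mass), or its
#' row-sum lumped diagonal.
#'
#' @param mesh a `lagrangian_mesh`.
#' @param lumped return the lumped diagonal as a vector instead.
#' @return a sparse symmetric [Matrix::Matrix] (or a numeric vector when
#'   `lumped = TRUE`).
#' @export
mass_matrix <- function(mesh, lumped = FALSE) {
  w <- mesh$quad_w
  idx <- mesh$quad_nodes
  bar <- mesh$quad_basis
  if (lumped)
    return(.project_rhs_cpp(idx, bar, rep(1, length(w)), w,
                            nrow(mesh$nodes)))
  ii <- jj <- vector("list", 9L); xx <- vector("list", 9L); k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- idx[, a]; jj[[k]] <- idx[, b]
    xx[[k]] <- bar[, a] * bar[, b] * w
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = rep(nrow(mesh$nodes), 2))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Project quadrature-point values onto mesh nodes (L2 projection)
#'
#' Solves \eqn{M c = b} with \eqn{b_l = \sum_Q \varphi_l(X_Q) q_Q \omega_Q};
#' constants and (with the default degree-2 rule) linear functions are
#' recovered exactly.  With `lumped = TRUE` the diagonal lumped mass is used
#' instead of the consistent solve.
#'
#' @param values numeric vector of quadrature-point values.
#' @param mesh a `lagrangian_mesh`.
#' @param lumped use the lumped (diagonal) mass matrix.
#' @param factor optional pre-computed Cholesky factorization of the
#'   consistent mass matrix (see [Matrix::Cholesky()]); reuse it across many
#'   projections on a stationary mesh.
#' @return numeric vector of nodal values.
#' @export
project_to_nodes <- function(values, mesh, lumped = FALSE, factor = NULL) {
  stopifnot(length(values) == nrow(mesh$quad_nodes))
  b <- .project_rhs_cpp(mesh$quad_nodes, mesh$quad_basis,
                        as.numeric(values), mesh$quad_w, nrow(mesh$nodes))
  if (lumped) {
    ml <- mass_matrix(mesh, lumped = TRUE)
    out <- ifelse(ml > 0, b / ml, 0)
    return(out)
  }
  if (is.null(factor)) {
    M <- mass_matrix(mesh)
    factor <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, perm = TRUE),
                       error = function(e)
                         stop("project_to_nodes: singular mass matrix (",
                              conditionMessage(e), ")"))
  }
  as.numeric(Matrix::solve(factor, b, system = "A"))
}
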