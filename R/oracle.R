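# Direct conforming-grid finite-difference solver of the normalized
# reaction-diffusion system on a rectangle.  This is a deliberately
# independent solution path (no Lagrangian structure, no delta-kernel
# transfer): both potential and recovery live on the same grid cells and the
# coupled system is advanced by the method of lines.  Used to verify the
# ghost-structure solver on conforming geometry.

#' Direct finite-difference solve of the FitzHugh-Nagumo system
#'
#' Solves \eqn{\partial u/\partial t = K_x u_{xx} + K_y u_{yy} + u(1-u)(u-a)
#' - v}, \eqn{\partial v/\partial t = \varepsilon(\beta u - \gamma v -
#' \sigma)} on the rectangle covered by `grid`, with homogeneous Dirichlet
#' values (0) on a one-cell ghost ring, using TVD-RK3 on the fully coupled
#' system.
#'
#' @param grid a [build_grid()] covering exactly the physical rectangle.
#' @param u0,v0 initial `n1 x n2` matrices.
#' @param params a [fhn_params()] list (supplies `Kx`, `Ky` too).
#' @param dt time step.
#' @param n_steps number of steps.
#' @return list with final `u`, `v` matrices and `t`.
#' @export
fd_monodomain_solve <- function(grid, u0, v0, params = fhn_params(), dt,
                                n_steps) {
  n1 <- grid$n1; n2 <- grid$n2
  stopifnot(all(dim(u0) == c(n1, n2)), all(dim(v0) == c(n1, n2)))
  rhs <- function(state, t) {
    u <- matrix(state[seq_len(n1 * n2)], n1, n2)
    v <- matrix(state[n1 * n2 + seq_len(n1 * n2)], n1, n2)
    du <- .laplacian_cpp(u, params$Kx, params$Ky, grid$dx1, grid$dx2, 0) +
      fhn_current(u, v, params)
    dv <- fhn_recovery_rhs(u, v, params)
    c(du, dv)
  }
  state <- c(u0, v0)
  t <- 0
  for (s in seq_len(n_steps)) {
    state <- rk3_step(rhs, state, dt, t)
    t <- t + dt
  }
  list(u = matrix(state[seq_len(n1 * n2)], n1, n2),
       v = matrix(state[n1 * n2 + seq_len(n1 * n2)], n1, n2), t = t)
}
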