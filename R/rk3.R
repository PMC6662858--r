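# Third-order TVD (Shu-Osher) Runge-Kutta stepping.

#' One TVD-RK3 step
#'
#' Three-stage explicit scheme
#' \deqn{s_1 = s^n + \Delta t\, L(s^n)}
#' \deqn{s_2 = s_1 + \tfrac{\Delta t}{4} [-3 L(s^n) + L(s_1)]}
#' \deqn{s^{n+1} = s_2 + \tfrac{\Delta t}{12} [-L(s^n) - L(s_1) + 8 L(s_2)]}
#' equivalent to the classical Shu-Osher convex-combination form; for linear
#' \eqn{L(s) = \lambda s} the amplification factor is \eqn{1 + z + z^2/2 +
#' z^3/6} with \eqn{z = \lambda \Delta t}, and time-dependent sources are
#' integrated by Simpson's rule (exact for cubics in t).
#'
#' @param rhs function `rhs(state, t)` returning the time derivative (same
#'   shape as `state`).
#' @param state numeric vector or matrix.
#' @param dt step size (> 0).
#' @param t current time passed through to `rhs` (stages see `t`, `t + dt`,
#'   `t + dt/2`).
#' @return the state after one step.
#' @export
rk3_step <- function(rhs, state, dt, t = 0) {
  stopifnot(dt > 0)
  k0 <- rhs(state, t)
  s1 <- state + dt * k0
  if (!all(is.finite(s1))) stop("rk3_step: non-finite value after stage 1")
  k1 <- rhs(s1, t + dt)
  s2 <- s1 + dt * 0.25 * (-3 * k0 + k1)
  if (!all(is.finite(s2))) stop("rk3_step: non-finite value after stage 2")
  k2 <- rhs(s2, t + dt / 2)
  out <- s2 + dt / 12 * (-k0 - k1 + 8 * k2)
  if (!all(is.finite(out))) stop("rk3_step: non-finite value after stage 3")
  out
}

#' One TVD-RK3 step of the membrane state ODEs
#'
#' Advances the Lagrangian state of every node with the cell model's `rhs`,
#' holding the nodal potential `vtilde` frozen across the three stages: the
#' gates are updated *after* the potential update of the same step, using the
#' freshly interpolated potential.
#'
#' @param model a [cell_model()].
#' @param vtilde numeric vector of nodal potentials (frozen).
#' @param y state matrix (`n x state_dim`).
#' @param dt step size.
#' @param t current time passed to `rhs`.
#' @return the updated state matrix.
#' @export
rk3_ode_step <- function(model, vtilde, y, dt, t = 0) {
  f <- function(yy, tt) model$rhs(vtilde, yy, tt)
  rk3_step(f, y, dt, t)
}
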