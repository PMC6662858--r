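# Membrane kinetics: the generic cell-model contract, the FitzHugh-Nagumo
# model, and a plateau-morphology surrogate ventricular model.

#' Cell-model contract
#'
#' A cell model couples to the monodomain solver through two functions: the
#' state right-hand side `rhs(vtilde, y, t)` giving \eqn{dy/dt}, and the
#' ionic current `current(vtilde, y)` giving \eqn{\tilde I_{ion}}.  Both must
#' be vectorized over points: `vtilde` is a numeric vector, `y` a matrix with
#' `state_dim` columns (one row per point).
#'
#' The solver advances the potential as \eqn{\partial V/\partial t = D\nabla^2
#' V - c (I_{ion} + I_s)}, i.e. the current is *subtracted*; `current()` must
#' return values in that convention.  `current_sign` records the sign of the
#' underlying model's printed ionic term (+1 when it *adds* to
#' \eqn{\partial V/\partial t}, as in the normalized FitzHugh-Nagumo
#' equations, in which case the adapter negates it), so that one solver loop
#' serves both conventions without silent sign errors.
#'
#' @param name model identifier.
#' @param state_dim number of Lagrangian state variables.
#' @param rhs,current the two coupling functions described above.
#' @param initial_state numeric vector of length `state_dim`.
#' @param rest_potential the resting potential (also the ghost-ring Dirichlet
#'   value).
#' @param current_sign +1 or -1, see above.
#' @param observables named list of accessor functions `function(y)` mapping
#'   the state matrix to a named per-point observable (e.g. intracellular
#'   calcium).
#' @param params parameter list, kept for provenance.
#' @return object of class `cell_model`.
#' @export
cell_model <- function(name, state_dim, rhs, current, initial_state,
                       rest_potential = 0, current_sign = -1,
                       observables = list(), params = list()) {
  stopifnot(is.function(rhs), is.function(current),
            length(initial_state) == state_dim,
            all(is.finite(initial_state)), is.finite(rest_potential))
  structure(list(name = name, state_dim = as.integer(state_dim), rhs = rhs,
                 current = current, initial_state = as.numeric(initial_state),
                 rest_potential = rest_potential, current_sign = current_sign,
                 observables = observables, params = params),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %s: %d state variable(s), V_rest = %g\n",
              x$name, x$state_dim, x$rest_potential))
  invisible(x)
}

#' FitzHugh-Nagumo parameters
#'
#' Defaults are the spiral-wave benchmark values `a = 0.1`, `epsilon = 0.01`,
#' `beta = 0.5`, `gamma = 1`, `sigma = 0` with isotropic diffusion
#' `Kx = Ky = 1e-4` (all dimensionless).
#'
#' @param a excitation threshold of the cubic nonlinearity.
#' @param epsilon time-scale separation of the recovery variable.
#' @param beta,gamma,sigma recovery kinetics coefficients.
#' @param Kx,Ky diffusion coefficients per axis.
#' @export
fhn_params <- function(a = 0.1, epsilon = 0.01, beta = 0.5, gamma = 1,
                       sigma = 0, Kx = 1e-4, Ky = 1e-4) {
  list(a = a, epsilon = epsilon, beta = beta, gamma = gamma, sigma = sigma,
       Kx = Kx, Ky = Ky)
}

#' FitzHugh-Nagumo ionic term and recovery right-hand side
#'
#' `fhn_current()` is the cubic ionic term \eqn{u(1-u)(u-a) - v} in the
#' model's native convention (it *adds* to \eqn{\partial u/\partial t});
#' `fhn_recovery_rhs()` is \eqn{\varepsilon(\beta u - \gamma v - \sigma)}.
#'
#' @param u normalized transmembrane potential.
#' @param v recovery variable.
#' @param params a [fhn_params()] list.
#' @export
fhn_current <- function(u, v, params = fhn_params()) {
  u * (1 - u) * (u - params$a) - v
}

#' @rdname fhn_current
#' @export
fhn_recovery_rhs <- function(u, v, params = fhn_params()) {
  params$epsilon * (params$beta * u - params$gamma * v - params$sigma)
}

#' The FitzHugh-Nagumo cell model
#'
#' One Lagrangian state variable (the recovery variable `v`), resting state
#' `(u, v) = (0, 0)`.  The adapter registers the cubic term negated so that
#' the solver's generic subtract-the-current update reproduces the native
#' add-the-current form exactly.
#'
#' @param params a [fhn_params()] list.
#' @return a [cell_model()].
#' @export
fhn_model <- function(params = fhn_params()) {
  cell_model(
    name = "fhn", state_dim = 1L,
    rhs = function(vtilde, y, t = 0)
      matrix(fhn_recovery_rhs(vtilde, y[, 1], params), ncol = 1),
    current = function(vtilde, y) -fhn_current(vtilde, y[, 1], params),
    initial_state = 0, rest_potential = 0, current_sign = +1,
    params = params)
}

#' Surrogate ventricular cell model (plateau action potential)
#'
#' A phenomenological three-quantity model for ventricular demonstrations: a
#' fast inward/slow outward current pair gated by a single recovery variable
#' `h` produces a plateau-shaped action potential with an upstroke (phase 0),
#' plateau (phase 2), repolarization (phase 3) and rest (phase 4), plus an
#' effective refractory period (the gate `h` must reopen before a second
#' upstroke is possible).  A phenomenological intracellular-calcium pulse
#' `ca` relaxes toward an activation level that tracks the upstroke, standing
#' in for the calcium transient of detailed ionic models.  It is *not* a
#' biophysically detailed human ventricular model; it provides the
#' plateau morphology and refractoriness needed for activation-sequence
#' studies at tissue scale.
#'
#' State: `y = (h, ca)`; membrane potential is dimensional (mV) with
#' normalized drive `u = (V - v_rest) / v_amp`.  The ionic current is
#' returned in uA/cm^2 in the subtract-the-current solver convention.
#'
#' @param v_rest resting potential (mV).
#' @param v_amp action-potential amplitude scale (mV).
#' @param tau_in,tau_out fast inward / slow outward time constants (ms);
#'   their ratio sets the excitation threshold.
#' @param tau_open,tau_close gate recovery / inactivation constants (ms);
#'   `tau_close` sets the plateau duration.
#' @param u_gate normalized gate-switch threshold.
#' @param cm membrane capacitance (uF/cm^2) used to convert the normalized
#'   reaction rate to a current density.
#' @param ca_rest,ca_amp,tau_ca resting level, pulse amplitude and relaxation
#'   time (ms) of the calcium observable (arbitrary concentration units).
#' @return a [cell_model()] with observable `calcium`.
#' @export
surrogate_ventricular_model <- function(v_rest = -85, v_amp = 100,
                                        tau_in = 0.3, tau_out = 6,
                                        tau_open = 120, tau_close = 150,
                                        u_gate = 0.13, cm = 1,
                                        ca_rest = 0.1, ca_amp = 1,
                                        tau_ca = 30) {
  params <- list(v_rest = v_rest, v_amp = v_amp, tau_in = tau_in,
                 tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, u_gate = u_gate, cm = cm,
                 ca_rest = ca_rest, ca_amp = ca_amp, tau_ca = tau_ca)
  cell_model(
    name = "surrogate_ventricular", state_dim = 2L,
    rhs = function(vtilde, y, t = 0) {
      u <- (vtilde - v_rest) / v_amp
      h <- y[, 1]; ca <- y[, 2]
      dh <- ifelse(u < u_gate, (1 - h) / tau_open, -h / tau_close)
      drive <- pmin(pmax(u, 0), 1)^2
      dca <- (ca_rest + ca_amp * drive - ca) / tau_ca
      cbind(dh, dca)
    },
    current = function(vtilde, y) {
      u <- (vtilde - v_rest) / v_amp
      -cm * v_amp * (y[, 1] * u^2 * (1 - u) / tau_in - u / tau_out)
    },
    initial_state = c(1, ca_rest), rest_potential = v_rest,
    current_sign = -1,
    observables = list(calcium = function(y) y[, 2]),
    params = params)
}

#' Integrate a cell model at a single point (0-D)
#'
#' Advances the coupled potential/state system of one isolated cell (no
#' diffusion) with the solver's TVD-RK3 splitting: the potential is stepped
#' first with the state frozen, then the state with the fresh potential
#' frozen.  Useful for threshold and restitution studies and as the
#' space-free reference for the tissue solver.
#'
#' @param model a [cell_model()].
#' @param v0 initial potential; defaults to the resting potential.
#' @param y0 initial state; defaults to the model's `initial_state`.
#' @param dt time step.
#' @param n_steps number of steps.
#' @param stim optional function `function(t)` returning a stimulus current
#'   (same units and convention as `model$current`).
#' @param cur_scale factor multiplying the subtracted current (1/Cm for
#'   dimensional models; 1 for normalized models).
#' @return data.frame with `time`, `V`, state columns, and observables.
#' @export
integrate_cell <- function(model, v0 = NULL, y0 = NULL, dt = 0.1,
                           n_steps = 1000, stim = NULL, cur_scale = 1) {
  stopifnot(inherits(model, "cell_model"))
  v <- if (is.null(v0)) model$rest_potential else v0
  y <- matrix(if (is.null(y0)) model$initial_state else y0, nrow = 1)
  nt <- n_steps + 1L
  out <- matrix(NA_real_, nt, 2L + model$state_dim)
  out[1, ] <- c(0, v, y)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    rhs_v <- function(vv, tt) {
      i <- model$current(vv, y)
      if (!is.null(stim)) i <- i + stim(tt)
      -cur_scale * i
    }
    v <- rk3_step(rhs_v, v, dt, t)
    y <- rk3_ode_step(model, v, y, dt, t)
    out[s + 1L, ] <- c(s * dt, v, y)
  }
  df <- as.data.frame(out)
  names(df) <- c("time", "V", paste0("y", seq_len(model$state_dim)))
  for (nm in names(model$observables))
    df[[nm]] <- model$observables[[nm]](df[, 2L + seq_len(model$state_dim),
                                            drop = FALSE] |> as.matrix())
  df
}
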