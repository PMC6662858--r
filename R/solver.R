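# The ghost-structure monodomain solver: problem setup, one coupled step,
# and the full simulation loop (reference R path and compiled fast path).

#' Effective diffusion and current scaling of the monodomain equation
#'
#' Centralizes the unit bookkeeping.  In `"dimensionless"` units the
#' diffusion coefficients are used as given and the current scale is 1
#' (Cm = Am = 1), making the normalized reaction-diffusion system a literal
#' special case of the monodomain equation.  In `"physiological"` units the
#' equation is evaluated in (mV, ms, mm, S/m, uF/cm^2, um^-1):
#' \eqn{D = \sigma_{mono} / (A_m C_m)} converted to mm^2/ms, and the
#' subtracted current (uA/cm^2) is scaled by \eqn{1/C_m} to mV/ms.
#'
#' @param sigma_mono named vector `c(l = , t = )` of effective monodomain
#'   conductivities (S/m), e.g. from [monodomain_conductivity()]; or the
#'   dimensionless diffusion coefficients.
#' @param Cm membrane capacitance (uF/cm^2).
#' @param Am surface-to-volume ratio (um^-1).
#' @param units `"dimensionless"` or `"physiological"`.
#' @return list with `diff` (length-2 diffusion coefficients, grid units^2
#'   per time unit) and `cur_scale`.
#' @export
monodomain_coefficients <- function(sigma_mono, Cm = 1, Am = 1,
                                    units = c("dimensionless", "physiological")) {
  units <- match.arg(units)
  sigma_mono <- as.numeric(sigma_mono)
  stopifnot(length(sigma_mono) == 2, all(sigma_mono > 0), Cm > 0, Am > 0)
  if (units == "dimensionless") {
    list(diff = sigma_mono, cur_scale = 1)
  } else {
    # sigma [S/m] / (Am [1/um] * 1e6 [um/m] * Cm [uF/cm^2] * 1e-2 [F m^-2 per
    # uF cm^-2]) = D [m^2/s]; times 1e-3 * 1e6 -> mm^2/ms
    d_si <- sigma_mono / (Am * 1e6 * Cm * 1e-2)
    list(diff = d_si * 1e3, cur_scale = 1 / Cm)
  }
}

#' Stimulus protocol on the Lagrangian structure
#'
#' Adds the amplitude to the Lagrangian stimulation current of all quadrature
#' points in the active regions during `[start, start + duration)`.  The
#' amplitude is signed in the solver's subtract-the-current convention, so a
#' *depolarizing* stimulus has negative amplitude.
#'
#' @param regions named list of quadrature-point index vectors (or logical
#'   masks); all listed regions receive the stimulus.
#' @param amplitude signed current amplitude (model units, e.g. uA/cm^2).
#' @param start,duration stimulus window; `duration > 0`.
#' @param mode optional label (`"healthy"`, `"lbbb"`) kept for provenance.
#' @export
stimulus_protocol <- function(regions, amplitude, start = 0, duration,
                              mode = NULL) {
  stopifnot(is.list(regions), length(regions) >= 1, duration > 0)
  structure(list(regions = regions, amplitude = amplitude, start = start,
                 duration = duration, mode = mode),
            class = "stimulus_protocol")
}

#' Apply a stimulus protocol to quadrature-point current values
#'
#' @param values numeric vector of Lagrangian current values (one per
#'   quadrature point).
#' @param protocol a [stimulus_protocol()] (or NULL for no stimulus).
#' @param t current time.
#' @return `values` with the amplitude added inside active regions when `t`
#'   lies in the stimulus window; unchanged otherwise.
#' @export
apply_stimulus <- function(values, protocol, t) {
  if (is.null(protocol)) return(values)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (t < protocol$start || t >= protocol$start + protocol$duration)
    return(values)
  sel <- rep(FALSE, length(values))
  for (r in protocol$regions) {
    if (is.logical(r)) sel <- sel | r else sel[r] <- TRUE
  }
  values[sel] <- values[sel] + protocol$amplitude
  values
}

#' Define a ghost-structure simulation problem
#'
#' Collects the grid, structure, cell model, physics and numerical options of
#' a run.  Defaults follow the reference formulation: reaction term
#' re-evaluated at every PDE stage, consistent-mass L2 projection, ghost
#' refresh every step.
#'
#' @param grid ghost-box [build_grid()].
#' @param mesh Lagrangian structure [triangulate()].
#' @param model a [cell_model()].
#' @param dt time step.
#' @param coefficients a [monodomain_coefficients()] list.
#' @param motion optional [motion_model()].
#' @param stimulus optional [stimulus_protocol()].
#' @param reaction_mode `"per_stage"` (re-evaluate the spread reaction field
#'   at each RK3 stage) or `"frozen"` (evaluate once per step).
#' @param projection `"consistent"` or `"lumped"` nodal L2 projection.
#' @param refresh_every reset ghost cells to rest every this many steps
#'   (0 disables).
#' @param refresh_region `"far"` resets only cells beyond the two-cell kernel
#'   halo of the structure (the halo is left to the PDE update so the kernel
#'   support never reads stale values); `"outside"` resets every cell whose
#'   kernel coverage by the structure is below one half, which places the
#'   effective homogeneous Dirichlet boundary at the structure boundary
#'   itself (the behaviour that matches a conforming-grid solve).
#' @param guard abort when `|V - V_rest|` exceeds this bound.
#' @export
gs_problem <- function(grid, mesh, model, dt, coefficients,
                       motion = NULL, stimulus = NULL,
                       reaction_mode = c("per_stage", "frozen"),
                       projection = c("consistent", "lumped"),
                       refresh_every = 1L,
                       refresh_region = c("far", "outside"), guard = 1e6) {
  stopifnot(inherits(grid, "cartesian_grid"),
            inherits(mesh, "lagrangian_mesh"),
            inherits(model, "cell_model"), dt > 0)
  structure(list(grid = grid, mesh = mesh, model = model, dt = dt,
                 coefficients = coefficients, motion = motion,
                 stimulus = stimulus,
                 reaction_mode = match.arg(reaction_mode),
                 projection = match.arg(projection),
                 refresh_every = as.integer(refresh_every),
                 refresh_region = match.arg(refresh_region), guard = guard),
            class = "gs_problem")
}

# cells kept alive by the ghost refresh.  "far": cells covered by the 4x4
# kernel stencils of the quadrature points (structure + two-cell halo).
# "outside": cells whose kernel coverage by the structure is at least 1/2
# (the spread of the constant 1), i.e. cells at least half inside.
active_cells <- function(mesh, grid, region = "far") {
  if (region == "outside")
    return(spread(1, mesh, grid)$values >= 0.5)
  cx <- (mesh$quad_current[, 1] - grid$lo[1]) / grid$dx1 - 0.5
  cy <- (mesh$quad_current[, 2] - grid$lo[2]) / grid$dx2 - 0.5
  i0 <- floor(cx) - 1; j0 <- floor(cy) - 1
  if (any(i0 < 0 | j0 < 0 | i0 + 3 >= grid$n1 | j0 + 3 >= grid$n2))
    stop("active_cells: quadrature point within two cells of the box edge")
  mask <- matrix(FALSE, grid$n1, grid$n2)
  for (a in 0:3) for (b in 0:3)
    mask[cbind(i0 + a + 1, j0 + b + 1)] <- TRUE
  mask
}

#' Initial coupled state from Lagrangian initial conditions
#'
#' Samples the initial potential at the quadrature points, spreads it through
#' the delta kernel to the Eulerian grid (the L2-consistent route), resets
#' the far ghost region to the resting potential, and evaluates the state
#' initial condition at the mesh nodes.
#'
#' @param problem a [gs_problem()].
#' @param potential function `(x, y) ->` initial potential, or a constant.
#' @param state function `(x, y) ->` state matrix (`n x state_dim`), or NULL
#'   for the model's `initial_state`.
#' @return list with class `gs_state`: `t`, `V` (matrix), `y`, `mesh`.
#' @export
gs_initial_state <- function(problem, potential = NULL, state = NULL) {
  grid <- problem$grid; mesh <- problem$mesh; model <- problem$model
  vrest <- model$rest_potential
  qp <- mesh$quad_current
  u0 <- if (is.null(potential)) rep(vrest, nrow(qp))
        else if (is.function(potential)) potential(qp[, 1], qp[, 2])
        else rep(potential, nrow(qp))
  V <- spread(u0, mesh, grid)$values
  mask <- active_cells(mesh, grid, problem$refresh_region)
  V[!mask] <- vrest
  nd <- mesh$current
  y <- if (is.null(state))
    matrix(model$initial_state, nrow(nd), model$state_dim, byrow = TRUE)
  else state(nd[, 1], nd[, 2])
  y <- matrix(y, nrow = nrow(nd))
  structure(list(t = 0, V = V, y = y, mesh = mesh), class = "gs_state")
}

#' One ghost-structure time step (reference implementation)
#'
#' Executes, in order: (1) motion update and weight/stencil refresh if the
#' structure moves; (2) evaluation of the Lagrangian ionic current at the
#' quadrature points (state interpolated from the nodes through the P1
#' basis), stimulus addition, and spreading to the Eulerian reaction field;
#' (3) TVD-RK3 advance of the potential with the reaction field re-evaluated
#' per stage (or frozen); (4) interpolation of the new potential to the
#' quadrature points and L2 projection to the nodes; (5) TVD-RK3 advance of
#' the nodal state with the fresh potential frozen; (6) ghost refresh of the
#' far non-tissue cells.
#'
#' The compiled benchmark loop reproduces exactly this arithmetic (it is
#' compared against this function in the tests).
#'
#' @param state a `gs_state`.
#' @param problem the [gs_problem()].
#' @param cache optional list of stationary-structure precomputations as
#'   built by [run_gs()]: `mass_factor` (Cholesky factor of the consistent
#'   mass matrix), `mlump` (lumped mass vector), `mask` (ghost-refresh
#'   active-cell mask).  Ignored while the structure moves.
#' @return the advanced `gs_state`.
#' @export
gs_step <- function(state, problem, cache = NULL) {
  grid <- problem$grid; model <- problem$model; dt <- problem$dt
  co <- problem$coefficients
  vrest <- model$rest_potential
  mesh <- state$mesh
  t <- state$t
  moving <- !is.null(problem$motion) && problem$motion$active &&
    t < problem$motion$t_stop
  if (moving) {
    h <- min(dt, problem$motion$t_stop - t)
    mesh <- advance_motion(mesh, problem$motion, h, grid)
    cache <- NULL
  }

  y <- state$y
  yq <- vapply(seq_len(model$state_dim),
               function(k) mesh_interp_to_quad(mesh, y[, k]),
               numeric(nrow(mesh$quad_nodes)))
  yq <- matrix(yq, ncol = model$state_dim)

  reaction_field <- function(V) {
    uq <- interpolate(V, mesh$quad_current, grid)
    iq <- model$current(uq, yq)
    iq <- apply_stimulus(iq, problem$stimulus, t)
    -co$cur_scale * spread(iq, mesh, grid)$values
  }

  lap <- function(V) .laplacian_cpp(V, co$diff[1], co$diff[2],
                                    grid$dx1, grid$dx2, vrest)

  V <- state$V
  Rf0 <- reaction_field(V)
  L0 <- Rf0 + lap(V)
  V1 <- V + dt * L0
  Rf1 <- if (problem$reaction_mode == "per_stage") reaction_field(V1) else Rf0
  L1 <- Rf1 + lap(V1)
  V2 <- V1 + dt * 0.25 * (-3 * L0 + L1)
  Rf2 <- if (problem$reaction_mode == "per_stage") reaction_field(V2) else Rf0
  L2 <- Rf2 + lap(V2)
  Vn <- V2 + dt / 12 * (-L0 - L1 + 8 * L2)

  uq_new <- interpolate(Vn, mesh$quad_current, grid)
  vt <- if (problem$projection == "lumped" && !is.null(cache$mlump)) {
    b <- .project_rhs_cpp(mesh$quad_nodes, mesh$quad_basis, uq_new,
                          mesh$quad_w, nrow(mesh$nodes))
    ifelse(cache$mlump > 0, b / cache$mlump, 0)
  } else {
    project_to_nodes(uq_new, mesh,
                     lumped = problem$projection == "lumped",
                     factor = cache$mass_factor)
  }
  y_new <- rk3_ode_step(model, vt, y, dt, t)

  if (problem$refresh_every > 0L) {
    step_no <- round(t / dt) + 1
    if (step_no %% problem$refresh_every == 0) {
      mask <- if (is.null(cache$mask))
        active_cells(mesh, grid, problem$refresh_region)
      else cache$mask
      Vn[!mask] <- vrest
    }
  }

  vmax <- max(abs(Vn - vrest))
  if (!is.finite(vmax) || vmax > problem$guard)
    stop(sprintf("gs_step: |V - V_rest| = %g exceeded the blow-up guard at t = %g",
                 vmax, t + dt))

  structure(list(t = t + dt, V = Vn, y = y_new, mesh = mesh),
            class = "gs_state")
}

probe_cell_index <- function(grid, positions) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  i <- pmin(pmax(floor((positions[, 1] - grid$lo[1]) / grid$dx1), 0), grid$n1 - 1)
  j <- pmin(pmax(floor((positions[, 2] - grid$lo[2]) / grid$dx2), 0), grid$n2 - 1)
  as.integer(i + grid$n1 * j)  # 0-based flat index
}

#' Run a ghost-structure simulation
#'
#' Advances the coupled system for `n_steps` steps, recording probe traces at
#' every step and full-field snapshots at the requested times.  The run is
#' fully deterministic: identical inputs give bit-identical outputs (there is
#' no randomness anywhere in the pipeline).
#'
#' For the FitzHugh-Nagumo model the loop can use a compiled fast path
#' (`engine = "compiled"`, requiring `projection = "lumped"` and no
#' stimulus); `engine = "auto"` picks it when eligible, and
#' `engine = "reference"` forces the pure-R step for arbitrary models.
#'
#' @param problem a [gs_problem()].
#' @param state initial `gs_state` from [gs_initial_state()].
#' @param n_steps number of steps to take.
#' @param probes optional `n x 2` matrix of probe positions (traces of V at
#'   the nearest cell center are recorded every step).
#' @param snapshot_times times (multiples of `dt`) at which to keep a full
#'   copy of the Eulerian potential; `t = 0` is always included.
#' @param engine `"auto"`, `"compiled"` or `"reference"`.
#' @return object of class `gs_run`: final `state`, `probes` data.frame
#'   (`time`, `probe_1`, ...), `snapshots` (list of matrices), `snap_times`,
#'   `problem`.
#' @export
run_gs <- function(problem, state = NULL, n_steps, probes = NULL,
                   snapshot_times = numeric(), engine = c("auto", "compiled",
                                                          "reference")) {
  engine <- match.arg(engine)
  if (is.null(state)) state <- gs_initial_state(problem)
  grid <- problem$grid
  dt <- problem$dt
  n_steps <- as.integer(n_steps)
  probe_cells <- if (is.null(probes)) integer() else probe_cell_index(grid, probes)
  snap_steps <- sort(unique(c(0L, as.integer(round(snapshot_times / dt)))))
  snap_steps <- snap_steps[snap_steps <= n_steps]

  eligible <- problem$model$name == "fhn" && is.null(problem$stimulus) &&
    problem$projection == "lumped"
  if (engine == "compiled" && !eligible)
    stop("run_gs: compiled engine requires the FitzHugh-Nagumo model, lumped ",
         "projection, and no stimulus")
  use_cpp <- (engine == "compiled") || (engine == "auto" && eligible)

  if (use_cpp) {
    p <- problem$model$params
    mo <- problem$motion
    args <- list(
      n1 = grid$n1, n2 = grid$n2, ox = grid$lo[1], oy = grid$lo[2],
      dx = grid$dx1, dy = grid$dx2,
      kx = problem$coefficients$diff[1], ky = problem$coefficients$diff[2],
      a = p$a, eps = p$epsilon, beta = p$beta, gamma = p$gamma,
      sigma = p$sigma, vrest = problem$model$rest_potential,
      dt = dt, nsteps = n_steps,
      per_stage = problem$reaction_mode == "per_stage",
      refresh_every = problem$refresh_every,
      refresh_outside = problem$refresh_region == "outside",
      guard = problem$guard,
      qp = state$mesh$quad_current, quad_frac = state$mesh$quad_frac,
      quad_elem = state$mesh$quad_elem, quad_nodes = state$mesh$quad_nodes,
      quad_basis = state$mesh$quad_basis, nodes = state$mesh$current,
      elements = state$mesh$elements,
      V0 = as.numeric(state$V), yinit = state$y[, 1],
      moving = !is.null(mo) && mo$active,
      probe_cells = probe_cells, snap_steps = snap_steps)
    if (isTRUE(args$moving)) {
      args$motion_cx <- mo$centroid[1]; args$motion_cy <- mo$centroid[2]
      args$motion_rate <- mo$rate
      args$motion_tstop <- min(mo$t_stop, n_steps * dt)
    }
    res <- .gs_run_fhn_cpp(args)
    mesh <- state$mesh
    mesh$current <- res$nodes_current
    mesh$quad_current <- res$qp_current
    if (!is.null(mo) && mo$active) {
      areas <- abs(tri_signed_area2(mesh$current, mesh$elements)) / 2
      mesh$quad_w <- areas[mesh$quad_elem] * mesh$quad_frac
    }
    final <- structure(list(t = state$t + n_steps * dt, V = res$V,
                            y = matrix(res$y, ncol = 1), mesh = mesh),
                       class = "gs_state")
    probes_df <- data.frame(time = as.numeric(res$probe_times))
    if (length(probe_cells))
      for (k in seq_along(probe_cells))
        probes_df[[paste0("probe_", k)]] <- res$probes[, k]
    out <- list(state = final, probes = probes_df,
                snapshots = res$snapshots, snap_times = res$snap_times,
                problem = problem)
  } else {
    stationary <- is.null(problem$motion) || !problem$motion$active
    cache <- NULL
    if (stationary) {
      cache <- list(mask = active_cells(state$mesh, problem$grid,
                                        problem$refresh_region))
      if (problem$projection == "consistent")
        cache$mass_factor <- Matrix::Cholesky(mass_matrix(state$mesh),
                                              LDL = FALSE, perm = TRUE)
      else
        cache$mlump <- mass_matrix(state$mesh, lumped = TRUE)
    }
    np <- length(probe_cells)
    ptr <- matrix(NA_real_, n_steps + 1L, np)
    if (np) ptr[1, ] <- as.numeric(state$V)[probe_cells + 1L]
    snaps <- list(); snap_t <- numeric()
    if (0L %in% snap_steps) { snaps <- list(state$V); snap_t <- state$t }
    for (s in seq_len(n_steps)) {
      moved_before <- !is.null(problem$motion) && problem$motion$active &&
        state$t < problem$motion$t_stop
      state <- gs_step(state, problem,
                       cache = if (moved_before) NULL else cache)
      if (np) ptr[s + 1L, ] <- as.numeric(state$V)[probe_cells + 1L]
      if (s %in% snap_steps) {
        snaps <- c(snaps, list(state$V)); snap_t <- c(snap_t, state$t)
      }
    }
    probes_df <- data.frame(time = seq(0, by = dt, length.out = n_steps + 1L))
    if (np) for (k in seq_len(np)) probes_df[[paste0("probe_", k)]] <- ptr[, k]
    out <- list(state = state, probes = probes_df, snapshots = snaps,
                snap_times = snap_t, problem = problem)
  }
  if (!is.null(probes))
    attr(out$probes, "positions") <- matrix(as.numeric(probes), ncol = 2)
  structure(out, class = "gs_run")
}

#' @export
print.gs_run <- function(x, ...) {
  cat(sprintf("<gs_run> t = %g, %d snapshot(s), %d probe trace(s)\n",
              x$state$t, length(x$snapshots), ncol(x$probes) - 1L))
  invisible(x)
}
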