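# Benchmark geometries, initial conditions, and the synthetic idealized
# ventricular sections with healthy/LBBB stimulus masks.  Everything here is
# generated programmatically; no external data.

#' Spiral-wave initial conditions on the rectangle
#'
#' The classic cross-field protocol on `[0, 2.5]^2`: the potential starts at
#' 1 on the lower-left quadrant (and 0 elsewhere) while the recovery variable
#' starts at 0.1 on the upper half (0 on the lower half).  The broken edge of
#' the excited quadrant curls into a single rotating spiral.  The quadrant
#' seams are tie-broken in the printed branch order (first match wins), and
#' the outer boundary is treated as closed so mesh nodes on it are valid.
#'
#' @param x,y coordinates (vectorized) inside `[0, 2.5]^2`.
#' @return list with components `u` and `v`.
#' @export
rectangle_ic <- function(x, y) {
  tol <- 1e-12
  if (any(x < -tol | x > 2.5 + tol | y < -tol | y > 2.5 + tol))
    stop("rectangle_ic: position outside [0, 2.5]^2")
  list(u = as.numeric(x <= 1.25 & y < 1.25),
       v = 0.1 * (y >= 1.25))
}

#' Spiral-wave initial conditions on the disc
#'
#' Arc-bounded analogue of [rectangle_ic()] on the disc of radius 1.25
#' centered at (1.25, 1.25): the potential starts at 1 on the lower-left
#' arc-bounded sector, the recovery variable at 0.1 on the upper half-disc.
#'
#' @param x,y coordinates (vectorized) inside the disc.
#' @return list with components `u` and `v`.
#' @export
circle_ic <- function(x, y) {
  r2 <- (x - 1.25)^2 + (y - 1.25)^2
  if (any(r2 > 1.25^2 * (1 + 1e-9)))
    stop("circle_ic: position outside the disc of radius 1.25")
  ax <- 1.25 - sqrt(pmax(0, 1.25^2 - (1.25 - y)^2))  # left arc at height y
  ay <- 1.25 - sqrt(pmax(0, 1.25^2 - (1.25 - x)^2))  # lower arc at abscissa x
  u <- as.numeric(ax < x & x <= 1.25 & ay < y & y <= 1.25)
  bx <- 2.5 - ax                                      # right arc at height y
  by <- 2.5 - ay                                      # upper arc at abscissa x
  v <- 0.1 * (ax < x & x < bx & 1.25 <= y & y < by)
  list(u = u, v = v)
}

#' Named benchmark specifications
#'
#' One-line presets reproducing the spiral-wave benchmark setups: ghost box,
#' grid resolution, time step, initial conditions and motion law.  The
#' stationary benchmarks use the box `[-0.1, 2.6]^2` at 275 x 275 cells, the
#' moving ones `[-0.75, 3.25]^2` at 408 x 408, both with `dt = 0.1` and
#' isotropic diffusion `K = 1e-4`.
#'
#' @param name one of `"rect_stationary"`, `"circle_stationary"`,
#'   `"rect_moving"`, `"circle_moving"`.
#' @return a configuration list (see [load_config()]).
#' @export
benchmark_spec <- function(name = c("rect_stationary", "circle_stationary",
                                    "rect_moving", "circle_moving")) {
  name <- match.arg(name)
  moving <- grepl("moving", name)
  circ <- grepl("circle", name)
  cfg <- list(
    schema_version = 1L,
    preset = name,
    grid = if (moving)
      list(extent = c(-0.75, 3.25, -0.75, 3.25), n1 = 408L, n2 = 408L)
    else
      list(extent = c(-0.1, 2.6, -0.1, 2.6), n1 = 275L, n2 = 275L),
    mesh = list(
      region = if (circ)
        list(type = "circle", center = c(1.25, 1.25), radius = 1.25)
      else
        list(type = "rectangle", lo = c(0, 0), hi = c(2.5, 2.5)),
      refinement_factor = 0.5,
      quad_order = 1L),
    cell_model = list(name = "fhn",
                      params = list(a = 0.1, epsilon = 0.01, beta = 0.5,
                                    gamma = 1, sigma = 0)),
    physics = list(units = "dimensionless", K = c(1e-4, 1e-4)),
    time = list(dt = 0.1, t_end = 1000),
    motion = list(active = moving, centroid = c(1.25, 1.25),
                  rate = 0.5 / 1.25, t_stop = 1.25),
    ic = if (circ) "circle" else "rectangle",
    numerics = list(reaction_mode = "frozen", projection = "lumped",
                    refresh_every = 1L, guard = 1e6),
    output = list(probes = list(speed_point = c(1.5, 1.5)),
                  snapshot_times = c(250, 500, 750, 995, 1000))
  )
  cfg
}

# ---------------------------------------------------------------------------
# Synthetic idealized ventricular sections
# ---------------------------------------------------------------------------

# distance from points to a vertical segment {x = xc, y in [ylo, yhi]}
dist_vseg <- function(x, y, xc, ylo, yhi) {
  dy <- pmax(0, ylo - y, y - yhi)
  sqrt((x - xc)^2 + dy^2)
}

ventricle_params_default <- function(kind) {
  if (kind == "transverse") {
    # two overlapping chambers in a 130 x 110 mm box: thick-walled LV ring,
    # thin-walled RV crescent wrapped around the septal side
    list(box = c(0, 130, 0, 110),
         lv_center = c(85, 55), lv_r_out = 40, lv_r_in = 26,
         rv_center = c(50, 55), rv_r_out = 44, rv_r_in = 36,
         endo_depth = 4, weld = 2, y_stim_max = 55)
  } else {
    # U-shaped biventricular outline in a 140 x 140 mm box: stadium-shaped
    # outer wall, two stadium cavities, septum between them
    list(box = c(0, 140, 0, 140),
         outer_xc = 70, outer_ylo = 78, outer_yhi = 120, outer_r = 55,
         rv_xc = 44, lv_xc = 96, cav_ylo = 45, cav_yhi = 130, cav_r = 17,
         endo_depth = 4, y_stim_max = 70)
  }
}

ventricle_indicator <- function(kind, p) {
  if (kind == "transverse") {
    function(x, y) {
      dL <- sqrt((x - p$lv_center[1])^2 + (y - p$lv_center[2])^2)
      dR <- sqrt((x - p$rv_center[1])^2 + (y - p$rv_center[2])^2)
      lv <- dL >= p$lv_r_in & dL <= p$lv_r_out
      rv <- dR >= p$rv_r_in & dR <= p$rv_r_out & dL >= p$lv_r_out - p$weld
      lv | rv
    }
  } else {
    function(x, y) {
      douter <- dist_vseg(x, y, p$outer_xc, p$outer_ylo, p$outer_yhi)
      dlv <- dist_vseg(x, y, p$lv_xc, p$cav_ylo, p$cav_yhi)
      drv <- dist_vseg(x, y, p$rv_xc, p$cav_ylo, p$cav_yhi)
      douter <= p$outer_r & y <= p$outer_yhi & dlv > p$cav_r & drv > p$cav_r
    }
  }
}

#' Synthetic idealized ventricular section with stimulus masks
#'
#' Constructs a parameterized stand-in for a ventricular cross-section (this
#' is *synthetic* geometry, not a patient-derived section): the transverse
#' kind is a thick-walled left-ventricular ring plus a thin-walled
#' right-ventricular crescent sharing a septum, fitting a 130 x 110 mm box;
#' the longitudinal kind is a U-shaped biventricular outline in a
#' 140 x 140 mm box.  Returns the triangulated tissue together with
#' quadrature-point masks for the septum and the middle-and-lower
#' endocardial stimulation bands of each chamber, and four probe positions
#' (right-ventricular free wall, septum, and two left-ventricular wall
#' points, the last on the lateral wall farthest from the right ventricle).
#'
#' @param kind `"transverse"` or `"longitudinal"`.
#' @param edge target maximal edge length of the triangulation (mm).
#' @param quad_order triangle quadrature order.
#' @param grid optional host grid for the leak-guard check.
#' @param params overrides of the geometric defaults (see source).
#' @return list with `kind`, `box` (grid extent), `mesh`, `masks` (named
#'   list of quadrature-point logicals: `septum`, `lv_endo_stim`,
#'   `rv_endo_stim`), `probes` (named 4 x 2 matrix), `params`.
#' @export
ventricle_section <- function(kind = c("transverse", "longitudinal"),
                              edge = 0.5, quad_order = 2, grid = NULL,
                              params = list()) {
  kind <- match.arg(kind)
  p <- utils::modifyList(ventricle_params_default(kind), params)
  inside <- ventricle_indicator(kind, p)
  mesh <- triangulate(region_indicator(inside, p$box), target_edge_length = edge,
                      grid = grid, quad_order = quad_order)
  qx <- mesh$quad_points[, 1]; qy <- mesh$quad_points[, 2]

  if (kind == "transverse") {
    dL <- sqrt((qx - p$lv_center[1])^2 + (qy - p$lv_center[2])^2)
    dR <- sqrt((qx - p$rv_center[1])^2 + (qy - p$rv_center[2])^2)
    lv <- dL >= p$lv_r_in & dL <= p$lv_r_out
    rv_wall <- !lv & dR >= p$rv_r_in & dR <= p$rv_r_out
    # the RV endocardial surface lines the whole RV cavity: the inner band of
    # the free wall plus the RV-facing (septal) surface of the LV outer wall
    rv_endo <- (rv_wall & dR <= p$rv_r_in + p$endo_depth) |
      (lv & dR < p$rv_r_in & dL >= p$lv_r_out - p$endo_depth)
    septum <- lv & dR <= p$rv_r_in & !rv_endo
    lv_endo <- lv & dL <= p$lv_r_in + p$endo_depth & !septum & !rv_endo
    stim_cut <- qy <= p$y_stim_max
    masks <- list(septum = septum & stim_cut,
                  lv_endo_stim = lv_endo & stim_cut,
                  rv_endo_stim = rv_endo & stim_cut)
    # the septal probe sits on the RV-facing septal endocardium, the region
    # the right bundle feeds in both conduction states
    probes <- rbind(rv_free = c(p$rv_center[1] - p$rv_r_in - 4, p$rv_center[2]),
                    septum = c(p$lv_center[1] - p$lv_r_out + 2, p$lv_center[2]),
                    lv_anterior = c(p$lv_center[1],
                                    p$lv_center[2] + p$lv_r_in + 7),
                    lv_lateral = c(p$lv_center[1] + p$lv_r_in + 7,
                                   p$lv_center[2]))
  } else {
    dlv <- dist_vseg(qx, qy, p$lv_xc, p$cav_ylo, p$cav_yhi)
    drv <- dist_vseg(qx, qy, p$rv_xc, p$cav_ylo, p$cav_yhi)
    mid <- (p$rv_xc + p$lv_xc) / 2
    septum <- abs(qx - mid) <= (p$lv_xc - p$rv_xc) / 2 - p$cav_r &
      qy >= p$cav_ylo - 2
    lv_endo <- dlv <= p$cav_r + p$endo_depth & !septum
    rv_endo <- drv <= p$cav_r + p$endo_depth & !septum
    stim_cut <- qy <= p$y_stim_max
    masks <- list(septum = septum & stim_cut,
                  lv_endo_stim = lv_endo & stim_cut,
                  rv_endo_stim = rv_endo & stim_cut)
    probes <- rbind(rv_free = c(p$rv_xc - p$cav_r - 4, 80),
                    septum = c(mid, 65),
                    lv_anterior = c(p$lv_xc, p$cav_ylo - p$cav_r - 4),
                    lv_lateral = c(p$lv_xc + p$cav_r + 4, 80))
  }
  if (!all(vapply(masks, any, logical(1))))
    stop("ventricle_section: an empty stimulus mask (check parameters)")
  list(kind = kind, box = p$box, mesh = mesh, masks = masks, probes = probes,
       params = p)
}

#' Healthy or LBBB stimulation protocol for a ventricular section
#'
#' Under healthy conduction the bundle branches deliver the stimulus to the
#' middle-and-lower-third endocardium of *both* chambers and the septum;
#' under complete left bundle branch block (LBBB) only the right-ventricular
#' endocardial band is stimulated, and the left ventricle activates by slow
#' transseptal myocardial spread.
#'
#' @param section a [ventricle_section()].
#' @param mode `"healthy"` or `"lbbb"`.
#' @param amplitude signed stimulus current (uA/cm^2; negative = depolarizing
#'   in the solver convention).  Default is about twice the surrogate
#'   model's diastolic threshold.
#' @param start,duration stimulus window (ms).
#' @return a [stimulus_protocol()].
#' @export
ventricle_stimulus <- function(section, mode = c("healthy", "lbbb"),
                               amplitude = -30, start = 0, duration = 2) {
  mode <- match.arg(mode)
  regions <- if (mode == "healthy")
    section$masks[c("septum", "lv_endo_stim", "rv_endo_stim")]
  else
    section$masks["rv_endo_stim"]
  stimulus_protocol(regions, amplitude = amplitude, start = start,
                    duration = duration, mode = mode)
}
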