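# Triangulated Lagrangian structure: region specs, structured triangulation,
# Gaussian quadrature on triangles, P1 basis bookkeeping, and the prescribed
# radial motion map.

#' Region specifications for the Lagrangian structure
#'
#' @param lo,hi numeric length-2 corners of the rectangle.
#' @return a `region_spec` list understood by [triangulate()].
#' @export
region_rectangle <- function(lo, hi) {
  stopifnot(length(lo) == 2, length(hi) == 2)
  if (any(hi <= lo)) stop("region_rectangle: degenerate rectangle")
  structure(list(type = "rectangle", lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "region_spec")
}

#' @rdname region_rectangle
#' @param center,radius circle center (length 2) and radius.
#' @export
region_circle <- function(center, radius) {
  stopifnot(length(center) == 2)
  if (!is.finite(radius) || radius <= 0) stop("region_circle: radius must be > 0")
  structure(list(type = "circle", center = as.numeric(center), radius = radius),
            class = "region_spec")
}

#' @rdname region_rectangle
#' @param vertices an `n x 2` matrix of polygon vertices (counter-clockwise,
#'   not self-intersecting).
#' @export
region_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("region_polygon: need at least 3 vertices")
  a <- polygon_area(vertices)
  if (abs(a) < 1e-12) stop("region_polygon: degenerate (zero-area) polygon")
  structure(list(type = "polygon", vertices = vertices), class = "region_spec")
}

#' @rdname region_rectangle
#' @param inside vectorized predicate `function(x, y)` returning TRUE inside
#'   the region; triangles are kept when their centroid is inside, so the
#'   boundary is resolved only to the target edge length.
#' @param bbox bounding box `c(x_lo, x_hi, y_lo, y_hi)` of the region.
#' @export
region_indicator <- function(inside, bbox) {
  stopifnot(is.function(inside), length(bbox) == 4)
  structure(list(type = "indicator", inside = inside, bbox = as.numeric(bbox)),
            class = "region_spec")
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(seq_len(nrow(v))[-1], 1L)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

point_in_polygon <- function(px, py, v) {
  # even-odd crossing rule, vectorized over the points
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Gaussian quadrature on a triangle
#'
#' Symmetric rules exact for polynomials up to `rule_order` on the triangle;
#' weights sum to the triangle area.
#'
#' @param element a `3 x 2` matrix of vertex coordinates.
#' @param rule_order 1 (centroid), 2 (three mid-edge points) or 4 (six-point
#'   rule).
#' @return list with `points` (`n x 2`) and `weights` (length `n`).
#' @export
element_quadrature <- function(element, rule_order = 2) {
  element <- as.matrix(element)
  stopifnot(nrow(element) == 3, ncol(element) == 2)
  a2 <- (element[2, 1] - element[1, 1]) * (element[3, 2] - element[1, 2]) -
        (element[3, 1] - element[1, 1]) * (element[2, 2] - element[1, 2])
  area <- 0.5 * abs(a2)
  if (area <= 0) stop("element_quadrature: degenerate triangle")
  r <- quad_rule_bary(rule_order)
  list(points = r$bary %*% element, weights = r$frac * area)
}

# Barycentric points (rows) and area-fraction weights of the supported rules.
quad_rule_bary <- function(rule_order) {
  if (rule_order == 1) {
    list(bary = matrix(1 / 3, 1, 3), frac = 1)
  } else if (rule_order == 2) {
    list(bary = matrix(c(0.5, 0.5, 0,
                         0, 0.5, 0.5,
                         0.5, 0, 0.5), 3, 3, byrow = TRUE),
         frac = rep(1 / 3, 3))
  } else if (rule_order == 4) {
    a <- 0.445948490915965; b <- 0.091576213509771
    list(bary = rbind(
           c(1 - 2 * a, a, a), c(a, 1 - 2 * a, a), c(a, a, 1 - 2 * a),
           c(1 - 2 * b, b, b), c(b, 1 - 2 * b, b), c(b, b, 1 - 2 * b)),
         frac = c(rep(0.223381589678011, 3), rep(0.109951743655322, 3)))
  } else {
    stop("element_quadrature: unsupported rule_order ", rule_order,
         " (supported: 1, 2, 4)")
  }
}

# structured 4-split pattern: each square of an nx x ny lattice is cut into 4
# triangles around its center node.  Max edge length = the square side.
split4_mesh <- function(xs, ys) {
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  corner <- as.matrix(expand.grid(x = xs, y = ys))
  cx <- (xs[-1] + xs[-(nx + 1)]) / 2
  cy <- (ys[-1] + ys[-(ny + 1)]) / 2
  center <- as.matrix(expand.grid(x = cx, y = cy))
  nodes <- rbind(corner, center)
  ncorner <- nrow(corner)
  cid <- function(i, j) (j - 1L) * (nx + 1L) + i          # corner (i, j)
  mid <- function(i, j) ncorner + (j - 1L) * nx + i       # center of square (i, j)
  ii <- rep(seq_len(nx), ny)
  jj <- rep(seq_len(ny), each = nx)
  p1 <- cid(ii, jj); p2 <- cid(ii + 1L, jj)
  p3 <- cid(ii + 1L, jj + 1L); p4 <- cid(ii, jj + 1L)
  pc <- mid(ii, jj)
  elements <- rbind(cbind(p1, p2, pc), cbind(p2, p3, pc),
                    cbind(p3, p4, pc), cbind(p4, p1, pc))
  list(nodes = unname(nodes), elements = unname(elements))
}

# square [-1,1]^2 -> unit disc, boundary exactly on the circle
square_to_disc <- function(p) {
  r2 <- sqrt(p[, 1]^2 + p[, 2]^2)
  rinf <- pmax(abs(p[, 1]), abs(p[, 2]))
  s <- ifelse(r2 > 0, rinf / r2, 0)
  p * s
}

tri_signed_area2 <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE]
  c <- nodes[elements[, 3], , drop = FALSE]
  (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])
}

max_edge_length <- function(nodes, elements) {
  e <- rbind(elements[, c(1, 2)], elements[, c(2, 3)], elements[, c(3, 1)])
  d <- nodes[e[, 1], , drop = FALSE] - nodes[e[, 2], , drop = FALSE]
  sqrt(max(d[, 1]^2 + d[, 2]^2))
}

#' Triangulate a region into a Lagrangian mesh
#'
#' Builds a conforming triangulation (structured squares cut into four
#' triangles each; for circles the square mesh is mapped smoothly onto the
#' disc so boundary nodes sit exactly on the circle), attaches the quadrature
#' rule and P1 basis bookkeeping, and enforces the leak guard: the maximal
#' edge must not exceed `refinement_factor` times the host grid spacing,
#' otherwise kernel-width gaps can open between the Lagrangian points and the
#' Eulerian cells they must cover.
#'
#' @param region a `region_spec` ([region_rectangle()] and friends).
#' @param target_edge_length requested maximal edge length; defaults to
#'   `refinement_factor * min(dx1, dx2)` when `grid` is given.
#' @param grid optional host [build_grid()]; when present the leak guard is
#'   enforced and construction fails loudly if violated.
#' @param refinement_factor leak-guard ratio (default 0.5: Lagrangian edges at
#'   most half the Eulerian spacing).
#' @param quad_order triangle quadrature order (see [element_quadrature()]).
#' @return an object of class `lagrangian_mesh`.
#' @export
triangulate <- function(region, target_edge_length = NULL, grid = NULL,
                        refinement_factor = 0.5, quad_order = 2) {
  stopifnot(inherits(region, "region_spec"))
  if (is.null(target_edge_length)) {
    if (is.null(grid))
      stop("triangulate: give target_edge_length or a host grid")
    target_edge_length <- refinement_factor * min(grid$dx1, grid$dx2)
  }
  if (target_edge_length <= 0) stop("triangulate: target_edge_length must be > 0")

  if (region$type == "rectangle") {
    wx <- region$hi[1] - region$lo[1]; wy <- region$hi[2] - region$lo[2]
    nx <- max(2L, ceiling(wx / target_edge_length))
    ny <- max(2L, ceiling(wy / target_edge_length))
    m <- split4_mesh(seq(region$lo[1], region$hi[1], length.out = nx + 1L),
                     seq(region$lo[2], region$hi[2], length.out = ny + 1L))
  } else if (region$type == "circle") {
    R <- region$radius
    m <- NULL
    half <- max(2L, ceiling(R / target_edge_length))
    for (it in 1:6) {
      s <- seq(-1, 1, length.out = 2L * half + 1L)
      mm <- split4_mesh(s, s)
      mm$nodes <- square_to_disc(mm$nodes) * R
      mm$nodes[, 1] <- mm$nodes[, 1] + region$center[1]
      mm$nodes[, 2] <- mm$nodes[, 2] + region$center[2]
      maxe <- max_edge_length(mm$nodes, mm$elements)
      if (maxe <= target_edge_length * (1 + 1e-12)) {
        m <- mm; break
      }
      # rescale by the measured overshoot (the mapping stretch is ~constant)
      half <- max(half + 1L, ceiling(half * maxe / target_edge_length) + 1L)
    }
    if (is.null(m)) stop("triangulate: could not satisfy the edge target on the disc")
  } else if (region$type %in% c("polygon", "indicator")) {
    if (region$type == "polygon") {
      bb <- c(range(region$vertices[, 1]), range(region$vertices[, 2]))
      inside <- function(x, y) point_in_polygon(x, y, region$vertices)
    } else {
      bb <- region$bbox
      inside <- region$inside
    }
    nx <- max(2L, ceiling((bb[2] - bb[1]) / target_edge_length))
    ny <- max(2L, ceiling((bb[4] - bb[3]) / target_edge_length))
    mm <- split4_mesh(seq(bb[1], bb[2], length.out = nx + 1L),
                      seq(bb[3], bb[4], length.out = ny + 1L))
    cen <- (mm$nodes[mm$elements[, 1], ] + mm$nodes[mm$elements[, 2], ] +
            mm$nodes[mm$elements[, 3], ]) / 3
    keep <- inside(cen[, 1], cen[, 2])
    if (!any(keep)) stop("triangulate: region is empty at this resolution")
    el <- mm$elements[keep, , drop = FALSE]
    used <- sort(unique(as.vector(el)))
    renum <- integer(nrow(mm$nodes)); renum[used] <- seq_along(used)
    m <- list(nodes = mm$nodes[used, , drop = FALSE],
              elements = matrix(renum[el], ncol = 3))
  } else stop("triangulate: unknown region type ", region$type)

  new_lagrangian_mesh(m$nodes, m$elements, grid = grid,
                      refinement_factor = refinement_factor,
                      quad_order = quad_order, region = region)
}

#' Assemble a Lagrangian mesh from node and element arrays
#'
#' @param nodes `M x 2` material node coordinates.
#' @param elements `T x 3` integer matrix of 1-based node indices.
#' @inheritParams triangulate
#' @param region optional region spec recorded for provenance.
#' @export
new_lagrangian_mesh <- function(nodes, elements, grid = NULL,
                                refinement_factor = 0.5, quad_order = 2,
                                region = NULL) {
  nodes <- unname(as.matrix(nodes)); storage.mode(nodes) <- "double"
  elements <- unname(as.matrix(elements)); storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 2, ncol(elements) == 3)
  a2 <- tri_signed_area2(nodes, elements)
  # orient all elements counter-clockwise, then demand positive area
  flip <- a2 < 0
  if (any(flip)) elements[flip, c(2, 3)] <- elements[flip, c(3, 2)]
  areas <- abs(a2) / 2
  if (any(areas <= 1e-300)) stop("new_lagrangian_mesh: degenerate element(s)")

  maxe <- max_edge_length(nodes, elements)
  if (!is.null(grid)) {
    lim <- refinement_factor * min(grid$dx1, grid$dx2)
    if (maxe > lim * (1 + 1e-12))
      stop(sprintf(paste0("new_lagrangian_mesh: leak guard violated: max edge %g",
                          " > %g = refinement_factor * min(dx); refine the mesh"),
                   maxe, lim))
  }

  rule <- quad_rule_bary(quad_order)
  nrule <- nrow(rule$bary)
  ntri <- nrow(elements)
  # quadrature bookkeeping, one block of nrule points per element
  quad_elem <- rep(seq_len(ntri), each = nrule)
  quad_frac <- rep(rule$frac, times = ntri)
  quad_nodes <- elements[quad_elem, , drop = FALSE]
  quad_basis <- rule$bary[rep(seq_len(nrule), times = ntri), , drop = FALSE]
  qx <- rowSums(matrix(nodes[quad_nodes, 1], ncol = 3) * quad_basis)
  qy <- rowSums(matrix(nodes[quad_nodes, 2], ncol = 3) * quad_basis)

  mesh <- structure(list(
    nodes = nodes, elements = elements, current = nodes,
    areas_material = areas, area = sum(areas),
    quad_points = cbind(qx, qy), quad_current = cbind(qx, qy),
    quad_elem = quad_elem, quad_frac = quad_frac,
    quad_nodes = quad_nodes, quad_basis = quad_basis,
    quad_w = areas[quad_elem] * quad_frac,
    quad_order = quad_order, refinement_factor = refinement_factor,
    max_edge = maxe, region = region), class = "lagrangian_mesh")

  stopifnot(abs(sum(mesh$quad_w) - mesh$area) <= 1e-10 * mesh$area)
  mesh
}

#' @export
print.lagrangian_mesh <- function(x, ...) {
  cat(sprintf(paste0("<lagrangian_mesh> %d nodes, %d elements, %d quadrature",
                     " points (order %d)\n  material area %.6g, max edge %.4g\n"),
              nrow(x$nodes), nrow(x$elements), nrow(x$quad_points),
              x$quad_order, x$area, x$max_edge))
  invisible(x)
}

#' Evaluate a nodal field at the quadrature points through the P1 basis
#'
#' @param mesh a `lagrangian_mesh`.
#' @param nodal numeric vector of length `nrow(mesh$nodes)`.
#' @export
mesh_interp_to_quad <- function(mesh, nodal) {
  stopifnot(length(nodal) == nrow(mesh$nodes))
  .basis_interp_cpp(mesh$quad_nodes, mesh$quad_basis, as.numeric(nodal))
}

#' Radial expansion motion of the structure
#'
#' Each material point moves in the normal direction \eqn{n(X) = (X - X_c) /
#' \lVert X - X_c \rVert} with speed \eqn{k(X) = \mathrm{rate} \cdot \lVert X
#' - X_c \rVert}; at the centroid the velocity is the zero vector.  Because
#' the velocity is attached to the material coordinate it is constant in
#' time, so points move on straight rays at constant speed (linear, not
#' exponential, expansion).
#'
#' @param centroid material centroid \eqn{X_c} of the structure.
#' @param rate speed per unit material distance; the spiral-wave benchmarks
#'   use 0.5/1.25 = 0.4.
#' @param active logical: a stationary structure has `active = FALSE`.
#' @param t_stop time after which the motion is switched off (the expansion
#'   otherwise pushes boundary points out of the ghost box).
#' @export
motion_model <- function(centroid, rate = 0.5 / 1.25, active = TRUE,
                         t_stop = Inf) {
  stopifnot(length(centroid) == 2, is.finite(rate))
  structure(list(centroid = as.numeric(centroid), rate = rate,
                 active = isTRUE(active), t_stop = t_stop),
            class = "motion_model")
}

#' Advance the structure by one motion step
#'
#' Explicit Euler update of the current positions of nodes and quadrature
#' points, \eqn{\chi^{n+1}(X) = \chi^n(X) + \Delta t \, k(X) n(X)}; element
#' areas and quadrature weights are re-derived from the updated node
#' positions.
#'
#' @param mesh a `lagrangian_mesh`.
#' @param motion a [motion_model()].
#' @param dt time step (> 0).
#' @param grid optional ghost-box grid; if any node leaves the box the
#'   simulation halts with a domain-overflow error.
#' @export
advance_motion <- function(mesh, motion, dt, grid = NULL) {
  stopifnot(inherits(motion, "motion_model"), dt > 0)
  if (!motion$active) return(mesh)
  vel_n <- motion$rate * sweep(mesh$nodes, 2, motion$centroid)
  vel_q <- motion$rate * sweep(mesh$quad_points, 2, motion$centroid)
  mesh$current <- mesh$current + dt * vel_n
  mesh$quad_current <- mesh$quad_current + dt * vel_q
  if (!is.null(grid)) {
    out <- mesh$current[, 1] < grid$lo[1] | mesh$current[, 1] > grid$hi[1] |
           mesh$current[, 2] < grid$lo[2] | mesh$current[, 2] > grid$hi[2]
    if (any(out))
      stop("advance_motion: ", sum(out), " node(s) left the ghost box")
  }
  areas <- abs(tri_signed_area2(mesh$current, mesh$elements)) / 2
  if (any(areas <= 0)) stop("advance_motion: motion degenerated an element")
  mesh$quad_w <- areas[mesh$quad_elem] * mesh$quad_frac
  mesh$max_edge <- max_edge_length(mesh$current, mesh$elements)
  mesh
}
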