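# Post-processing: activation-time maps, front speed at a point, spiral-arm
# width, and rotation sense.

#' First threshold-crossing times of a snapshot series
#'
#' Per cell, the linearly interpolated time of the first upward (or
#' downward) crossing of `threshold`; cells that never cross hold `NA`.
#'
#' @param snapshots list of `n1 x n2` matrices (one per frame).
#' @param times frame times (strictly increasing, same length).
#' @param threshold crossing level.
#' @param direction `"up"` or `"down"`.
#' @return matrix of activation times (`NA` = never activated).
#' @export
activation_times <- function(snapshots, times, threshold, direction = "up") {
  stopifnot(length(snapshots) == length(times), length(snapshots) >= 2,
            all(diff(times) > 0))
  sgn <- if (direction == "up") 1 else -1
  act <- matrix(NA_real_, nrow(snapshots[[1]]), ncol(snapshots[[1]]))
  prev <- sgn * snapshots[[1]]
  thr <- sgn * threshold
  act[prev >= thr] <- times[1]
  for (k in 2:length(snapshots)) {
    cur <- sgn * snapshots[[k]]
    new <- is.na(act) & prev < thr & cur >= thr
    if (any(new)) {
      frac <- (thr - prev[new]) / (cur[new] - prev[new])
      act[new] <- times[k - 1] + frac * (times[k] - times[k - 1])
    }
    prev <- cur
  }
  act
}

#' All upward crossing times of a single trace
#'
#' @param v numeric trace.
#' @param times sampling times (uniform, increasing).
#' @param threshold crossing level.
#' @return vector of linearly interpolated upstroke times (possibly empty).
#' @export
upstroke_times <- function(v, times, threshold) {
  lo <- v[-length(v)] < threshold & v[-1] >= threshold
  idx <- which(lo)
  if (!length(idx)) return(numeric())
  frac <- (threshold - v[idx]) / (v[idx + 1] - v[idx])
  times[idx] + frac * (times[idx + 1] - times[idx])
}

#' Probe positions needed by the front-speed estimator
#'
#' The estimator needs upstroke times at the cell straddling `point` and its
#' four axis neighbours; request exactly these five cell centers as probes of
#' [run_gs()].
#'
#' @param grid a [build_grid()].
#' @param point target position.
#' @return a 5 x 2 matrix of cell-center positions (center, +x, -x, +y, -y).
#' @export
speed_probe_positions <- function(grid, point) {
  cc <- cell_centers(grid)
  i <- which.min(abs(cc$x - point[1]))
  j <- which.min(abs(cc$y - point[2]))
  stopifnot(i > 1, i < grid$n1, j > 1, j < grid$n2)
  rbind(c(cc$x[i], cc$y[j]),
        c(cc$x[i + 1], cc$y[j]), c(cc$x[i - 1], cc$y[j]),
        c(cc$x[i], cc$y[j + 1]), c(cc$x[i], cc$y[j - 1]))
}

#' Mean front propagation speed at a point
#'
#' For every pass of the wave front over the probe point, the local slowness
#' vector is estimated by central differences of the interpolated upstroke
#' times at the four straddling cells, \eqn{s = (\partial t/\partial x,
#' \partial t/\partial y)}, and the pass speed is \eqn{1/\lVert s \rVert}
#' (the spacing along the front normal divided by the upstroke-time
#' difference).  The result is the mean over all passes whose center
#' upstroke falls in `window`.
#'
#' @param run a `gs_run` whose probes include the five positions of
#'   [speed_probe_positions()] (in that order), or a data.frame shaped like
#'   `run$probes` with a `positions` attribute.
#' @param grid the grid (taken from `run$problem` when `run` is a `gs_run`).
#' @param threshold upstroke threshold (0.5 for normalized potentials).
#' @param window time window `c(t0, t1)` over which passes are averaged.
#' @return the mean speed, with per-pass details in attribute `"passes"`.
#' @export
front_speed_at_point <- function(run, grid = NULL, threshold = 0.5,
                                 window = c(500, 1000)) {
  if (inherits(run, "gs_run")) {
    grid <- run$problem$grid
    probes <- run$probes
  } else probes <- run
  pos <- attr(probes, "positions")
  if (is.null(pos) || nrow(pos) < 5)
    stop("front_speed_at_point: need the five probes of speed_probe_positions()")
  tt <- probes$time
  tr <- as.matrix(probes[, -1, drop = FALSE])[, 1:5]
  cross <- lapply(1:5, function(k) upstroke_times(tr[, k], tt, threshold))
  t0 <- cross[[1]][cross[[1]] >= window[1] & cross[[1]] <= window[2]]
  if (length(t0) < 2)
    stop("front_speed_at_point: fewer than two front passes in the window")
  # pair each center pass with the nearest neighbour crossings
  gap <- min(diff(sort(cross[[1]])))
  max_lag <- gap / 2
  dx <- grid$dx1; dy <- grid$dx2
  passes <- lapply(t0, function(tc) {
    tn <- vapply(2:5, function(k) {
      d <- cross[[k]] - tc
      if (!length(d) || min(abs(d)) > max_lag) return(NA_real_)
      cross[[k]][which.min(abs(d))]
    }, numeric(1))
    if (anyNA(tn)) return(NULL)
    sx <- (tn[1] - tn[2]) / (2 * dx)   # (t_east - t_west) / 2 dx
    sy <- (tn[3] - tn[4]) / (2 * dy)
    sn <- sqrt(sx^2 + sy^2)
    if (sn == 0) return(NULL)
    data.frame(t = tc, sx = sx, sy = sy, speed = 1 / sn)
  })
  passes <- do.call(rbind, passes)
  if (is.null(passes) || nrow(passes) < 1)
    stop("front_speed_at_point: no usable passes (front too oblique or sparse)")
  structure(mean(passes$speed), passes = passes)
}

# bilinear interpolation of a cell-centered field at arbitrary points
bilinear <- function(V, grid, px, py) {
  cx <- (px - grid$lo[1]) / grid$dx1 - 0.5
  cy <- (py - grid$lo[2]) / grid$dx2 - 0.5
  i0 <- pmin(pmax(floor(cx), 0), grid$n1 - 2)
  j0 <- pmin(pmax(floor(cy), 0), grid$n2 - 2)
  fx <- cx - i0; fy <- cy - j0
  v00 <- V[cbind(i0 + 1, j0 + 1)]; v10 <- V[cbind(i0 + 2, j0 + 1)]
  v01 <- V[cbind(i0 + 1, j0 + 2)]; v11 <- V[cbind(i0 + 2, j0 + 2)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# super-threshold chord through p0 along unit direction d; endpoints refined
# by bisection on the bilinear interpolant.  Returns c(lo, hi) arclengths.
chord_along <- function(V, grid, thr, p0, d, step) {
  smax <- sqrt(sum((grid$hi - grid$lo)^2))
  f <- function(s) bilinear(V, grid, p0[1] + s * d[1], p0[2] + s * d[2])
  inside_box <- function(s) {
    x <- p0[1] + s * d[1]; y <- p0[2] + s * d[2]
    x >= grid$lo[1] + grid$dx1 & x <= grid$hi[1] - grid$dx1 &
      y >= grid$lo[2] + grid$dx2 & y <= grid$hi[2] - grid$dx2
  }
  if (f(0) < thr) return(NULL)
  march <- function(sign) {
    s <- 0
    repeat {
      s2 <- s + sign * step
      if (!inside_box(s2)) return(s)           # clipped by the domain
      if (f(s2) < thr) {
        a <- s; b <- s2                        # bisection refinement
        for (it in 1:50) {
          m <- (a + b) / 2
          if (f(m) >= thr) a <- m else b <- m
        }
        return((a + b) / 2)
      }
      s <- s2
      if (abs(s) > smax) return(s)
    }
  }
  c(march(-1), march(1))
}

#' Width of a spiral arm at a point
#'
#' Measures the length of the maximal super-threshold segment along the line
#' through `point` normal to the local wave front.  The front normal is the
#' direction of the potential gradient, estimated at the two edges of the
#' arm (where the gradient is large) and refined once: a first chord is
#' found by scanning the axis directions, the normal is re-estimated at its
#' edges, and the width is re-measured along the refined normal through the
#' chord midpoint.  Endpoints are located with sub-cell precision by
#' bisection on the bilinear interpolant.
#'
#' @param field an [eulerian_field()] or matrix (then `grid` required).
#' @param grid grid for a plain matrix.
#' @param threshold super-threshold level defining the excited arm.
#' @param point a position on or near the arm.
#' @return the width, with the chord endpoints in attribute `"endpoints"`.
#' @export
spiral_arm_width <- function(field, grid = NULL, threshold = 0.5, point) {
  if (inherits(field, "eulerian_field")) { grid <- field$grid; V <- field$values }
  else V <- field
  step <- 0.25 * min(grid$dx1, grid$dx2)
  p <- as.numeric(point)
  if (bilinear(V, grid, p[1], p[2]) < threshold) {
    # slide to the nearest super-threshold point along the four axis rays
    best <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      for (s in seq(step, 0.5 * min(grid$hi - grid$lo), by = step)) {
        q <- p + s * d
        if (q[1] < grid$lo[1] + grid$dx1 || q[1] > grid$hi[1] - grid$dx1 ||
            q[2] < grid$lo[2] + grid$dx2 || q[2] > grid$hi[2] - grid$dx2) break
        if (bilinear(V, grid, q[1], q[2]) >= threshold) {
          if (is.null(best) || s < best$s) best <- list(s = s, q = q)
          break
        }
      }
    }
    if (is.null(best))
      stop("spiral_arm_width: no super-threshold segment near the point")
    p <- best$q
  }
  # central-difference gradient averaged over a small sample disc: robust to
  # the staircase texture of near-binary fields
  grad_at <- function(q) {
    h <- min(grid$dx1, grid$dx2)
    offs <- rbind(c(0, 0), c(0.7, 0), c(-0.7, 0), c(0, 0.7), c(0, -0.7),
                  c(0.5, 0.5), c(-0.5, 0.5), c(0.5, -0.5), c(-0.5, -0.5)) * h
    g <- c(0, 0)
    for (k in seq_len(nrow(offs))) {
      qq <- q + offs[k, ]
      g <- g + c(bilinear(V, grid, qq[1] + h, qq[2]) -
                   bilinear(V, grid, qq[1] - h, qq[2]),
                 bilinear(V, grid, qq[1], qq[2] + h) -
                   bilinear(V, grid, qq[1], qq[2] - h)) / (2 * h)
    }
    g / nrow(offs)
  }
  dir <- c(1, 0)
  width <- NA_real_; ends <- NULL
  for (iter in 1:3) {
    ch <- chord_along(V, grid, threshold, p, dir, step)
    if (is.null(ch))
      stop("spiral_arm_width: point left the super-threshold region")
    mid <- p + mean(ch) * dir
    e1 <- p + ch[1] * dir; e2 <- p + ch[2] * dir
    g <- grad_at(e1) - grad_at(e2)   # both point into the arm, opposite senses
    gn <- sqrt(sum(g^2))
    newdir <- if (gn > 0) g / gn else dir
    p <- mid
    dir <- newdir
    ch2 <- chord_along(V, grid, threshold, p, dir, step)
    if (is.null(ch2)) break
    width <- diff(ch2)
    ends <- rbind(p + ch2[1] * dir, p + ch2[2] * dir)
  }
  if (!is.finite(width))
    stop("spiral_arm_width: width measurement did not converge")
  structure(width, endpoints = ends)
}

#' Spiral-arm width averaged over the arms nearest the domain centroid
#'
#' Scans the horizontal and vertical lines through the centroid of the
#' physical domain for super-threshold chords, picks the crossing(s) nearest
#' the centroid (up to `n_arms` distinct arms), measures each with
#' [spiral_arm_width()], and returns the mean.
#'
#' @inheritParams spiral_arm_width
#' @param center domain centroid; defaults to the ghost-box center.
#' @param n_arms number of nearest arm crossings to average (default 2).
#' @export
spiral_width_near_center <- function(field, grid = NULL, threshold = 0.5,
                                     center = NULL, n_arms = 2) {
  if (inherits(field, "eulerian_field")) { grid <- field$grid; V <- field$values }
  else V <- field
  if (is.null(center)) center <- (grid$lo + grid$hi) / 2
  step <- 0.5 * min(grid$dx1, grid$dx2)
  hits <- list()
  for (d in list(c(1, 0), c(0, 1))) {
    span <- 0.5 * sqrt(sum((grid$hi - grid$lo)^2))
    ss <- seq(-span, span, by = step)
    px <- center[1] + ss * d[1]; py <- center[2] + ss * d[2]
    keep <- px > grid$lo[1] + grid$dx1 & px < grid$hi[1] - grid$dx1 &
            py > grid$lo[2] + grid$dx2 & py < grid$hi[2] - grid$dx2
    ss <- ss[keep]
    vv <- bilinear(V, grid, px[keep], py[keep])
    sup <- vv >= threshold
    if (!any(sup)) next
    r <- rle(sup)
    stop_i <- cumsum(r$lengths); start_i <- stop_i - r$lengths + 1
    for (k in which(r$values)) {
      smid <- mean(ss[c(start_i[k], stop_i[k])])
      hits[[length(hits) + 1]] <-
        list(p = center + smid * d, dist = abs(smid))
    }
  }
  if (!length(hits))
    stop("spiral_width_near_center: no super-threshold arm near the centroid")
  ord <- order(vapply(hits, `[[`, numeric(1), "dist"))
  widths <- c()
  for (k in ord) {
    w <- tryCatch(spiral_arm_width(V, grid, threshold, hits[[k]]$p),
                  error = function(e) NULL)
    if (!is.null(w)) widths <- c(widths, as.numeric(w))
    if (length(widths) >= n_arms) break
  }
  if (!length(widths))
    stop("spiral_width_near_center: width measurement failed on all arms")
  mean(widths)
}

#' Rotation sense of a spiral between two snapshots
#'
#' Samples the field on a circle around `center`, estimates the angular
#' shift between the two frames by maximizing the circular cross-correlation,
#' and reports the sense of rotation (in the standard mathematical
#' orientation: x right, y up, angles counter-clockwise).
#'
#' @param snap_a,snap_b two field matrices, `snap_b` later in time.
#' @param grid the grid.
#' @param center circle center; defaults to the box center.
#' @param radius sampling radius; defaults to a quarter of the box width.
#' @param n_theta angular samples.
#' @return `"clockwise"` or `"counterclockwise"`, with the estimated shift
#'   (radians, positive = counter-clockwise) in attribute `"angle"`.
#' @export
rotation_sense <- function(snap_a, snap_b, grid, center = NULL, radius = NULL,
                           n_theta = 720) {
  if (is.null(center)) center <- (grid$lo + grid$hi) / 2
  if (is.null(radius)) radius <- 0.25 * min(grid$hi - grid$lo)
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  a <- bilinear(snap_a, grid, center[1] + radius * cos(th),
                center[2] + radius * sin(th))
  b <- bilinear(snap_b, grid, center[1] + radius * cos(th),
                center[2] + radius * sin(th))
  a <- a - mean(a); b <- b - mean(b)
  # circular cross-correlation: c(k) = sum_j a[(j + k) mod n] * b[j];
  # if b is a rotated by +phi (counter-clockwise), the maximum sits at k
  # corresponding to +phi
  cc <- vapply(0:(n_theta - 1), function(k) {
    sum(a[((0:(n_theta - 1) + k) %% n_theta) + 1] * b)
  }, numeric(1))
  kbest <- which.max(cc) - 1
  shift <- kbest / n_theta * 2 * pi
  if (shift > pi) shift <- shift - 2 * pi
  angle <- -shift  # a[(j+k)] matches b[j] => b lags a by -k
  structure(if (angle < 0) "clockwise" else "counterclockwise",
            angle = angle)
}
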