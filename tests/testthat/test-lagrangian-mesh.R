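test_that("triangulations carry the region area in their quadrature weights", {
  m1 <- triangulate(region_rectangle(c(0, 0), c(1, 1)), 0.5)
  expect_equal(sum(m1$quad_w), 1.0, tolerance = 1e-12)

  m2 <- triangulate(region_rectangle(c(0, 0), c(2.5, 2.5)), 0.1)
  expect_equal(sum(m2$quad_w), 6.25, tolerance = 1e-10)

  m3 <- triangulate(region_circle(c(1.25, 1.25), 1.25), 0.02)
  expect_lt(abs(sum(m3$quad_w) - pi * 1.25^2) / (pi * 1.25^2), 0.01)
  expect_lte(m3$max_edge, 0.02 * (1 + 1e-12))
  # boundary nodes sit on the circle
  r <- sqrt(rowSums(sweep(m3$nodes, 2, c(1.25, 1.25))^2))
  expect_lt(max(r), 1.25 + 1e-12)
})

test_that("triangle quadrature rules are exact at their stated degree", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  q2 <- element_quadrature(tri, 2)
  expect_equal(q2$weights, rep(1 / 6, 3))
  expect_equal(sum(q2$weights), 0.5)
  # integral of x over the unit simplex is 1/6
  expect_equal(sum(q2$points[, 1] * q2$weights), 1 / 6, tolerance = 1e-14)
  # degree-2 exactness: x^2 and xy
  expect_equal(sum(q2$points[, 1]^2 * q2$weights), 1 / 12, tolerance = 1e-14)
  expect_equal(sum(q2$points[, 1] * q2$points[, 2] * q2$weights), 1 / 24,
               tolerance = 1e-14)

  rough <- rbind(c(0.3, -1), c(2, 0.4), c(-0.2, 1.7))
  area <- 0.5 * abs(det(cbind(rough[2, ] - rough[1, ], rough[3, ] - rough[1, ])))
  for (ord in c(1, 2, 4)) {
    q <- element_quadrature(rough, ord)
    expect_equal(sum(q$weights), area, tolerance = 1e-13)
    expect_equal(sum(3.7 * q$weights), 3.7 * area, tolerance = 1e-12)
  }
  expect_error(element_quadrature(tri, 3), "unsupported")
  expect_error(element_quadrature(rbind(c(0, 0), c(1, 1), c(2, 2)), 2),
               "degenerate")
})

test_that("P1 basis interpolation reproduces linear functions exactly", {
  m <- triangulate(region_rectangle(c(0, 0), c(1, 2)), 0.23, quad_order = 2)
  f <- function(x, y) 2.5 * x - 1.3 * y + 0.7
  nodal <- f(m$nodes[, 1], m$nodes[, 2])
  at_quad <- mesh_interp_to_quad(m, nodal)
  expect_lt(max(abs(at_quad - f(m$quad_points[, 1], m$quad_points[, 2]))),
            1e-12)
})

test_that("radial motion moves material points as printed", {
  m <- one_triangle_mesh(rbind(c(2.5, 1.25), c(1.25, 2.5), c(1.25, 1.25)))
  mo <- motion_model(c(1.25, 1.25), rate = 0.5 / 1.25)
  m2 <- advance_motion(m, mo, dt = 0.1)
  # k((2.5,1.25)) = 0.5*1.25/1.25 = 0.5 along +x
  expect_equal(m2$current[1, ], c(2.55, 1.25))
  expect_equal(m2$current[2, ], c(1.25, 2.55))   # radial symmetry
  expect_equal(m2$current[3, ], c(1.25, 1.25))   # centroid does not move
})

test_that("motion is linear in time (constant material velocity)", {
  m <- triangulate(region_rectangle(c(1, 1), c(2, 2)), 0.3)
  mo <- motion_model(c(1.5, 1.5), rate = 0.4)
  d0 <- sqrt(rowSums(sweep(m$nodes, 2, c(1.5, 1.5))^2))
  cur <- m
  for (k in 1:5) {
    cur <- advance_motion(cur, mo, 0.25)
    d <- sqrt(rowSums(sweep(cur$current, 2, c(1.5, 1.5))^2))
    expect_equal(d, d0 * (1 + 0.4 * 0.25 * k), tolerance = 1e-12)
  }
  # quadrature weights track the deformed element areas
  expect_equal(sum(cur$quad_w), 1 * (1 + 0.4 * 1.25)^2, tolerance = 1e-10)
})

test_that("leak guard rejects meshes coarser than the grid allows", {
  g <- build_grid(c(-0.5, 1.5, -0.5, 1.5), 100, 100)  # dx = 0.02
  expect_error(triangulate(region_rectangle(c(0, 0), c(1, 1)),
                           target_edge_length = 0.05, grid = g),
               "leak guard")
  # a looser refinement factor admits the same mesh
  m <- triangulate(region_rectangle(c(0, 0), c(1, 1)),
                   target_edge_length = 0.05, grid = g,
                   refinement_factor = 2.6)
  expect_s3_class(m, "lagrangian_mesh")
})

test_that("motion that exits the ghost box halts with a domain error", {
  g <- build_grid(c(-0.5, 1.5, -0.5, 1.5), 100, 100)
  m <- triangulate(region_rectangle(c(0, 0), c(1, 1)), grid = g)
  mo <- motion_model(c(0.5, 0.5), rate = 2)
  expect_error(advance_motion(m, mo, dt = 1, grid = g), "left the ghost box")
})

test_that("degenerate regions are rejected", {
  expect_error(region_circle(c(0, 0), 0), "radius")
  expect_error(region_rectangle(c(0, 0), c(0, 1)), "degenerate")
  expect_error(region_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero-area")
})
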