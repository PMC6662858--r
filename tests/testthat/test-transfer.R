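test_that("the four-point kernel matches its printed branches", {
  expect_equal(psi(0), 1)
  expect_equal(psi(0.5), 0.5625)
  expect_equal(psi(1.5), -0.0625)
  expect_equal(psi(c(1, 2, 2.5, -2.5)), c(0, 0, 0, 0))
  # four-point stencil at offset 0.5 sums to one
  expect_equal(sum(psi(0.5 - c(-1, 0, 1, 2))), 1)
})

test_that("kernel satisfies the partition of unity on a dense sample", {
  r <- seq(0, 1, length.out = 10000)
  s <- psi(r + 1) + psi(r) + psi(r - 1) + psi(r - 2)
  expect_lt(max(abs(s - 1)), 1e-12)
})

test_that("spreading conserves the Lagrangian integral", {
  g <- build_grid(c(-0.5, 1.5, -0.5, 1.5), 40, 40)
  m <- triangulate(region_rectangle(c(0, 0), c(1, 1)), grid = g,
                   quad_order = 2)
  f0 <- spread(rep(0, nrow(m$quad_points)), m, g)
  expect_equal(max(abs(f0$values)), 0)

  fc <- spread(3.2, m, g)
  expect_equal(sum(fc$values) * g$dx1 * g$dx2, 3.2 * m$area,
               tolerance = 1e-10)

  # still conservative after the structure moves
  m2 <- advance_motion(m, motion_model(c(0.5, 0.5), rate = 0.3), 0.5, g)
  fm <- spread(3.2, m2, g)
  expect_equal(sum(fm$values) * g$dx1 * g$dx2, 3.2 * sum(m2$quad_w),
               tolerance = 1e-10)
})

test_that("a quadrature point on a cell center spreads to that cell only", {
  g <- build_grid(c(0, 1, 0, 1), 10, 10)   # centers at 0.05, 0.15, ...
  # centroid of this triangle is exactly the cell center (0.45, 0.55)
  tri <- rbind(c(0.40, 0.50), c(0.55, 0.50), c(0.40, 0.65))
  m <- one_triangle_mesh(tri)
  expect_equal(m$quad_points[1, ], c(0.45, 0.55), ignore_attr = TRUE)
  f <- spread(2, m, g)
  w <- m$quad_w[1]
  expect_equal(f$values[5, 6], 2 * w / (g$dx1 * g$dx2))
  expect_equal(sum(f$values != 0), 1L)
})

test_that("interpolation reproduces constants, cell values, and linears", {
  g <- build_grid(c(0, 2, 0, 1), 40, 20)
  cc <- cell_centers(g)
  const <- matrix(4.2, 40, 20)
  pts <- with_seed(7, cbind(runif(50, 0.2, 1.8), runif(50, 0.2, 0.8)))
  expect_lt(max(abs(interpolate(const, pts, g) - 4.2)), 1e-12)

  V <- with_seed(8, matrix(rnorm(800), 40, 20))
  expect_equal(interpolate(V, cbind(cc$x[7], cc$y[9]), g), V[7, 9])

  lin <- outer(cc$x, cc$y, function(x, y) 1.7 * x - 0.4 * y + 2)
  got <- interpolate(lin, pts, g)
  expect_lt(max(abs(got - (1.7 * pts[, 1] - 0.4 * pts[, 2] + 2))), 1e-10)
})

test_that("positions too close to the box edge raise a domain error", {
  g <- build_grid(c(0, 1, 0, 1), 10, 10)
  expect_error(interpolate(matrix(0, 10, 10), cbind(0.05, 0.5), g),
               "two cells")
})

test_that("spreading and interpolation are mutually adjoint", {
  g <- build_grid(c(-0.5, 1.5, -0.5, 1.5), 32, 32)
  m <- triangulate(region_rectangle(c(0, 0), c(1, 1)), grid = g,
                   quad_order = 2)
  nq <- nrow(m$quad_points)
  q <- with_seed(21, rnorm(nq))
  E <- with_seed(22, matrix(rnorm(32 * 32), 32, 32))
  lhs <- sum(spread(q, m, g)$values * E) * g$dx1 * g$dx2
  rhs <- sum(q * interpolate(E, m$quad_current, g) * m$quad_w)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("spread-then-interpolate round trip is flat away from the boundary", {
  g <- build_grid(c(-0.5, 1.5, -0.5, 1.5), 64, 64)
  m <- triangulate(region_rectangle(c(0, 0), c(1, 1)), grid = g)
  f <- spread(1, m, g)
  inner <- m$quad_current[, 1] > 0.1 & m$quad_current[, 1] < 0.9 &
           m$quad_current[, 2] > 0.1 & m$quad_current[, 2] < 0.9
  back <- interpolate(f, m$quad_current[inner, ], g)
  expect_lt(max(abs(back - 1)), 0.02)
})

test_that("L2 projection recovers constants, linears, and the dense solve", {
  m <- triangulate(region_rectangle(c(0, 0), c(1, 1)), 0.21, quad_order = 2)
  nq <- nrow(m$quad_points)
  expect_lt(max(abs(project_to_nodes(rep(2.2, nq), m) - 2.2)), 1e-10)
  expect_lt(max(abs(project_to_nodes(rep(2.2, nq), m, lumped = TRUE) - 2.2)),
            1e-10)

  f <- function(x, y) 0.3 * x + 1.1 * y - 0.2
  got <- project_to_nodes(f(m$quad_points[, 1], m$quad_points[, 2]), m)
  expect_lt(max(abs(got - f(m$nodes[, 1], m$nodes[, 2]))), 1e-10)

  # tiny two-triangle mesh against an independent dense assembly
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  elems <- rbind(c(1, 2, 3), c(1, 3, 4))
  m2 <- new_lagrangian_mesh(nodes, elems, quad_order = 2)
  q <- with_seed(31, rnorm(nrow(m2$quad_points)))
  Md <- matrix(0, 4, 4); bd <- numeric(4)
  for (k in seq_len(nrow(m2$quad_points))) {
    phi <- numeric(4)
    phi[m2$quad_nodes[k, ]] <- m2$quad_basis[k, ]
    Md <- Md + outer(phi, phi) * m2$quad_w[k]
    bd <- bd + phi * q[k] * m2$quad_w[k]
  }
  expect_equal(project_to_nodes(q, m2), solve(Md, bd), tolerance = 1e-12)
})

test_that("singular mass systems are reported", {
  # a mesh whose quadrature cannot see one node: duplicate-node triangle
  nodes <- rbind(c(0, 0), c(1, 0), c(0, 1))
  m <- one_triangle_mesh(nodes, quad_order = 1)
  # centroid rule alone makes the 3x3 mass matrix rank one
  expect_error(suppressWarnings(project_to_nodes(c(1), m)), "singular")
})
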