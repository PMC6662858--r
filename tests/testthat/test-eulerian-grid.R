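test_that("grid construction reproduces the benchmark spacings and centers", {
  g <- build_grid(c(-0.1, 2.6, -0.1, 2.6), 275, 275)
  expect_equal(g$dx1, 2.7 / 275)
  expect_equal(g$dx2, 2.7 / 275)

  g2 <- build_grid(c(-0.75, 3.25, -0.75, 3.25), 408, 408)
  expect_equal(g2$dx1, 4.0 / 408)

  g4 <- build_grid(c(0, 1, 0, 1), 4, 4)
  cc <- cell_centers(g4)
  expect_equal(cc$x[1], 0.125)
  expect_equal(cc$y, c(0.125, 0.375, 0.625, 0.875))

  expect_error(build_grid(c(0, 1, 0, 1), 1, 1), "n1 and n2")
  expect_error(build_grid(c(1, 0, 0, 1), 8, 8), "non-degenerate")
})

test_that("laplacian annihilates constants and linears on interior cells", {
  g <- build_grid(c(0, 1, 0, 1), 10, 10)
  cond <- c(2, 0.5)
  interior <- as.matrix(expand.grid(2:9, 2:9))

  Lc <- anisotropic_laplacian(matrix(3.7, 10, 10), cond, grid = g,
                              vrest = 3.7)
  expect_equal(max(abs(Lc[interior])), 0)

  cc <- cell_centers(g)
  lin <- outer(cc$x, cc$y, function(x, y) x)
  Ll <- anisotropic_laplacian(lin, cond, grid = g)
  expect_lt(max(abs(Ll[interior])), 1e-12)
})

test_that("unit impulse produces the five-point stencil", {
  g <- build_grid(c(0, 8, 0, 8), 8, 8)  # dx = dy = 1
  V <- matrix(0, 8, 8); V[4, 5] <- 1
  L <- anisotropic_laplacian(V, c(1, 1), grid = g)
  expect_equal(L[4, 5], -4)
  expect_equal(L[3, 5], 1)
  expect_equal(L[5, 5], 1)
  expect_equal(L[4, 4], 1)
  expect_equal(L[4, 6], 1)
  expect_equal(sum(abs(L)), 8)
})

test_that("operator equals the dense stencil matrix on small grids", {
  for (dims in list(c(5, 7), c(8, 8))) {
    g <- build_grid(c(0, 1.3, -0.2, 1.1), dims[1], dims[2])
    sl <- 0.8; st <- 2.3
    A <- dense_laplacian_matrix(g, sl, st)
    V <- with_seed(11, matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2]))
    L <- anisotropic_laplacian(V, c(sl, st), grid = g)
    expect_equal(as.numeric(L), as.numeric(A %*% as.numeric(V)),
                 tolerance = 1e-13)
  }
})

test_that("operator is symmetric under the zero-Dirichlet convention", {
  g <- build_grid(c(0, 1, 0, 2), 7, 9)
  u <- with_seed(3, matrix(rnorm(63), 7, 9))
  w <- with_seed(4, matrix(rnorm(63), 7, 9))
  Lu <- anisotropic_laplacian(u, c(1.5, 0.3), grid = g)
  Lw <- anisotropic_laplacian(w, c(1.5, 0.3), grid = g)
  expect_equal(sum(Lu * w), sum(u * Lw), tolerance = 1e-12)
})

test_that("laplacian converges at second order on a smooth field", {
  err <- sapply(c(16, 32, 64), function(n) {
    g <- build_grid(c(0, 1, 0, 1), n, n)
    cc <- cell_centers(g)
    V <- outer(cc$x, cc$y, function(x, y) sin(pi * x) * sin(pi * y))
    L <- anisotropic_laplacian(V, c(1, 2), grid = g)
    exact <- -pi^2 * 3 * V
    interior <- as.matrix(expand.grid(3:(n - 2), 3:(n - 2)))
    max(abs(L[interior] - exact[interior]))
  })
  rate <- log2(err[1] / err[2])
  rate2 <- log2(err[2] / err[3])
  expect_gt(rate, 1.8); expect_lt(rate, 2.2)
  expect_gt(rate2, 1.8); expect_lt(rate2, 2.2)
})

test_that("per-direction harmonic conductivity generalizes the lambda form", {
  # equal anisotropy: sigma_e = lambda sigma_i reduces to lambda/(1+lambda)
  ct <- conductivity_tensor(0.4, 0.1, lambda = 1.5)
  expect_equal(unname(monodomain_conductivity(ct)),
               1.5 / 2.5 * c(0.4, 0.1))
  # measured human ventricular values (unequal anisotropy)
  potse <- conductivity_tensor(0.3, 0.03, sigma_e_l = 0.3, sigma_e_t = 0.12)
  expect_equal(unname(monodomain_conductivity(potse)),
               c(0.3 * 0.3 / 0.6, 0.03 * 0.12 / 0.15))
  expect_error(conductivity_tensor(-1, 1, lambda = 1), "positive")
})

test_that("field container validates shape and finiteness", {
  g <- build_grid(c(0, 1, 0, 1), 4, 4)
  expect_error(eulerian_field(g, matrix(0, 3, 4)), "matrix matching")
  expect_error(eulerian_field(g, matrix(c(NaN, rep(0, 15)), 4, 4)), "finite")
  expect_error(anisotropic_laplacian(matrix(0, 5, 5), c(1, 1), grid = g),
               "shape")
})
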