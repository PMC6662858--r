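test_that("rectangle initial conditions follow the printed piecewise table", {
  expect_equal(rectangle_ic(0.5, 0.5), list(u = 1, v = 0))
  expect_equal(rectangle_ic(2.0, 2.0), list(u = 0, v = 0.1))
  expect_equal(rectangle_ic(0.5, 2.0), list(u = 0, v = 0.1))
  # seams resolved in printed branch order (first match wins)
  expect_equal(rectangle_ic(1.25, 0.5)$u, 1)
  expect_equal(rectangle_ic(0.5, 1.25)$v, 0.1)
  expect_error(rectangle_ic(3, 0.5), "outside")
})

test_that("circle initial conditions follow the printed arc bounds", {
  expect_equal(circle_ic(1.0, 1.0)$u, 1)
  expect_equal(circle_ic(1.0, 1.0)$v, 0)
  expect_equal(circle_ic(1.0, 1.5)$v, 0.1)
  expect_equal(circle_ic(1.0, 1.5)$u, 0)
  expect_equal(circle_ic(2.0, 0.5), list(u = 0, v = 0))
  expect_error(circle_ic(2.5, 2.5), "outside")
  # purity: identical inputs give identical outputs
  expect_identical(circle_ic(c(1, 2), c(1, 0.5)), circle_ic(c(1, 2), c(1, 0.5)))
})

test_that("spread initial fields match the indicator away from the interface", {
  g <- build_grid(c(-0.1, 2.6, -0.1, 2.6), 100, 100)
  m <- triangulate(region_rectangle(c(0, 0), c(2.5, 2.5)), grid = g,
                   quad_order = 1)
  pr <- gs_problem(g, m, fhn_model(), dt = 0.1,
                   coefficients = monodomain_coefficients(c(1e-4, 1e-4)),
                   projection = "lumped")
  st <- gs_initial_state(pr, potential = function(x, y) rectangle_ic(x, y)$u)
  cc <- cell_centers(g)
  deep_in <- outer(cc$x, cc$y, function(x, y)
    x > 0.1 & x < 1.15 & y > 0.1 & y < 1.15)
  deep_out <- outer(cc$x, cc$y, function(x, y)
    x > 1.35 & x < 2.4 & y > 0.1 & y < 2.4)
  expect_lt(max(abs(st$V[deep_in] - 1)), 1e-3)
  expect_lt(max(abs(st$V[deep_out])), 1e-3)
})

test_that("benchmark presets reproduce the printed domains and resolutions", {
  rs <- benchmark_spec("rect_stationary")
  expect_equal(rs$grid$extent, c(-0.1, 2.6, -0.1, 2.6))
  expect_equal(rs$grid$n1, 275L)
  expect_equal(rs$time$dt, 0.1)
  expect_equal(rs$physics$K, c(1e-4, 1e-4))
  expect_equal(rs$cell_model$params$epsilon, 0.01)
  expect_false(rs$motion$active)

  rm <- benchmark_spec("rect_moving")
  expect_equal(rm$grid$extent, c(-0.75, 3.25, -0.75, 3.25))
  expect_equal(rm$grid$n1, 408L)
  expect_true(rm$motion$active)
  expect_equal(rm$motion$rate, 0.4)

  cs <- benchmark_spec("circle_stationary")
  expect_equal(cs$mesh$region$center, c(1.25, 1.25))
  expect_equal(cs$mesh$region$radius, 1.25)
})

test_that("benchmark specs round-trip through YAML serialization", {
  cfg <- benchmark_spec("circle_moving")
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(cfg, path)
  back <- load_config(path)
  expect_equal(back$grid$extent, cfg$grid$extent)
  expect_equal(back$motion, cfg$motion, tolerance = 1e-15)
  expect_equal(back$mesh$region$radius, cfg$mesh$region$radius)
})

test_that("transverse ventricular section has disjoint, adjacent masks", {
  sec <- ventricle_section("transverse", edge = 1.5)
  expect_true(all(vapply(sec$masks, any, logical(1))))
  # pairwise disjoint
  expect_false(any(sec$masks$septum & sec$masks$lv_endo_stim))
  expect_false(any(sec$masks$septum & sec$masks$rv_endo_stim))
  expect_false(any(sec$masks$lv_endo_stim & sec$masks$rv_endo_stim))
  # the septum touches both chambers: it contains points close to the LV
  # cavity and points close to the RV cavity
  qp <- sec$mesh$quad_points[sec$masks$septum, , drop = FALSE]
  p <- sec$params
  dL <- sqrt((qp[, 1] - p$lv_center[1])^2 + (qp[, 2] - p$lv_center[2])^2)
  dR <- sqrt((qp[, 1] - p$rv_center[1])^2 + (qp[, 2] - p$rv_center[2])^2)
  expect_lt(min(dL), p$lv_r_in + 2)
  expect_lt(min(dR), p$rv_r_in + 2)
  # probes inside the tissue
  inside <- ghostwave:::ventricle_indicator("transverse", p)
  expect_true(all(inside(sec$probes[, 1], sec$probes[, 2])))
})

test_that("longitudinal section builds and fits its box", {
  sec <- ventricle_section("longitudinal", edge = 2)
  expect_true(all(vapply(sec$masks, any, logical(1))))
  nd <- sec$mesh$nodes
  expect_true(all(nd[, 1] >= 0 & nd[, 1] <= 140 &
                  nd[, 2] >= 0 & nd[, 2] <= 140))
})

test_that("healthy and LBBB stimulation cover the printed region sets", {
  sec <- ventricle_section("transverse", edge = 1.5)
  healthy <- ventricle_stimulus(sec, "healthy")
  expect_setequal(names(healthy$regions),
                  c("septum", "lv_endo_stim", "rv_endo_stim"))
  lbbb <- ventricle_stimulus(sec, "lbbb")
  expect_identical(names(lbbb$regions), "rv_endo_stim")
  expect_lt(lbbb$amplitude, 0)   # depolarizing in the subtract convention
})
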