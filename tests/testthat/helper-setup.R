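# Shared builders for small test problems.  Everything is generated in code;
# sizes are kept small so the unit suite stays fast.

# small conforming setup: rectangle [0,1]^2 inside the box [-0.1,1.1]^2
small_grid <- function(n = 24) build_grid(c(-0.1, 1.1, -0.1, 1.1), n, n)

small_mesh <- function(grid, quad_order = 1, factor = 0.5) {
  triangulate(region_rectangle(c(0, 0), c(1, 1)), grid = grid,
              refinement_factor = factor, quad_order = quad_order)
}

small_problem <- function(n = 24, K = c(1e-4, 1e-4), quad_order = 1,
                          reaction_mode = "frozen", projection = "lumped",
                          ...) {
  g <- small_grid(n)
  m <- small_mesh(g, quad_order = quad_order)
  gs_problem(g, m, fhn_model(), dt = 0.1,
             coefficients = monodomain_coefficients(K),
             reaction_mode = reaction_mode, projection = projection, ...)
}

# scaled spiral initial conditions on [0,1]^2
unit_square_ic <- function(x, y) rectangle_ic(2.5 * x, 2.5 * y)

unit_square_state <- function(problem) {
  gs_initial_state(problem,
                   potential = function(x, y) unit_square_ic(x, y)$u,
                   state = function(x, y)
                     matrix(unit_square_ic(x, y)$v, ncol = 1))
}

# a single-triangle mesh (no grid-based leak check)
one_triangle_mesh <- function(verts, quad_order = 1) {
  new_lagrangian_mesh(verts, matrix(1:3, 1), quad_order = quad_order)
}

# dense matrix of the anisotropic 5-point stencil with a zero-Dirichlet ring
dense_laplacian_matrix <- function(grid, sl, st) {
  n1 <- grid$n1; n2 <- grid$n2
  N <- n1 * n2
  A <- matrix(0, N, N)
  id <- function(i, j) (j - 1) * n1 + i
  cx <- sl / grid$dx1^2; cy <- st / grid$dx2^2
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    r <- id(i, j)
    A[r, r] <- -2 * cx - 2 * cy
    if (i > 1) A[r, id(i - 1, j)] <- cx
    if (i < n1) A[r, id(i + 1, j)] <- cx
    if (j > 1) A[r, id(i, j - 1)] <- cy
    if (j < n2) A[r, id(i, j + 1)] <- cy
  }
  A
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
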