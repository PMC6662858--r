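# Configuration files, snapshot/trace writers, and mesh readers.

config_schema <- function() {
  list(
    schema_version = "integer",
    preset = "character",
    grid = list(extent = "numeric4", n1 = "integer", n2 = "integer"),
    mesh = list(region = "list", refinement_factor = "numeric",
                quad_order = "integer", target_edge_length = "numeric"),
    cell_model = list(name = "character", params = "list"),
    physics = list(units = "character", K = "numeric2",
                   conductivity = "list", Cm = "numeric", Am = "numeric"),
    time = list(dt = "numeric", t_end = "numeric"),
    motion = list(active = "logical", centroid = "numeric2",
                  rate = "numeric", t_stop = "numeric"),
    ic = "character",
    stimulus = list(mode = "character", amplitude = "numeric",
                    start = "numeric", duration = "numeric"),
    numerics = list(reaction_mode = "character", projection = "character",
                    refresh_every = "integer", guard = "numeric"),
    output = list(probes = "list", snapshot_times = "numeric_vec")
  )
}

check_scalar <- function(value, type, path) {
  ok <- switch(type,
    integer = is.numeric(value) && length(value) == 1 &&
      value == round(value),
    numeric = is.numeric(value) && length(value) == 1,
    numeric2 = is.numeric(value) && length(value) == 2,
    numeric4 = is.numeric(value) && length(value) == 4,
    numeric_vec = is.numeric(value),
    character = is.character(value) && length(value) == 1,
    logical = is.logical(value) && length(value) == 1,
    list = is.list(value),
    TRUE)
  if (!ok)
    stop(sprintf("config: field '%s' must be %s", path, type), call. = FALSE)
}

validate_config <- function(cfg, schema = config_schema(), path = "") {
  if (!is.list(cfg)) stop("config: '", path, "' must be a mapping")
  for (key in names(cfg)) {
    sub <- schema[[key]]
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (is.null(sub))
      stop("config: unknown field '", here, "'", call. = FALSE)
    if (is.list(sub) && !identical(key, "mesh$region")) {
      if (key %in% c("mesh", "grid", "cell_model", "physics", "time",
                     "motion", "stimulus", "numerics", "output"))
        validate_config(cfg[[key]], sub, here)
    } else if (is.character(sub)) {
      check_scalar(cfg[[key]], sub, here)
    }
  }
  invisible(cfg)
}

validate_ranges <- function(cfg) {
  fail <- function(path, msg)
    stop(sprintf("config: field '%s' %s", path, msg), call. = FALSE)
  if (!is.null(cfg$time$dt) && cfg$time$dt <= 0) fail("time.dt", "must be > 0")
  if (!is.null(cfg$time$t_end) && cfg$time$t_end < 0)
    fail("time.t_end", "must be >= 0")
  if (!is.null(cfg$grid)) {
    if (cfg$grid$n1 < 4 || cfg$grid$n2 < 4) fail("grid.n1/n2", "must be >= 4")
    e <- cfg$grid$extent
    if (e[2] <= e[1] || e[4] <= e[3]) fail("grid.extent", "is degenerate")
  }
  if (!is.null(cfg$physics$K) && any(cfg$physics$K <= 0))
    fail("physics.K", "must be > 0")
  if (!is.null(cfg$stimulus$duration) && cfg$stimulus$duration <= 0)
    fail("stimulus.duration", "must be > 0")
  if (!is.null(cfg$numerics$reaction_mode) &&
      !cfg$numerics$reaction_mode %in% c("per_stage", "frozen"))
    fail("numerics.reaction_mode", "must be 'per_stage' or 'frozen'")
  if (!is.null(cfg$numerics$projection) &&
      !cfg$numerics$projection %in% c("consistent", "lumped"))
    fail("numerics.projection", "must be 'consistent' or 'lumped'")
  invisible(cfg)
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(override[[key]]) && is.list(base[[key]]) &&
        !key %in% c("region", "probes"))
      base[[key]] <- merge_config(base[[key]], override[[key]])
    else base[[key]] <- override[[key]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, expands the `preset:` key (one of the named
#' benchmarks of [benchmark_spec()], with the remaining keys overriding the
#' preset), validates the schema (unknown keys and out-of-range values are
#' rejected with field-precise messages), and fills defaults.
#'
#' @param path file path, or a list already in configuration form.
#' @return validated configuration list of class `gw_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    yaml::read_yaml(path)
  } else path
  if (!is.list(cfg)) stop("load_config: configuration must be a mapping")
  # yaml scalars arrive as length-1; coerce known vector fields
  if (!is.null(cfg$preset)) {
    base <- benchmark_spec(cfg$preset)
    cfg$preset <- NULL
    cfg <- merge_config(base, cfg)
  }
  validate_config(cfg)
  validate_ranges(cfg)
  defaults <- list(
    schema_version = 1L,
    physics = list(units = "dimensionless", Cm = 1, Am = 1),
    numerics = list(reaction_mode = "per_stage", projection = "consistent",
                    refresh_every = 1L, guard = 1e6),
    output = list(snapshot_times = numeric(), probes = list()))
  cfg <- merge_config(defaults, cfg)
  class(cfg) <- c("gw_config", "list")
  cfg
}

region_from_config <- function(rc) {
  switch(rc$type,
    rectangle = region_rectangle(rc$lo, rc$hi),
    circle = region_circle(rc$center, rc$radius),
    polygon = region_polygon(do.call(rbind, rc$vertices)),
    stop("config: unknown mesh.region.type '", rc$type, "'"))
}

#' Build a runnable problem from a configuration
#'
#' @param cfg a [load_config()] configuration.
#' @return list with `problem` ([gs_problem()]), `state` (initial
#'   [gs_initial_state()]), `n_steps`, `probes`, `snapshot_times`.
#' @export
build_problem <- function(cfg) {
  if (!inherits(cfg, "gw_config")) cfg <- load_config(cfg)
  grid <- build_grid(cfg$grid$extent, cfg$grid$n1, cfg$grid$n2)
  model <- switch(cfg$cell_model$name,
    fhn = fhn_model(do.call(fhn_params, cfg$cell_model$params %||% list())),
    surrogate_ventricular =
      do.call(surrogate_ventricular_model, cfg$cell_model$params %||% list()),
    stop("config: unknown cell_model.name '", cfg$cell_model$name, "'"))
  motion <- NULL
  stretch <- 1
  if (isTRUE(cfg$motion$active)) {
    motion <- motion_model(cfg$motion$centroid, cfg$motion$rate,
                           active = TRUE, t_stop = cfg$motion$t_stop)
    stretch <- 1 + motion$rate * min(motion$t_stop, cfg$time$t_end)
  }
  rf <- cfg$mesh$refinement_factor %||% 0.5
  edge <- cfg$mesh$target_edge_length %||%
    (rf * min(grid$dx1, grid$dx2) / stretch)
  mesh <- triangulate(region_from_config(cfg$mesh$region),
                      target_edge_length = edge, grid = grid,
                      refinement_factor = rf,
                      quad_order = cfg$mesh$quad_order %||% 2L)
  co <- if (!is.null(cfg$physics$K)) {
    monodomain_coefficients(cfg$physics$K, units = "dimensionless")
  } else {
    ct <- cfg$physics$conductivity
    cond <- conductivity_tensor(ct$sigma_l, ct$sigma_t, lambda = ct$lambda,
                                sigma_e_l = ct$sigma_e_l,
                                sigma_e_t = ct$sigma_e_t)
    monodomain_coefficients(monodomain_conductivity(cond),
                            Cm = cfg$physics$Cm, Am = cfg$physics$Am,
                            units = "physiological")
  }
  problem <- gs_problem(grid, mesh, model, dt = cfg$time$dt,
                        coefficients = co, motion = motion,
                        reaction_mode = cfg$numerics$reaction_mode,
                        projection = cfg$numerics$projection,
                        refresh_every = cfg$numerics$refresh_every,
                        guard = cfg$numerics$guard)
  icf <- switch(cfg$ic %||% "rest",
    rectangle = function(x, y) rectangle_ic(x, y),
    circle = function(x, y) circle_ic(x, y),
    rest = NULL,
    stop("config: unknown ic '", cfg$ic, "'"))
  state <- if (is.null(icf)) gs_initial_state(problem)
  else gs_initial_state(problem,
                        potential = function(x, y) icf(x, y)$u,
                        state = function(x, y) matrix(icf(x, y)$v, ncol = 1))
  probes <- NULL
  if (length(cfg$output$probes)) {
    pts <- lapply(cfg$output$probes, function(p) {
      if (identical(p, "speed_point") || length(p) != 2) NULL else p
    })
    sp <- cfg$output$probes$speed_point
    probes <- do.call(rbind, c(
      if (!is.null(sp)) list(speed_probe_positions(grid, sp)),
      Filter(Negate(is.null), pts[names(pts) != "speed_point"])))
  }
  list(problem = problem, state = state,
       n_steps = as.integer(round(cfg$time$t_end / cfg$time$dt)),
       probes = probes,
       snapshot_times = cfg$output$snapshot_times %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read an Eulerian field as a legacy-VTK structured-points file
#'
#' ASCII, one scalar per cell center, full 64-bit precision (`%.17g`), so a
#' write/read round trip is lossless.
#'
#' @param field an [eulerian_field()] or matrix (then `grid` required).
#' @param path output file.
#' @param grid grid for a plain matrix.
#' @param name scalar field name in the file.
#' @export
write_vtk_field <- function(field, path, grid = NULL, name = "V") {
  if (inherits(field, "eulerian_field")) { grid <- field$grid; V <- field$values }
  else V <- field
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ghostwave field snapshot",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$n1, grid$n2),
               sprintf("ORIGIN %.17g %.17g 0",
                       grid$lo[1] + grid$dx1 / 2, grid$lo[2] + grid$dx2 / 2),
               sprintf("SPACING %.17g %.17g 1", grid$dx1, grid$dx2),
               sprintf("POINT_DATA %d", grid$n1 * grid$n2),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.17g", as.numeric(V)), con)
  invisible(path)
}

#' @rdname write_vtk_field
#' @export
read_vtk_field <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
    lines[grepl("^DIMENSIONS", lines)])), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "",
    lines[grepl("^ORIGIN", lines)])), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
    lines[grepl("^SPACING", lines)])), "\\s+")[[1]])
  start <- which(grepl("^LOOKUP_TABLE", lines))[1] + 1L
  vals <- as.numeric(lines[start:(start + dims[1] * dims[2] - 1L)])
  grid <- build_grid(c(origin[1] - spacing[1] / 2,
                       origin[1] + spacing[1] * (dims[1] - 0.5),
                       origin[2] - spacing[2] / 2,
                       origin[2] + spacing[2] * (dims[2] - 0.5)),
                     dims[1], dims[2])
  eulerian_field(grid, matrix(vals, dims[1], dims[2]))
}

#' Write an Eulerian field as flat binary with a JSON sidecar
#'
#' Little-endian 64-bit doubles in column-major order plus `<path>.json`
#' describing extent, cell counts and spacing.
#'
#' @inheritParams write_vtk_field
#' @export
write_field_bin <- function(field, path, grid = NULL) {
  if (inherits(field, "eulerian_field")) { grid <- field$grid; V <- field$values }
  else V <- field
  con <- file(path, "wb")
  writeBin(as.numeric(V), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(kind = "ghostwave_field", dtype = "float64", endian = "little",
         order = "column_major", n1 = grid$n1, n2 = grid$n2,
         extent = c(grid$lo[1], grid$hi[1], grid$lo[2], grid$hi[2]),
         spacing = c(grid$dx1, grid$dx2)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_bin
#' @export
read_field_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  vals <- readBin(con, "double", n = meta$n1 * meta$n2, size = 8,
                  endian = "little")
  close(con)
  grid <- build_grid(meta$extent, meta$n1, meta$n2)
  eulerian_field(grid, matrix(vals, meta$n1, meta$n2))
}

#' Write all snapshots and traces of a run to a directory
#'
#' Emits, per snapshot, a legacy-VTK structured-points file and a
#' mesh-positions file with zero-padded step indices in the filenames, plus
#' the probe traces as CSV and a `run.json` with enough metadata (package
#' version, final time, grid) to re-execute the run.
#'
#' @param run a `gs_run`.
#' @param dir output directory (created if missing).
#' @param config optional configuration list to copy alongside.
#' @export
write_run_dir <- function(run, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- run$problem$grid
  dt <- run$problem$dt
  for (k in seq_along(run$snapshots)) {
    step <- as.integer(round(run$snap_times[k] / dt))
    write_vtk_field(run$snapshots[[k]],
                    file.path(dir, sprintf("V_%06d.vtk", step)), grid)
    write_mesh_text(run$state$mesh,
                    file.path(dir, sprintf("mesh_%06d.txt", step)),
                    current = TRUE)
  }
  write.csv(format(run$probes, digits = 17, scientific = FALSE),
            file.path(dir, "probes.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(package = "ghostwave",
         version = as.character(utils::packageVersion("ghostwave")),
         schema_version = 1L, t_final = run$state$t, dt = dt,
         grid = list(extent = c(grid$lo[1], grid$hi[1], grid$lo[2],
                                grid$hi[2]),
                     n1 = grid$n1, n2 = grid$n2),
         config = config),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Plain-text mesh format (nodes + elements)
#'
#' Whitespace format: a comment header, a line `M T`, then `M` node lines
#' `x y` and `T` element lines of 1-based node indices `i j k`.
#'
#' @param mesh a `lagrangian_mesh`.
#' @param path file path.
#' @param current write current (deformed) positions instead of material.
#' @export
write_mesh_text <- function(mesh, path, current = FALSE) {
  nodes <- if (current) mesh$current else mesh$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ghostwave mesh (nodes: x y; elements: i j k, 1-based)",
               sprintf("%d %d", nrow(nodes), nrow(mesh$elements))), con)
  writeLines(sprintf("%.17g %.17g", nodes[, 1], nodes[, 2]), con)
  writeLines(sprintf("%d %d %d", mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_text
#' @inheritParams triangulate
#' @export
read_mesh_text <- function(path, grid = NULL, refinement_factor = 0.5,
                           quad_order = 2) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  counts <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  m <- counts[1]; tr <- counts[2]
  nodes <- do.call(rbind, lapply(strsplit(trimws(lines[2:(1 + m)]), "\\s+"),
                                 as.numeric))
  elements <- do.call(rbind,
    lapply(strsplit(trimws(lines[(2 + m):(1 + m + tr)]), "\\s+"), as.integer))
  new_lagrangian_mesh(nodes, elements, grid = grid,
                      refinement_factor = refinement_factor,
                      quad_order = quad_order)
}

#' Read a Gmsh MSH (ASCII v2.2) triangle mesh
#'
#' Parses `$Nodes` and the 3-node-triangle entries of `$Elements`; other
#' element types (points, lines) are ignored.
#'
#' @param path `.msh` file.
#' @inheritParams triangulate
#' @export
read_gmsh <- function(path, grid = NULL, refinement_factor = 0.5,
                      quad_order = 2) {
  lines <- readLines(path)
  sec <- function(tag) {
    i0 <- which(lines == paste0("$", tag))
    i1 <- which(lines == paste0("$End", tag))
    if (!length(i0) || !length(i1)) stop("read_gmsh: missing $", tag)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1])
  ndat <- do.call(rbind, lapply(strsplit(trimws(nd[2:(1 + nn)]), "\\s+"),
                                as.numeric))
  ids <- as.integer(ndat[, 1])
  nodes <- matrix(NA_real_, max(ids), 2)
  nodes[ids, ] <- ndat[, 2:3]
  el <- sec("Elements")
  ne <- as.integer(el[1])
  rows <- strsplit(trimws(el[2:(1 + ne)]), "\\s+")
  tris <- list()
  for (r in rows) {
    v <- as.integer(r)
    if (v[2] == 2L) {          # type 2 = 3-node triangle; v[3] = #tags
      ntag <- v[3]
      tris[[length(tris) + 1L]] <- v[(4L + ntag):(6L + ntag)]
    }
  }
  if (!length(tris)) stop("read_gmsh: no 3-node triangles in file")
  elements <- do.call(rbind, tris)
  used <- sort(unique(as.vector(elements)))
  renum <- integer(nrow(nodes)); renum[used] <- seq_along(used)
  new_lagrangian_mesh(nodes[used, , drop = FALSE],
                      matrix(renum[elements], ncol = 3), grid = grid,
                      refinement_factor = refinement_factor,
                      quad_order = quad_order)
}
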