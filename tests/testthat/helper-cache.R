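# Shared fixtures, memoized across test files (the default mesh, its
# operators, the calibrated infiltration diffusivity, and the long healing
# runs used by the qualitative-sequence tests).

.th_cache <- new.env(parent = emptyenv())

th_cached <- function(key, expr) {
  if (!exists(key, envir = .th_cache)) {
    assign(key, force(expr), envir = .th_cache)
  }
  get(key, envir = .th_cache)
}

default_mesh <- function() th_cached("mesh", build_mesh(geometry_params()))

default_ops <- function() th_cached("ops", mesh_operators(default_mesh()))

default_D <- function() {
  th_cached("D_cells", as.numeric(
    calibrate_cell_infiltration(default_mesh(), ops = default_ops())))
}

# Small, fast geometry for simulation plumbing tests.
tiny_geometry <- function() {
  geometry_params(n_cross = 2L, n_axial_stump = 1L, n_axial_callus = 2L)
}

tiny_config <- function(..., horizon = 5L, seed = 7L,
                        transport = list(D_cells = 0.5)) {
  simulation_config(geometry = tiny_geometry(), transport = transport,
                    horizon = horizon, seed = seed, ...)
}

# 140-day study runs on the default mesh, shared seed, calibrated D.
healing_run <- function(key) {
  th_cached(paste0("run_", key), {
    tr <- list(D_cells = default_D())
    cfg <- switch(
      key,
      PE = simulation_config(rule_set = "PE", horizon = 140L, seed = 42L,
                             transport = tr),
      ENDO20 = simulation_config(rule_set = "PE-ENDO",
                                 endo = endo_gate_params(rho_c = 0.20),
                                 horizon = 140L, seed = 42L, transport = tr),
      ENDO25 = simulation_config(rule_set = "PE-ENDO",
                                 endo = endo_gate_params(rho_c = 0.25),
                                 horizon = 140L, seed = 42L, transport = tr),
      OXY = simulation_config(rule_set = "PE-OXY", horizon = 140L,
                              seed = 42L, transport = tr),
      OXY_AOSS3 = simulation_config(rule_set = "PE-OXY", horizon = 140L,
                                    seed = 42L,
                                    transport = c(tr, list(a_oss = 3))),
      OXY_O025 = simulation_config(rule_set = "PE-OXY", horizon = 140L,
                                   seed = 42L,
                                   transport = c(tr, list(O = 0.25))),
      OXY_A025 = simulation_config(rule_set = "PE-OXY", horizon = 140L,
                                   seed = 42L,
                                   transport = c(tr, list(A = 0.25))),
      OXY_C075 = simulation_config(rule_set = "PE-OXY", horizon = 140L,
                                   seed = 42L,
                                   transport = c(tr, list(C = 0.75))),
      stop("unknown run key: ", key))
    run_healing(cfg)
  })
}

# Hand-built diffusion oracle for the unit-cube hexahedron: Laplacian
# entries derived by hand from the trilinear shape functions (diagonal 1/3,
# edge neighbours 0, face and body diagonals -1/12) and lumped mass 1/8.
unit_cube_laplacian <- function() {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  L <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    shared <- sum(corners[i, ] == corners[j, ])
    # self, edge neighbour, face diagonal, body diagonal
    L[i, j] <- switch(4 - shared, 1 / 3, 0, -1 / 12, -1 / 12)
  }
  L
}

# Unit cube split into 6 tetrahedra (a Kuhn triangulation).
unit_cube_tets <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  elems <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                 c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  list(nodes = nodes, elems = elems)
}
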