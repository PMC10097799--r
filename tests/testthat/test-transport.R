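test_that("a uniform field without sources is a diffusion fixed point", {
  m <- fixture_bar(3)
  rho <- rep(0.4, nrow(m$nodes))
  out <- diffuse_step(m, rho, D = 0.7, dt = 1)
  expect_equal(out, rho, tolerance = 1e-12)
})

test_that("diffusion without sources conserves lumped mass", {
  mesh <- default_mesh()
  ops <- default_ops()
  set.seed(3)
  rho <- runif(nrow(mesh$nodes), 0.2, 0.8)
  m0 <- sum(ops$lumped * rho)
  out <- rho
  for (k in 1:3) out <- diffuse_step(mesh, out, D = 0.3, dt = 1, ops = ops)
  expect_equal(sum(ops$lumped * out), m0, tolerance = 1e-10)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("the implicit source step matches the hand-derived recursion", {
  # Unit-cube fixture, bottom face held at 1: by symmetry the four free
  # nodes share one value x obeying x_{k+1} = (m x_k + dt D a) / (m + dt D a)
  # with lumped mass m = 1/8 and a = sum of conductances to the source
  # face, read off the hand-built unit-cube Laplacian.
  L <- unit_cube_laplacian()
  a <- -sum(L[5, 1:4])   # = 1/4
  expect_equal(a, 1 / 4)
  m <- 1 / 8
  D <- 0.23
  dt <- 1
  x <- 0
  mesh <- fixture_single_element()
  rho <- numeric(8)
  for (k in 1:5) {
    x <- (m * x + dt * D * a) / (m + dt * D * a)
    rho <- diffuse_step(mesh, rho, D, dt, sources = 1:4)
    expect_equal(unname(rho[5:8]), rep(x, 4), tolerance = 1e-12)
  }
  # free nodes approach the source value monotonically from below
  expect_true(all(diff(c(0, x)) > 0) && x < 1)
})

test_that("oxygen consumption follows the closed-form exponential decay", {
  mesh <- fixture_single_element()
  rho <- rep(1, 8)
  cells <- rep(1, 8)
  for (k in 1:2)
    rho <- oxygen_step(mesh, rho, O = 0.5, C = 0.5, cells = cells, dt = 1)
  expect_equal(rho, rep(exp(-0.5 * 2), 8), tolerance = 1e-12)
})

test_that("oxygen with zero cells reduces to plain diffusion", {
  bar <- fixture_bar(4)
  set.seed(5)
  rho <- runif(nrow(bar$nodes))
  src <- bar$sets$surface
  a <- oxygen_step(bar, rho, O = 0.3, C = 0.5, cells = numeric(nrow(bar$nodes)),
                   dt = 1, sources = src)
  b <- diffuse_step(bar, rho, D = 0.3, dt = 1, sources = src)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("consumption only ever lowers oxygen", {
  mesh <- build_mesh(tiny_geometry())
  src <- mesh$sets$surface
  with_sink <- without <- numeric(nrow(mesh$nodes))
  cells <- rep(1, nrow(mesh$nodes))
  for (k in 1:10) {
    with_sink <- oxygen_step(mesh, with_sink, O = 0.1, C = 0.5,
                             cells = cells, dt = 1, sources = src)
    without <- oxygen_step(mesh, without, O = 0.1, C = 0,
                           cells = cells, dt = 1, sources = src)
  }
  expect_true(all(with_sink <= without + 1e-12))
  free <- setdiff(seq_len(nrow(mesh$nodes)), src)
  expect_true(all(with_sink[free] < 1))
})

test_that("angiogenesis only advances through sub-threshold elements", {
  bar <- fixture_bar(10)
  gate <- angio_gate(a_oss = 6)
  src <- bar$sets$surface                  # fixed face, nodes 1:4
  oss <- c(rep(1, 5), rep(10, 5))          # distal half above threshold
  rho <- numeric(nrow(bar$nodes))
  rho[src] <- 1
  for (k in 1:20)
    rho <- angiogenesis_step(bar, rho, A = 1, dt = 1, stimuli = oss,
                             gate = gate, sources = src)
  # reachability on the gated conductance graph: elements 1-5 span nodes
  # 1:24; everything beyond stays at zero
  expect_true(all(rho[5:24] > 0))
  expect_equal(unname(rho[25:44]), rep(0, 20))

  # fully gated: nothing moves
  rho2 <- numeric(nrow(bar$nodes))
  rho2[src] <- 1
  out2 <- angiogenesis_step(bar, rho2, A = 1, dt = 1,
                            stimuli = rep(10, 10), gate = gate,
                            sources = src)
  expect_equal(out2, rho2)

  # ungated: identical to plain diffusion
  rho3 <- numeric(nrow(bar$nodes))
  out3 <- angiogenesis_step(bar, rho3, A = 1, dt = 1,
                            stimuli = rep(1, 10), gate = gate,
                            sources = src)
  expect_equal(out3, diffuse_step(bar, rho3, D = 1, dt = 1, sources = src),
               tolerance = 1e-12)
})

test_that("angiogenesis is non-decreasing under a shifting gate", {
  bar <- fixture_bar(6)
  src <- bar$sets$surface
  rho <- numeric(nrow(bar$nodes))
  rho[src] <- 1
  set.seed(9)
  for (k in 1:15) {
    oss <- runif(6, 0, 12)   # random gate pattern each day
    nxt <- angiogenesis_step(bar, rho, A = 0.4, dt = 1, stimuli = oss,
                             gate = angio_gate(6), sources = src)
    expect_true(all(nxt >= rho - 1e-15))
    rho <- nxt
  }
})

test_that("vessel maturation is strict and monotone", {
  expect_true(mature_vessels(0.95, FALSE))
  expect_false(mature_vessels(0.90, FALSE))    # strictly more than 90%
  expect_true(mature_vessels(0.90 + 1e-12, FALSE))
  # once flagged, stays flagged even if the field drops
  flags <- mature_vessels(c(0.95, 0.5), c(FALSE, FALSE))
  expect_equal(mature_vessels(c(0.1, 0.1), flags), flags)
})

test_that("calibrated infiltration reaches the day-14 target", {
  mesh <- default_mesh()
  ops <- default_ops()
  D <- default_D()
  rho <- numeric(nrow(mesh$nodes))
  for (d in 1:14)
    rho <- diffuse_step(mesh, rho, D, 1, mesh$sets$surface, ops)
  m14 <- callus_mean(mesh, rho, ops)
  expect_gte(m14, 0.95)
  expect_lte(m14, 0.97)

  # doubling D strictly increases the day-14 mean
  rho2 <- numeric(nrow(mesh$nodes))
  for (d in 1:14)
    rho2 <- diffuse_step(mesh, rho2, 2 * D, 1, mesh$sets$surface, ops)
  expect_gt(callus_mean(mesh, rho2, ops), m14)

  # vanishing D leaves only a boundary layer
  rho3 <- numeric(nrow(mesh$nodes))
  for (d in 1:14)
    rho3 <- diffuse_step(mesh, rho3, 1e-4, 1, mesh$sets$surface, ops)
  expect_lt(callus_mean(mesh, rho3, ops), 0.5)
})

test_that("transport steps validate their inputs", {
  m <- fixture_bar(2)
  rho <- numeric(nrow(m$nodes))
  expect_error(diffuse_step(m, rho, D = -1, dt = 1), "D must be > 0")
  expect_error(diffuse_step(m, rho, D = 1, dt = 0), "dt must be > 0")
  expect_error(oxygen_step(m, rho, O = 1, C = -0.1, cells = rho, dt = 1),
               "C must be >= 0")
  expect_error(angiogenesis_step(m, rho, A = 1, dt = 1, stimuli = NULL),
               "missing")
  expect_error(
    calibrate_cell_infiltration(fixture_bar(2), bracket = c(1e-6, 2e-6)),
    "unreachable")
})
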