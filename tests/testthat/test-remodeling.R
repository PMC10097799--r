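mk_state <- function(densities = c(fat = 0, tendon = 0.1, cartilage = 0,
                                   bone = 0)) {
  mesh <- fixture_single_element()
  set.seed(1)
  state <- element_state_init(mesh)
  state$densities[1, ] <- densities[c("fat", "tendon", "cartilage", "bone")]
  state
}

test_that("production increments follow the daily rates", {
  # bone at 1.2%/day, full cells, past the inflammatory phase
  st <- mk_state()
  out <- produce_and_degrade(st, "bone", rate = 0.012, cells = 1, dt = 1,
                             day = 10)
  expect_equal(unname(out$densities[1, "bone"]), 0.012, tolerance = 1e-12)

  # default rate at half cell density: 0.02 * 0.5 = 0.01
  out2 <- produce_and_degrade(mk_state(), "cartilage", rate = 0.02,
                              cells = 0.5, dt = 1, day = 10)
  expect_equal(unname(out2$densities[1, "cartilage"]), 0.01, tolerance = 1e-12)

  # no cells, no production
  out3 <- produce_and_degrade(mk_state(), "bone", rate = 0.012, cells = 0,
                              dt = 1, day = 10)
  expect_equal(out3$densities, mk_state()$densities)
})

test_that("the inflammatory baseline makes tendon at half the default rate", {
  st <- mk_state()
  out <- produce_and_degrade(st, "none", rate = 0, cells = 1, dt = 1,
                             day = 3)
  expect_equal(unname(out$densities[1, "tendon"]) - 0.1, 0.5 * 0.02,
               tolerance = 1e-12)
  # after day 5 the baseline no longer applies
  out2 <- produce_and_degrade(mk_state(), "none", rate = 0, cells = 1,
                              dt = 1, day = 6)
  expect_equal(out2$densities, mk_state()$densities)
})

test_that("degradation is proportional to the current composition", {
  st <- mk_state(c(fat = 0, tendon = 0.4, cartilage = 0.1, bone = 0))
  out <- produce_and_degrade(st, "bone", rate = 0.012, cells = 1, dt = 1,
                             day = 10)
  expect_equal(unname(out$densities[1, "tendon"]), 0.4 - 0.0096, tolerance = 1e-12)
  expect_equal(unname(out$densities[1, "cartilage"]), 0.1 - 0.0024,
               tolerance = 1e-12)
  expect_equal(unname(out$densities[1, "bone"]), 0.012, tolerance = 1e-12)
})

test_that("density bookkeeping never leaves [0, 1]", {
  set.seed(21)
  st <- mk_state(c(fat = 0.2, tendon = 0.5, cartilage = 0.2, bone = 0.1))
  for (k in 1:300) {
    tis <- sample(c("fat", "tendon", "cartilage", "bone", "none"), 1)
    st <- produce_and_degrade(st, tis, rate = runif(1, 0, 0.05),
                              cells = runif(1), dt = 1, day = 10)
    d <- st$densities[1, ]
    expect_true(all(d >= -1e-12))
    expect_lte(sum(d), 1 + 1e-9)
  }
})

test_that("production into an otherwise empty element is pure gain", {
  st <- mk_state(c(fat = 0, tendon = 0, cartilage = 0, bone = 0))
  out <- produce_and_degrade(st, "cartilage", rate = 0.02, cells = 1,
                             dt = 1, day = 10)
  expect_equal(sum(out$densities[1, ]), 0.02, tolerance = 1e-12)
})

test_that("stump elements are immutable", {
  mesh <- build_mesh(tiny_geometry())
  set.seed(2)
  st <- element_state_init(mesh)
  out <- produce_and_degrade(st, "bone", rate = 0.012, cells = 1, dt = 1,
                             day = 10)
  stump <- st$region == "stump"
  expect_equal(out$densities[stump, ], st$densities[stump, ])
  expect_true(all(out$densities[!stump, "bone"] > 0))
  mat <- update_material_state(out)
  expect_equal(mat$multiplier[stump], rep(1, sum(stump)))
})

test_that("unknown tissue labels are rejected", {
  expect_error(produce_and_degrade(mk_state(), "muscle", 0.02, 1, 1, 10),
               "unknown tissue")
})

test_that("fibril reorientation follows the linear-in-time schedule", {
  st <- mk_state()
  target <- c(0, 0, 1)
  # a fibril parallel to the target is a fixed point
  st$fibrils[1, , ] <- matrix(rep(c(0, 0, 1), each = 13), 13, 3)
  out <- reorient_fibrils(st, target)
  expect_equal(out$fibrils[1, , ], st$fibrils[1, , ], tolerance = 1e-12)

  # perpendicular fibril: one step rotates by 90/28 degrees
  st2 <- mk_state()
  st2$fibrils[1, , ] <- matrix(rep(c(1, 0, 0), each = 13), 13, 3)
  out2 <- reorient_fibrils(st2, target)
  ang <- acos(out2$fibrils[1, 1, ] %*% c(1, 0, 0))
  expect_equal(as.numeric(ang) * 180 / pi, 90 / 28, tolerance = 1e-8)

  # after 28 daily steps the fibril is aligned to within 1 degree
  st3 <- mk_state()
  st3$fibrils[1, , ] <- matrix(rep(c(1, 0, 0), each = 13), 13, 3)
  for (d in 1:28) st3 <- reorient_fibrils(st3, target)
  ang3 <- acos(pmin(1, abs(st3$fibrils[1, 1, ] %*% c(0, 0, 1))))
  expect_lt(as.numeric(ang3) * 180 / pi, 1)
})

test_that("reorientation is sign-symmetric and rotation-invariant", {
  st <- mk_state()
  stm <- mk_state()
  out_p <- reorient_fibrils(st, c(0, 0, 1))
  out_m <- reorient_fibrils(stm, c(0, 0, -1))
  expect_equal(out_p$fibrils, out_m$fibrils, tolerance = 1e-12)

  # rotating fibrils and target together commutes with the update
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  a <- mk_state()
  b <- mk_state()
  b$fibrils[1, , ] <- a$fibrils[1, , ] %*% t(R)
  upd_a <- reorient_fibrils(a, c(0, 1, 0))
  upd_b <- reorient_fibrils(b, as.numeric(R %*% c(0, 1, 0)))
  expect_equal(upd_b$fibrils[1, , ], upd_a$fibrils[1, , ] %*% t(R),
               tolerance = 1e-10)
})

test_that("reorientation rejects degenerate targets", {
  expect_error(reorient_fibrils(mk_state(), c(0, 0, 0)), "nonzero")
})

test_that("fibril unit norm is preserved through many updates", {
  st <- mk_state()
  set.seed(4)
  for (d in 1:40) {
    tgt <- rnorm(3)
    st <- reorient_fibrils(st, tgt / sqrt(sum(tgt^2)))
  }
  nrm <- sqrt(rowSums(st$fibrils[1, , ]^2))
  expect_equal(nrm, rep(1, 13), tolerance = 1e-9)
})

test_that("element state snapshots round-trip through disk", {
  st <- mk_state(c(fat = 0.1, tendon = 0.3, cartilage = 0.2, bone = 0.1))
  path <- tempfile(fileext = ".rds")
  write_state(st, path)
  back <- read_state(path)
  expect_equal(back, st)
  saveRDS(list(), path)
  expect_error(read_state(path), "element state")
})
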