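test_that("the combined shear/flow stimulus evaluates its closed form", {
  expect_equal(stim_combined(0, 0), 0)
  expect_equal(stim_combined(3.75, 0), 1)
  expect_equal(stim_combined(3.75, 3), 2)
  expect_equal(stim_combined(7.5, 6), 4)
  expect_error(stim_combined(-1, 0), "non-negative")
})

test_that("classification examples follow the rule tables", {
  pe <- rule_set("PE")
  expect_equal(classify(pe, e1 = 1), "bone")
  expect_equal(classify(pe, e1 = 3), "cartilage")
  expect_equal(classify(pe, e1 = 6), "tendon")
  # ties closed on the cartilage side
  expect_equal(classify(pe, e1 = 2), "cartilage")
  expect_equal(classify(pe, e1 = 4), "cartilage")

  ossff <- rule_set("OSS-FF")
  expect_equal(classify(ossff, oss = 1.875, ff = 0), "bone")  # stim = 0.5
  expect_equal(classify(ossff, oss = 0, ff = 6), "cartilage") # stim = 2
  expect_equal(classify(ossff, oss = 15, ff = 3), "tendon")   # stim = 5
  expect_equal(classify(ossff, oss = 3.75, ff = 0), "cartilage")

  oxy <- rule_set("PE-OXY")
  expect_equal(classify(oxy, e1 = 50, oxygen = 2, blood = TRUE), "cartilage")
  expect_equal(classify(oxy, e1 = 30, oxygen = 50, blood = TRUE), "fat")
  expect_equal(classify(oxy, e1 = 1, oxygen = 50, blood = TRUE), "bone")
  expect_equal(classify(oxy, e1 = 10, oxygen = 50, blood = TRUE), "tendon")
  expect_equal(classify(oxy, e1 = 10, oxygen = 50, blood = FALSE), "none")

  hs <- rule_set("PE-HS")
  expect_equal(classify(hs, e1 = 3, hydro = -0.5), "cartilage")
  expect_equal(classify(hs, e1 = 3, hydro = -0.1), "bone")
  expect_equal(classify(hs, e1 = 8, hydro = -0.1), "tendon")

  pp <- rule_set("PE-PP")
  expect_equal(classify(pp, e1 = 10, pp = 0.5), "cartilage")
  expect_equal(classify(pp, e1 = 3, pp = 0.05), "bone")
  expect_equal(classify(pp, e1 = 3, pp = -0.5), "tendon")
  expect_equal(classify(pp, e1 = 20, pp = 0.05), "tendon")
})

test_that("all rule sets are exclusive and exhaustive on random tuples", {
  for (nm in c("PE", "PE-HS", "PE-PP", "OSS-FF", "PE-OXY", "PE-ENDO")) {
    rs <- rule_set(nm)
    res <- validate_rule_set(rs, n = 3000, seed = 17)
    expect_lte(res$max_matches, 1L)
    # exhaustiveness: every tuple classifies to exactly one known label
    set.seed(17)
    labs <- classify_elements(rs, list(
      e1 = runif(500, -5, 45), hydro = runif(500, -1, 1),
      pp = runif(500, -1, 1), oss = runif(500, 0, 25),
      ff = runif(500, 0, 12), oxygen = runif(500, 0, 100),
      blood = sample(c(TRUE, FALSE), 500, TRUE)))
    expect_true(all(labs %in% c("fat", "tendon", "cartilage", "bone",
                                "none")))
  }
})

test_that("bisection recovers every printed threshold", {
  tol <- 1e-5  # bisection brackets to 1e-6 absolute
  pe <- rule_set("PE")
  expect_equal(classification_boundary(pe, "e1", 0, 10), 2,
               tolerance = tol)
  expect_equal(classification_boundary(pe, "e1", 2.5, 10), 4,
               tolerance = tol)

  hs <- rule_set("PE-HS")
  expect_equal(classification_boundary(hs, "e1", 0.5, 10,
                                       fixed = list(hydro = -0.1)), 5,
               tolerance = tol)
  expect_equal(classification_boundary(hs, "hydro_comp", 0, 1,
                                       fixed = list(e1 = 3)), 0.2,
               tolerance = tol)

  pp <- rule_set("PE-PP")
  expect_equal(classification_boundary(pp, "pp", 0, 1,
                                       fixed = list(e1 = 10)), 0.15,
               tolerance = tol)
  expect_equal(classification_boundary(pp, "e1", 10, 20,
                                       fixed = list(pp = 0.5)), 15,
               tolerance = tol)

  ossff <- rule_set("OSS-FF")
  expect_equal(classification_boundary(ossff, "stim", 0, 2), 1,
               tolerance = tol)
  expect_equal(classification_boundary(ossff, "stim", 2, 5), 3,
               tolerance = tol)

  oxy <- rule_set("PE-OXY")
  expect_equal(classification_boundary(oxy, "e1", 10, 40,
                                       fixed = list(oxygen = 50,
                                                    blood = TRUE)), 25,
               tolerance = tol)
  expect_equal(classification_boundary(oxy, "oxygen", 0, 20,
                                       fixed = list(e1 = 10,
                                                    blood = TRUE)), 3,
               tolerance = tol)
})

test_that("the endochondral gate requires a cartilage or bone template", {
  p20 <- endo_gate_params(rho_c = 0.20)
  p25 <- endo_gate_params(rho_c = 0.25)
  expect_equal(endochondral_gate("bone", 1, 0.30, 0, p25), "bone")
  expect_equal(endochondral_gate("bone", 1, 0.10, 0, p25), "none")
  expect_equal(endochondral_gate("bone", 1, 0, 0.05, p25), "bone")
  expect_equal(endochondral_gate("bone", 3, 0.30, 0.5, p25), "none")
  expect_equal(endochondral_gate("bone", 1, 0.22, 0, p20), "bone")
  expect_equal(endochondral_gate("bone", 1, 0.22, 0, p25), "none")
  # non-bone proposals pass through
  expect_equal(endochondral_gate(c("tendon", "cartilage"), c(1, 1),
                                 c(0, 0), c(0, 0), p25),
               c("tendon", "cartilage"))
})

test_that("the strain-dependent tendon law rises to a peak then falls", {
  expect_equal(tendon_rate_law(0), 0)
  expect_equal(tendon_rate_law(15), 0.02)
  expect_equal(tendon_rate_law(7.5), 0.01)
  expect_equal(tendon_rate_law(22.5), 0.01)
  expect_equal(tendon_rate_law(30), 0)
  expect_equal(tendon_rate_law(45), 0)
  expect_error(tendon_rate_law(-1), "negative")
  # continuity at the breakpoints
  eps <- 1e-9
  expect_equal(tendon_rate_law(15 - eps), tendon_rate_law(15 + eps),
               tolerance = 1e-6)
  expect_equal(tendon_rate_law(30 - eps), 0, tolerance = 1e-6)
})

test_that("the phase diagram tabulates rule regions over a stimulus pair", {
  pe <- rule_set("PE")
  pd <- phase_diagram(pe, "e1", "oxygen", x = c(1, 3, 6), y = c(0, 50))
  expect_equal(dim(pd), c(3L, 2L))
  expect_equal(unname(pd[, 1]), c("bone", "cartilage", "tendon"))
  expect_equal(pd[, 1], pd[, 2])  # PE ignores oxygen
  hs <- rule_set("PE-HS")
  pd2 <- phase_diagram(hs, "e1", "hydro_comp", x = c(3, 8),
                       y = c(0.1, 0.4))
  expect_equal(unname(pd2), rbind(c("bone", "cartilage"),
                                  c("tendon", "tendon")))
})
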