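test_that("body-weight adjustment is the cube root of bw/70", {
  expect_equal(bw_adjustment(70), 1)
  expect_equal(bw_adjustment(60), (60 / 70)^(1 / 3))
  expect_equal(bw_adjustment(60), 0.9499, tolerance = 1e-4)
  expect_equal(bw_adjustment(18), 0.63590, tolerance = 1e-4)
  expect_error(bw_adjustment(0), "positive")
  expect_error(bw_adjustment(-5), "positive")
})

test_that("exposure profiles carry the screening defaults and validate", {
  a <- exposure_profile("adult")
  expect_equal(a[c("ir_ing", "ir_inh", "sa", "af", "abs", "ef", "ed", "bw", "at")],
               list(ir_ing = 100, ir_inh = 20, sa = 5700, af = 0.07,
                    abs = 0.13, ef = 365, ed = 24, bw = 60, at = 25550))
  k <- exposure_profile("child")
  expect_equal(k[c("ir_ing", "ir_inh", "sa", "af", "ed", "bw")],
               list(ir_ing = 200, ir_inh = 10, sa = 2800, af = 0.2,
                    ed = 6, bw = 18))
  over <- exposure_profile("child", ir_inh = 9.6)
  expect_equal(over$ir_inh, 9.6)
  expect_error(exposure_profile("adult", bw = -1), "positive")
  expect_error(exposure_profile("adult", abs = 2), "fraction")
  expect_error(exposure_profile("adult", ef = 400), "366")
  expect_error(exposure_profile("adult", at = 10), "averaging time")
  expect_error(exposure_profile("adult", nonsense = 1), "unknown")
})

test_that("each ILCR route matches direct evaluation of its formula", {
  p <- exposure_profile("adult")
  s <- slope_factors()
  c0 <- 42.5
  adj <- (p$bw / 70)^(1 / 3)
  expect_equal(ilcr_ingestion(c0, p, s),
               c0 * 7.3 * adj * 100 * 365 * 24 / (60 * 25550 * 1e6))
  expect_equal(ilcr_inhalation(c0, p, s),
               c0 * 3.85 * adj * 20 * 365 * 24 / (60 * 25550 * 1.36e9))
  expect_equal(ilcr_dermal(c0, p, s),
               c0 * 25 * adj * 5700 * 0.07 * 0.13 * 365 * 24 / (60 * 25550 * 1e6))
  # zero concentration, zero absorption
  expect_equal(ilcr_ingestion(0, p, s), 0)
  p0 <- exposure_profile("adult")
  expect_equal(ilcr_dermal(c0, exposure_profile("adult", abs = 1e-12), s) /
                 ilcr_dermal(c0, p0, s), 1e-12 / 0.13)
  expect_error(ilcr_ingestion(-1, p, s), "nonnegative")
})

test_that("inhalation risk is inversely proportional to the PEF", {
  p <- exposure_profile("child")
  base <- ilcr_inhalation(50, p, slope_factors())
  halved <- ilcr_inhalation(50, p, slope_factors(pef = 2 * 1.36e9))
  expect_equal(halved, base / 2)
})

test_that("routes are linear in c, EF and ED, and decrease in body weight", {
  s <- slope_factors()
  routes <- list(ilcr_ingestion, ilcr_inhalation, ilcr_dermal)
  set.seed(31)
  for (f in routes) {
    c0 <- stats::runif(1, 1, 100)
    p <- exposure_profile("adult")
    expect_equal(f(2 * c0, p, s), 2 * f(c0, p, s))
    expect_equal(f(c0, exposure_profile("adult", ef = 146), s),
                 f(c0, p, s) * 146 / 365)
    expect_equal(f(c0, exposure_profile("adult", ed = 12), s),
                 f(c0, p, s) / 2)
    # (bw/70)^(1/3)/bw is strictly decreasing in bw
    expect_lt(f(c0, exposure_profile("adult", bw = 120), s), f(c0, p, s))
  }
})

test_that("total ILCR conserves the route sum", {
  set.seed(37)
  s <- slope_factors()
  for (rc in c("adult", "child")) {
    p <- exposure_profile(rc)
    c0 <- stats::runif(1, 1, 200)
    r <- assess_risk(c0, p, s)
    expect_equal(r$ilcr_total,
                 r$ilcr_ingestion + r$ilcr_inhalation + r$ilcr_dermal)
    expect_true(all(unlist(r[c("ilcr_ingestion", "ilcr_inhalation",
                               "ilcr_dermal", "ilcr_total")]) >= 0))
  }
})

test_that("EDI matches hand evaluation for both receptors", {
  c0 <- 98.34
  expect_equal(edi(c0, exposure_profile("adult")),
               98.34 * 100 * 24 * 365 / (25550 * 60))
  expect_equal(edi(c0, exposure_profile("adult")), 56.194, tolerance = 1e-4)
  expect_equal(edi(c0, exposure_profile("child")), 93.657, tolerance = 1e-4)
  expect_equal(edi(0, exposure_profile("child")), 0)
  expect_error(edi(c0, exposure_profile("adult"), cf = 0), "cf")
})

test_that("hazard quotient is EDI/RfD and scale-equivariant in (CF, RfD)", {
  expect_equal(hazard_quotient(3, 2), 1.5)
  expect_equal(hazard_quotient(2e-3, 2e-3), 1)
  expect_error(hazard_quotient(1, 0), "positive")
  p <- exposure_profile("adult")
  for (k in c(1e-3, 1, 1e3)) {
    hq1 <- hazard_quotient(edi(98.34, p, cf = 1), rfd = 2e-3)
    hq2 <- hazard_quotient(edi(98.34, p, cf = k), rfd = 2e-3 * k)
    expect_equal(hq2, hq1)
  }
})

test_that("screening classification uses strict thresholds", {
  r <- assess_risk(98.34, exposure_profile("adult"))
  expect_true(r$cancer_exceeds)
  expect_true(r$noncancer_exceeds)
  low <- list(ilcr_total = 1e-7, hq = 0.5)
  cl <- classify_risk(low)
  expect_false(cl$cancer_exceeds)
  expect_false(cl$noncancer_exceeds)
  # exactly at the limit is not an exceedance
  expect_false(classify_risk(list(ilcr_total = 1e-6, hq = 1))$cancer_exceeds)
  expect_false(classify_risk(list(ilcr_total = 1e-6, hq = 1))$noncancer_exceeds)
})
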