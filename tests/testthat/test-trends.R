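years21 <- 1997:2017

test_that("a noiseless exponential series recovers its slope exactly", {
  py <- rep(1e9, 21)
  cnt <- 1e-4 * 1.03^(years21 - 1997) * py
  f <- fit_segmented_loglinear(years21, cnt, py)
  expect_equal(f$n_joinpoints, 0L)
  expect_equal(f$slopes[1], log(1.03), tolerance = 1e-10)
  expect_equal(aapc(f)$aapc, 3, tolerance = 1e-8)

  # constant series: zero slope, zero joinpoints
  f0 <- fit_segmented_loglinear(years21, rep(500, 21), rep(1e6, 21))
  expect_equal(f0$n_joinpoints, 0L)
  expect_equal(f0$slopes[1], 0, tolerance = 1e-10)
})

test_that("a deterministic two-phase series yields the true joinpoint and the
          closed-form length-weighted AAPC", {
  py <- rep(1e9, 21)
  b1 <- log(1.05); b2 <- log(1.01)
  rate <- ifelse(years21 <= 2007, 1e-4 * exp(b1 * (years21 - 1997)),
                 1e-4 * exp(b1 * 10 + b2 * (years21 - 2007)))
  f <- fit_segmented_loglinear(years21, rate * py, py, max_joinpoints = 2)
  expect_equal(f$n_joinpoints, 1L)
  expect_equal(f$breakpoints, 2007)
  expect_equal(f$slopes, c(b1, b2), tolerance = 1e-8)
  # equal-length segments: AAPC = 100*(exp((b1+b2)/2) - 1) ~ 2.981
  est <- aapc(f)
  expect_equal(est$aapc, 100 * (exp((b1 + b2) / 2) - 1), tolerance = 1e-8)
  # interval entirely inside the first segment: AAPC equals that segment's APC
  est1 <- aapc(f, interval = c(1998, 2005))
  expect_equal(est1$aapc, 100 * (exp(b1) - 1), tolerance = 1e-8)
  # sub-interval weighting: [2002, 2012] covers 5 years of each segment
  est2 <- aapc(f, interval = c(2002, 2012))
  expect_equal(est2$weights, c(0.5, 0.5))
  expect_error(aapc(f, interval = c(2005, 2005)), "empty")
  expect_error(aapc(f, interval = c(1990, 2005)), "outside")
})

test_that("AAPC is invariant to rescaling counts and person-years at fixed
          segmentation", {
  # joint rescaling leaves every per-segment slope unchanged; the BIC choice
  # of segment count is compared at matched k since evidence scales with
  # counts
  with_seed_local(4, {
    py <- rep(2e6, 21)
    cnt <- rpois(21, 3e-4 * 1.02^(years21 - 1997) * py)
    for (k in 0:1) {
      f1 <- fit_segmented_loglinear(years21, cnt, py, max_joinpoints = k)
      f2 <- fit_segmented_loglinear(years21, 7 * cnt, 7 * py,
                                    max_joinpoints = k)
      if (f1$n_joinpoints == f2$n_joinpoints)
        expect_equal(aapc(f1)$aapc, aapc(f2)$aapc, tolerance = 1e-8)
    }
    f0a <- fit_segmented_loglinear(years21, cnt, py, max_joinpoints = 0)
    f0b <- fit_segmented_loglinear(years21, 13 * cnt, 13 * py,
                                   max_joinpoints = 0)
    expect_equal(f0a$slopes, f0b$slopes, tolerance = 1e-8)
  })
})

test_that("BIC does not overfit single-segment data with large counts", {
  for (s in 1:3) {
    with_seed_local(100 + s, {
      py <- rep(5e6, 21)
      cnt <- rpois(21, 2e-4 * 1.03^(years21 - 1997) * py)
      f <- fit_segmented_loglinear(years21, cnt, py, max_joinpoints = 2)
      expect_equal(f$n_joinpoints, 0L)
    })
  }
})

test_that("series length and shape preconditions are enforced", {
  expect_error(fit_segmented_loglinear(2000:2004, rep(1, 5), rep(1e4, 5),
                                       max_joinpoints = 2),
               "too short")
  expect_error(fit_segmented_loglinear(c(2000, 2002, 2003), c(1, 1, 1),
                                       rep(1e4, 3), max_joinpoints = 0),
               "consecutive")
})

test_that("WLS-on-log-rate mode reproduces an exact log-linear series", {
  py <- rep(1e6, 21)
  cnt <- 50 * 1.04^(years21 - 1997)
  f <- fit_segmented_loglinear(years21, cnt, py, method = "wls")
  expect_equal(f$slopes[1], log(1.04), tolerance = 1e-8)
})

test_that("per-area AAPC matches the national fit for an identical series and
          flags all-zero areas", {
  inc <- as_incidence_table(data.frame(
    sex = "male", histology = "adenocarcinoma",
    area_id = rep(c("A1", "A2"), each = 21),
    year = rep(years21, 2), age_group = "50-54",
    count = c(round(200 * 1.03^(0:20)), rep(0, 21))))
  py <- as_person_years_table(data.frame(
    sex = "male", area_id = rep(c("A1", "A2"), each = 21),
    year = rep(years21, 2), age_group = "50-54", person_years = 1e6))
  expect_warning(
    aa <- area_aapc(inc, py, groups_30_84, years21, sex = "male",
                    histology = "adenocarcinoma"),
    "unestimable")
  expect_false(aa$estimable[aa$area_id == "A2"])
  expect_true(is.na(aa$aapc[aa$area_id == "A2"]))
  nat <- fit_segmented_loglinear(years21, round(200 * 1.03^(0:20)),
                                 rep(1e6, 21), max_joinpoints = 1)
  expect_equal(aa$aapc[aa$area_id == "A1"], aapc(nat)$aapc,
               tolerance = 1e-8)
})

test_that("per-area AAPC recovers a known trend within Monte-Carlo error", {
  with_seed_local(7, {
    cnt <- rpois(21, 1e-4 * 1.02^(years21 - 1997) * 5e6)
    inc <- as_incidence_table(data.frame(
      sex = "male", histology = "adenocarcinoma", area_id = "A1",
      year = years21, age_group = "50-54", count = cnt))
    py <- as_person_years_table(data.frame(
      sex = "male", area_id = "A1", year = years21, age_group = "50-54",
      person_years = 5e6))
    aa <- area_aapc(inc, py, groups_30_84, years21, sex = "male",
                    histology = "adenocarcinoma")
    # CI from the fit should cover the generating 2%/yr trend
    expect_true(aa$ci_low < 2 & 2 < aa$ci_high)
    expect_equal(aa$aapc, 2, tolerance = 0.5)
  })
})
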