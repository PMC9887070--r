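test_that("the 11x4 grid has 44 cells and 14 cohorts with the right birth years", {
  reg <- small_registry()
  grid <- build_apc_grid(reg$incidence, reg$person_years,
                         age_range = c(30, 84), period_range = c(1997, 2016),
                         sex = "male", histology = "adenocarcinoma")
  expect_equal(grid$A * grid$P, 44L)
  expect_equal(grid$C, 14L)
  expect_equal(grid$cohort_year, seq(1917, 1982, by = 5))
  # oldest age group, first period: 1999 - 82 -> 1917 cohort
  expect_equal(grid$cohort_index[11, 1], 0L)
  expect_equal(grid$cohort_year[grid$cohort_index[11, 1] + 1L], 1917)
  # counts and person-years aggregate consistently
  expect_equal(sum(grid$O),
               sum(reg$incidence$count[reg$incidence$sex == "male" &
                     reg$incidence$histology == "adenocarcinoma"]))
})

test_that("degenerate and malformed grids are rejected or minimal", {
  g1 <- new_apc_grid(matrix(2, 1, 1), matrix(1e4, 1, 1), 32, 1999)
  expect_equal(g1$C, 1L)
  tt <- tiny_tables()
  expect_error(build_apc_grid(tt$incidence, tt$person_years,
                              c(30, 84), c(2010, 2014)), "empty")
})

test_that("cohort bookkeeping bijects diagonals onto cohort indices", {
  for (dims in list(c(11L, 4L), c(3L, 5L), c(2L, 2L))) {
    A <- dims[1]; P <- dims[2]
    g <- new_apc_grid(matrix(1, A, P), matrix(1, A, P),
                      seq(32, by = 5, length.out = A),
                      seq(1999, by = 5, length.out = P))
    expect_setequal(as.vector(unique(g$cohort_index)), 0:(A + P - 2))
    # every diagonal is constant: same cohort for all its cells
    for (ci in 0:(A + P - 2)) {
      cells <- which(g$cohort_index == ci, arr.ind = TRUE)
      expect_true(all(cells[, 2] - cells[, 1] == cells[1, 2] - cells[1, 1]))
    }
  }
})

test_that("the reference fit is saturated on a 2x2 grid", {
  O <- matrix(c(12, 40, 7, 33), 2, 2)
  N <- matrix(c(1e4, 2e4, 1.5e4, 2.5e4), 2, 2)
  g <- new_apc_grid(O, N, c(32, 37), c(1999, 2004))
  fit <- fit_apc_reference(g)
  fitted <- N * exp(apc_fitted_lograte(fit))
  expect_equal(unname(fitted), O, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$deviance, 0, tolerance = 1e-8)
})

test_that("a pure age model yields null period and cohort effects", {
  eff <- list(alpha = make_crv_effects()$alpha, pi = rep(0, 4),
              gamma = rep(0, 14))
  sim <- generate_apc_grid(effects = eff, seed = 3)
  noise_free <- sim$grid
  noise_free$O <- sim$truth$lambda
  fit <- fit_apc_reference(noise_free)
  expect_equal_num(fit$pi, rep(0, 4), 1e-10)
  expect_equal_num(fit$gamma, rep(0, 14), 1e-10)
  expect_equal_num(fit$curv_period, rep(0, 2), 1e-10)
  expect_equal_num(fit$curv_cohort, rep(0, 12), 1e-10)
  expect_equal_num(fit$alpha, eff$alpha, 1e-8)
})

test_that("curvatures are recovered and are drift-invariant", {
  sim <- generate_apc_grid(seed = 5)
  fit <- fit_apc_reference(sim$grid)
  # second differences are estimable: compare with the generating truth
  expect_equal_num(fit$curv_cohort, diff(sim$truth$gamma, differences = 2),
                   0.02)
  expect_equal_num(fit$curv_period, diff(sim$truth$pi, differences = 2),
                   0.02)
  # and exactly invariant under drift reallocation
  for (d in c(-0.2, 0.01, 0.37)) {
    e2 <- drift_reallocate(fit, d)
    expect_equal(e2$curv_cohort, fit$curv_cohort, tolerance = 1e-12)
    expect_equal(e2$curv_period, fit$curv_period, tolerance = 1e-12)
    expect_equal(e2$net_drift, fit$net_drift, tolerance = 1e-10)
  }
})

test_that("drift reallocation is an exact involution leaving the fit unchanged", {
  sim <- generate_apc_grid(seed = 5)
  fit <- fit_apc_reference(sim$grid)
  expect_equal(drift_reallocate(fit, 0)$pi, fit$pi)
  for (d in c(-0.1, 0.05, 0.5)) {
    e2 <- drift_reallocate(fit, d)
    # fitted cell log-rates unchanged
    expect_equal_num(apc_fitted_lograte(e2), apc_fitted_lograte(fit), 1e-10)
    # Poisson deviance constant along the flat direction
    expect_lt(abs(regimap:::apc_deviance(e2) - regimap:::apc_deviance(fit)),
              1e-8)
    # zero-sum coding preserved
    expect_lt(abs(sum(e2$pi)) + abs(sum(e2$gamma)) + abs(sum(e2$alpha)), 1e-10)
    # reallocating back restores the original effects
    e3 <- drift_reallocate(e2, -d)
    expect_equal(e3$pi, fit$pi, tolerance = 1e-12)
    expect_equal(e3$gamma, fit$gamma, tolerance = 1e-12)
    expect_equal(e3$alpha, fit$alpha, tolerance = 1e-12)
  }
})

test_that("relative variation is the CV on the rate-ratio scale", {
  expect_equal(relative_variation(c(0, 0, 0)), 0)
  # exp effects {1, 3}: population SD 1, mean 2 -> RV 0.5
  expect_equal(relative_variation(c(log(1), log(3))), 0.5)
  # shift-free on the ratio scale
  v <- c(-0.2, 0.1, 0.4)
  expect_equal(relative_variation(v), relative_variation(v + 1.3),
               tolerance = 1e-12)
  expect_error(relative_variation(0.5), "at least 2")
})

test_that("the CRV solution balances the two relative variations and recovers
          effects generated under the equal-RV condition", {
  sim <- generate_apc_grid(seed = 7)
  eff <- solve_crv(sim$grid)
  expect_lt(abs(eff$rv_period - eff$rv_cohort), 1e-8)
  expect_equal_num(eff$alpha, sim$truth$alpha, 0.02)
  expect_equal_num(eff$pi, sim$truth$pi, 0.02)
  expect_equal_num(eff$gamma, sim$truth$gamma, 0.02)
  # the profile shows the two RV curves crossing inside the bracket
  prof <- eff$profile
  gg <- prof$rv_period - prof$rv_cohort
  expect_true(sign(gg[1]) != sign(gg[nrow(prof)]))
})

test_that("the exactly-null grid returns the drift-free solution and the noisy
          pure-age grid fails loudly with candidate minima", {
  eff <- list(alpha = make_crv_effects()$alpha, pi = rep(0, 4),
              gamma = rep(0, 14))
  sim <- generate_apc_grid(effects = eff, seed = 3)
  exact <- sim$grid
  exact$O <- sim$truth$lambda
  s <- solve_crv(exact)
  expect_equal(s$delta_star, 0)
  expect_equal_num(s$pi, rep(0, 4), 1e-10)
  expect_equal_num(s$gamma, rep(0, 14), 1e-10)
  expect_error(solve_crv(sim$grid), "candidate .g. minima")
})

test_that("falling-drift strata solve just as well as rising ones", {
  sim <- generate_apc_grid(effects = make_crv_effects(cohort_drift = -0.03),
                           seed = 9)
  eff <- solve_crv(sim$grid)
  expect_lt(abs(eff$rv_period - eff$rv_cohort), 1e-8)
  expect_equal_num(eff$gamma, sim$truth$gamma, 0.02)
})

test_that("bootstrap bands bracket the point estimates", {
  sim <- generate_apc_grid(seed = 7)
  eff <- solve_crv(sim$grid)
  bands <- apc_bootstrap_bands(eff, n_boot = 25, seed = 2)
  expect_true(all(bands$band_low <= bands$effect + 1e-9))
  expect_true(all(bands$effect <= bands$band_high + 1e-9))
  p <- plot_apc_effects(eff, bands)
  expect_s3_class(p, "ggplot")
})
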