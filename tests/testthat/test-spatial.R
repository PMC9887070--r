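test_that("between-area variance estimator honors its limit cases", {
  expect_equal(estimate_tau2(rep(1, 10), runif(10, 0.1, 1), 1), 0)
  v <- c(0.4, 1.2, 1.6, 0.9)
  expect_equal(estimate_tau2(v, rep(0, 4), 1), mean((v - 1)^2))
  expect_error(estimate_tau2(1, 0.1, 1), "at least 2")
})

test_that("between-area variance is recovered on synthetic areas", {
  with_seed_local(42, {
    n <- 300
    s2 <- runif(n, 0.005, 0.03)
    b <- rnorm(n, 0, sqrt(0.04))
    v <- 1 + b + rnorm(n, 0, sqrt(s2))
    est <- estimate_tau2(v, s2, 1)
    # the estimable target is the realized between-area second moment
    expect_lt(abs(est - mean(b^2)) / mean(b^2), 0.25)
    expect_lt(abs(est - 0.04) / 0.04, 0.35)
  })
})

test_that("shrinkage obeys its contract at the limits and in between", {
  expect_equal(shrink_to_null(2, 0, 0.5, 1)$stabilized, 2)    # sigma = 0
  expect_equal(shrink_to_null(2, 0.5, 0, 1)$stabilized, 1)    # tau2 = 0
  expect_equal(shrink_to_null(2, 0.3, 0.3, 1)$stabilized, 1.5)  # half weight
  d <- shrink_to_null(2, 0, 0, 1)
  expect_true(d$degenerate)
  expect_equal(d$stabilized, 1)
  # |z - m0| strictly decreasing in sigma^2 for fixed v - m0
  s2 <- seq(0, 5, by = 0.25)
  z <- shrink_to_null(rep(2, length(s2)), s2, 0.8, 1)$stabilized
  expect_true(all(diff(abs(z - 1)) < 0))
  expect_true(all(z >= 1 & z <= 2))
})

test_that("empirical variogram matches its definition on small fixtures", {
  # two points with values differing by d: single semivariance d^2/2
  e <- empirical_variogram(c(0, 3), c(0, 4), c(1, 4), n_bins = 1,
                           max_dist = 10)
  expect_equal(e$gamma, 9 / 2)
  expect_equal(e$n_pairs, 1)
  # constant field: identically zero
  with_seed_local(1, {
    x <- runif(30); y <- runif(30)
    e0 <- empirical_variogram(x, y, rep(3.3, 30))
    expect_true(all(e0$gamma == 0))
  })
  expect_error(empirical_variogram(c(1, 1), c(2, 2), c(0, 1)), "coincident")
})

test_that("a white-noise field has a flat variogram within 3 Monte-Carlo SDs", {
  g <- expand.grid(x = 1:20, y = 1:20)
  s2 <- 0.25
  # Monte-Carlo SD of the Matheron estimator per bin, by direct simulation
  reps <- with_seed_local(999, replicate(100, {
    empirical_variogram(g$x, g$y, rnorm(400, 0, sqrt(s2)))$gamma
  }))
  mc_sd <- apply(reps, 1, sd)
  emp <- with_seed_local(42, empirical_variogram(g$x, g$y,
                                                 rnorm(400, 0, sqrt(s2))))
  expect_true(all(abs(emp$gamma - s2) <= 3 * mc_sd))
})

test_that("variogram fitting recovers exponential parameters and degrades to
          a pure nugget when appropriate", {
  g <- expand.grid(x = seq(0, 190, by = 10), y = seq(0, 190, by = 10))
  u <- generate_spatial_field(g, nugget = 0.01, psill = 0.09, range = 30,
                              seed = 42)
  vg <- fit_variogram(empirical_variogram(g$x, g$y, u, n_bins = 15))
  expect_lt(abs(vg$psill - 0.09) / 0.09, 0.3)
  expect_lt(abs(vg$range - 30) / 30, 0.3)
  expect_lt(abs(vg$nugget - 0.01), 0.02)
  # pure-nugget input: partial sill collapses
  u2 <- generate_spatial_field(g, nugget = 0.04, psill = 0, range = 1,
                               seed = 42)
  vg2 <- fit_variogram(empirical_variogram(g$x, g$y, u2, n_bins = 15))
  expect_lt(vg2$psill, 0.25 * (vg2$psill + vg2$nugget))
  expect_error(fit_variogram(data.frame(dist = 1:2, gamma = c(1, 1),
                                        n_pairs = c(5, 5))),
               "at least 3")
})

test_that("ordinary kriging equals a direct linear-system oracle for n <= 6", {
  with_seed_local(3, {
    for (n in c(3, 5, 6)) {
      x <- runif(n) * 10; y <- runif(n) * 10; z <- rnorm(n)
      vg <- make_variogram("exponential", nugget = 0.01, psill = 0.2,
                           range = 3)
      e2 <- runif(n, 0, 0.1)
      grid <- data.frame(x = runif(4) * 10, y = runif(4) * 10)
      k <- krige(x, y, z, vg, grid, error_var = e2)
      # independent brute-force solve of the (n+1) augmented system
      sill <- 0.21
      D <- as.matrix(dist(cbind(x, y)))
      C <- sill - semivariance(vg, D)
      diag(C) <- sill + e2
      for (i in seq_len(4)) {
        c0 <- sill - semivariance(vg, sqrt((x - grid$x[i])^2 +
                                             (y - grid$y[i])^2))
        sol <- solve(rbind(cbind(C, 1), c(rep(1, n), 0)), c(c0, 1))
        expect_equal(k$pred[i], sum(sol[seq_len(n)] * z), tolerance = 1e-10)
        expect_equal(k$krige_var[i],
                     max(0, sill - sum(sol[seq_len(n)] * c0) - sol[n + 1]),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("kriging interpolates exactly with zero nugget and is unbiased", {
  with_seed_local(8, {
    x <- runif(6) * 5; y <- runif(6) * 5; z <- rnorm(6)
    vg0 <- make_variogram("exponential", nugget = 0, psill = 0.3, range = 2)
    k <- krige(x, y, z, vg0, data.frame(x = x, y = y))
    expect_equal_num(k$pred, z, 1e-10)
    # constant field reproduced everywhere (weights sum to 1)
    grid <- expand.grid(x = seq(0, 5, by = 1), y = seq(0, 5, by = 1))
    kc <- krige(x, y, rep(2.5, 6), vg0, grid)
    expect_equal_num(kc$pred, rep(2.5, nrow(grid)), 1e-10)
    w <- attr(kc, "weights")
    expect_equal_num(colSums(w), rep(1, nrow(grid)), 1e-10)
  })
})

test_that("positive measurement error smooths instead of interpolating", {
  # 5-point fixture: a deviant center among a level neighborhood
  x <- c(0, 1, 0, -1, 0); y <- c(0, 0, 1, 0, -1)
  z <- c(3, 1, 1, 1, 1)
  vg <- make_variogram("exponential", nugget = 0, psill = 0.5, range = 2)
  k <- krige(x, y, z, vg, data.frame(x = 0, y = 0), error_var = 0.2)
  expect_lt(k$pred, 3)           # pulled off the datum ...
  expect_gt(k$pred, mean(z))     # ... but not past the local mean
  expect_error(krige(c(0, 0), c(1, 1), c(1, 2), vg, data.frame(x = 0, y = 0)),
               "coincident")
})

test_that("surface classification applies relative and absolute bands", {
  expect_equal(as.character(classify_surface(1, 1, 0.1, relative = TRUE)),
               "near")
  expect_equal(as.character(classify_surface(1.2, 1, 0.1, relative = TRUE)),
               "above")
  expect_equal(as.character(classify_surface(c(0.5, 1.5), 1, 0)),
               c("below", "above"))
  expect_equal(as.character(classify_surface(c(-3, 0.2, 2), 0, 0.5)),
               c("below", "near", "above"))
})

test_that("prediction grids are clipped to the polygon union", {
  geom <- area_grid_geometry(3, 2)
  g <- make_prediction_grid(geom, resolution = 0.5)
  expect_true(all(g$x > 0 & g$x < 3 & g$y > 0 & g$y < 2))
  expect_equal(nrow(g), 6 * 4)  # 4 interior points per unit square
})

test_that("the stabilize-and-krige chain runs and shrinks noisy areas more", {
  reg <- small_registry()
  yrs <- sort(unique(reg$person_years$year))
  sr <- standard_rates(reg$incidence, reg$person_years, groups_30_84, yrs,
                       sex = "male", histology = "adenocarcinoma")
  pyw <- reg$person_years[reg$person_years$sex == "male", ]
  risk <- sir(observed_counts(reg$incidence, groups_30_84, yrs, sex = "male",
                              histology = "adenocarcinoma"),
              expected_counts(pyw, sr, groups_30_84))
  mp <- stabilized_krige(risk, reg$geometry, null = 1, value_col = "sir")
  expect_gte(mp$tau2, 0)
  expect_true(all(mp$areas$weight >= 0 & mp$areas$weight <= 1))
  # higher sampling variance implies more shrinkage toward the null
  hi <- which.max(mp$areas$variance); lo <- which.min(mp$areas$variance)
  expect_lt(mp$areas$weight[hi], mp$areas$weight[lo])
  expect_true(all(c("pred", "krige_var", "class") %in% names(mp$surface)))
  p <- render_map(mp, reg$geometry)
  expect_s3_class(p, "ggplot")
  expect_error(render_map(mp, regimap:::new_area_geometry(list())), "empty")
})
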