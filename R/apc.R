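#' Build a cross-classified age x period grid with cohort indices
#'
#' Aggregates an incidence and a person-years table to an `A x P` grid of
#' counts and person-years over equal-width age and period bands, and
#' derives the diagonal cohort bookkeeping: cohort index
#' `c = p - a + (A - 1)` (0-based), giving `A + P - 1` cohorts, with each
#' cohort's median birth year equal to the period midpoint minus the age
#' midpoint.  With eleven 5-year age bands 30-84 and four 5-year periods
#' 1997-2016 this yields 44 cells and 14 cohorts with median birth years
#' 1917, 1922, ..., 1982.  Records outside the age or period range are
#' excluded.
#'
#' @param incidence an `incidence_table` (filter to one stratum first, or
#'   use `sex`/`histology` selectors).
#' @param person_years a `person_years_table`.
#' @param age_range `c(lower, upper)` inclusive years, e.g. `c(30, 84)`.
#' @param period_range `c(first_year, last_year)` inclusive, e.g.
#'   `c(1997, 2016)`.
#' @param band_width width of both age and period bands (default 5).
#' @param sex,histology optional stratum selectors.
#' @return Object of class `apc_grid`: list with matrices `O`, `N`
#'   (`A x P`), `age` (midpoints), `period` (midpoints), `cohort_index`
#'   (`A x P`), `cohort_year` (median birth year per cohort), `A`, `P`,
#'   `C = A + P - 1`, `band_width`.
#' @export
build_apc_grid <- function(incidence, person_years, age_range, period_range,
                           band_width = 5L, sex = NULL, histology = NULL) {
  groups <- make_age_groups(age_range[1], age_range[2], band_width)
  pspan <- period_range[2] - period_range[1] + 1
  if (pspan <= 0 || pspan %% band_width != 0)
    stop("period range is not divisible into bands of width ", band_width)
  p_lo <- seq(period_range[1], period_range[2], by = band_width)
  p_mid <- p_lo + (band_width - 1) / 2
  A <- nrow(groups); P <- length(p_lo)

  inc <- incidence
  py <- person_years
  if (!is.null(sex)) {
    inc <- inc[inc$sex %in% sex, ]
    py <- py[py$sex %in% sex, ]
  }
  if (!is.null(histology)) inc <- inc[inc$histology %in% histology, ]

  band_of_year <- function(y) {
    b <- (y - period_range[1]) %/% band_width
    b[y < period_range[1] | y > period_range[2]] <- NA_integer_
    as.integer(b)
  }
  O <- N <- matrix(0, A, P)
  ai <- age_group_index(inc$age_group, groups)
  pi_ <- band_of_year(inc$year)
  keep <- !is.na(ai) & !is.na(pi_)
  if (any(keep)) {
    agg <- tapply(inc$count[keep], list(ai[keep], pi_[keep]), sum)
    O[cbind(as.integer(rownames(agg))[row(agg)] + 1L,
            as.integer(colnames(agg))[col(agg)] + 1L)] <-
      ifelse(is.na(agg), 0, agg)
  }
  aj <- age_group_index(py$age_group, groups)
  pj <- band_of_year(py$year)
  keep <- !is.na(aj) & !is.na(pj)
  if (any(keep)) {
    agg <- tapply(py$person_years[keep], list(aj[keep], pj[keep]), sum)
    N[cbind(as.integer(rownames(agg))[row(agg)] + 1L,
            as.integer(colnames(agg))[col(agg)] + 1L)] <-
      ifelse(is.na(agg), 0, agg)
  }
  if (all(N == 0)) stop("empty APC grid: no person-years in range")
  new_apc_grid(O, N, groups$midpoint, p_mid, band_width)
}

#' Construct an `apc_grid` from matrices
#'
#' Low-level constructor used by [build_apc_grid()] and the synthetic
#' generator.
#'
#' @param O,N `A x P` matrices of counts and person-years.
#' @param age_mid,period_mid band midpoints (ages in years, periods in
#'   calendar years).
#' @param band_width band width in years.
#' @return An `apc_grid`.
#' @export
new_apc_grid <- function(O, N, age_mid, period_mid, band_width = 5L) {
  A <- length(age_mid); P <- length(period_mid)
  stopifnot(all(dim(O) == c(A, P)), all(dim(N) == c(A, P)))
  a_idx <- row(O) - 1L; p_idx <- col(O) - 1L
  cohort_index <- p_idx - a_idx + (A - 1L)
  # cohort median birth year = period midpoint - age midpoint, per diagonal
  cohort_year <- numeric(A + P - 1L)
  for (ci in 0:(A + P - 2L)) {
    cells <- which(cohort_index == ci, arr.ind = TRUE)
    cohort_year[ci + 1L] <-
      period_mid[cells[1, 2]] - age_mid[cells[1, 1]]
  }
  structure(list(O = O, N = N, age = age_mid, period = period_mid,
                 cohort_index = cohort_index, cohort_year = cohort_year,
                 A = A, P = P, C = A + P - 1L, band_width = band_width),
            class = "apc_grid")
}

# Centered integer scores for each axis (units of one band).
apc_scores <- function(n) {
  s <- seq_len(n) - 1
  s - mean(s)
}

#' Reference-constrained age-period-cohort fit
#'
#' Poisson log-linear fit of cell counts on age, period and cohort factors
#' with a log person-years offset.  The model is unidentified because
#' cohort = period - age; the reference constraint used here assigns all
#' drift to cohort: period effects are restricted to zero sum *and* zero
#' linear trend (orthogonal-polynomial curvature basis), while age and
#' cohort effects are zero-sum coded.  Returned alongside the effects are
#' the constraint-free (estimable) quantities: second differences
#' (curvatures) of the period and cohort effects, and the net drift.
#'
#' @param grid an `apc_grid` with nonzero person-years in every cell.
#' @param tol IRLS convergence tolerance passed to [stats::glm.fit()].
#' @return Object of class `apc_effects`: list with `mu` (intercept,
#'   log rate), `alpha` (age, zero-sum), `pi` (period, zero-sum + zero
#'   linear trend), `gamma` (cohort, zero-sum), `deviance`, `net_drift`
#'   (log-rate per band), `curv_period`, `curv_cohort` (second differences),
#'   `grid`, `delta` (drift reallocation applied so far; 0 here).
#' @export
fit_apc_reference <- function(grid, tol = 1e-10) {
  stopifnot(inherits(grid, "apc_grid"))
  if (any(grid$N <= 0))
    stop("every cell must have positive person-years; zero found")
  A <- grid$A; P <- grid$P; C <- grid$C
  y <- as.vector(grid$O)
  n <- as.vector(grid$N)
  a <- as.vector(row(grid$O))          # 1..A
  p <- as.vector(col(grid$O))          # 1..P
  cc <- as.vector(grid$cohort_index) + 1L  # 1..C

  SA <- stats::contr.sum(A)            # A x (A-1), zero-sum coding
  SC <- stats::contr.sum(C)
  CP <- stats::contr.poly(P)[, -1, drop = FALSE]  # zero-sum & zero-linear basis
  X <- cbind(1, SA[a, , drop = FALSE], CP[p, , drop = FALSE],
             SC[cc, , drop = FALSE])
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::poisson(), offset = log(n),
                   control = stats::glm.control(epsilon = tol, maxit = 100)),
    warning = function(w) {   # noise-free grids carry non-integer counts
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("APC Poisson fit did not converge after ", fit$iter,
         " IRLS iterations; deviance trace ends at ", format(fit$deviance))
  b <- fit$coefficients
  i_a <- 1 + seq_len(A - 1)
  i_p <- A + seq_len(max(P - 2, 0))
  i_c <- A + max(P - 2, 0) + seq_len(C - 1)
  alpha <- drop(SA %*% b[i_a])
  # for P = 2 the zero-sum + zero-linear constraint forces a null period effect
  pi_eff <- if (P >= 3) drop(CP %*% b[i_p]) else rep(0, P)
  gamma <- drop(SC %*% b[i_c])
  new_apc_effects(mu = b[1], alpha = alpha, pi = pi_eff, gamma = gamma,
                  grid = grid, deviance = fit$deviance, delta = 0)
}

new_apc_effects <- function(mu, alpha, pi, gamma, grid, deviance, delta) {
  sc <- apc_scores(length(gamma))
  sp <- apc_scores(length(pi))
  slope <- function(e, s) sum(e * s) / sum(s^2)
  structure(list(
    mu = unname(mu), alpha = alpha, pi = pi, gamma = gamma,
    deviance = deviance, delta = delta,
    net_drift = slope(pi, sp) + slope(gamma, sc),
    curv_period = if (length(pi) >= 3) diff(pi, differences = 2) else numeric(0),
    curv_cohort = if (length(gamma) >= 3) diff(gamma, differences = 2) else numeric(0),
    grid = grid), class = "apc_effects")
}

#' Fitted cell log-rates of an APC effect set
#' @param effects an `apc_effects`.
#' @return `A x P` matrix of `mu + alpha_a + pi_p + gamma_c`.
#' @export
apc_fitted_lograte <- function(effects) {
  g <- effects$grid
  effects$mu + outer(effects$alpha, effects$pi, `+`) +
    matrix(effects$gamma[g$cohort_index + 1L], g$A, g$P)
}

# Poisson deviance of an effect set against its grid's observed counts.
apc_deviance <- function(effects) {
  g <- effects$grid
  mu_hat <- g$N * exp(apc_fitted_lograte(effects))
  O <- g$O
  2 * sum(ifelse(O > 0, O * log(O / mu_hat), 0) - (O - mu_hat))
}

#' Reallocate drift between period and cohort effects
#'
#' Moves the model along its flat (unidentified) likelihood direction:
#' `pi_p <- pi_p + delta * (p - pbar)`, `gamma_c <- gamma_c - delta *
#' (c - cbar)`, with the compensating age-linear term `alpha_a <- alpha_a -
#' delta * (a - abar)` required by cohort = period - age, so that every
#' fitted cell log-rate is exactly unchanged.  `delta` is in log-rate per
#' band (5-year unit by default) moved from cohort to period.  Zero-sum
#' coding is preserved because all adjustments are centered.
#'
#' @param effects an `apc_effects`.
#' @param delta drift amount (log-rate per band).
#' @return A new `apc_effects` with identical fitted rates and deviance.
#' @export
drift_reallocate <- function(effects, delta) {
  stopifnot(inherits(effects, "apc_effects"))
  sa <- apc_scores(length(effects$alpha))
  sp <- apc_scores(length(effects$pi))
  sc <- apc_scores(length(effects$gamma))
  new_apc_effects(
    mu = effects$mu,
    alpha = effects$alpha - delta * sa,
    pi = effects$pi + delta * sp,
    gamma = effects$gamma - delta * sc,
    grid = effects$grid, deviance = effects$deviance,
    delta = effects$delta + delta)
}

#' Relative variation of an effect vector
#'
#' Coefficient of variation on the rate-ratio scale: the population
#' standard deviation of `exp(effects)` divided by its mean.  Dimensionless
#' and invariant to adding a constant to all effects (a common rate-ratio
#' rescaling).
#'
#' @param effects numeric vector of log-scale effects, length >= 2.
#' @return Nonnegative scalar.
#' @examples
#' relative_variation(c(log(1), log(3)))  # 0.5
#' @export
relative_variation <- function(effects) {
  if (length(effects) < 2)
    stop("relative variation needs at least 2 effects")
  e <- exp(effects)
  m <- mean(e)
  sqrt(mean((e - m)^2)) / m
}

#' Age-period-cohort decomposition under the constant-relative-variation
#' constraint
#'
#' Resolves the APC identifiability problem by treating the age curve as
#' deterministic and choosing the drift allocation `delta*` at which the
#' period and the cohort effect sets have equal relative variation
#' ([relative_variation()] on the rate-ratio scale).  Starting from the
#' reference fit (all drift in cohort), the root of
#' `g(delta) = RV(pi(delta)) - RV(gamma(delta))` is bracketed between the
#' two pure allocations (all drift in cohort, `delta = 0`, and all drift in
#' period, `delta` equal to the cohort linear trend) and solved to
#' `|g| <= g_tol`.  If no sign change exists in the (expanded) bracket the
#' function fails loudly, reporting all local minima of `|g|` on a profile
#' grid rather than silently picking one.
#'
#' @param grid an `apc_grid`.
#' @param g_tol tolerance on `|g(delta*)|` (default 1e-8).
#' @param profile_points number of delta values in the returned diagnostic
#'   profile (default 101).
#' @return An `apc_effects` at `delta*`, with extra fields `delta_star`,
#'   `rv_period`, `rv_cohort`, and `profile` (data frame
#'   `delta, rv_period, rv_cohort`).
#' @export
solve_crv <- function(grid, g_tol = 1e-8, profile_points = 101L) {
  ref <- fit_apc_reference(grid)
  sc <- apc_scores(length(ref$gamma))
  b_gamma <- sum(ref$gamma * sc) / sum(sc^2)  # cohort linear trend at reference

  g_fun <- function(d) {
    e <- drift_reallocate(ref, d)
    relative_variation(e$pi) - relative_variation(e$gamma)
  }

  span <- abs(b_gamma)
  if (span < 1e-12 && max(abs(ref$pi), abs(ref$gamma)) < 1e-12) {
    # exactly null period/cohort structure: drift-free solution
    e <- ref
    dstar <- 0
  } else {
    lo <- min(0, b_gamma); hi <- max(0, b_gamma)
    pad <- 0.1 * span
    lo <- lo - pad; hi <- hi + pad
    # widen beyond the two pure allocations if needed (e.g. near-null
    # structure, where the balancing root sits at noise scale)
    step <- max(span, 0.01)
    max_half_span <- max(1, 2 * span)  # |delta| beyond ~1 log per band is absurd
    found <- FALSE
    repeat {
      if (sign(g_fun(lo)) != sign(g_fun(hi))) { found <- TRUE; break }
      if (max(abs(lo), abs(hi)) >= max_half_span) break
      lo <- max(lo - step, -max_half_span)
      hi <- min(hi + step, max_half_span)
      step <- 2 * step
    }
    if (!found) {
      dd <- seq(lo, hi, length.out = 401)
      gg <- vapply(dd, function(d) abs(g_fun(d)), numeric(1))
      locmin <- unique(c(which(diff(sign(diff(gg))) > 0) + 1L, which.min(gg)))
      stop("no sign change of RV(period) - RV(cohort) over the drift bracket [",
           signif(lo, 4), ", ", signif(hi, 4), "]; ",
           "candidate |g| minima at delta = ",
           paste(signif(dd[locmin], 6), collapse = ", "),
           " with |g| = ", paste(signif(gg[locmin], 6), collapse = ", "))
    }
    # refuse to pick silently among several balancing allocations
    dd_scan <- seq(lo, hi, length.out = 101)
    gg_scan <- vapply(dd_scan, g_fun, numeric(1))
    cross <- which(diff(sign(gg_scan)) != 0)
    if (length(cross) > 1)
      stop("multiple CRV balancing roots inside the drift bracket, near ",
           "delta = ", paste(signif(dd_scan[cross], 5), collapse = ", "),
           "; inspect the RV profile and choose an allocation explicitly")
    root <- stats::uniroot(g_fun, c(lo, hi), tol = 1e-12)
    dstar <- root$root
    if (abs(g_fun(dstar)) > g_tol)
      stop("CRV root search did not reach |g| <= ", g_tol,
           ": |g(delta*)| = ", abs(g_fun(dstar)))
    e <- drift_reallocate(ref, dstar)
  }
  dd <- seq(min(0, b_gamma) - 0.1 * max(span, 1e-3),
            max(0, b_gamma) + 0.1 * max(span, 1e-3),
            length.out = profile_points)
  prof <- data.frame(
    delta = dd,
    rv_period = vapply(dd, function(d) relative_variation(drift_reallocate(ref, d)$pi), numeric(1)),
    rv_cohort = vapply(dd, function(d) relative_variation(drift_reallocate(ref, d)$gamma), numeric(1)))
  e$delta_star <- dstar
  e$rv_period <- relative_variation(e$pi)
  e$rv_cohort <- relative_variation(e$gamma)
  e$profile <- prof
  e
}

#' Tidy table of APC effects
#'
#' @param effects an `apc_effects`.
#' @return Data frame `(term, level, effect, rate_ratio)` where `level` is
#'   the age midpoint, period midpoint, or cohort median birth year.
#' @export
apc_effects_table <- function(effects) {
  g <- effects$grid
  rbind(
    data.frame(term = "age", level = g$age, effect = effects$alpha,
               rate_ratio = exp(effects$alpha)),
    data.frame(term = "period", level = g$period, effect = effects$pi,
               rate_ratio = exp(effects$pi)),
    data.frame(term = "cohort", level = g$cohort_year, effect = effects$gamma,
               rate_ratio = exp(effects$gamma)))
}

#' Parametric-bootstrap confidence bands for APC effect curves
#'
#' Resamples cell counts as Poisson around the fitted means, refits the CRV
#' solution, and returns pointwise quantile bands for each effect curve.
#'
#' @param effects a [solve_crv()] result.
#' @param n_boot number of replicates (default 200).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for reproducibility.
#' @return The [apc_effects_table()] with `band_low` and `band_high` columns.
#' @export
apc_bootstrap_bands <- function(effects, n_boot = 200L, conf = 0.95,
                                seed = 1L) {
  g <- effects$grid
  mu_hat <- g$N * exp(apc_fitted_lograte(effects))
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      gb <- g
      gb$O <- matrix(stats::rpois(length(mu_hat), as.vector(mu_hat)),
                     g$A, g$P)
      eb <- tryCatch(solve_crv(gb), error = function(e) NULL)
      if (is.null(eb)) return(NULL)
      c(eb$alpha, eb$pi, eb$gamma)
    })
  })
  draws <- do.call(rbind, Filter(Negate(is.null), draws))
  if (is.null(draws) || nrow(draws) < 10)
    stop("bootstrap produced too few successful refits")
  lo <- apply(draws, 2, stats::quantile, probs = (1 - conf) / 2)
  hi <- apply(draws, 2, stats::quantile, probs = 1 - (1 - conf) / 2)
  tab <- apc_effects_table(effects)
  tab$band_low <- lo
  tab$band_high <- hi
  tab
}

#' Three-panel APC effect plot
#'
#' Age, period and cohort effect curves on the rate-ratio (log) scale.
#'
#' @param effects an `apc_effects` (optionally with bootstrap bands via
#'   `bands =` an [apc_bootstrap_bands()] table).
#' @param bands optional band table.
#' @return A ggplot object.
#' @export
plot_apc_effects <- function(effects, bands = NULL) {
  tab <- if (is.null(bands)) apc_effects_table(effects) else bands
  tab$term <- factor(tab$term, levels = c("age", "period", "cohort"))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$level,
                                         y = .data$rate_ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "rate ratio") +
    ggplot2::theme_minimal()
  if (!is.null(bands) && all(c("band_low", "band_high") %in% names(tab)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = exp(.data$band_low), ymax = exp(.data$band_high)),
      alpha = 0.2)
  p
}
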