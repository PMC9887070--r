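#' Construct age, period and cohort effects satisfying the
#' equal-relative-variation condition
#'
#' Builds a ground-truth effect set for simulation: a saturating log-age
#' incidence curve (power-law rise with a mild old-age flattening, the
#' typical adult-carcinoma shape), a period effect with slope and
#' curvature, and a cohort effect carrying the drift.  The period vector is
#' rescaled by root search so that the period and cohort effect sets have
#' exactly equal relative variation ([relative_variation()]), i.e. the
#' truth satisfies the identifying condition the estimator imposes.
#'
#' @param A,P numbers of age and period bands.
#' @param cohort_drift cohort log-linear trend per band (sign sets rising
#'   vs falling cohort risk; default 0.03).
#' @param cohort_curv amplitude of the cohort curvature component.
#' @param period_shape unscaled period shape (slope + curvature); rescaled
#'   internally to satisfy the equal-RV condition.
#' @param age_span total log-range of the age curve (default 5, i.e. a
#'   ~150-fold rise over the age range).
#' @return List `(alpha, pi, gamma)`, all zero-sum, with
#'   `relative_variation(pi) == relative_variation(gamma)`.
#' @export
make_crv_effects <- function(A = 11L, P = 4L, cohort_drift = 0.03,
                             cohort_curv = 0.04,
                             period_shape = NULL, age_span = 5) {
  m <- seq_len(A)                              # band ordinals
  lm_ <- log(m / mean(m))
  alpha <- age_span * (lm_ - 0.18 * lm_^2) / diff(range(lm_))
  alpha <- alpha - mean(alpha)
  sc <- apc_scores(A + P - 1L)
  gamma <- cohort_drift * sc + cohort_curv * sin(sc / 2.5)
  gamma <- gamma - mean(gamma)
  if (is.null(period_shape)) {
    sp <- apc_scores(P)
    # the period drift shares the cohort drift's sign, so the balanced
    # allocation lies between the two pure allocations the solver brackets
    sgn <- if (cohort_drift < 0) -1 else 1
    period_shape <- sgn * 0.01 * sp + 0.005 * (sp^2 - mean(sp^2))
  }
  period_shape <- period_shape - mean(period_shape)
  target <- relative_variation(gamma)
  f <- function(k) relative_variation(k * period_shape) - target
  k <- stats::uniroot(f, c(1e-9, 200), tol = 1e-12)$root
  list(alpha = alpha, pi = k * period_shape, gamma = gamma)
}

#' Simulate an age x period grid with known APC structure
#'
#' Draws cell counts `O_ap ~ Poisson(N_ap * exp(mu + alpha_a + pi_p +
#' gamma_c))` on a grid with constant person-years per cell.  The shipped
#' defaults define the grid-level validation scenario: the 11 x 4 design
#' (ages 30-84, periods 1997-2016 in 5-year bands) with effects from
#' [make_crv_effects()] and person-years large enough (1e9 per cell, rate
#' scale 4e-4) that estimation error in every effect is negligible — the
#' lowest-rate cell then has an expected count above 2e4, i.e. a cell
#' log-rate standard error below 0.007.
#'
#' @param effects list `(alpha, pi, gamma)` (default [make_crv_effects()]).
#' @param base_rate rate (cases per person-year) at the effect origin.
#' @param py_per_cell person-years in every cell.
#' @param age_range,period_range,band_width grid layout.
#' @param seed RNG seed.
#' @return List `(grid, truth)`: an `apc_grid` plus
#'   `truth = (mu, alpha, pi, gamma)`.
#' @export
generate_apc_grid <- function(effects = make_crv_effects(),
                              base_rate = 4e-4, py_per_cell = 1e9,
                              age_range = c(30, 84),
                              period_range = c(1997, 2016),
                              band_width = 5L, seed = 1L) {
  groups <- make_age_groups(age_range[1], age_range[2], band_width)
  p_lo <- seq(period_range[1], period_range[2], by = band_width)
  A <- nrow(groups); P <- length(p_lo)
  stopifnot(length(effects$alpha) == A, length(effects$pi) == P,
            length(effects$gamma) == A + P - 1L)
  mu <- log(base_rate)
  skeleton <- new_apc_grid(matrix(0, A, P), matrix(py_per_cell, A, P),
                           groups$midpoint, p_lo + (band_width - 1) / 2,
                           band_width)
  lam <- py_per_cell * exp(mu + outer(effects$alpha, effects$pi, `+`) +
                             matrix(effects$gamma[skeleton$cohort_index + 1L],
                                    A, P))
  O <- with_seed(seed, matrix(stats::rpois(A * P, as.vector(lam)), A, P))
  grid <- new_apc_grid(O, skeleton$N, skeleton$age, skeleton$period,
                       band_width)
  list(grid = grid,
       truth = list(mu = mu, alpha = effects$alpha, pi = effects$pi,
                    gamma = effects$gamma, lambda = lam))
}

#' Sample a Gaussian random field on area centroids
#'
#' Mean-zero Gaussian field with covariance implied by an exponential
#' variogram: `Cov(u_i, u_j) = c1 * exp(-d_ij / phi)` for distinct points
#' plus nugget `c0` on the diagonal, sampled by Cholesky factorization.
#'
#' @param coords 2-column matrix (or data frame) of planar coordinates.
#' @param nugget,psill,range variogram parameters (`c0`, `c1`, `phi`).
#' @param seed RNG seed.
#' @return Numeric field vector, one value per coordinate row.
#' @export
generate_spatial_field <- function(coords, nugget = 0, psill = 0.09,
                                   range = 4, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (psill + nugget == 0) return(numeric(n))  # degenerate flat field
  D <- as.matrix(stats::dist(coords))
  Sigma <- psill * exp(-D / range)
  diag(Sigma) <- psill + nugget
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("field covariance is not positive definite (nugget = ", nugget,
         ", psill = ", psill, ", range = ", range, ")"))
  with_seed(seed, drop(crossprod(L, stats::rnorm(n))))
}

#' Square-lattice area geometry
#'
#' Lays `nx * ny` unit-square administrative areas on a planar grid,
#' row-major area ids `A0001, A0002, ...`; centroids at cell centers.
#'
#' @param nx,ny lattice dimensions.
#' @param cell_size square side length (CRS units).
#' @return An `area_geometry`.
#' @export
area_grid_geometry <- function(nx, ny, cell_size = 1) {
  polys <- list()
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      x0 <- (i - 1) * cell_size; y0 <- (j - 1) * cell_size
      polys[[sprintf("A%04d", k)]] <- cbind(
        c(x0, x0 + cell_size, x0 + cell_size, x0, x0),
        c(y0, y0, y0 + cell_size, y0 + cell_size, y0))
    }
  }
  new_area_geometry(polys)
}

#' Default synthetic-registry configuration
#'
#' The default scenario mirrors the design of a 20-year national registry
#' analysis: eleven 5-year age bands 30-84, calendar years 1997-2016 in
#' 5-year periods, ~300 administrative areas on a lattice, male and female
#' strata with a rising adenocarcinoma-like and a falling
#' squamous-cell-like cohort trend, a spatially correlated area-level
#' log-relative-risk field with an exponential variogram, and log-normal
#' area population sizes with a stable age structure.
#'
#' @param nx,ny area lattice (default 18 x 17 = 306 areas).
#' @param years calendar years covered.
#' @param age_range,band_width age banding.
#' @param py_scale median person-years per area, year and sex, summed over
#'   the age range.
#' @param py_sdlog log-normal dispersion of area population sizes.
#' @param age_structure person-years share per age band (defaults to a
#'   gently declining adult pyramid; normalized internally).
#' @param strata data frame `(sex, histology, base_rate, cohort_drift)`
#'   defining the strata to simulate.
#' @param field list `(nugget, psill, range)` of the true spatial
#'   log-relative-risk variogram (distances in lattice units).
#' @param area_trend_sd SD of the per-area extra log-linear time trend
#'   (per year) that makes area-level AAPCs vary spatially.
#' @param seed master seed; all stages draw named substreams from it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(nx = 18L, ny = 17L, years = 1997:2016,
                             age_range = c(30, 84), band_width = 5L,
                             py_scale = 20000, py_sdlog = 0.6,
                             age_structure = NULL,
                             strata = NULL,
                             field = list(nugget = 0.005, psill = 0.09,
                                          range = 4),
                             area_trend_sd = 0.005, seed = 1L) {
  groups <- make_age_groups(age_range[1], age_range[2], band_width)
  if (is.null(age_structure))
    age_structure <- c(1.05, 1.05, 1, 0.95, 0.9, 0.8, 0.65, 0.5,
                       0.38, 0.26, 0.16)[seq_len(nrow(groups))]
  if (length(age_structure) != nrow(groups))
    stop("age_structure must have one weight per age band")
  if (any(age_structure < 0)) stop("age_structure weights must be >= 0")
  if (is.null(strata))
    strata <- data.frame(
      sex = c("male", "male", "female", "female"),
      histology = c("adenocarcinoma", "squamous cell carcinoma",
                    "adenocarcinoma", "squamous cell carcinoma"),
      base_rate = c(1.8e-4, 1.2e-4, 1.5e-4, 3e-5),
      cohort_drift = c(0.04, -0.03, 0.05, -0.03),
      stringsAsFactors = FALSE)
  if (!all(c("sex", "histology", "base_rate", "cohort_drift") %in%
             names(strata)))
    stop("strata must have columns sex, histology, base_rate, cohort_drift")
  if (any(strata$base_rate <= 0)) stop("base rates must be positive")
  if (length(years) %% band_width != 0)
    stop("number of years must be divisible by band_width")
  if (any(vapply(field, length, 1L) != 1) ||
      field$nugget < 0 || field$psill < 0 || field$range <= 0)
    stop("invalid spatial field parameters")
  if (area_trend_sd < 0 || py_sdlog < 0 || py_scale <= 0)
    stop("variance/scale parameters must be nonnegative")
  structure(list(nx = nx, ny = ny, years = years, age_range = age_range,
                 band_width = band_width, py_scale = py_scale,
                 py_sdlog = py_sdlog,
                 age_structure = age_structure / sum(age_structure),
                 strata = strata, field = field,
                 area_trend_sd = area_trend_sd, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic multi-area registry with known truth
#'
#' Samples counts `O ~ Poisson(N_{i,a,t} * exp(mu + alpha_a + pi_p(t) +
#' gamma_c(a,t) + u_i + theta_i * (t - tbar)))` for each stratum: an APC
#' structure from [make_crv_effects()] (cohort drift per stratum), a
#' spatially correlated area field `u_i` from [generate_spatial_field()],
#' and an optional per-area trend perturbation `theta_i`.  Person-years are
#' log-normal per area with a stable age structure, constant over years.
#' Fully reproducible from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return List: `incidence` (`incidence_table`), `person_years`
#'   (`person_years_table`), `geometry` (`area_geometry`), `truth` (per
#'   stratum: effects, `u`, `theta`, expectation array
#'   `lambda[area, age, year]`, per-area true log-linear trend and AAPC),
#'   `config`.
#' @export
generate_registry <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- make_age_groups(config$age_range[1], config$age_range[2],
                            config$band_width)
  A <- nrow(groups)
  years <- config$years
  Tn <- length(years)
  P <- Tn %/% config$band_width
  geom <- area_grid_geometry(config$nx, config$ny)
  areas <- geom$areas$area_id
  n_area <- length(areas)
  p_of_t <- (years - years[1]) %/% config$band_width           # 0-based
  cohort_of <- function(a0, p0) p0 - a0 + (A - 1L)             # 0-based

  sexes <- unique(config$strata$sex)
  # area population sizes per sex (PY per year over all ages)
  size <- with_seed(child_seed(config$seed, "popsize"), {
    m <- matrix(stats::rlnorm(n_area * length(sexes),
                              meanlog = log(config$py_scale),
                              sdlog = config$py_sdlog),
                n_area, length(sexes), dimnames = list(areas, sexes))
    m
  })
  w_age <- config$age_structure

  py_rows <- list()
  for (sx in sexes) {
    py_rows[[sx]] <- data.frame(
      sex = sx,
      area_id = rep(areas, each = A * Tn),
      year = rep(rep(years, each = A), times = n_area),
      age_group = rep(groups$label, times = n_area * Tn),
      person_years = as.vector(vapply(areas, function(a)
        as.vector(outer(w_age * size[a, sx], rep(1, Tn))), numeric(A * Tn))),
      stringsAsFactors = FALSE)
  }
  person_years <- as_person_years_table(do.call(rbind, py_rows))

  tbar <- mean(years)
  inc_rows <- list()
  truth <- list()
  for (si in seq_len(nrow(config$strata))) {
    st <- config$strata[si, ]
    key <- paste(st$sex, st$histology, sep = "|")
    eff <- make_crv_effects(A = A, P = P, cohort_drift = st$cohort_drift)
    u <- generate_spatial_field(
      geom$areas[, c("cx", "cy")], nugget = config$field$nugget,
      psill = config$field$psill, range = config$field$range,
      seed = child_seed(config$seed, paste0("field|", key)))
    names(u) <- areas
    theta <- with_seed(child_seed(config$seed, paste0("trend|", key)),
                       stats::rnorm(n_area, 0, config$area_trend_sd))
    names(theta) <- areas
    mu <- log(st$base_rate)
    # lambda[area, age, year]
    lam <- array(0, dim = c(n_area, A, Tn),
                 dimnames = list(areas, groups$label, years))
    for (ti in seq_len(Tn)) {
      p0 <- p_of_t[ti]
      lr_age <- mu + eff$alpha + eff$pi[p0 + 1L] +
        eff$gamma[cohort_of(seq_len(A) - 1L, p0) + 1L]
      py_at <- outer(size[, st$sex], w_age)            # n_area x A
      lam[, , ti] <- py_at * exp(outer(u + theta * (years[ti] - tbar),
                                       lr_age, `+`))
    }
    O <- with_seed(child_seed(config$seed, paste0("counts|", key)),
                   array(stats::rpois(length(lam), as.vector(lam)),
                         dim = dim(lam), dimnames = dimnames(lam)))
    nz <- which(O > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      inc_rows[[key]] <- data.frame(
        sex = st$sex, histology = st$histology,
        area_id = areas[nz[, 1]],
        year = years[nz[, 3]],
        age_group = groups$label[nz[, 2]],
        count = O[nz],
        stringsAsFactors = FALSE)
    }
    # per-area true trend: OLS slope of log expected rate on year
    rate_at <- apply(lam, c(1, 3), sum) / outer(rowSums(outer(size[, st$sex], w_age)), rep(1, Tn))
    yc <- years - tbar
    slope <- as.vector((log(rate_at) %*% yc) / sum(yc^2))
    truth[[key]] <- list(sex = st$sex, histology = st$histology, mu = mu,
                         alpha = eff$alpha, pi = eff$pi, gamma = eff$gamma,
                         u = u, theta = theta, lambda = lam,
                         trend_slope = stats::setNames(slope, areas),
                         aapc = stats::setNames(100 * (exp(slope) - 1), areas))
  }
  incidence <- as_incidence_table(do.call(rbind, inc_rows))
  list(incidence = incidence, person_years = person_years, geometry = geom,
       truth = truth, config = config)
}
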