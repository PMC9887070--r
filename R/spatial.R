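#' Method-of-moments between-area variance
#'
#' Estimates the between-area variance `tau^2` of the underlying risk
#' values about the null `m0` by an inverse-variance-weighted moment
#' equation about the null (the DerSimonian-Laird form with known mean):
#' `tau^2 = max(0, (sum_i w_i (v_i - m0)^2 - n) / sum_i w_i)` with
#' `w_i = 1 / sigma_i^2`.  Weighting by precision keeps a handful of areas
#' with enormous sampling variance (tiny populations, degenerate trend
#' fits) from swamping the estimate; when all sampling variances are equal
#' the estimator reduces to the plain moment form
#' `mean((v - m0)^2) - sigma^2`, and when they are all zero it returns the
#' empirical variance about the null.  `tau^2 = 0` is legal and means
#' total shrinkage to the null.
#'
#' @param values per-area raw values (SIR or AAPC).
#' @param variances their sampling variances.
#' @param null null value (1 for SIR, 0 for AAPC).
#' @return Nonnegative scalar `tau^2`.
#' @export
estimate_tau2 <- function(values, variances, null) {
  stopifnot(length(values) == length(variances), all(variances >= 0))
  if (length(values) < 2) stop("need at least 2 areas to estimate tau^2")
  if (all(variances == 0)) return(mean((values - null)^2))
  floor_v <- min(variances[variances > 0]) * 1e-6  # zero-variance areas get a
  w <- 1 / pmax(variances, floor_v)                # large but finite weight
  max(0, (sum(w * (values - null)^2) - length(values)) / sum(w))
}

#' Shrink noisy area values toward the null
#'
#' Empirical-Bayes stabilization: `z = m0 + w * (v - m0)` with weight
#' `w = tau^2 / (tau^2 + sigma^2)`.  An area with small population (large
#' sampling variance) is shrunken toward the null considerably; an area
#' with large population is shrunken minimally.
#'
#' @param values raw values `v`.
#' @param variances sampling variances `sigma^2` (>= 0).
#' @param tau2 between-area variance (from [estimate_tau2()]).
#' @param null null value `m0`.
#' @return Data frame `(value, variance, weight, stabilized, degenerate)`;
#'   `degenerate` flags rows where both `tau2` and the variance are zero
#'   (then `stabilized = null`).
#' @export
shrink_to_null <- function(values, variances, tau2, null) {
  stopifnot(length(values) == length(variances), tau2 >= 0,
            all(variances >= 0))
  degen <- tau2 == 0 & variances == 0
  w <- ifelse(degen, 0, tau2 / (tau2 + variances))
  data.frame(value = values, variance = variances, weight = w,
             stabilized = null + w * (values - null), degenerate = degen)
}

# Parametric semivariogram models: gamma(h) for h > 0, gamma(0) = 0.
variogram_value <- function(h, model, c0, c1, phi) {
  g <- switch(model,
    exponential = c0 + c1 * (1 - exp(-h / phi)),
    spherical = ifelse(h >= phi, c0 + c1,
                       c0 + c1 * (1.5 * h / phi - 0.5 * (h / phi)^3)),
    stop("unknown variogram model: ", model))
  ifelse(h <= 0, 0, g)
}

#' Empirical (Matheron) semivariogram
#'
#' Bins all point pairs by separation distance and computes
#' `gamma_hat(h_k) = (1 / (2 N_k)) * sum (z_i - z_j)^2` over pairs in bin k;
#' empty bins are dropped.
#'
#' @param x,y planar coordinates.
#' @param z values at the points.
#' @param n_bins number of distance bins (default 15).
#' @param max_dist maximum pair distance used (default half the largest
#'   pairwise distance, the usual variography practice).
#' @return Data frame `(dist, gamma, n_pairs)` with bin-mean distances.
#' @export
empirical_variogram <- function(x, y, z, n_bins = 15L, max_dist = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  if (length(x) < 2) stop("need at least 2 points")
  d <- as.vector(stats::dist(cbind(x, y)))
  if (all(d == 0)) stop("all points are coincident")
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) stop("max_dist must be positive")
  dz2 <- as.vector(stats::dist(matrix(z, ncol = 1)))^2
  keep <- d > 0 & d <= max_dist
  d <- d[keep]; dz2 <- dz2[keep]
  br <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    dist = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(dz2, bin, function(v) sum(v) / (2 * length(v)))),
    n_pairs = as.numeric(tapply(dz2, bin, length)))
  out <- out[!is.na(out$dist), ]
  rownames(out) <- NULL
  out
}

#' Fit a parametric variogram model by weighted least squares
#'
#' Minimizes the Cressie-weighted squared error
#' `sum_k N_k * (gamma_hat_k - gamma(h_k))^2 / gamma(h_k)^2` under
#' nonnegativity constraints on nugget and partial sill, with the range
#' bounded by the maximum bin distance.
#'
#' @param emp an [empirical_variogram()] table with >= 3 nonempty bins.
#' @param model `"exponential"` (default) or `"spherical"`.
#' @return Object of class `variogram`: list `(model, nugget, psill, range,
#'   objective)`.
#' @export
fit_variogram <- function(emp, model = c("exponential", "spherical")) {
  model <- match.arg(model)
  if (nrow(emp) < 3)
    stop("need at least 3 nonempty variogram bins, got ", nrow(emp),
         "; input: ", paste(signif(emp$gamma, 4), collapse = ", "))
  h <- emp$dist; g <- emp$gamma; nk <- emp$n_pairs
  obj <- function(par) {
    gm <- variogram_value(h, model, par[1], par[2], par[3])
    sum(nk * (g - gm)^2 / pmax(gm, 1e-10)^2)
  }
  gscale <- max(mean(g), 1e-10)
  fit <- NULL
  for (phi0 in max(h) * c(0.1, 1 / 3, 0.75)) {   # multi-start on the range
    f <- tryCatch(
      stats::optim(c(c0 = 0.1 * gscale, c1 = gscale, phi = phi0), obj,
                   method = "L-BFGS-B",
                   lower = c(0, 0, max(h) * 1e-3),
                   upper = c(Inf, Inf, max(h) * 2),
                   control = list(parscale = c(gscale, gscale, max(h)),
                                  maxit = 500)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || f$value < fit$value)) fit <- f
  }
  if (is.null(fit))
    stop("variogram optimizer failed; binned input gamma: ",
         paste(signif(g, 4), collapse = ", "))
  structure(list(model = model, nugget = unname(fit$par[1]),
                 psill = unname(fit$par[2]), range = unname(fit$par[3]),
                 objective = fit$value), class = "variogram")
}

#' Construct a variogram object directly
#' @param model `"exponential"` or `"spherical"`.
#' @param nugget nonnegative nugget `c0`.
#' @param psill nonnegative partial sill `c1`.
#' @param range positive range `phi` (distance units of the CRS).
#' @return A `variogram`.
#' @export
make_variogram <- function(model = "exponential", nugget = 0, psill = 1,
                           range = 1) {
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(model = model, nugget = nugget, psill = psill,
                 range = range, objective = NA_real_), class = "variogram")
}

#' Semivariance of a fitted variogram at distance h
#' @param vario a `variogram`.
#' @param h nonnegative distances.
#' @return `gamma(h)` with `gamma(0) = 0`.
#' @export
semivariance <- function(vario, h) {
  variogram_value(h, vario$model, vario$nugget, vario$psill, vario$range)
}

#' Ordinary kriging with heteroscedastic measurement error
#'
#' Solves, at each prediction point, the ordinary-kriging system with
#' covariance `C(h) = c0 + c1 - gamma(h)` between distinct points and the
#' per-datum measurement-error variance `e_i^2` added only to the diagonal
#' of the data-data covariance (error does not propagate to
#' data-prediction covariances); weights are constrained to sum to 1.
#' With zero nugget and zero measurement error the predictor interpolates
#' the data exactly; with positive measurement error it smooths.
#'
#' @param x,y data coordinates (no duplicates).
#' @param z data values (e.g. stabilized SIRs).
#' @param error_var per-datum measurement-error variances `e_i^2`
#'   (default 0).
#' @param vario a `variogram`.
#' @param grid data frame with columns `x, y` of prediction locations.
#' @return Data frame `(x, y, pred, krige_var)`; attribute `"weights"`
#'   holds the `n x m` kriging-weight matrix (points x predictions).
#' @export
krige <- function(x, y, z, vario, grid, error_var = 0) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, nrow(grid) >= 1)
  if (length(error_var) == 1L) error_var <- rep(error_var, n)
  stopifnot(length(error_var) == n)
  D <- as.matrix(stats::dist(cbind(x, y)))
  if (any(D[upper.tri(D)] == 0))
    stop("duplicate/coincident data centroids make the kriging system singular")
  sill <- vario$nugget + vario$psill
  Cdd <- sill - semivariance(vario, D)
  diag(Cdd) <- sill + error_var
  K <- rbind(cbind(Cdd, 1), c(rep(1, n), 0))
  Kinv <- tryCatch(solve(K), error = function(e)
    stop("singular kriging system: check for coincident centroids (",
         conditionMessage(e), ")"))
  dx <- outer(x, grid$x, `-`); dy <- outer(y, grid$y, `-`)
  H0 <- sqrt(dx^2 + dy^2)
  C0 <- sill - semivariance(vario, H0)       # n x m
  rhs <- rbind(C0, 1)
  sol <- Kinv %*% rhs                        # (n+1) x m
  w <- sol[seq_len(n), , drop = FALSE]
  mlag <- sol[n + 1L, ]
  pred <- drop(crossprod(w, z))
  kv <- sill - colSums(w * C0) - mlag
  out <- data.frame(x = grid$x, y = grid$y, pred = pred,
                    krige_var = pmax(kv, 0))
  attr(out, "weights") <- w
  out
}

#' Classify a surface about its null value
#'
#' Tri-class labels for mapping: `above` / `near` / `below` the null, with a
#' symmetric tolerance band.  For ratio-type values (SIR, null 1) the band
#' is relative, `(m0 * (1 - t), m0 * (1 + t))`; for difference-type values
#' (AAPC, null 0) it is absolute, `(m0 - t, m0 + t)`.
#'
#' @param values numeric surface or area values.
#' @param null the null value `m0`.
#' @param tolerance nonnegative half-width `t` of the "near" band
#'   (default 0: strict sign classification about the null).
#' @param relative logical; relative (ratio) band if `TRUE`.
#' @return Factor with levels `below, near, above`.
#' @export
classify_surface <- function(values, null, tolerance = 0, relative = FALSE) {
  stopifnot(tolerance >= 0)
  hi <- if (relative) null * (1 + tolerance) else null + tolerance
  lo <- if (relative) null * (1 - tolerance) else null - tolerance
  cls <- ifelse(values > hi, "above", ifelse(values < lo, "below", "near"))
  factor(cls, levels = c("below", "near", "above"))
}

#' Regular prediction grid clipped to the mapped areas
#'
#' Lays a regular grid over the bounding box of the area polygons and keeps
#' the points falling inside any polygon (point-in-polygon via
#' [mgcv::in.out()]).
#'
#' @param geom an `area_geometry`.
#' @param resolution grid spacing in CRS units.
#' @return Data frame `(x, y)` of retained grid points.
#' @export
make_prediction_grid <- function(geom, resolution) {
  stopifnot(inherits(geom, "area_geometry"), resolution > 0)
  if (!length(geom$polygons)) stop("empty geometry")
  allxy <- do.call(rbind, geom$polygons)
  xs <- seq(min(allxy[, 1]) + resolution / 2, max(allxy[, 1]), by = resolution)
  ys <- seq(min(allxy[, 2]) + resolution / 2, max(allxy[, 2]), by = resolution)
  g <- expand.grid(x = xs, y = ys)
  # boundary for in.out: rings separated by NA rows
  bnd <- do.call(rbind, lapply(geom$polygons, function(m) rbind(m, c(NA, NA))))
  inside <- mgcv::in.out(bnd, as.matrix(g))
  g[inside, , drop = FALSE]
}

#' Stabilize-and-krige pipeline for one area-level indicator
#'
#' The full mapping chain.  The between-area variance `tau^2` is estimated
#' and every area's value is shrunk toward the null with weight
#' `w_i = tau^2 / (tau^2 + sigma_i^2)` (these per-area stabilized estimates
#' are returned and classified).  The signal variogram is then estimated
#' from the stabilized values -- they are robust to areas with enormous
#' sampling variance -- by subtracting the mean residual noise
#' `mean(w_i^2 sigma_i^2)` from the binned semivariances and undoing the
#' mean shrinkage attenuation (division by `mean(w)^2`) before fitting.
#'
#' The surface itself is produced, by default, by a *joint* stabilization:
#' ordinary kriging of the raw values with the full heteroscedastic
#' sampling variance `e_i^2 = sigma_i^2` on the data-data diagonal
#' (`error_mode = "joint"`).  The kriging system then performs shrinkage
#' and spatial pooling in one linear predictor: an area with a small
#' population (large `sigma_i^2`) is trusted little and its prediction is
#' pulled strongly toward the level of its neighborhood, i.e. toward the
#' null when the surroundings are unremarkable, while a large-population
#' area is honored almost exactly.  `error_mode = "twostage"` instead
#' kriges the pre-shrunken values with the residual post-shrinkage
#' uncertainty `e_i^2 = w_i * sigma_i^2`; it is retained for comparison but
#' double-attenuates the signal (shrinkage and kriging each pull toward the
#' mean) and has measurably worse recovery of simulated truth.
#'
#' @param risk data frame with `area_id`, a value column, and `variance`
#'   (e.g. an `area_risk` with `value_col = "sir"`, or an `area_trend` with
#'   `value_col = "aapc"`); rows with `NA` values are excluded from kriging
#'   input.
#' @param geom an `area_geometry` covering the areas.
#' @param null null value (1 for SIR, 0 for AAPC).
#' @param value_col name of the value column.
#' @param grid optional prediction grid (default [make_prediction_grid()]
#'   at `resolution`).
#' @param resolution default grid spacing (CRS units).
#' @param n_bins,max_dist passed to [empirical_variogram()].
#' @param model variogram model.
#' @param tolerance near-null band half width for classification.
#' @param relative relative band (SIR-style) if `TRUE`.
#' @param error_mode `"joint"` (default) or `"twostage"` (see Details).
#' @return List of class `stabilized_map`: `areas` (input + `weight`,
#'   `stabilized`, `class`), `tau2`, `variogram`, `surface` (grid with
#'   `pred`, `krige_var`, `class`), `null`.
#' @export
stabilized_krige <- function(risk, geom, null, value_col = "sir",
                             grid = NULL, resolution = 1,
                             n_bins = 15L, max_dist = NULL,
                             model = "exponential", tolerance = 0.05,
                             relative = null != 0,
                             error_mode = c("joint", "twostage")) {
  error_mode <- match.arg(error_mode)
  v <- risk[[value_col]]
  ok <- !is.na(v) & !is.na(risk$variance)
  d <- risk[ok, , drop = FALSE]
  v <- v[ok]
  m <- merge(d, geom$areas, by = "area_id")
  if (nrow(m) < nrow(d))
    stop("geometry missing for area(s): ",
         paste(setdiff(d$area_id, geom$areas$area_id), collapse = ", "))
  tau2 <- estimate_tau2(v, d$variance, null)
  sh <- shrink_to_null(m[[value_col]], m$variance, tau2, null)
  m$weight <- sh$weight
  m$stabilized <- sh$stabilized
  # signal variography on the stabilized values: their semivariogram
  # estimates (attenuated signal) + mean residual noise; remove the noise
  # share and undo the mean attenuation before fitting
  emp <- empirical_variogram(m$cx, m$cy, m$stabilized, n_bins = n_bins,
                             max_dist = max_dist)
  emp$gamma <- pmax((emp$gamma - mean(m$weight^2 * m$variance)) /
                      max(mean(m$weight)^2, 1e-6), 1e-12)
  vg <- fit_variogram(emp, model = model)
  if (is.null(grid)) grid <- make_prediction_grid(geom, resolution)
  surf <- switch(error_mode,
    joint = krige(m$cx, m$cy, m[[value_col]], vg, grid,
                  error_var = m$variance),
    twostage = krige(m$cx, m$cy, m$stabilized, vg, grid,
                     error_var = m$weight * m$variance))
  surf$class <- classify_surface(surf$pred, null, tolerance, relative)
  m$class <- classify_surface(m$stabilized, null, tolerance, relative)
  structure(list(areas = m, tau2 = tau2, variogram = vg, surface = surf,
                 null = null), class = "stabilized_map")
}

#' Render a tri-color stabilized map with contour lines
#'
#' Filled red/white/blue surface (above / near / below the null) with
#' overlaid contour lines of the kriged values, clipped to the mapped
#' polygons.  Areas excluded from kriging input (unestimable) are drawn
#' hatched-grey by outline.  Deterministic given inputs.
#'
#' @param map a [stabilized_krige()] result.
#' @param geom the `area_geometry` used.
#' @param contour_levels contour levels; default `null * c(0.8, 0.9, 1, 1.1,
#'   1.25)` for ratio maps and `c(-2, -1, 0, 1, 2)` for difference maps.
#' @param path optional output file (`.png`/`.svg`/`.pdf`); written with
#'   [ggplot2::ggsave()] if given.
#' @param width,height,dpi device settings for `ggsave`.
#' @return The ggplot object, invisibly if `path` is given.
#' @export
render_map <- function(map, geom, contour_levels = NULL, path = NULL,
                       width = 6, height = 6, dpi = 150) {
  stopifnot(inherits(map, "stabilized_map"), inherits(geom, "area_geometry"))
  if (!length(geom$polygons)) stop("empty geometry")
  if (is.null(contour_levels))
    contour_levels <- if (map$null != 0)
      map$null * c(0.8, 0.9, 1, 1.1, 1.25) else c(-2, -1, 0, 1, 2)
  s <- map$surface
  poly_df <- do.call(rbind, lapply(names(geom$polygons), function(id) {
    m <- geom$polygons[[id]]
    data.frame(area_id = id, x = m[, 1], y = m[, 2])
  }))
  missing_ids <- setdiff(geom$areas$area_id, map$areas$area_id)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = s,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$class)) +
    ggplot2::scale_fill_manual(
      values = c(below = "#4575b4", near = "#ffffff", above = "#d73027"),
      drop = FALSE) +
    ggplot2::geom_contour(data = s,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       z = .data$pred),
                          breaks = contour_levels, colour = "grey30",
                          linewidth = 0.3) +
    ggplot2::geom_path(data = poly_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$area_id),
                       colour = "grey60", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (length(missing_ids)) {
    miss_df <- poly_df[poly_df$area_id %in% missing_ids, ]
    p <- p + ggplot2::geom_polygon(
      data = miss_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$area_id),
      fill = "grey80", colour = "grey50", linewidth = 0.2)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
    return(invisible(p))
  }
  p
}
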