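#' Segmented log-linear trend fit with joinpoint selection
#'
#' Fits continuous piecewise log-linear trends to an annual incidence
#' series.  For each candidate number of joinpoints `0..max_joinpoints`, the
#' best breakpoint placement is found by exhaustive grid search over
#' interior integer years (minimum segment length `min_segment` years); the
#' number of joinpoints is then chosen by BIC.  The default model is Poisson
#' on counts with a log person-years offset (handles zero counts); a
#' weighted-least-squares fit on log rates (`method = "wls"`, weights
#' proportional to counts) is available to mimic common registry software.
#'
#' Continuity at breakpoints is enforced by the hinge parameterization
#' `log rate = b0 + b1 * t + sum_j d_j * max(0, t - bp_j)`; segment slopes
#' are the cumulative sums `b1, b1 + d_1, ...`.
#'
#' @param year ordered vector of consecutive calendar years.
#' @param count nonnegative case counts per year.
#' @param person_years person-years at risk per year (or a positive constant
#'   when fitting precomputed rates).
#' @param max_joinpoints maximum number of joinpoints searched (default 2).
#' @param min_segment minimum number of years per segment (default 3).
#' @param method `"poisson"` (default) or `"wls"` (on `log(count/person_years)`,
#'   zero counts excluded with weight 0).
#' @return Object of class `segfit`: list with `year`, `breakpoints`
#'   (numeric, possibly empty), `slopes` (per-segment log-rate change per
#'   year), `vcov_slopes`, `n_joinpoints`, `bic` (per candidate k), `fit`.
#' @export
fit_segmented_loglinear <- function(year, count, person_years,
                                    max_joinpoints = 2L, min_segment = 3L,
                                    method = c("poisson", "wls")) {
  method <- match.arg(method)
  stopifnot(length(year) == length(count))
  if (length(person_years) == 1L) person_years <- rep(person_years, length(year))
  stopifnot(length(person_years) == length(year))
  if (any(diff(year) != 1))
    stop("years must be strictly increasing and consecutive")
  if (any(count < 0)) stop("counts must be nonnegative")
  n <- length(year)
  need <- 2L * (max_joinpoints + 1L) + 1L
  if (n < need)
    stop("series too short: ", n, " years; need at least ", need,
         " for max_joinpoints = ", max_joinpoints)

  t0 <- year - year[1]
  fit_one <- function(bps) {
    X <- cbind(1, t0)
    for (b in bps) X <- cbind(X, pmax(0, t0 - (b - year[1])))
    if (method == "poisson") {
      fit <- withCallingHandlers(
        stats::glm.fit(X, count, family = stats::poisson(),
                       offset = log(person_years)),
        warning = function(w) {
          if (grepl("non-integer", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      mu <- fit$fitted.values
      # Poisson log-likelihood up to data-only constants
      ll <- sum(ifelse(count > 0, count * log(mu), 0) - mu)
      list(coef = fit$coefficients, ll = ll,
           vcov = tryCatch(chol2inv(chol(crossprod(X * sqrt(mu)))),
                           error = function(e) matrix(NA, ncol(X), ncol(X))))
    } else {
      wls_w <- count
      pos <- count > 0
      y <- log(ifelse(pos, count / person_years, NA))
      fit <- stats::lm.wfit(X[pos, , drop = FALSE], y[pos], w = wls_w[pos])
      res <- fit$residuals
      df <- sum(pos) - ncol(X)
      s2 <- if (df > 0) sum(wls_w[pos] * res^2) / df else 0
      XtWX <- crossprod(X[pos, , drop = FALSE] * sqrt(wls_w[pos]))
      ll <- -0.5 * sum(pos) * log(max(s2, 1e-300)) # gaussian profile likelihood
      list(coef = fit$coefficients, ll = ll,
           vcov = s2 * chol2inv(chol(XtWX)))
    }
  }

  candidate_breaks <- function(k) {
    if (k == 0) return(list(numeric(0)))
    lo <- year[1] + (min_segment - 1L)
    hi <- year[n] - (min_segment - 1L)
    if (lo > hi) return(list())
    pos <- seq(lo, hi)
    combos <- utils::combn(pos, k, simplify = FALSE)
    Filter(function(b) k == 1 || all(diff(b) >= min_segment - 1L), combos)
  }

  best <- vector("list", max_joinpoints + 1L)
  bic <- rep(NA_real_, max_joinpoints + 1L)
  for (k in 0:max_joinpoints) {
    cands <- candidate_breaks(k)
    if (!length(cands)) next
    fits <- lapply(cands, fit_one)
    lls <- vapply(fits, `[[`, numeric(1), "ll")
    i <- which.max(lls)
    p <- 2L + k  # intercept + base slope + k hinge terms (breakpoints count via BIC k too)
    bic[k + 1L] <- -2 * lls[i] + (p + k) * log(n)  # each breakpoint costs a df as well
    best[[k + 1L]] <- list(bps = cands[[i]], fit = fits[[i]])
  }
  kstar <- which.min(bic) - 1L
  sel <- best[[kstar + 1L]]
  coefs <- sel$fit$coef
  nseg <- kstar + 1L
  # slopes are cumulative sums of (b1, d1, ..., dk)
  L <- matrix(0, nseg, length(coefs))
  for (j in seq_len(nseg)) L[j, 2:(1 + j)] <- 1
  slopes <- as.numeric(L %*% coefs)
  vc <- L %*% sel$fit$vcov %*% t(L)
  structure(list(year = year, breakpoints = sel$bps, slopes = slopes,
                 vcov_slopes = vc, n_joinpoints = kstar, bic = bic,
                 method = method, coef = coefs),
            class = "segfit")
}

#' Average annual percent change over an interval
#'
#' Length-weighted AAPC, `100 * (exp(sum_j w_j * beta_j) - 1)`, where
#' `beta_j` are segment slopes on the log scale and `w_j` the fraction of
#' the interval covered by segment `j`.  The confidence interval is the
#' large-sample normal interval on the log scale using the slope covariance.
#'
#' @param fit a [fit_segmented_loglinear()] object.
#' @param interval `c(year_start, year_end)`; defaults to the fitted range.
#' @param conf confidence level (default 0.95).
#' @return List of class `trend_estimate`: `aapc`, `ci_low`, `ci_high`
#'   (percent per year), `se_log`, `weights`, `slopes`, `breakpoints`,
#'   `n_joinpoints`, `interval`.
#' @export
aapc <- function(fit, interval = NULL, conf = 0.95) {
  stopifnot(inherits(fit, "segfit"))
  rng <- range(fit$year)
  if (is.null(interval)) interval <- rng
  if (interval[2] <= interval[1])
    stop("empty AAPC interval [", interval[1], ", ", interval[2], "]")
  if (interval[1] < rng[1] || interval[2] > rng[2])
    stop("interval outside fitted range ", rng[1], "-", rng[2])
  bounds <- c(rng[1], fit$breakpoints, rng[2])
  w <- numeric(length(fit$slopes))
  for (j in seq_along(w)) {
    w[j] <- max(0, min(bounds[j + 1], interval[2]) - max(bounds[j], interval[1]))
  }
  w <- w / (interval[2] - interval[1])
  est <- sum(w * fit$slopes)
  se <- sqrt(drop(t(w) %*% fit$vcov_slopes %*% w))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(
    aapc = 100 * (exp(est) - 1),
    ci_low = 100 * (exp(est - z * se) - 1),
    ci_high = 100 * (exp(est + z * se) - 1),
    se_log = se, weights = w, slopes = fit$slopes,
    breakpoints = fit$breakpoints, n_joinpoints = fit$n_joinpoints,
    interval = interval), class = "trend_estimate")
}

#' Per-area AAPC of one stratum
#'
#' Builds each area's annual series (cases summed over the age range) and
#' fits [fit_segmented_loglinear()] followed by [aapc()].  Areas with no
#' cases over the interval are flagged unestimable and carry `NA` values;
#' they are meant to be excluded from kriging input (the spatial stage does
#' this) but can still be rendered.
#'
#' @param incidence an `incidence_table`.
#' @param person_years a `person_years_table`.
#' @param groups age-group table restricting the ages used.
#' @param years calendar years of the analysis interval (consecutive).
#' @param sex,histology stratum selectors.
#' @param max_joinpoints default 1 (per-area series are short and noisy).
#' @return Data frame of class `area_trend`: `area_id, aapc, ci_low,
#'   ci_high, variance` (variance of the AAPC on the percent scale, by the
#'   delta method), `n_joinpoints`, `estimable`.
#' @export
area_aapc <- function(incidence, person_years, groups, years,
                      sex = NULL, histology = NULL, max_joinpoints = 1L) {
  inc <- incidence
  py <- person_years
  if (!is.null(sex)) {
    inc <- inc[inc$sex %in% sex, ]
    py <- py[py$sex %in% sex, ]
  }
  if (!is.null(histology)) inc <- inc[inc$histology %in% histology, ]
  inc <- inc[inc$year %in% years, ]
  py <- py[py$year %in% years, ]
  gi <- age_group_index(inc$age_group, groups)
  inc <- inc[!is.na(gi), ]
  gp <- age_group_index(py$age_group, groups)
  py <- py[!is.na(gp), ]

  areas <- sort(unique(py$area_id))
  n_unest <- 0L
  rows <- lapply(areas, function(a) {
    pa <- py[py$area_id == a, ]
    P <- tapply(pa$person_years, pa$year, sum)
    yr <- as.integer(names(P))
    ia <- inc[inc$area_id == a, ]
    O <- setNames(numeric(length(yr)), yr)
    if (nrow(ia)) {
      oa <- tapply(ia$count, ia$year, sum)
      O[names(oa)] <- oa
    }
    if (sum(O) < 1) {
      n_unest <<- n_unest + 1L
      return(data.frame(area_id = a, aapc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, variance = NA_real_,
                        n_joinpoints = NA_integer_, estimable = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- fit_segmented_loglinear(yr, as.numeric(O), as.numeric(P),
                                   max_joinpoints = max_joinpoints)
    est <- aapc(fit)
    # delta method: var(100*(exp(x)-1)) = (100*exp(x))^2 * var(x)
    x <- log(1 + est$aapc / 100)
    data.frame(area_id = a, aapc = est$aapc, ci_low = est$ci_low,
               ci_high = est$ci_high,
               variance = (100 * exp(x))^2 * est$se_log^2,
               n_joinpoints = est$n_joinpoints, estimable = TRUE,
               stringsAsFactors = FALSE)
  })
  if (n_unest > 0)
    warning(n_unest, " area(s) with zero cases flagged unestimable and ",
            "excluded from kriging input")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("area_trend", "data.frame")
  out
}
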