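#' WHO 2000 world standard population
#'
#' The 18-band (0-4, 5-9, ..., 85+) world standard age distribution used for
#' direct age standardization, shipped as a versioned fixture table and
#' normalized so the weights sum to one.
#'
#' @return Data frame of class `standard_population` with columns
#'   `lower, upper, weight` (weights normalized to sum 1).
#' @export
who2000_standard <- function() {
  path <- system.file("extdata", "who2000_standard.csv", package = "regimap",
                      mustWork = TRUE)
  std <- utils::read.csv(path)
  std$weight <- std$weight / sum(std$weight)
  class(std) <- c("standard_population", "data.frame")
  std
}

#' Restrict a standard population to an age-group table
#'
#' Picks the standard bands matching each analysis band by its lower bound
#' and re-normalizes the weights over the restricted range (needed when the
#' analysis covers e.g. ages 30-84 only).
#'
#' @param groups an [make_age_groups()] table (5-year bands aligned with the
#'   standard's bands).
#' @param std a `standard_population` (default WHO 2000).
#' @return Numeric weight vector, one per age group, summing to 1.
#' @export
standard_weights <- function(groups, std = who2000_standard()) {
  stopifnot(inherits(groups, "age_groups"))
  w <- std$weight[match(groups$lower, std$lower)]
  if (anyNA(w))
    stop("standard population has no band starting at age(s): ",
         paste(groups$lower[is.na(w)], collapse = ", "))
  w / sum(w)
}

#' Age-specific incidence rates per 100,000 person-years
#'
#' @param observed vector of case counts by age group.
#' @param person_years matching person-years by age group (> 0 wherever
#'   `observed > 0`).
#' @return Rates per 100,000 person-years; `NA` (flagged missing) where both
#'   count and person-years are zero.
#' @export
age_specific_rates <- function(observed, person_years) {
  stopifnot(length(observed) == length(person_years))
  if (any(observed < 0) || any(person_years < 0))
    stop("counts and person-years must be nonnegative")
  bad <- observed > 0 & person_years == 0
  if (any(bad))
    stop("data inconsistency: positive count with zero person-years in age group(s) ",
         paste(which(bad), collapse = ", "))
  rate <- ifelse(person_years == 0, NA_real_, 1e5 * observed / person_years)
  rate
}

#' Directly age-standardized rate (ASR) per 100,000
#'
#' `ASR = sum_a w_a * rate_a` with standard weights `w`, plus the Poisson
#' delta-method variance `sum_a w_a^2 * rate_a * 1e5 / P_a` and a gamma
#' approximation confidence interval (registry practice for low counts).
#'
#' @param rates age-specific rates per 100,000 (from [age_specific_rates()]).
#' @param weights standard weights (normalized internally).
#' @param person_years person-years per age group (needed for the variance;
#'   optional if only the point estimate is wanted).
#' @param conf confidence level (default 0.95).
#' @return List with `asr`, `variance`, `ci_low`, `ci_high` (all per 100,000;
#'   variance/CI are `NA` when `person_years` is missing).
#' @export
direct_asr <- function(rates, weights, person_years = NULL, conf = 0.95) {
  stopifnot(length(rates) == length(weights))
  miss <- is.na(rates) & weights > 0
  if (any(miss))
    stop("missing age-specific rate where the standard weight is positive: age group(s) ",
         paste(which(miss), collapse = ", "))
  w <- weights / sum(weights)
  use <- w > 0
  asr <- sum(w[use] * rates[use])
  if (is.null(person_years))
    return(list(asr = asr, variance = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_))
  stopifnot(length(person_years) == length(rates))
  v <- sum(w[use]^2 * rates[use] * 1e5 / pmax(person_years[use], 1e-12))
  # gamma interval (Fay & Feuer 1997) on the standardized rate
  alpha <- 1 - conf
  if (asr <= 0) {
    wmax <- max(w[use] * 1e5 / pmax(person_years[use], 1e-12))
    lo <- 0
    hi <- wmax / 2 * stats::qchisq(1 - alpha / 2, df = 2) # zero-count upper bound
  } else {
    wmax <- max(w[use] * 1e5 / pmax(person_years[use], 1e-12))
    lo <- v / (2 * asr) * stats::qchisq(alpha / 2, df = 2 * asr^2 / v)
    hi <- (v + wmax^2) / (2 * (asr + wmax)) *
      stats::qchisq(1 - alpha / 2, df = 2 * (asr + wmax)^2 / (v + wmax^2))
  }
  list(asr = asr, variance = v, ci_low = lo, ci_high = hi)
}

#' ASR time series for each (sex, histology) stratum
#'
#' Convenience wrapper producing the tidy table behind incidence-trend
#' figures: one ASR (+ CI) per stratum and calendar year, pooled over areas.
#'
#' @param incidence an `incidence_table`.
#' @param person_years a `person_years_table`.
#' @param groups age-group table defining the standardization range.
#' @param std standard population (default WHO 2000).
#' @return Data frame `(sex, histology, year, asr, ci_low, ci_high)`.
#' @export
asr_series <- function(incidence, person_years, groups,
                       std = who2000_standard()) {
  check_coverage(incidence, person_years)
  w <- standard_weights(groups, std)
  py <- stats::aggregate(person_years ~ sex + year + age_group,
                         data = person_years, FUN = sum)
  strata <- unique(incidence[, c("sex", "histology")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sx <- strata$sex[i]; hs <- strata$histology[i]
    inc <- incidence[incidence$sex == sx & incidence$histology == hs, ]
    for (yr in sort(unique(py$year[py$sex == sx]))) {
      pyy <- py[py$sex == sx & py$year == yr, ]
      O <- P <- numeric(nrow(groups))
      gi <- age_group_index(pyy$age_group, groups)
      P[gi + 1L] <- pyy$person_years
      iy <- inc[inc$year == yr, ]
      if (nrow(iy)) {
        gi2 <- age_group_index(iy$age_group, groups)
        ok <- !is.na(gi2)
        agg <- tapply(iy$count[ok], gi2[ok], sum)
        O[as.integer(names(agg)) + 1L] <- agg
      }
      if (all(P == 0)) next
      r <- age_specific_rates(O, P)
      r[is.na(r)] <- 0  # no population in band: contributes 0 to ASR
      a <- direct_asr(r, w, P)
      out[[length(out) + 1L]] <- data.frame(
        sex = sx, histology = hs, year = yr, asr = a$asr,
        ci_low = a$ci_low, ci_high = a$ci_high, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reference age-specific rates over a window (for indirect standardization)
#'
#' Pools observed counts and person-years over all areas in `years` and
#' returns the average age-specific rates, the standard rates used to
#' compute expected counts and SIRs.  Typically the last five data years.
#'
#' @param incidence an `incidence_table` (one stratum: filter sex/histology
#'   first, or pass `sex`/`histology` selectors).
#' @param person_years a `person_years_table`.
#' @param groups age-group table.
#' @param years integer vector of calendar years defining the reference
#'   window.
#' @param sex,histology optional selectors applied to `incidence` (sex also
#'   applied to person-years).
#' @return Data frame of class `standard_rates`: `age_group` (0-based index),
#'   `rate` (cases per person-year).
#' @export
standard_rates <- function(incidence, person_years, groups, years,
                           sex = NULL, histology = NULL) {
  if (!is.null(sex)) {
    incidence <- incidence[incidence$sex %in% sex, ]
    person_years <- person_years[person_years$sex %in% sex, ]
  }
  if (!is.null(histology))
    incidence <- incidence[incidence$histology %in% histology, ]
  inc <- incidence[incidence$year %in% years, ]
  py <- person_years[person_years$year %in% years, ]
  O <- P <- numeric(nrow(groups))
  gi <- age_group_index(py$age_group, groups)
  ok <- !is.na(gi)
  P_agg <- tapply(py$person_years[ok], gi[ok], sum)
  P[as.integer(names(P_agg)) + 1L] <- P_agg
  if (nrow(inc)) {
    gi2 <- age_group_index(inc$age_group, groups)
    ok2 <- !is.na(gi2)
    O_agg <- tapply(inc$count[ok2], gi2[ok2], sum)
    O[as.integer(names(O_agg)) + 1L] <- O_agg
  }
  if (any(O > 0 & P == 0))
    stop("reference window has cases but no person-years in some age group")
  rate <- ifelse(P > 0, O / P, 0)
  out <- data.frame(age_group = groups$index, rate = rate)
  class(out) <- c("standard_rates", "data.frame")
  out
}

#' Expected case counts per area
#'
#' Indirect standardization: `E_i = sum_a P_{i,a} * R_a` with reference rates
#' `R_a` applied to each area's person-years.
#'
#' @param person_years a `person_years_table` (already restricted to the sex
#'   and observation window of interest).
#' @param std_rates a [standard_rates()] table covering every age group
#'   present.
#' @param groups age-group table used to index `age_group`.
#' @return Data frame `(area_id, expected)`.
#' @export
expected_counts <- function(person_years, std_rates, groups) {
  gi <- age_group_index(person_years$age_group, groups)
  keep <- !is.na(gi)
  py <- person_years[keep, ]
  gi <- gi[keep]
  r <- std_rates$rate[match(gi, std_rates$age_group)]
  if (anyNA(r))
    stop("standard rates missing for age group index(es): ",
         paste(unique(gi[is.na(r)]), collapse = ", "))
  e <- tapply(py$person_years * r, py$area_id, sum)
  data.frame(area_id = names(e), expected = as.numeric(e),
             stringsAsFactors = FALSE)
}

#' Standardized incidence ratios with sampling variances
#'
#' `SIR_i = O_i / E_i`.  The sampling variance uses the delta-method Poisson
#' form with a one-case floor, `var_i = max(O_i, 1) / E_i^2`, so that
#' zero-count areas get a finite, large variance (needed for shrinkage)
#' instead of zero.
#'
#' @param observed data frame `(area_id, observed)` or named numeric vector.
#' @param expected data frame `(area_id, expected)` from [expected_counts()].
#' @return Data frame of class `area_risk`: `area_id, observed, expected,
#'   sir, variance`.
#' @export
sir <- function(observed, expected) {
  if (is.numeric(observed))
    observed <- data.frame(area_id = names(observed), observed = as.numeric(observed),
                           stringsAsFactors = FALSE)
  m <- merge(expected, observed, by = "area_id", all.x = TRUE)
  m$observed[is.na(m$observed)] <- 0
  if (any(m$expected <= 0))
    stop("nonpositive expected count for area(s): ",
         paste(m$area_id[m$expected <= 0], collapse = ", "))
  m$sir <- m$observed / m$expected
  m$variance <- pmax(m$observed, 1) / m$expected^2
  m <- m[order(m$area_id), c("area_id", "observed", "expected", "sir", "variance")]
  rownames(m) <- NULL
  class(m) <- c("area_risk", "data.frame")
  m
}

#' Per-area observed counts for one stratum and window
#'
#' @param incidence an `incidence_table`.
#' @param groups age-group table (records outside are dropped).
#' @param years calendar years of the observation window.
#' @param sex,histology optional stratum selectors.
#' @return Data frame `(area_id, observed)`.
#' @export
observed_counts <- function(incidence, groups, years, sex = NULL,
                            histology = NULL) {
  inc <- incidence
  if (!is.null(sex)) inc <- inc[inc$sex %in% sex, ]
  if (!is.null(histology)) inc <- inc[inc$histology %in% histology, ]
  inc <- inc[inc$year %in% years, ]
  gi <- age_group_index(inc$age_group, groups)
  inc <- inc[!is.na(gi), ]
  if (nrow(inc) == 0)
    return(data.frame(area_id = character(), observed = numeric(),
                      stringsAsFactors = FALSE))
  o <- tapply(inc$count, inc$area_id, sum)
  data.frame(area_id = names(o), observed = as.numeric(o),
             stringsAsFactors = FALSE)
}

#' Annual histology-type proportions
#'
#' Share of each histological type among cases, by sex and year.  Years with
#' zero cases in a sex are flagged missing (`NA`), not 0/0.
#'
#' @param incidence an `incidence_table`.
#' @return Data frame `(sex, year, histology, proportion)`; proportions sum
#'   to 1 within each `(sex, year)` having any cases.
#' @export
histology_proportions <- function(incidence) {
  tot <- stats::aggregate(count ~ sex + year, data = incidence, FUN = sum)
  byh <- stats::aggregate(count ~ sex + year + histology, data = incidence,
                          FUN = sum)
  m <- merge(byh, tot, by = c("sex", "year"), suffixes = c("", "_total"))
  m$proportion <- ifelse(m$count_total > 0, m$count / m$count_total, NA_real_)
  m <- m[order(m$sex, m$year, m$histology),
         c("sex", "year", "histology", "proportion")]
  rownames(m) <- NULL
  m
}
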