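#' Construct contiguous age bands
#'
#' Builds the banded age axis used throughout the package: contiguous,
#' sorted bands of equal width with inclusive integer bounds (registry
#' tables are banded, not continuous).  The default call
#' `make_age_groups(30, 84)` reproduces the eleven 5-year bands
#' 30-34, 35-39, ..., 80-84 commonly used for adult cancer incidence.
#'
#' @param lower lowest age (years, inclusive) of the first band.
#' @param upper highest age (years, inclusive) of the last band.
#' @param width band width in years (default 5).
#' @return A data frame of class `age_groups` with columns `index`
#'   (0-based ordinal), `lower`, `upper` (inclusive years), `midpoint`
#'   (`(lower+upper)/2`) and `label` (e.g. `"30-34"`).
#' @examples
#' make_age_groups(30, 84)
#' @export
make_age_groups <- function(lower, upper, width = 5L) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, width >= 1)
  span <- upper - lower + 1
  if (span <= 0 || span %% width != 0)
    stop("age range [", lower, ", ", upper, "] is not divisible into bands of width ",
         width)
  lo <- seq(lower, upper, by = width)
  hi <- lo + width - 1
  out <- data.frame(
    index    = seq_along(lo) - 1L,
    lower    = lo,
    upper    = hi,
    midpoint = (lo + hi) / 2,
    label    = paste0(lo, "-", hi),
    stringsAsFactors = FALSE
  )
  class(out) <- c("age_groups", "data.frame")
  out
}

#' Match ages or band labels to an age-group index
#'
#' @param x integer ages in years, or character band labels such as `"30-34"`.
#' @param groups an [make_age_groups()] table.
#' @return Integer 0-based group indices; `NA` where `x` falls outside the
#'   covered range (callers decide whether that is an error or an exclusion).
#' @export
age_group_index <- function(x, groups) {
  stopifnot(inherits(groups, "age_groups"))
  if (is.character(x) || is.factor(x)) {
    idx <- groups$index[match(as.character(x), groups$label)]
  } else {
    x <- as.numeric(x)
    idx <- rep(NA_integer_, length(x))
    inside <- !is.na(x) & x >= groups$lower[1] & x <= groups$upper[nrow(groups)]
    width <- groups$upper[1] - groups$lower[1] + 1
    idx[inside] <- as.integer((x[inside] - groups$lower[1]) %/% width)
  }
  idx
}
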