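# Tiny in-code fixtures shared across tests.

groups_30_84 <- make_age_groups(30, 84)

# A minimal two-area, two-year incidence + person-years pair.
tiny_tables <- function() {
  inc <- as_incidence_table(data.frame(
    sex = "male", histology = "adenocarcinoma",
    area_id = rep(c("A1", "A2"), each = 4),
    year = rep(c(2000, 2000, 2001, 2001), 2),
    age_group = rep(c("30-34", "35-39"), 4),
    count = c(2, 3, 1, 4, 5, 0, 2, 2)))
  py <- as_person_years_table(data.frame(
    sex = "male",
    area_id = rep(c("A1", "A2"), each = 4),
    year = rep(c(2000, 2000, 2001, 2001), 2),
    age_group = rep(c("30-34", "35-39"), 4),
    person_years = rep(c(1e4, 2e4), 4)))
  list(incidence = inc, person_years = py)
}

# Small synthetic registry reused by several suites (single stratum keeps it
# fast); memoised so generation cost is paid once per test run.
small_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        nx = 8, ny = 7, py_scale = 30000, seed = 21,
        strata = data.frame(sex = "male", histology = "adenocarcinoma",
                            base_rate = 1.8e-4, cohort_drift = 0.04))
      cache <<- generate_registry(cfg)
    }
    cache
  }
})

default_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_registry(synthetic_config(seed = 11))
    cache
  }
})

expect_equal_num <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)

with_seed_local <- function(seed, code) withr::with_seed(seed, code)
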