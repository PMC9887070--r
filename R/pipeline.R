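#' Pipeline run configuration
#'
#' Bundles everything an end-to-end registry analysis needs: inputs (paths
#' to incidence / person-years / geometry files, or a
#' [synthetic_config()] to simulate them), stratum selectors, banding, the
#' reference window for indirect standardization, AAPC interval, kriging
#' settings, output directory and master seed.  The config round-trips
#' through YAML unchanged via [write_run_config()] / [read_run_config()].
#'
#' @param outdir output directory (created if needed).
#' @param synthetic optional [synthetic_config()]; when present, stage
#'   `simulate` generates the inputs.
#' @param incidence_path,person_years_path,geometry_path input files used
#'   when `synthetic` is `NULL` (or after `simulate` has written them).
#' @param sex,histology stratum selectors for the trend/APC/map stages
#'   (default: first stratum found).
#' @param age_range,band_width age banding.
#' @param apc_period_range period range of the APC stage.
#' @param reference_years reference window for standard rates (default:
#'   last five data years).
#' @param aapc_interval optional `c(start, end)` sub-interval for AAPC.
#' @param map_years observation window for SIR maps (default all years).
#' @param kriging list of kriging settings (`resolution`, `n_bins`,
#'   `tolerance`, `model`).
#' @param seed master seed; every stage draws a named substream.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, synthetic = NULL,
                       incidence_path = NULL, person_years_path = NULL,
                       geometry_path = NULL,
                       sex = NULL, histology = NULL,
                       age_range = c(30, 84), band_width = 5L,
                       apc_period_range = NULL, reference_years = NULL,
                       aapc_interval = NULL, map_years = NULL,
                       kriging = list(resolution = 1, n_bins = 15L,
                                      tolerance = 0.05,
                                      model = "exponential"),
                       seed = 1L) {
  structure(list(outdir = outdir, synthetic = synthetic,
                 incidence_path = incidence_path,
                 person_years_path = person_years_path,
                 geometry_path = geometry_path,
                 sex = sex, histology = histology,
                 age_range = age_range, band_width = band_width,
                 apc_period_range = apc_period_range,
                 reference_years = reference_years,
                 aapc_interval = aapc_interval, map_years = map_years,
                 kriging = kriging, seed = seed),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns the `run_config`; the writer returns
#'   the path invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- if (!is.null(x$synthetic)) {
    s <- unclass(x$synthetic)
    s$strata <- as.list(as.data.frame(s$strata))
    s
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    x$synthetic <- synthetic_config(
      nx = s$nx, ny = s$ny, years = unlist(s$years),
      age_range = unlist(s$age_range), band_width = s$band_width,
      py_scale = s$py_scale, py_sdlog = s$py_sdlog,
      age_structure = unlist(s$age_structure),
      strata = as.data.frame(s$strata, stringsAsFactors = FALSE),
      field = s$field, area_trend_sd = s$area_trend_sd, seed = s$seed)
  }
  for (f in c("age_range", "apc_period_range", "reference_years",
              "aapc_interval", "map_years"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  do.call(run_config, x[setdiff(names(x), character(0))])
}

#' Run the end-to-end registry analysis
#'
#' Orchestrates the stages `simulate` (write synthetic inputs), `rates`
#' (ASR series + SIR table), `trends` (national and per-area AAPC), `apc`
#' (CRV-constrained effect decomposition) and `map` (stabilized kriged SIR
#' and AAPC surfaces); `"all"` runs them in order, reusing inputs from
#' disk when no synthetic config is given.  Each stage writes tidy CSVs
#' under `config$outdir`, and a `manifest.json` records input checksums,
#' the config echo, package version and seed, so a run can be reproduced
#' exactly.  Any stage failure aborts with the stage name and leaves a
#' `FAILED` marker next to the partial outputs.
#'
#' @param config a [run_config()].
#' @param stages character vector from
#'   `c("simulate", "rates", "trends", "apc", "map", "all")`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "rates", "trends", "apc", "map")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  if (is.null(config$synthetic)) stages <- setdiff(stages, "simulate")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  stage_now <- NA_character_
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage_now, "-", conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    stop("pipeline failed at stage '", stage_now, "': ",
         conditionMessage(e), call. = FALSE)
  }
  groups <- make_age_groups(config$age_range[1], config$age_range[2],
                            config$band_width)

  load_inputs <- function() {
    inc_p <- config$incidence_path %||% file.path(config$outdir, "incidence.csv")
    py_p <- config$person_years_path %||% file.path(config$outdir, "person_years.csv")
    gj_p <- config$geometry_path %||% file.path(config$outdir, "areas.geojson")
    for (p in c(inc_p, py_p, gj_p))
      if (!file.exists(p)) stop("missing input file: ", p)
    list(incidence = read_incidence(inc_p),
         person_years = read_person_years(py_p),
         geometry = read_area_geojson(gj_p),
         paths = c(inc_p, py_p, gj_p))
  }

  tryCatch({
    if ("simulate" %in% stages) {
      stage_now <- "simulate"
      message("[simulate] generating synthetic registry")
      syn <- config$synthetic
      syn$seed <- child_seed(config$seed, "simulate")
      reg <- generate_registry(syn)
      artifacts$incidence <- file.path(config$outdir, "incidence.csv")
      artifacts$person_years <- file.path(config$outdir, "person_years.csv")
      artifacts$geometry <- file.path(config$outdir, "areas.geojson")
      write_incidence(reg$incidence, artifacts$incidence)
      write_person_years(reg$person_years, artifacts$person_years)
      write_area_geojson(reg$geometry, artifacts$geometry)
      truth_small <- lapply(reg$truth, function(t)
        t[c("sex", "histology", "mu", "alpha", "pi", "gamma")])
      artifacts$truth <- file.path(config$outdir, "truth.json")
      jsonlite::write_json(truth_small, artifacts$truth, auto_unbox = TRUE,
                           digits = NA)
      message("[simulate] ", nrow(reg$incidence), " incidence rows, ",
              nrow(reg$person_years), " person-years rows")
    }

    inp <- load_inputs()
    sexes <- config$sex %||% unique(inp$incidence$sex)[1]
    hists <- config$histology %||% unique(inp$incidence$histology)[1]
    years <- sort(unique(inp$person_years$year))
    ref_years <- config$reference_years %||% utils::tail(years, 5)
    map_years <- config$map_years %||% years

    if ("rates" %in% stages) {
      stage_now <- "rates"
      message("[rates] ASR series and SIR tables")
      asr <- asr_series(inp$incidence, inp$person_years, groups)
      artifacts$asr <- file.path(config$outdir, "asr.csv")
      utils::write.csv(asr, artifacts$asr, row.names = FALSE)
      sir_rows <- list()
      for (sx in sexes) for (hs in hists) {
        sr <- standard_rates(inp$incidence, inp$person_years, groups,
                             ref_years, sex = sx, histology = hs)
        pyw <- inp$person_years[inp$person_years$sex == sx &
                                  inp$person_years$year %in% map_years, ]
        e <- expected_counts(pyw, sr, groups)
        o <- observed_counts(inp$incidence, groups, map_years, sex = sx,
                             histology = hs)
        s <- sir(o, e)
        s$sex <- sx; s$histology <- hs
        sir_rows[[paste(sx, hs)]] <- s
      }
      artifacts$sir <- file.path(config$outdir, "sir.csv")
      utils::write.csv(do.call(rbind, sir_rows), artifacts$sir,
                       row.names = FALSE)
    }

    if ("trends" %in% stages) {
      stage_now <- "trends"
      message("[trends] national and per-area AAPC")
      rows <- list()
      for (sx in sexes) for (hs in hists) {
        inc <- inp$incidence[inp$incidence$sex == sx &
                               inp$incidence$histology == hs, ]
        py <- inp$person_years[inp$person_years$sex == sx, ]
        gi <- age_group_index(inc$age_group, groups)
        inc <- inc[!is.na(gi), ]
        O <- tapply(inc$count, factor(inc$year, levels = years), sum)
        O[is.na(O)] <- 0
        gp <- age_group_index(py$age_group, groups)
        py <- py[!is.na(gp), ]
        P <- tapply(py$person_years, factor(py$year, levels = years), sum)
        fit <- fit_segmented_loglinear(years, as.numeric(O), as.numeric(P),
                                       max_joinpoints = 2L)
        est <- aapc(fit, interval = config$aapc_interval)
        rows[[paste(sx, hs)]] <- data.frame(
          sex = sx, histology = hs, area_id = "ALL", aapc = est$aapc,
          ci_low = est$ci_low, ci_high = est$ci_high,
          n_joinpoints = est$n_joinpoints,
          breakpoints = paste(est$breakpoints, collapse = ";"),
          stringsAsFactors = FALSE)
        aa <- area_aapc(inp$incidence, inp$person_years, groups, years,
                        sex = sx, histology = hs)
        rows[[paste(sx, hs, "area")]] <- data.frame(
          sex = sx, histology = hs, area_id = aa$area_id, aapc = aa$aapc,
          ci_low = aa$ci_low, ci_high = aa$ci_high,
          n_joinpoints = aa$n_joinpoints, breakpoints = "",
          stringsAsFactors = FALSE)
      }
      artifacts$aapc <- file.path(config$outdir, "aapc.csv")
      utils::write.csv(do.call(rbind, rows), artifacts$aapc,
                       row.names = FALSE)
    }

    if ("apc" %in% stages) {
      stage_now <- "apc"
      message("[apc] CRV-constrained age-period-cohort decomposition")
      period_range <- config$apc_period_range %||%
        c(years[1], years[1] + (length(years) %/% config$band_width) *
            config$band_width - 1)
      rows <- list()
      for (sx in sexes) for (hs in hists) {
        grid <- build_apc_grid(inp$incidence, inp$person_years,
                               config$age_range, period_range,
                               config$band_width, sex = sx, histology = hs)
        eff <- solve_crv(grid)
        tab <- apc_effects_table(eff)
        tab$sex <- sx; tab$histology <- hs; tab$delta_star <- eff$delta_star
        rows[[paste(sx, hs)]] <- tab
      }
      artifacts$apc <- file.path(config$outdir, "apc_effects.csv")
      utils::write.csv(do.call(rbind, rows), artifacts$apc,
                       row.names = FALSE)
    }

    if ("map" %in% stages) {
      stage_now <- "map"
      message("[map] stabilized kriged SIR and AAPC surfaces")
      kg <- config$kriging
      surf_rows <- list()
      for (sx in sexes) for (hs in hists) {
        sr <- standard_rates(inp$incidence, inp$person_years, groups,
                             ref_years, sex = sx, histology = hs)
        pyw <- inp$person_years[inp$person_years$sex == sx &
                                  inp$person_years$year %in% map_years, ]
        e <- expected_counts(pyw, sr, groups)
        o <- observed_counts(inp$incidence, groups, map_years, sex = sx,
                             histology = hs)
        risk <- sir(o, e)
        m_sir <- stabilized_krige(risk, inp$geometry, null = 1,
                                  value_col = "sir",
                                  resolution = kg$resolution,
                                  n_bins = kg$n_bins,
                                  tolerance = kg$tolerance,
                                  model = kg$model)
        aa <- area_aapc(inp$incidence, inp$person_years, groups, years,
                        sex = sx, histology = hs)
        m_aapc <- stabilized_krige(aa, inp$geometry, null = 0,
                                   value_col = "aapc",
                                   resolution = kg$resolution,
                                   n_bins = kg$n_bins, tolerance = 0.5,
                                   model = kg$model)
        for (nm in c("sir", "aapc")) {
          m <- if (nm == "sir") m_sir else m_aapc
          s <- m$surface
          s$sex <- sx; s$histology <- hs; s$indicator <- nm
          surf_rows[[paste(sx, hs, nm)]] <- s
          png_path <- file.path(config$outdir,
                                paste0("map_", nm, "_", gsub("[^a-z]", "_", sx),
                                       "_", gsub("[^a-z ]", "", hs), ".png"))
          png_path <- gsub(" ", "_", png_path)
          try(render_map(m, inp$geometry, path = png_path), silent = TRUE)
        }
      }
      artifacts$surfaces <- file.path(config$outdir, "surfaces.csv")
      utils::write.csv(do.call(rbind, surf_rows), artifacts$surfaces,
                       row.names = FALSE)
    }

    stage_now <- "manifest"
    files <- unlist(artifacts)
    files <- files[file.exists(files)]
    manifest <- list(
      package_version = as.character(utils::packageVersion("regimap")),
      r_version = R.version.string,
      seed = config$seed,
      stages = stages,
      checksums = as.list(tools::md5sum(files)),
      config = jsonlite::fromJSON(jsonlite::toJSON(
        unclass(config[setdiff(names(config), "synthetic")]),
        auto_unbox = TRUE, null = "null", digits = NA)))
    artifacts$manifest <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest, artifacts$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }, error = on_fail)
  invisible(artifacts)
}
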