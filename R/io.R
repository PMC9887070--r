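#' Read an incidence table from CSV
#'
#' Expects a UTF-8 CSV with header columns `sex`, `year`, `age_group`,
#' `area_id`, `count` and either `histology` (labels) or `morphology`
#' (4-digit ICD-O-3 codes, classified on read via `map`).  Rows sharing the
#' same `(sex, histology, area_id, year, age_group)` key are aggregated by
#' summing counts, so the returned table has unique keys.
#'
#' @param path CSV file path.
#' @param map `histology_map` used when a `morphology` column is present.
#' @return A data frame of class `incidence_table` with columns
#'   `sex, histology, area_id, year, age_group, count`.
#' @export
read_incidence <- function(path, map = default_histology_map()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("sex", "year", "age_group", "area_id", "count")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("incidence file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"histology" %in% names(raw)) {
    if (!"morphology" %in% names(raw))
      stop("incidence file ", path,
           " must contain a 'histology' or 'morphology' column")
    raw$histology <- classify_histology(raw$morphology, map)
  }
  as_incidence_table(raw)
}

#' Coerce a data frame to a validated incidence table
#'
#' @param df data frame with columns `sex, histology, area_id, year,
#'   age_group, count` (extra columns such as `topography` are kept until
#'   aggregation and then dropped).
#' @return An `incidence_table` with unique keys and summed counts.
#' @export
as_incidence_table <- function(df) {
  required <- c("sex", "histology", "area_id", "year", "age_group", "count")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("incidence table is missing column(s): ", paste(missing, collapse = ", "))
  df$count <- as.numeric(df$count)
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad))
    stop("invalid (negative or unparseable) count in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (nrow(df) == 0) {
    out <- df[, required]
  } else {
    out <- stats::aggregate(
      count ~ sex + histology + area_id + year + age_group,
      data = df, FUN = sum)
    out <- out[, required]
    out <- out[order(out$sex, out$histology, out$area_id, out$year, out$age_group), ]
  }
  rownames(out) <- NULL
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Write an incidence table to CSV
#' @param x an `incidence_table`.
#' @param path destination CSV path.
#' @export
write_incidence <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a person-years table from CSV
#'
#' Header columns: `sex`, `year`, `age_group`, `area_id`, `person_years`.
#' Duplicate keys are summed.
#'
#' @param path CSV file path.
#' @return Data frame of class `person_years_table`.
#' @export
read_person_years <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_person_years_table(raw)
}

#' Coerce a data frame to a validated person-years table
#' @param df data frame with columns `sex, area_id, year, age_group,
#'   person_years`.
#' @return A `person_years_table`.
#' @export
as_person_years_table <- function(df) {
  required <- c("sex", "area_id", "year", "age_group", "person_years")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("person-years table is missing column(s): ",
         paste(missing, collapse = ", "))
  df$person_years <- as.numeric(df$person_years)
  bad <- which(is.na(df$person_years) | df$person_years < 0)
  if (length(bad))
    stop("invalid person-years in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (nrow(df) == 0) {
    out <- df[, required]
  } else {
    out <- stats::aggregate(person_years ~ sex + area_id + year + age_group,
                            data = df, FUN = sum)
    out <- out[, required]
    out <- out[order(out$sex, out$area_id, out$year, out$age_group), ]
  }
  rownames(out) <- NULL
  class(out) <- c("person_years_table", "data.frame")
  out
}

#' Write a person-years table to CSV
#' @param x a `person_years_table`.
#' @param path destination CSV path.
#' @export
write_person_years <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Check that person-years cover every incidence key
#'
#' Every `(sex, area_id, year, age_group)` combination present in the
#' incidence table must have a person-years row; otherwise rates are
#' undefined and the join is refused.
#'
#' @param incidence an `incidence_table`.
#' @param person_years a `person_years_table`.
#' @return Invisibly `TRUE`; errors listing missing keys otherwise.
#' @export
check_coverage <- function(incidence, person_years) {
  key <- function(d) paste(d$sex, d$area_id, d$year, d$age_group, sep = "|")
  miss <- setdiff(unique(key(incidence)), unique(key(person_years)))
  if (length(miss))
    stop("person-years table does not cover incidence key(s): ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) sprintf(" ... (%d total)", length(miss)) else "")
  invisible(TRUE)
}

#' Filter records by ICD-O topography site family
#'
#' Keeps records whose `topography` code belongs to one of the given site
#' families; matching is by 3-character prefix, so `"C34"` matches any
#' subsite `C34.x`.  The number of dropped records is reported via
#' [message()].
#'
#' @param records data frame with a `topography` column.
#' @param code_set character vector of 3-character ICD-O site codes
#'   (e.g. `c("C33", "C34")` for trachea + lung); must be nonempty.
#' @return The filtered records (possibly zero rows).
#' @export
filter_topography <- function(records, code_set) {
  if (length(code_set) == 0)
    stop("empty topography filter")
  if (!"topography" %in% names(records))
    stop("records carry no 'topography' column")
  prefix <- toupper(substr(gsub("\\.", "", records$topography), 1, 3))
  keep <- prefix %in% toupper(substr(code_set, 1, 3))
  dropped <- sum(!keep)
  if (dropped > 0)
    message("filter_topography: dropped ", dropped, " of ", length(keep),
            " record(s) outside ", paste(code_set, collapse = ", "))
  records[keep, , drop = FALSE]
}

# ---- area geometries (GeoJSON) ----------------------------------------------

#' Read area geometries from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon (first ring used) carrying an `area_id`
#' property.  Coordinates are taken as planar (projected CRS); no
#' reprojection is performed.
#'
#' @param path GeoJSON file path.
#' @return An object of class `area_geometry`: list with `areas` (data frame
#'   `area_id, cx, cy` of polygon centroids) and `polygons` (named list of
#'   2-column coordinate matrices).
#' @export
read_area_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features))
    stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list()
  ids <- character()
  for (f in gj$features) {
    id <- f$properties$area_id
    if (is.null(id)) stop("feature without 'area_id' property in ", path)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys[[as.character(id)]] <- m
    ids <- c(ids, as.character(id))
  }
  if (anyDuplicated(ids))
    stop("duplicate area_id in geometry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  new_area_geometry(polys)
}

new_area_geometry <- function(polygons) {
  cent <- t(vapply(polygons, polygon_centroid, numeric(2)))
  areas <- data.frame(area_id = names(polygons),
                      cx = cent[, 1], cy = cent[, 2],
                      stringsAsFactors = FALSE)
  rownames(areas) <- NULL
  structure(list(areas = areas, polygons = polygons), class = "area_geometry")
}

#' Write area geometries to GeoJSON
#' @param geom an `area_geometry`.
#' @param path destination path.
#' @param crs optional CRS identifier recorded as a foreign member.
#' @export
write_area_geojson <- function(geom, path, crs = NULL) {
  stopifnot(inherits(geom, "area_geometry"))
  features <- lapply(names(geom$polygons), function(id) {
    m <- geom$polygons[[id]]
    ring <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    list(type = "Feature",
         properties = list(area_id = id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(crs)) fc$crs_id <- crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Shoelace centroid of a closed (or implicitly closed) planar ring.
polygon_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  n <- length(x)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * 100) return(c(mean(m[, 1]), mean(m[, 2])))
  cx <- sum((x[-n] + x[-1]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cross) / (6 * a)
  c(cx, cy)
}
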