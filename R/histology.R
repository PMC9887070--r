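#' Default morphology-to-histology map for lung cancer
#'
#' Ordered classification rules mapping 4-digit ICD-O-3 morphology codes to
#' the five histological types conventionally reported for lung cancer:
#' adenocarcinoma, squamous cell carcinoma, large cell carcinoma, small cell
#' carcinoma, and a fallback of "other specified or unspecified carcinoma".
#' The groupings follow standard ICD-O-3 practice (squamous 8050-8078 and
#' 8083-8084; small cell 8041-8045; adenocarcinoma 8140-8147, 8250-8260,
#' 8310, 8480-8490 and 8550-8574; large cell 8012-8014).  Registries differ
#' at the margins, so the map is fully overrideable: supply your own via
#' [read_histology_map()] or by building the same structure by hand.
#'
#' @return An object of class `histology_map`: a list with `rules` (ordered
#'   list of `list(label =, codes = integer vector)`) and `fallback`.
#' @export
default_histology_map <- function() {
  rules <- list(
    list(label = "squamous cell carcinoma",
         codes = c(8050:8078, 8083:8084)),
    list(label = "small cell carcinoma",
         codes = 8041:8045),
    list(label = "adenocarcinoma",
         codes = c(8140:8147, 8250:8260, 8310, 8480:8490, 8550:8574)),
    list(label = "large cell carcinoma",
         codes = 8012:8014)
  )
  new_histology_map(rules, fallback = "other specified or unspecified carcinoma")
}

new_histology_map <- function(rules, fallback) {
  all_codes <- unlist(lapply(rules, `[[`, "codes"))
  if (anyDuplicated(all_codes))
    stop("histology map code sets are not disjoint: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  structure(list(rules = rules, fallback = fallback), class = "histology_map")
}

#' Read a histology map from a YAML config file
#'
#' The file holds one key per label whose value is a list of code ranges
#' (`"8050-8078"`) or single codes, plus an optional `fallback` key.
#'
#' @param path path to a YAML file.
#' @return A `histology_map`.
#' @export
read_histology_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  fallback <- cfg$fallback %||% "other specified or unspecified carcinoma"
  cfg$fallback <- NULL
  rules <- lapply(names(cfg), function(label) {
    codes <- unlist(lapply(cfg[[label]], function(r) {
      r <- as.character(r)
      if (grepl("-", r)) {
        bounds <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
        seq(bounds[1], bounds[2])
      } else as.integer(r)
    }))
    list(label = label, codes = codes)
  })
  new_histology_map(rules, fallback)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify ICD-O-3 morphology codes into histological types
#'
#' Applies the ordered rules of a [histology map][default_histology_map];
#' codes matching no rule receive the fallback label, so the classifier is
#' total over 4-digit codes.
#'
#' @param morphology vector of 4-digit ICD-O-3 morphology codes (integer or
#'   strings of digits).
#' @param map a `histology_map`; the shipped default if omitted.
#' @return Character vector of histology labels, same length as `morphology`.
#' @examples
#' classify_histology(c(8140, 8070, 9999))
#' @export
classify_histology <- function(morphology, map = default_histology_map()) {
  stopifnot(inherits(map, "histology_map"))
  if (is.character(morphology) || is.factor(morphology)) {
    chr <- as.character(morphology)
    bad <- !grepl("^[0-9]+$", chr)
    if (any(bad))
      stop("non-numeric morphology code(s): ",
           paste(utils::head(chr[bad], 5), collapse = ", "))
    morphology <- as.integer(chr)
  }
  if (!is.numeric(morphology) || anyNA(morphology))
    stop("morphology codes must be numeric and non-missing")
  # first matching rule wins (code sets are disjoint, but keep the contract)
  assigned <- rep(FALSE, length(morphology))
  out <- rep(map$fallback, length(morphology))
  for (rule in map$rules) {
    hit <- !assigned & morphology %in% rule$codes
    out[hit] <- rule$label
    assigned <- assigned | hit
  }
  out
}
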