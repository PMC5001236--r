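PRIORS_SCHEMA_VERSION <- 1L

#' Serialize a signal prior set to JSON
#'
#' Writes the full model (zone scheme, Gaussian cells with imputation flags,
#' length prior) as a versioned JSON document at full numeric precision, so
#' that `load_priors(save_priors(x))` round-trips field-for-field.
#'
#' @param priors A [signal_priors()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_priors <- function(priors, path) {
  stopifnot(inherits(priors, "signal_priors"))
  doc <- list(
    schema_version = PRIORS_SCHEMA_VERSION,
    zone_scheme = list(
      profile = priors$zone_scheme$profile,
      zone_width = priors$zone_scheme$zone_width,
      n_zones = priors$zone_scheme$n_zones
    ),
    length_range = priors$length_range,
    note = priors$note,
    cells = priors$cells,
    length_prior = priors$length_prior
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Load a signal prior set from JSON
#'
#' @param path Path to a file written by [save_priors()] (or hand-edited in
#'   the same schema).
#' @return A [signal_priors()] object.
#' @export
load_priors <- function(path) {
  if (!file.exists(path)) abort(sprintf("priors file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("schema_version", "zone_scheme", "length_range", "cells",
                  "length_prior")) {
    if (is.null(doc[[field]])) {
      abort(sprintf("priors file is missing required field `%s`", field))
    }
  }
  if (!identical(as.integer(doc$schema_version), PRIORS_SCHEMA_VERSION)) {
    abort(sprintf(
      "unsupported priors schema_version %s (expected %d)",
      doc$schema_version, PRIORS_SCHEMA_VERSION
    ))
  }
  zs <- doc$zone_scheme
  scheme <- if (identical(zs$profile, "custom")) {
    zone_scheme("custom", zone_width = zs$zone_width, n_zones = zs$n_zones)
  } else {
    zone_scheme(zs$profile)
  }
  cells <- as_tibble(doc$cells) |>
    dplyr::mutate(
      zone = as.integer(.data$zone),
      length = as.integer(.data$length),
      n_obs = as.integer(.data$n_obs),
      imputed = as.logical(.data$imputed)
    )
  lp <- as_tibble(doc$length_prior) |>
    dplyr::mutate(length = as.integer(.data$length))
  signal_priors(cells, lp, scheme, as.integer(doc$length_range),
                note = doc$note)
}
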