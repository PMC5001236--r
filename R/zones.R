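#' Read-position zone schemes
#'
#' Flow voltage distributions drift along the read, so homopolymer positions
#' are binned into zones of equal width measured from the read start. The
#' `"torrent"` profile uses four 75 bp zones (Z1: 1-75, Z2: 76-150,
#' Z3: 151-225, Z4: 226-300); the `"proton"` profile uses five 50 bp zones.
#' Positions past the last boundary are clamped to the last zone.
#'
#' @param profile `"torrent"`, `"proton"`, or `"custom"` (requires
#'   `zone_width` and `n_zones`).
#' @param zone_width Zone width in bp (custom profile).
#' @param n_zones Number of zones (custom profile).
#' @return A `zone_scheme` object (list with `profile`, `zone_width`,
#'   `n_zones`).
#' @examples
#' zone_scheme("torrent")
#' assign_zone(c(75, 76, 1000), zone_scheme("torrent"))
#' @export
zone_scheme <- function(profile = c("torrent", "proton", "custom"),
                        zone_width = NULL, n_zones = NULL) {
  profile <- match.arg(profile)
  if (profile == "torrent") {
    zone_width <- 75L
    n_zones <- 4L
  } else if (profile == "proton") {
    zone_width <- 50L
    n_zones <- 5L
  } else {
    if (is.null(zone_width) || is.null(n_zones)) {
      abort("custom zone scheme requires `zone_width` and `n_zones`")
    }
  }
  zone_width <- as.integer(zone_width)
  n_zones <- as.integer(n_zones)
  if (zone_width < 1L || n_zones < 1L) {
    abort("`zone_width` and `n_zones` must be positive integers")
  }
  structure(
    list(profile = profile, zone_width = zone_width, n_zones = n_zones),
    class = "zone_scheme"
  )
}

#' @export
print.zone_scheme <- function(x, ...) {
  cat(sprintf(
    "<zone_scheme: %s, %d zones x %d bp>\n",
    x$profile, x$n_zones, x$zone_width
  ))
  invisible(x)
}

#' Assign read positions to zones
#'
#' Maps 1-based read positions onto zone indices: `ceiling(position / width)`,
#' clamped to the last zone. Total and monotone non-decreasing in position.
#'
#' @param read_position Integer vector of 1-based base offsets within a read.
#' @param scheme A [zone_scheme()].
#' @return Integer vector of 1-based zone indices.
#' @export
assign_zone <- function(read_position, scheme = zone_scheme("torrent")) {
  stopifnot(inherits(scheme, "zone_scheme"))
  if (any(is.na(read_position)) || any(read_position < 1)) {
    abort("`read_position` must be >= 1 and non-missing")
  }
  pmin(as.integer(ceiling(read_position / scheme$zone_width)), scheme$n_zones)
}
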