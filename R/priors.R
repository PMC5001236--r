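#' Construct a signal prior set
#'
#' A `signal_priors` object holds the trained flow-signal model: one Gaussian
#' voltage distribution per (nucleotide, zone, homopolymer length) cell, plus
#' the marginal length prior P(L). The marginal voltage probability P(V) is
#' represented implicitly as the normalizing constant of the posterior over
#' lengths at fixed (nucleotide, zone).
#'
#' @param cells Tibble with columns `nucleotide`, `zone`, `length`, `mean`,
#'   `stdev`, `n_obs`, `imputed`; one row per model cell, covering every
#'   length in `length_range` for every (nucleotide, zone).
#' @param length_prior Tibble with columns `length`, `prob`, summing to 1
#'   over `length_range`.
#' @param scheme The [zone_scheme()] the cells are indexed by.
#' @param length_range Inclusive integer pair of supported candidate lengths.
#' @param note Optional free-text provenance note carried through
#'   serialization.
#' @return A `signal_priors` object.
#' @seealso [fit_priors()], [default_priors()], [save_priors()]
#' @export
signal_priors <- function(cells, length_prior, scheme, length_range,
                          note = NULL) {
  stopifnot(inherits(scheme, "zone_scheme"))
  cells <- as_tibble(cells)
  length_prior <- as_tibble(length_prior)
  assert_columns(
    cells, c("nucleotide", "zone", "length", "mean", "stdev", "n_obs", "imputed"),
    "`cells`"
  )
  assert_columns(length_prior, c("length", "prob"), "`length_prior`")
  assert_nucleotide(cells$nucleotide)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] > length_range[2]) {
    abort("`length_range` must be an inclusive integer pair [min, max]")
  }
  lengths <- seq(length_range[1], length_range[2])
  grid <- tidyr::expand_grid(
    nucleotide = NUCLEOTIDES, zone = seq_len(scheme$n_zones), length = lengths
  )
  have <- dplyr::anti_join(grid, cells, by = c("nucleotide", "zone", "length"))
  if (nrow(have) > 0) {
    abort(sprintf(
      "`cells` must cover every (nucleotide, zone, length); %d cell(s) missing",
      nrow(have)
    ))
  }
  if (any(cells$stdev <= 0)) abort("all `stdev` must be > 0")
  lp <- length_prior$prob[match(lengths, length_prior$length)]
  if (anyNA(lp) || abs(sum(lp) - 1) > 1e-9) {
    abort("`length_prior` must cover length_range and sum to 1 (tol 1e-9)")
  }
  structure(
    list(
      cells = dplyr::arrange(cells, .data$nucleotide, .data$zone, .data$length),
      length_prior = tibble(length = lengths, prob = lp),
      zone_scheme = scheme,
      length_range = length_range,
      note = note
    ),
    class = "signal_priors"
  )
}

#' @export
print.signal_priors <- function(x, ...) {
  cat(sprintf(
    "<signal_priors: %d cells (%d imputed), lengths %d-%d, %s zones>\n",
    nrow(x$cells), sum(x$cells$imputed),
    x$length_range[1], x$length_range[2], x$zone_scheme$profile
  ))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Detect homopolymer candidates in a flowgram table
#'
#' A flow is a homopolymer candidate when its voltage strictly exceeds the
#' detection threshold (default 1.5 incorporation units, so single-base and
#' empty flows are excluded). Candidates get a read-position zone assigned;
#' all other columns (e.g. `ref_length`, `true_length`) pass through.
#'
#' @param flowgram Data frame with columns `nucleotide`, `read_position`,
#'   `voltage` (and typically `read_id`, `flow_index`).
#' @param threshold Detection threshold in voltage units; strict inequality.
#' @param scheme [zone_scheme()] used for zone assignment.
#' @return Tibble of candidate rows with a `zone` column added.
#' @examples
#' fg <- tibble::tibble(
#'   read_id = "r1", flow_index = 0:3, nucleotide = "A",
#'   read_position = c(1, 10, 80, 200), voltage = c(0.9, 1.5, 1.6, 3.7)
#' )
#' detect_candidates(fg)
#' @export
detect_candidates <- function(flowgram, threshold = 1.5,
                              scheme = zone_scheme("torrent")) {
  flowgram <- as_tibble(flowgram)
  assert_columns(flowgram, c("nucleotide", "read_position", "voltage"),
                 "flowgram")
  bad <- which(
    !flowgram$nucleotide %in% NUCLEOTIDES |
      is.na(flowgram$read_position) | flowgram$read_position < 1 |
      is.na(flowgram$voltage) | flowgram$voltage < 0
  )
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed flowgram row(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  out <- dplyr::filter(flowgram, .data$voltage > threshold)
  dplyr::mutate(out, zone = assign_zone(.data$read_position, scheme))
}

#' Fit the class-conditional Gaussian voltage model
#'
#' Groups labelled candidates by (nucleotide, zone, true length) and fits each
#' cell with at least two observations by its sample mean and sample standard
#' deviation (n-1 denominator). Cells with fewer than two observations (or
#' zero voltage variance) are imputed (see Details) and flagged. The length prior is the empirical
#' frequency of `true_length` over all candidates.
#'
#' @details Imputation: a missing cell for length L takes
#' `mean = L * slope`, where the per-base slope is fitted through the origin
#' across the populated cells of the same (nucleotide, zone); its stdev is
#' copied from the nearest populated length. A (nucleotide, zone) stratum with
#' no populated cells at all borrows the populated cells of the nearest zone
#' of the same nucleotide, then of the pooled same-zone cells, and as a last
#' resort uses a unit per-base slope with stdev 0.25.
#'
#' @param candidates Tibble of labelled candidates: columns `nucleotide`,
#'   `voltage`, `true_length`, and `read_position` (or a precomputed `zone`).
#'   Every `true_length` must lie inside `length_range`.
#' @param scheme [zone_scheme()].
#' @param length_range Inclusive integer pair of lengths to model.
#' @return A [signal_priors()] object.
#' @examples
#' set.seed(1)
#' cand <- tibble::tibble(
#'   nucleotide = "A", read_position = 10,
#'   true_length = rep(2:3, c(80, 20)),
#'   voltage = rnorm(100, rep(c(1.85, 2.78), c(80, 20)), 0.14)
#' )
#' fit_priors(cand, length_range = c(2, 3))
#' @export
fit_priors <- function(candidates, scheme = zone_scheme("torrent"),
                       length_range = c(2L, 6L)) {
  candidates <- as_tibble(candidates)
  assert_columns(candidates, c("nucleotide", "voltage", "true_length"),
                 "`candidates`")
  assert_nucleotide(candidates$nucleotide)
  if (!"zone" %in% names(candidates)) {
    assert_columns(candidates, "read_position", "`candidates`")
    candidates$zone <- assign_zone(candidates$read_position, scheme)
  }
  labelled <- dplyr::filter(candidates, !is.na(.data$true_length))
  if (nrow(labelled) == 0) abort("no labelled candidates to fit priors from")
  length_range <- as.integer(length_range)
  out_of_range <- labelled$true_length < length_range[1] |
    labelled$true_length > length_range[2]
  if (any(out_of_range)) {
    abort(sprintf(
      "%d candidate(s) have true_length outside [%d, %d]; filter them first",
      sum(out_of_range), length_range[1], length_range[2]
    ))
  }

  fitted <- labelled |>
    dplyr::group_by(.data$nucleotide, .data$zone, length = .data$true_length) |>
    dplyr::summarise(
      mean = mean(.data$voltage),
      stdev = sd(.data$voltage),
      n_obs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_obs >= 2L, is.finite(.data$stdev),
                  .data$stdev > 0) |>
    dplyr::mutate(imputed = FALSE)

  cells <- impute_missing_cells(fitted, scheme, length_range)

  lp <- labelled |>
    dplyr::count(length = .data$true_length) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::select("length", "prob") |>
    tidyr::complete(length = seq(length_range[1], length_range[2]),
                    fill = list(prob = 0))

  signal_priors(cells, lp, scheme, length_range)
}

# Fill every (nucleotide, zone, length) grid cell absent from `fitted`.
# Mean: L x per-base slope fitted through the origin on the stratum's
# populated cells; stdev: nearest populated length's. Empty strata borrow
# the nearest zone of the same nucleotide, then the pooled zone, then fall
# back to slope 1 / stdev 0.25.
impute_missing_cells <- function(fitted, scheme, length_range) {
  lengths <- seq(length_range[1], length_range[2])
  grid <- tidyr::expand_grid(
    nucleotide = NUCLEOTIDES, zone = seq_len(scheme$n_zones), length = lengths
  )
  missing <- dplyr::anti_join(grid, fitted,
                              by = c("nucleotide", "zone", "length"))
  if (nrow(missing) == 0) return(fitted)

  donor_cells <- function(nt, zn) {
    own <- dplyr::filter(fitted, .data$nucleotide == nt, .data$zone == zn)
    if (nrow(own) > 0) return(own)
    same_nt <- dplyr::filter(fitted, .data$nucleotide == nt)
    if (nrow(same_nt) > 0) {
      nearest <- same_nt$zone[which.min(abs(same_nt$zone - zn))]
      return(dplyr::filter(same_nt, .data$zone == nearest))
    }
    same_zone <- dplyr::filter(fitted, .data$zone == zn)
    if (nrow(same_zone) > 0) return(same_zone)
    fitted
  }

  imputed <- missing |>
    dplyr::group_by(.data$nucleotide, .data$zone) |>
    dplyr::group_modify(function(rows, key) {
      donors <- donor_cells(key$nucleotide, key$zone)
      if (nrow(donors) == 0) {
        slope <- 1
        sd_for <- function(L) 0.25
      } else {
        slope <- sum(donors$mean * donors$length) / sum(donors$length^2)
        sd_for <- function(L) donors$stdev[which.min(abs(donors$length - L))]
      }
      dplyr::mutate(
        rows,
        mean = .data$length * slope,
        stdev = purrr::map_dbl(.data$length, sd_for),
        n_obs = 0L,
        imputed = TRUE
      )
    }) |>
    dplyr::ungroup()

  dplyr::bind_rows(fitted, imputed)
}

#' Look up Gaussian parameters for (nucleotide, zone, length)
#'
#' Vectorized lookup into the prior table. Lengths outside the modelled range
#' (e.g. single-base flows emitted by the simulator) are extrapolated on the
#' fly with the same per-base-slope rule used for imputation.
#'
#' @param priors A [signal_priors()] object.
#' @param nucleotide,zone,length Vectors (recycled to common size).
#' @return Tibble with columns `mean`, `stdev` (one row per query).
#' @export
lookup_gaussian <- function(priors, nucleotide, zone, length) {
  stopifnot(inherits(priors, "signal_priors"))
  q <- tibble(nucleotide = nucleotide, zone = as.integer(zone),
              length = as.integer(length))
  res <- dplyr::left_join(q, priors$cells,
                          by = c("nucleotide", "zone", "length"))
  miss <- which(is.na(res$mean))
  if (length(miss) > 0) {
    strata <- dplyr::distinct(res[miss, c("nucleotide", "zone")])
    for (k in seq_len(nrow(strata))) {
      cells <- dplyr::filter(
        priors$cells,
        .data$nucleotide == strata$nucleotide[k],
        .data$zone == strata$zone[k]
      )
      slope <- sum(cells$mean * cells$length) / sum(cells$length^2)
      idx <- miss[res$nucleotide[miss] == strata$nucleotide[k] &
                    res$zone[miss] == strata$zone[k]]
      res$mean[idx] <- res$length[idx] * slope
      res$stdev[idx] <- purrr::map_dbl(
        res$length[idx], function(L) cells$stdev[which.min(abs(cells$length - L))]
      )
    }
  }
  res[, c("mean", "stdev")]
}

#' @rdname tidy.signal_priors
#' @param x A `signal_priors` object.
#' @param ... Unused.
#' @export
tidy.signal_priors <- function(x, ...) x$cells

#' Tidy and summarise a fitted signal prior set
#'
#' `tidy()` returns the per-(nucleotide, zone, length) Gaussian cells;
#' `glance()` a one-row model summary.
#'
#' @return `tidy()`: tibble of cells; `glance()`: one-row tibble.
#' @name tidy.signal_priors
#' @export
glance.signal_priors <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n_fitted = sum(!x$cells$imputed),
    n_imputed = sum(x$cells$imputed),
    n_obs = sum(x$cells$n_obs, na.rm = TRUE),
    length_min = x$length_range[1],
    length_max = x$length_range[2],
    n_zones = x$zone_scheme$n_zones,
    zone_width = x$zone_scheme$zone_width
  )
}
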