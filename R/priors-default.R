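#' Built-in flow-signal parameter table
#'
#' A `signal_priors` object reconstructed from the published Gaussian
#' parameters for Ion Torrent flow voltages. The anchor cells are:
#' A homopolymers in zone Z1 at lengths 2-6 (means 1.85, 2.78, 3.68, 4.64,
#' 5.57; standard deviation rising linearly from 0.14 at L=2 to 0.38 at L=6),
#' C at (Z1, L=4) with mean 3.74 / stdev 0.30, G and T at (Z1, L=4) with mean
#' 3.68 / stdev 0.24, and the per-zone drift of A at L=4 (means 3.68, 3.57,
#' 3.54, 3.57 for Z1-Z4, stdev 0.24). All remaining cells are filled by the
#' per-base-slope imputation rule and flagged `imputed`.
#'
#' The default length prior is a geometric decay (ratio 0.5) over lengths
#' 2-6, matching the simulator's default homopolymer run-length spectrum
#' conditional on candidate lengths.
#'
#' @param profile Zone profile passed to [zone_scheme()]; the `"proton"`
#'   profile keeps the Z1 anchor cells and imputes its five 50 bp zones.
#' @param length_range Inclusive pair of modelled candidate lengths.
#' @return A [signal_priors()] object; reconstructed anchor cells carry
#'   `n_obs = NA` since the underlying counts were not published.
#' @examples
#' pri <- default_priors()
#' tidy(pri)
#' @export
default_priors <- function(profile = c("torrent", "proton"),
                           length_range = c(2L, 6L)) {
  profile <- match.arg(profile)
  scheme <- zone_scheme(profile)

  anchors <- dplyr::bind_rows(
    tibble(
      nucleotide = "A", zone = 1L, length = 2:6,
      mean = c(1.85, 2.78, 3.68, 4.64, 5.57),
      stdev = seq(0.14, 0.38, length.out = 5)
    ),
    tibble(nucleotide = "C", zone = 1L, length = 4L, mean = 3.74, stdev = 0.30),
    tibble(nucleotide = c("G", "T"), zone = 1L, length = 4L,
           mean = 3.68, stdev = 0.24)
  )
  if (profile == "torrent") {
    anchors <- dplyr::bind_rows(
      anchors,
      tibble(nucleotide = "A", zone = 2:4, length = 4L,
             mean = c(3.57, 3.54, 3.57), stdev = 0.24)
    )
  }
  anchors <- dplyr::mutate(anchors, n_obs = NA_integer_, imputed = FALSE)

  length_range <- as.integer(length_range)
  cells <- impute_missing_cells(anchors, scheme, length_range)

  lengths <- seq(length_range[1], length_range[2])
  w <- 0.5^(lengths - length_range[1])
  lp <- tibble(length = lengths, prob = w / sum(w))

  signal_priors(cells, lp, scheme, length_range,
                note = "reconstructed from printed values")
}

#' Default homopolymer run-length spectrum for the simulator
#'
#' Probability of each run length in a simulated reference: mass `p1` on
#' single bases and a geometric decay (ratio `decay`) over lengths 2 to
#' `max_length`. The default mirrors the built-in table's length prior once
#' conditioned on candidate lengths (>= 2).
#'
#' @param p1 Probability of a length-1 run.
#' @param decay Geometric ratio between successive candidate lengths.
#' @param max_length Longest run generated.
#' @return Named numeric vector of probabilities summing to 1 (names are
#'   lengths).
#' @export
default_spectrum <- function(p1 = 0.55, decay = 0.5, max_length = 6L) {
  stopifnot(p1 >= 0, p1 < 1, decay > 0, max_length >= 2)
  w <- decay^(seq(2L, max_length) - 2L)
  probs <- c(p1, (1 - p1) * w / sum(w))
  setNames(probs, seq_len(max_length))
}
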