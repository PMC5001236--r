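#' Reference mismatch penalty scheme
#'
#' Scores agreement between a candidate homopolymer length and the reference
#' genome at the same locus: 0 for a perfect match, -1 when the length matches
#' but the nucleotide differs (substitution), -2 when the lengths differ
#' (insertion/deletion).
#'
#' @param match,substitution,indel Penalty values; must satisfy
#'   `match >= substitution >= indel`.
#' @return A `penalty_scheme` object.
#' @export
penalty_scheme <- function(match = 0, substitution = -1, indel = -2) {
  if (!(match >= substitution && substitution >= indel)) {
    abort("penalties must satisfy match >= substitution >= indel")
  }
  structure(list(match = match, substitution = substitution, indel = indel),
            class = "penalty_scheme")
}

#' Evaluate the reference penalty
#'
#' @param length Candidate homopolymer length(s), >= 0.
#' @param ref_length Reference homopolymer length(s) at the locus, >= 0.
#' @param same_nucleotide Logical; whether the candidate and reference runs
#'   are the same nucleotide.
#' @param scheme A [penalty_scheme()].
#' @return Numeric penalty vector.
#' @examples
#' reference_penalty(4, 4)        # match: 0
#' reference_penalty(5, 4)        # indel: -2
#' reference_penalty(4, 4, FALSE) # substitution: -1
#' @export
reference_penalty <- function(length, ref_length, same_nucleotide = TRUE,
                              scheme = penalty_scheme()) {
  if (any(is.na(length)) || any(is.na(ref_length)) ||
      any(length < 0) || any(ref_length < 0)) {
    abort("`length` and `ref_length` must be non-missing and >= 0")
  }
  dplyr::case_when(
    length != ref_length ~ scheme$indel,
    same_nucleotide ~ scheme$match,
    .default = scheme$substitution
  )
}

#' Configuration for the integrated caller
#'
#' @param weight Weighting factor W in `[0, 1]` balancing the log posterior
#'   (W = 1: Bayesian only) against the reference penalty (W = 0: reference
#'   only). The default 0.28 is the published optimum for A homopolymers in
#'   zone Z1; optimize per dataset with [optimize_weight()].
#' @param penalties A [penalty_scheme()].
#' @param length_range Optional inclusive pair overriding the prior set's
#'   candidate length range.
#' @param log_floor Tiny positive floor applied to posterior probabilities
#'   inside the logarithm so the score stays finite and the penalty term can
#'   still discriminate.
#' @return An `integrated_config` object.
#' @export
integrated_config <- function(weight = 0.28, penalties = penalty_scheme(),
                              length_range = NULL, log_floor = 1e-300) {
  if (is.na(weight) || weight < 0 || weight > 1) {
    abort("`weight` must lie in [0, 1]")
  }
  if (log_floor <= 0) abort("`log_floor` must be > 0")
  stopifnot(inherits(penalties, "penalty_scheme"))
  structure(
    list(weight = weight, penalties = penalties,
         length_range = length_range, log_floor = log_floor),
    class = "integrated_config"
  )
}

# n x K penalty matrix: Pen(L_k | ref_i). NA ref rows stay at the indel
# penalty (callers overwrite them via the Bayesian fallback).
penalty_matrix <- function(ref, same_nt, lengths, penalties) {
  pen <- matrix(penalties$indel, length(ref), length(lengths))
  hit <- which(!is.na(ref) & ref >= min(lengths) & ref <= max(lengths))
  if (length(hit) > 0) {
    col <- match(ref[hit], lengths)
    pen[cbind(hit, col)] <- ifelse(same_nt[hit], penalties$match,
                                   penalties$substitution)
  }
  pen
}

# Shared candidate validation + zone completion for the callers.
prepare_candidates <- function(candidates, priors) {
  candidates <- as_tibble(candidates)
  assert_columns(candidates, c("nucleotide", "voltage"), "`candidates`")
  assert_nucleotide(candidates$nucleotide)
  if (!"zone" %in% names(candidates)) {
    assert_columns(candidates, "read_position", "`candidates`")
    candidates$zone <- assign_zone(candidates$read_position,
                                   priors$zone_scheme)
  }
  if (any(candidates$zone < 1 | candidates$zone > priors$zone_scheme$n_zones)) {
    abort("candidate `zone` outside the prior set's zone scheme")
  }
  candidates
}

# n x K matrix of log N(V; mean, stdev) per candidate (rows) and length
# (columns); lengths attached as an attribute.
log_likelihood_matrix <- function(candidates, priors, lengths) {
  n <- nrow(candidates)
  ll <- matrix(NA_real_, n, length(lengths))
  for (k in seq_along(lengths)) {
    par <- lookup_gaussian(priors, candidates$nucleotide, candidates$zone,
                           lengths[k])
    ll[, k] <- dnorm(candidates$voltage, par$mean, par$stdev, log = TRUE)
  }
  attr(ll, "lengths") <- lengths
  ll
}

# Posterior over lengths at fixed (nucleotide, zone): Gaussian likelihood
# times length prior, normalized over the candidate lengths in log space so
# extreme voltages never produce NaN.
posterior_matrix <- function(candidates, priors) {
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  ll <- log_likelihood_matrix(candidates, priors, lengths)
  lp <- log(priors$length_prior$prob)
  lj <- sweep(ll, 2, lp, "+")
  row_max <- apply(lj, 1, max)
  post <- exp(lj - row_max)
  post <- post / rowSums(post)
  attr(post, "lengths") <- lengths
  post
}

#' Posterior homopolymer length probabilities
#'
#' Computes, for each candidate flow, the Bayesian posterior over candidate
#' lengths: the Gaussian voltage likelihood of the candidate's (nucleotide,
#' zone) cell times the length prior, normalized over the modelled length
#' range. Computation is done in log space, so posteriors are well-defined
#' (and sum to 1) even for voltages far outside the fitted range.
#'
#' @param candidates Tibble with `nucleotide`, `voltage`, and `zone` or
#'   `read_position`.
#' @param priors A [signal_priors()] object.
#' @return Long tibble: one row per candidate per length, with `.row`
#'   (candidate row index), `length`, and `posterior`.
#' @examples
#' pri <- default_priors()
#' posterior_lengths(
#'   tibble::tibble(nucleotide = "A", read_position = 10, voltage = 3.7),
#'   pri
#' )
#' @export
posterior_lengths <- function(candidates, priors) {
  stopifnot(inherits(priors, "signal_priors"))
  candidates <- prepare_candidates(candidates, priors)
  post <- posterior_matrix(candidates, priors)
  lengths <- attr(post, "lengths")
  tibble(
    .row = rep(seq_len(nrow(candidates)), times = length(lengths)),
    length = rep(lengths, each = nrow(candidates)),
    posterior = as.vector(post)
  ) |>
    dplyr::arrange(.data$.row, .data$length)
}

#' Integrated score for one candidate's posterior
#'
#' Combines the log posterior with the reference penalty:
#' `S(L) = W * ln(max(posterior(L), log_floor)) + (1 - W) * Pen(L | ref)`.
#'
#' @param posterior Named numeric vector of posterior probabilities (names are
#'   lengths) or a tibble with `length` and `posterior` columns.
#' @param ref_length Reference homopolymer length at the candidate's locus.
#' @param config An [integrated_config()].
#' @param same_nucleotide Whether the reference run is the same nucleotide as
#'   the candidate's.
#' @return Tibble with `length`, `posterior`, `penalty`, `score`.
#' @export
integrated_score <- function(posterior, ref_length,
                             config = integrated_config(),
                             same_nucleotide = TRUE) {
  stopifnot(inherits(config, "integrated_config"))
  if (is.data.frame(posterior)) {
    lengths <- as.integer(posterior$length)
    p <- posterior$posterior
  } else {
    lengths <- as.integer(names(posterior))
    p <- as.numeric(posterior)
  }
  if (anyNA(lengths)) abort("`posterior` must be indexed by integer lengths")
  pen <- reference_penalty(lengths, ref_length, same_nucleotide,
                           config$penalties)
  w <- config$weight
  tibble(
    length = lengths, posterior = p, penalty = pen,
    score = w * log(pmax(p, config$log_floor)) + (1 - w) * pen
  )
}

#' Call homopolymer lengths
#'
#' The package's central verb: assigns a called length to every candidate
#' flow, by one of four methods.
#'
#' * `"integrated"` — maximizes
#'   `S(L) = W * ln P(L | N, Z, V) + (1 - W) * Pen(L | ref)` over the
#'   modelled lengths; requires a `ref_length` column (candidates with a
#'   missing `ref_length` fall back to the Bayesian call with a warning).
#' * `"bayes"` — maximizes the posterior `P(L | N, Z, V)`.
#' * `"nearest_mean"` — nearest prior-mean baseline: minimizes
#'   `|V - mean(N, Z, L)|`.
#' * `"reference_only"` — the integrated score at W = 0, i.e. the reference
#'   length whenever it lies in the modelled range.
#'
#' Ties are broken toward the larger posterior, then the smaller length
#' (undercalls being the conservative, documented failure mode);
#' `"nearest_mean"` ties break toward the smaller length.
#'
#' @param candidates Tibble with `nucleotide`, `voltage`, `zone` or
#'   `read_position`; `ref_length` (and optionally `ref_nucleotide`) for the
#'   reference-aware methods. Extra columns pass through.
#' @param priors A [signal_priors()] object.
#' @param method Calling method (see above).
#' @param config An [integrated_config()]; its `weight` is only used by
#'   `"integrated"`.
#' @return The input tibble with `method`, `called_length`, `posterior_max`
#'   (posterior at the called length) and, for the reference-aware methods,
#'   `score_max` columns added.
#' @examples
#' pri <- default_priors()
#' cand <- tibble::tibble(
#'   nucleotide = "A", read_position = 10, voltage = c(1.9, 3.7, 4.5),
#'   ref_length = c(2L, 4L, 4L)
#' )
#' call_homopolymers(cand, pri, method = "integrated")
#' @export
call_homopolymers <- function(candidates, priors,
                              method = c("integrated", "bayes",
                                         "nearest_mean", "reference_only"),
                              config = integrated_config()) {
  stopifnot(inherits(priors, "signal_priors"),
            inherits(config, "integrated_config"))
  method <- match.arg(method)
  candidates <- prepare_candidates(candidates, priors)
  lengths <- if (is.null(config$length_range)) {
    seq(priors$length_range[1], priors$length_range[2])
  } else {
    seq(config$length_range[1], config$length_range[2])
  }
  n <- nrow(candidates)
  out <- dplyr::mutate(candidates, method = method)
  if (n == 0) {
    return(dplyr::mutate(out, called_length = integer(),
                         posterior_max = numeric(), score_max = numeric()))
  }

  if (method == "nearest_mean") {
    dist <- matrix(NA_real_, n, length(lengths))
    for (k in seq_along(lengths)) {
      par <- lookup_gaussian(priors, candidates$nucleotide, candidates$zone,
                             lengths[k])
      dist[, k] <- abs(candidates$voltage - par$mean)
    }
    best <- max.col(-dist, ties.method = "first")
    post <- posterior_matrix(candidates, priors)
    return(dplyr::mutate(
      out,
      called_length = lengths[best],
      posterior_max = post[cbind(seq_len(n), best)],
      score_max = NA_real_
    ))
  }

  post <- posterior_matrix(candidates, priors)

  if (method == "bayes") {
    best <- max.col(post, ties.method = "first")
    return(dplyr::mutate(
      out,
      called_length = lengths[best],
      posterior_max = post[cbind(seq_len(n), best)],
      score_max = NA_real_
    ))
  }

  # reference-aware methods
  weight <- if (method == "reference_only") 0 else config$weight
  assert_columns(candidates, "ref_length", "`candidates`")
  ref <- candidates$ref_length
  same_nt <- if ("ref_nucleotide" %in% names(candidates)) {
    candidates$nucleotide == candidates$ref_nucleotide
  } else {
    rep(TRUE, n)
  }

  no_ref <- is.na(ref)
  if (any(no_ref) && method == "integrated") {
    warn(sprintf(
      "%d candidate(s) have no ref_length; falling back to Bayesian call",
      sum(no_ref)
    ))
  }

  pen <- penalty_matrix(ref, same_nt, lengths, config$penalties)

  score <- weight * log(pmax(post, config$log_floor)) + (1 - weight) * pen
  if (any(no_ref)) {
    # Bayesian fallback: score by log posterior alone for those rows
    score[no_ref, ] <- log(pmax(post[no_ref, , drop = FALSE],
                                config$log_floor))
  }
  best <- argmax_rows(score, prefer = post)
  dplyr::mutate(
    out,
    called_length = lengths[best],
    posterior_max = post[cbind(seq_len(n), best)],
    score_max = score[cbind(seq_len(n), best)]
  )
}
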