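#' Optimize the integrated-model weight by cross-validation
#'
#' Grid-searches the weighting factor W of the integrated score, scoring each
#' grid value by its mean held-out misclassification rate over k folds
#' (candidates are shuffled into folds with a seeded permutation). The
#' returned best weight is the grid value with the smallest CV error, ties
#' going to the smaller W (i.e. leaning on the reference, the conservative
#' side).
#'
#' @param candidates Labelled candidates: `nucleotide`, `voltage`, `zone` or
#'   `read_position`, `ref_length`, `true_length` (all non-missing).
#' @param priors A [signal_priors()] object.
#' @param grid Numeric grid of candidate weights in `[0, 1]`. The default
#'   steps by 0.02, the resolution at which published optima are reported.
#' @param folds Number of cross-validation folds.
#' @param seed Optional integer seed for the fold shuffle.
#' @param config An [integrated_config()] supplying penalties and log floor
#'   (its `weight` is ignored).
#' @return A `weight_fit` object: `best_weight`, the CV `curve` tibble
#'   (`weight`, `cv_error` rate, `errors` total held-out errors), `folds`,
#'   `n`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' pri <- default_priors()
#' cand <- simulate_candidates(500, pri, seed = 1)
#' fit <- optimize_weight(cand, pri, grid = seq(0, 1, 0.1), seed = 1)
#' glance(fit)
#' @export
optimize_weight <- function(candidates, priors, grid = seq(0, 1, by = 0.02),
                            folds = 5L, seed = NULL,
                            config = integrated_config()) {
  stopifnot(inherits(priors, "signal_priors"))
  if (any(grid < 0 | grid > 1)) abort("`grid` values must lie in [0, 1]")
  candidates <- prepare_candidates(candidates, priors)
  assert_columns(candidates, c("ref_length", "true_length"), "`candidates`")
  if (anyNA(candidates$ref_length) || anyNA(candidates$true_length)) {
    abort("every candidate needs a non-missing `ref_length` and `true_length`")
  }
  n <- nrow(candidates)
  if (n < folds) {
    abort(sprintf("need at least as many candidates (%d) as folds (%d)",
                  n, folds))
  }

  fold_id <- with_seed_if(seed, sample(rep(seq_len(folds), length.out = n)))
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  post <- posterior_matrix(candidates, priors)
  same_nt <- if ("ref_nucleotide" %in% names(candidates)) {
    candidates$nucleotide == candidates$ref_nucleotide
  } else {
    rep(TRUE, n)
  }
  pen <- penalty_matrix(candidates$ref_length, same_nt, lengths,
                        config$penalties)
  log_post <- log(pmax(post, config$log_floor))

  curve <- purrr::map_dfr(grid, function(w) {
    called <- lengths[argmax_rows(w * log_post + (1 - w) * pen, prefer = post)]
    wrong <- called != candidates$true_length
    fold_rates <- tapply(wrong, fold_id, mean)
    tibble(weight = w, cv_error = mean(fold_rates), errors = sum(wrong))
  })

  best <- curve$weight[order(curve$cv_error, curve$weight)][1]
  structure(
    list(best_weight = best, curve = curve, folds = folds, n = n),
    class = "weight_fit"
  )
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf(
    "<weight_fit: best W = %.2f (%d-fold CV on %d candidates, CV error %.4f)>\n",
    x$best_weight, x$folds, x$n,
    x$curve$cv_error[match(x$best_weight, x$curve$weight)]
  ))
  invisible(x)
}

#' @rdname tidy.weight_fit
#' @param x A `weight_fit` object.
#' @param ... Unused.
#' @export
tidy.weight_fit <- function(x, ...) x$curve

#' Tidy and summarise a weight optimization
#'
#' `tidy()` returns the cross-validation error curve over the weight grid;
#' `glance()` a one-row summary with the selected weight.
#'
#' @return `tidy()`: tibble (`weight`, `cv_error`, `errors`); `glance()`:
#'   one-row tibble.
#' @name tidy.weight_fit
#' @export
glance.weight_fit <- function(x, ...) {
  i <- match(x$best_weight, x$curve$weight)
  tibble(
    best_weight = x$best_weight,
    cv_error = x$curve$cv_error[i],
    errors = x$curve$errors[i],
    folds = x$folds,
    n = x$n
  )
}
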