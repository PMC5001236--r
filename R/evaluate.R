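#' Score calls against ground truth
#'
#' Joins calls to ground-truth records by (`read_id`, `flow_index`) and
#' tallies identification errors (called length different from true length),
#' per (nucleotide, zone) cell and overall, per method. Error accounting is
#' per homopolymer, not per base.
#'
#' @param calls Tibble from [call_homopolymers()] (possibly several methods
#'   row-bound together): needs `read_id`, `flow_index`, `nucleotide`,
#'   `zone`, `method`, `called_length`.
#' @param truth Tibble of ground-truth records with `read_id`, `flow_index`,
#'   `true_length` (e.g. from [simulate_flowgrams()]). May be `NULL` when
#'   `calls` already carries a `true_length` column.
#' @return An `hp_evaluation` object: list with `by_cell` (tibble:
#'   `nucleotide`, `zone`, `method`, `count`, `errors`, `error_percent`) and
#'   `overall` (per method). Percentages are reported to 3 decimals.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' pri <- default_priors()
#' cand <- simulate_candidates(300, pri, seed = 7)
#' calls <- call_homopolymers(cand, pri, method = "bayes")
#' glance(evaluate_calls(calls))
#' @export
evaluate_calls <- function(calls, truth = NULL) {
  calls <- as_tibble(calls)
  assert_columns(calls, c("nucleotide", "zone", "method", "called_length"),
                 "`calls`")
  if (is.null(truth)) {
    assert_columns(calls, "true_length", "`calls` (with `truth = NULL`)")
    joined <- calls
  } else {
    truth <- as_tibble(truth)
    assert_columns(truth, c("read_id", "flow_index", "true_length"), "`truth`")
    assert_columns(calls, c("read_id", "flow_index"), "`calls`")
    joined <- dplyr::inner_join(
      calls, dplyr::select(truth, "read_id", "flow_index", "true_length"),
      by = c("read_id", "flow_index")
    )
    n_methods <- dplyr::n_distinct(calls$method)
    if (nrow(joined) < nrow(calls)) {
      orphans <- dplyr::anti_join(calls, truth,
                                  by = c("read_id", "flow_index"))
      abort(sprintf(
        "%d call(s) have no ground-truth record, e.g. %s",
        nrow(orphans),
        paste(head(sprintf("%s/%d", orphans$read_id, orphans$flow_index), 3),
              collapse = ", ")
      ))
    }
    orphan_truth <- dplyr::anti_join(truth, calls,
                                     by = c("read_id", "flow_index"))
    if (nrow(orphan_truth) > 0) {
      abort(sprintf(
        "%d ground-truth record(s) have no call, e.g. %s",
        nrow(orphan_truth),
        paste(head(sprintf("%s/%d", orphan_truth$read_id,
                           orphan_truth$flow_index), 3), collapse = ", ")
      ))
    }
  }
  if (anyNA(joined$true_length)) {
    abort("ground truth contains missing `true_length` values")
  }

  tally <- function(df) {
    dplyr::summarise(
      df,
      count = dplyr::n(),
      errors = sum(.data$called_length != .data$true_length),
      error_percent = round(100 * .data$errors / .data$count, 3),
      .groups = "drop"
    )
  }
  by_cell <- joined |>
    dplyr::group_by(.data$nucleotide, .data$zone, .data$method) |>
    tally() |>
    dplyr::arrange(.data$nucleotide, .data$zone, .data$method)
  overall <- joined |>
    dplyr::group_by(.data$method) |>
    tally()
  structure(list(by_cell = by_cell, overall = overall),
            class = "hp_evaluation")
}

#' @export
print.hp_evaluation <- function(x, ...) {
  cat("<hp_evaluation>\n")
  print(x$overall)
  invisible(x)
}

#' @rdname tidy.hp_evaluation
#' @param x An `hp_evaluation` object.
#' @param ... Unused.
#' @export
tidy.hp_evaluation <- function(x, ...) x$by_cell

#' Tidy and summarise an evaluation
#'
#' `tidy()` returns per-(nucleotide, zone, method) error rows; `glance()` the
#' overall per-method error table.
#'
#' @return Tibbles as described.
#' @name tidy.hp_evaluation
#' @export
glance.hp_evaluation <- function(x, ...) x$overall

#' Lay an evaluation out as a per-cell comparison table
#'
#' Pivots an evaluation into the standard report layout: one row per
#' (nucleotide, zone) cell with columns `No`, `Nt`, `Pos` (the zone's bp
#' range), `Count`, one error-percent column per method, and `Weight`.
#'
#' @param evaluation An `hp_evaluation` from [evaluate_calls()].
#' @param scheme The [zone_scheme()] used (for the `Pos` labels).
#' @param weights Optional weight column: a single number, or a tibble with
#'   `nucleotide`, `zone`, `weight` for per-cell weights.
#' @return Tibble in the fixed column order above.
#' @export
evaluation_table <- function(evaluation, scheme = zone_scheme("torrent"),
                             weights = NULL) {
  stopifnot(inherits(evaluation, "hp_evaluation"))
  wide <- evaluation$by_cell |>
    dplyr::select("nucleotide", "zone", "method", "count", "error_percent") |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = "error_percent") |>
    dplyr::arrange(.data$nucleotide, .data$zone)
  counts <- evaluation$by_cell |>
    dplyr::distinct(.data$nucleotide, .data$zone, .data$count)
  wide <- wide |>
    dplyr::select(-"count") |>
    dplyr::left_join(counts, by = c("nucleotide", "zone"))
  out <- wide |>
    dplyr::mutate(
      No = dplyr::row_number(),
      Nt = .data$nucleotide,
      Pos = sprintf("%d-%d", (.data$zone - 1L) * scheme$zone_width + 1L,
                    .data$zone * scheme$zone_width),
      Count = .data$count
    )
  if (is.null(weights)) {
    out$Weight <- NA_real_
  } else if (is.data.frame(weights)) {
    out <- dplyr::left_join(
      out, dplyr::rename(as_tibble(weights), Weight = "weight"),
      by = c("nucleotide", "zone")
    )
  } else {
    out$Weight <- as.numeric(weights)
  }
  method_cols <- setdiff(names(wide), c("nucleotide", "zone", "count"))
  dplyr::select(out, "No", "Nt", "Pos", "Count",
                dplyr::all_of(method_cols), "Weight")
}

#' Descriptive weight-sweep error curve
#'
#' Evaluates the integrated caller at every weight on the grid over the full
#' candidate set (the descriptive error-frequency curve), and reports the
#' cross-validation-selected best weight alongside. The curve's endpoints
#' equal the reference-only (W = 0) and Bayesian-only (W = 1) error counts.
#'
#' @inheritParams optimize_weight
#' @return A `weight_sweep` object: `curve` tibble (`weight`, `errors`,
#'   `error_percent`, `cv_error`), `best_weight` (CV-selected), `n`.
#'   Supports [tidy()] and [autoplot()].
#' @export
weight_sweep <- function(candidates, priors, grid = seq(0, 1, by = 0.02),
                         folds = 5L, seed = NULL,
                         config = integrated_config()) {
  fit <- optimize_weight(candidates, priors, grid = grid, folds = folds,
                         seed = seed, config = config)
  curve <- fit$curve |>
    dplyr::mutate(error_percent = round(100 * .data$errors / fit$n, 3)) |>
    dplyr::select("weight", "errors", "error_percent", "cv_error")
  structure(
    list(curve = curve, best_weight = fit$best_weight, n = fit$n),
    class = "weight_sweep"
  )
}

#' @export
print.weight_sweep <- function(x, ...) {
  cat(sprintf("<weight_sweep: %d grid points, CV best W = %.2f>\n",
              nrow(x$curve), x$best_weight))
  invisible(x)
}

#' @rdname tidy.hp_evaluation
#' @export
tidy.weight_sweep <- function(x, ...) x$curve

#' Rewrite reads with called homopolymer lengths
#'
#' Rebuilds each read's sequence from its homopolymer runs, replacing the
#' length of every run that has a call (keyed by `read_id` and `flow_index` =
#' 0-based run index within the read) with the called length. Runs without a
#' call, including all single-base runs, are left unchanged.
#'
#' @param reads Tibble with `read_id` and `sequence` (e.g. from
#'   [simulate_flowgrams()] or [read_fasta()]).
#' @param calls Tibble with `read_id`, `flow_index`, `called_length`.
#' @return Tibble (`read_id`, `sequence`) with corrected sequences.
#' @export
correct_reads <- function(reads, calls) {
  reads <- as_tibble(reads)
  calls <- as_tibble(calls)
  assert_columns(reads, c("read_id", "sequence"), "`reads`")
  assert_columns(calls, c("read_id", "flow_index", "called_length"),
                 "`calls`")
  calls_by_read <- split(calls[, c("flow_index", "called_length")],
                         calls$read_id)
  unknown <- setdiff(names(calls_by_read), reads$read_id)
  if (length(unknown) > 0) {
    abort(sprintf("calls reference unknown read(s): %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  corrected <- purrr::map2_chr(reads$read_id, reads$sequence, function(id, sq) {
    cl <- calls_by_read[[id]]
    if (is.null(cl)) return(sq)
    runs <- rle(strsplit(sq, "", fixed = TRUE)[[1]])
    if (any(cl$flow_index < 0 | cl$flow_index >= length(runs$lengths))) {
      abort(sprintf("call for a nonexistent run in read %s", id))
    }
    runs$lengths[cl$flow_index + 1L] <- cl$called_length
    paste(strrep(runs$values, runs$lengths), collapse = "")
  })
  tibble(read_id = reads$read_id, sequence = corrected)
}
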