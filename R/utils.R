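NUCLEOTIDES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Sets the seed only when one is supplied, restoring the caller's RNG state
#' afterwards, so seeded pipeline stages are reproducible without clobbering
#' the session RNG.
#' @noRd
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), force(code))
}

assert_nucleotide <- function(x, arg = "nucleotide") {
  bad <- !x %in% NUCLEOTIDES
  if (any(bad)) {
    abort(sprintf(
      "`%s` must be one of A, C, G, T; got %s",
      arg, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Validate a candidate / flowgram data frame's required columns
#' @noRd
assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Row-wise argmax over a numeric matrix with explicit tie-breaking.
# `prefer` (optional, same shape) breaks exact ties by its larger value;
# remaining ties go to the lowest column index.
argmax_rows <- function(score, prefer = NULL) {
  stopifnot(is.matrix(score))
  best <- max.col(score, ties.method = "first")
  row_max <- score[cbind(seq_len(nrow(score)), best)]
  n_tied <- rowSums(score == row_max)
  tied <- which(n_tied > 1)
  if (length(tied) > 0 && !is.null(prefer)) {
    for (i in tied) {
      cand <- which(score[i, ] == row_max[i])
      cand <- cand[prefer[i, cand] == max(prefer[i, cand])]
      best[i] <- cand[1]
    }
  }
  best
}
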