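# Independent brute-force implementations used as oracles. These deliberately
# avoid the package's vectorized/log-space code paths: plain per-candidate
# loops over explicitly normalized Gaussian densities.

# Posterior over lengths for one candidate, by direct density evaluation.
oracle_posterior <- function(voltage, nucleotide, zone, priors) {
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  num <- vapply(lengths, function(L) {
    cell <- priors$cells[priors$cells$nucleotide == nucleotide &
                           priors$cells$zone == zone &
                           priors$cells$length == L, ]
    prior <- priors$length_prior$prob[priors$length_prior$length == L]
    dnorm(voltage, cell$mean, cell$stdev) * prior
  }, numeric(1))
  setNames(num / sum(num), lengths)
}

# Argmax with the callers' tie rules: score first, then larger posterior,
# then smaller length (vectors ordered by ascending length).
oracle_argmax <- function(score, posterior) {
  i <- which(score == max(score))
  i <- i[posterior[i] == max(posterior[i])]
  i[1]
}

# Integrated call for one candidate by exhaustive scoring of every length.
oracle_call_integrated <- function(voltage, nucleotide, zone, ref_length,
                                   priors, weight, log_floor = 1e-300,
                                   same_nt = TRUE) {
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  post <- oracle_posterior(voltage, nucleotide, zone, priors)
  pen <- vapply(lengths, function(L) {
    if (L != ref_length) -2 else if (same_nt) 0 else -1
  }, numeric(1))
  s <- weight * log(pmax(post, log_floor)) + (1 - weight) * pen
  lengths[oracle_argmax(s, post)]
}

# Per-grid-point exhaustive weight evaluation: full-set error count and mean
# held-out fold error rate, from an oracle posterior matrix built row by row.
oracle_grid_eval <- function(candidates, priors, grid, fold_id,
                             log_floor = 1e-300) {
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  n <- nrow(candidates)
  post <- t(vapply(seq_len(n), function(i) {
    oracle_posterior(candidates$voltage[i], candidates$nucleotide[i],
                     candidates$zone[i], priors)
  }, numeric(length(lengths))))
  pen <- t(vapply(seq_len(n), function(i) {
    vapply(lengths, function(L) {
      if (L != candidates$ref_length[i]) -2 else 0
    }, numeric(1))
  }, numeric(length(lengths))))
  lp <- log(pmax(post, log_floor))
  res <- lapply(grid, function(w) {
    s <- w * lp + (1 - w) * pen
    called <- lengths[vapply(seq_len(n),
                             function(i) oracle_argmax(s[i, ], post[i, ]),
                             numeric(1))]
    wrong <- called != candidates$true_length
    list(errors = sum(wrong),
         cv_error = mean(tapply(wrong, fold_id, mean)))
  })
  data.frame(
    weight = grid,
    errors = vapply(res, `[[`, numeric(1), "errors"),
    cv_error = vapply(res, `[[`, numeric(1), "cv_error")
  )
}

# Acceptance-scale oracle: direct (non-log-space) density posterior matrix,
# built by plain match() lookups into the cell table.
oracle_posterior_matrix <- function(candidates, priors) {
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  num <- matrix(NA_real_, nrow(candidates), length(lengths))
  for (k in seq_along(lengths)) {
    idx <- match(
      paste(candidates$nucleotide, candidates$zone, lengths[k]),
      paste(priors$cells$nucleotide, priors$cells$zone, priors$cells$length)
    )
    prior_k <- priors$length_prior$prob[priors$length_prior$length == lengths[k]]
    num[, k] <- dnorm(candidates$voltage, priors$cells$mean[idx],
                      priors$cells$stdev[idx]) * prior_k
  }
  num / rowSums(num)
}

# Exhaustive per-grid-point scorer for large n: row-wise which.max (tie rules
# are irrelevant here because scores are generically distinct and W = 0 has a
# unique 0-penalty maximum whenever ref_length is in range).
oracle_grid_eval_fast <- function(candidates, priors, grid, fold_id,
                                  log_floor = 1e-300) {
  lengths <- seq(priors$length_range[1], priors$length_range[2])
  post <- oracle_posterior_matrix(candidates, priors)
  lp <- log(pmax(post, log_floor))
  pen <- matrix(-2, nrow(candidates), length(lengths))
  pen[cbind(seq_len(nrow(candidates)),
            match(candidates$ref_length, lengths))] <- 0
  res <- lapply(grid, function(w) {
    s <- w * lp + (1 - w) * pen
    called <- lengths[apply(s, 1, which.max)]
    wrong <- called != candidates$true_length
    list(called = called, errors = sum(wrong),
         cv_error = mean(tapply(wrong, fold_id, mean)))
  })
  list(
    curve = data.frame(
      weight = grid,
      errors = vapply(res, `[[`, numeric(1), "errors"),
      cv_error = vapply(res, `[[`, numeric(1), "cv_error")
    ),
    calls = lapply(res, `[[`, "called")
  )
}

# Naive per-run read rewrite used as the correct_reads oracle.
oracle_rewrite_read <- function(sequence, flow_index, called_length) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- rle(chars)
  for (j in seq_along(flow_index)) {
    runs$lengths[flow_index[j] + 1L] <- called_length[j]
  }
  paste(rep(runs$values, runs$lengths), collapse = "")
}

# Small two-length toy prior set used by several caller tests.
toy_priors <- function(mean2 = 2, mean3 = 3, sd2 = 0.2, sd3 = 0.2,
                       p2 = 0.5) {
  cells <- tidyr::expand_grid(
    nucleotide = c("A", "C", "G", "T"), zone = 1:4, length = 2:3
  )
  cells$mean <- ifelse(cells$length == 2, mean2, mean3)
  cells$stdev <- ifelse(cells$length == 2, sd2, sd3)
  cells$n_obs <- 10L
  cells$imputed <- FALSE
  signal_priors(
    cells,
    tibble::tibble(length = 2:3, prob = c(p2, 1 - p2)),
    zone_scheme("torrent"),
    c(2L, 3L)
  )
}

# Default-table priors with a uniform length prior (for likelihood-only
# posterior checks).
uniform_prior_default <- function() {
  pri <- default_priors()
  signal_priors(
    pri$cells,
    tibble::tibble(length = 2:6, prob = rep(0.2, 5)),
    pri$zone_scheme, pri$length_range
  )
}
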