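test_that("nearest-mean calls the closest prior mean, ties to smaller length", {
  pri <- default_priors()
  cand <- tibble::tibble(
    nucleotide = "A", read_position = 10L,
    voltage = c(3.68, (1.85 + 2.78) / 2, 5.2)
  )
  calls <- call_homopolymers(cand, pri, method = "nearest_mean")
  means <- dplyr::filter(pri$cells, nucleotide == "A", zone == 1) |>
    dplyr::arrange(length)
  # brute-force distance scan for the non-trivial voltage
  expect_equal(calls$called_length[3],
               means$length[which.min(abs(5.2 - means$mean))])
  expect_equal(calls$called_length[1], 4L) # exact hit on the L=4 mean
  expect_equal(calls$called_length[2], 2L) # equidistant -> smaller length
})

test_that("nearest-mean matches a brute-force scan on random voltages", {
  pri <- default_priors()
  cand <- withr::with_seed(21, tibble::tibble(
    nucleotide = sample(c("A", "C", "G", "T"), 500, TRUE),
    read_position = sample(1:300, 500, TRUE),
    voltage = runif(500, 0, 8)
  ))
  calls <- call_homopolymers(cand, pri, method = "nearest_mean")
  expected <- vapply(seq_len(nrow(cand)), function(i) {
    zn <- assign_zone(cand$read_position[i], pri$zone_scheme)
    cells <- dplyr::filter(pri$cells, nucleotide == cand$nucleotide[i],
                           zone == zn) |>
      dplyr::arrange(length)
    cells$length[which.min(abs(cand$voltage[i] - cells$mean))]
  }, integer(1))
  expect_equal(calls$called_length, expected)
})

test_that("posterior reduces to symmetry and to the prior in degenerate cases", {
  # equal priors, equal stdevs, voltage at the midpoint -> 50/50
  pri <- toy_priors(mean2 = 2, mean3 = 3, sd2 = 0.2, sd3 = 0.2, p2 = 0.5)
  post <- posterior_lengths(
    tibble::tibble(nucleotide = "A", zone = 1L, voltage = 2.5), pri
  )
  expect_equal(post$posterior, c(0.5, 0.5), tolerance = 1e-12)

  # identical Gaussians for both lengths -> posterior equals the prior
  pri <- toy_priors(mean2 = 2.5, mean3 = 2.5, sd2 = 0.2, sd3 = 0.2, p2 = 0.8)
  post <- posterior_lengths(
    tibble::tibble(nucleotide = "C", zone = 2L, voltage = 1.7), pri
  )
  expect_equal(post$posterior, c(0.8, 0.2), tolerance = 1e-12)
})

test_that("posterior at an anchor voltage concentrates on its length", {
  pri <- uniform_prior_default()
  post <- posterior_lengths(
    tibble::tibble(nucleotide = "A", read_position = 10L, voltage = 1.85), pri
  )
  expect_gt(post$posterior[post$length == 2], 0.999)
  # oracle: explicit density evaluation at all five lengths
  expect_equal(post$posterior,
               unname(oracle_posterior(1.85, "A", 1L, pri)),
               tolerance = 1e-12)
})

test_that("posteriors are normalized to 1e-9 across extreme voltages", {
  pri <- default_priors()
  grid <- tidyr::expand_grid(
    nucleotide = c("A", "C", "G", "T"),
    read_position = c(1L, 80L, 160L, 260L),
    voltage = seq(0, 10, by = 0.25)
  )
  post <- posterior_lengths(grid, pri)
  sums <- tapply(post$posterior, post$.row, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_false(any(is.na(post$posterior)))
})

test_that("reference penalty returns exactly 0 / -1 / -2", {
  expect_identical(reference_penalty(4, 4, TRUE), 0)
  expect_identical(reference_penalty(5, 4, TRUE), -2)
  expect_identical(reference_penalty(3, 4, TRUE), -2)
  expect_identical(reference_penalty(4, 4, FALSE), -1)
  expect_equal(reference_penalty(c(4, 5, 4), c(4, 4, 4), c(TRUE, TRUE, FALSE)),
               c(0, -2, -1))
  expect_error(reference_penalty(-1, 4), ">= 0")
  expect_error(penalty_scheme(match = -3), "match >= substitution")
})

test_that("integrated score follows W * ln(posterior) + (1 - W) * penalty", {
  post <- c(`2` = 0.9, `3` = 0.1)
  s1 <- integrated_score(post, ref_length = 2,
                         config = integrated_config(weight = 1))
  expect_equal(s1$score, log(c(0.9, 0.1)))
  s0 <- integrated_score(post, ref_length = 2,
                         config = integrated_config(weight = 0))
  expect_equal(s0$score, c(0, -2))
  s28 <- integrated_score(post, ref_length = 2,
                          config = integrated_config(weight = 0.28))
  expect_equal(s28$score[1], 0.28 * log(0.9))
  expect_equal(s28$score[1], -0.0295, tolerance = 1e-3)
  # log floor keeps the score finite at zero posterior
  s <- integrated_score(c(`2` = 1, `3` = 0), ref_length = 3)
  expect_true(all(is.finite(s$score)))
})

test_that("integrated caller reduces to Bayes at W = 1 and reference at W = 0", {
  pri <- default_priors()
  cand <- simulate_candidates(10000, pri, variant_rate = 0.05, seed = 101)
  bayes <- call_homopolymers(cand, pri, method = "bayes")
  w1 <- call_homopolymers(cand, pri, method = "integrated",
                          config = integrated_config(weight = 1))
  expect_equal(w1$called_length, bayes$called_length)
  w0 <- call_homopolymers(cand, pri, method = "integrated",
                          config = integrated_config(weight = 0))
  expect_equal(w0$called_length, as.integer(cand$ref_length))
  ref_only <- call_homopolymers(cand, pri, method = "reference_only")
  expect_equal(ref_only$called_length, w0$called_length)
})

test_that("integrated calls match the exhaustive per-length oracle", {
  pri <- default_priors()
  cand <- simulate_candidates(2000, pri, nucleotides = "A", zones = 1L,
                              variant_rate = 0.01, seed = 55)
  cfg <- integrated_config(weight = 0.28)
  calls <- call_homopolymers(cand, pri, method = "integrated", config = cfg)
  expected <- vapply(seq_len(nrow(cand)), function(i) {
    oracle_call_integrated(cand$voltage[i], cand$nucleotide[i], cand$zone[i],
                           cand$ref_length[i], pri, weight = 0.28)
  }, numeric(1))
  expect_equal(calls$called_length, as.integer(expected))
})

test_that("missing ref_length falls back to the Bayesian call with a warning", {
  pri <- default_priors()
  cand <- simulate_candidates(50, pri, seed = 9)
  cand$ref_length[c(3, 7)] <- NA
  expect_warning(
    calls <- call_homopolymers(cand, pri, method = "integrated"),
    "ref_length"
  )
  bayes <- call_homopolymers(cand, pri, method = "bayes")
  expect_equal(calls$called_length[c(3, 7)], bayes$called_length[c(3, 7)])
})

test_that("substituted reference nucleotide downgrades the match penalty", {
  pri <- toy_priors(p2 = 0.5)
  cand <- tibble::tibble(
    nucleotide = "A", zone = 1L, voltage = 2.0,
    ref_length = 2L, ref_nucleotide = c("A", "C")
  )
  calls <- call_homopolymers(cand, pri, method = "reference_only")
  # same-nucleotide match scores 0; substitution -1: both still beat the
  # indel alternative, so the reference length is called either way
  expect_equal(calls$called_length, c(2L, 2L))
  expect_equal(calls$score_max, c(0, -1))
})

test_that("raising W moves calls from the reference toward the posterior mode", {
  # construct a maximal disagreement: voltage squarely at L = 3, reference
  # says 2; sweep W upward and require agreement with the reference to be
  # monotone non-increasing
  pri <- toy_priors(p2 = 0.5)
  cand <- tibble::tibble(nucleotide = "A", zone = 1L, voltage = 3.0,
                         ref_length = 2L)
  agree <- vapply(seq(0, 1, by = 0.05), function(w) {
    call_homopolymers(cand, pri, method = "integrated",
                      config = integrated_config(weight = w))$called_length ==
      cand$ref_length
  }, logical(1))
  expect_true(all(diff(as.integer(agree)) <= 0))
  expect_true(agree[1])          # W = 0: reference wins
  expect_false(agree[length(agree)]) # W = 1: posterior wins
})
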