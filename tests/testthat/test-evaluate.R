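make_calls <- function(n, n_errors, nucleotide = "A", zone = 1L,
                       method = "integrated") {
  tibble::tibble(
    read_id = sprintf("r%06d", seq_len(n)), flow_index = 0L,
    nucleotide = nucleotide, zone = zone, method = method,
    called_length = c(rep(5L, n_errors), rep(4L, n - n_errors)),
    true_length = 4L
  )
}

test_that("all-correct calls score 0.000 percent everywhere", {
  ev <- evaluate_calls(make_calls(500, 0))
  expect_equal(ev$overall$error_percent, 0)
  expect_equal(ev$by_cell$error_percent, 0)
  expect_equal(ev$overall$count, 500L)
})

test_that("error percentages are reported to three decimals", {
  # 360 wrong calls among 144,230 candidates -> 0.250 %
  ev <- evaluate_calls(make_calls(144230, 360))
  expect_equal(ev$overall$error_percent, 0.250)
  expect_equal(ev$overall$errors, 360L)
})

test_that("per-cell percentages equal an independent recount", {
  pri <- default_priors()
  cand <- simulate_candidates(2000, pri, variant_rate = 0.05, seed = 61)
  calls <- dplyr::bind_rows(
    call_homopolymers(cand, pri, "bayes"),
    call_homopolymers(cand, pri, "nearest_mean")
  )
  ev <- evaluate_calls(calls)
  # brute-force tally oracle
  recount <- aggregate(
    cbind(n = rep(1, nrow(calls)),
          err = calls$called_length != calls$true_length),
    by = list(nucleotide = calls$nucleotide, zone = calls$zone,
              method = calls$method),
    FUN = sum
  )
  recount <- recount[order(recount$nucleotide, recount$zone, recount$method), ]
  expect_equal(ev$by_cell$count, recount$n)
  expect_equal(ev$by_cell$errors, recount$err)
  expect_equal(ev$by_cell$error_percent,
               round(100 * recount$err / recount$n, 3))
})

test_that("evaluation is invariant under row shuffling", {
  pri <- default_priors()
  cand <- simulate_candidates(1000, pri, seed = 62)
  calls <- call_homopolymers(cand, pri, "bayes")
  truth <- dplyr::select(calls, read_id, flow_index, true_length)
  ev1 <- evaluate_calls(dplyr::select(calls, -true_length), truth)
  shuffle <- withr::with_seed(63, sample(nrow(calls)))
  ev2 <- evaluate_calls(dplyr::select(calls, -true_length)[shuffle, ],
                        truth[withr::with_seed(64, sample(nrow(truth))), ])
  expect_equal(ev1$by_cell, ev2$by_cell)
  expect_equal(ev1$overall, ev2$overall)
})

test_that("unmatched calls or truth records raise a join error with IDs", {
  calls <- make_calls(5, 0)
  truth <- dplyr::select(calls, read_id, flow_index, true_length)
  expect_error(
    evaluate_calls(dplyr::select(calls, -true_length), truth[-1, ]),
    "r000001"
  )
  expect_error(
    evaluate_calls(dplyr::select(calls[-2, ], -true_length), truth),
    "r000002"
  )
})

test_that("evaluation table follows the fixed report layout", {
  pri <- default_priors()
  cand <- simulate_candidates(4000, pri, seed = 65)
  calls <- dplyr::bind_rows(
    call_homopolymers(cand, pri, "integrated"),
    call_homopolymers(cand, pri, "bayes")
  )
  tab <- evaluation_table(evaluate_calls(calls), weights = 0.28)
  expect_equal(names(tab),
               c("No", "Nt", "Pos", "Count", "bayes", "integrated", "Weight"))
  expect_equal(nrow(tab), 16L) # 4 nucleotides x 4 zones
  expect_equal(tab$Pos[tab$Nt == "A"],
               c("1-75", "76-150", "151-225", "226-300"))
  expect_equal(tab$Weight, rep(0.28, 16))
  per_cell <- tibble::tibble(nucleotide = "A", zone = 1L, weight = 0.14)
  tab2 <- evaluation_table(evaluate_calls(calls), weights = per_cell)
  expect_equal(tab2$Weight[tab2$Nt == "A" & tab2$Pos == "1-75"], 0.14)
})

test_that("weight sweep endpoints equal the reference-only and Bayesian errors", {
  pri <- default_priors()
  cand <- simulate_candidates(3000, pri, variant_rate = 0.01, seed = 66)
  sw <- weight_sweep(cand, pri, grid = c(0, 0.5, 1), seed = 3)
  ref_err <- sum(call_homopolymers(cand, pri, "reference_only")$called_length !=
                   cand$true_length)
  bay_err <- sum(call_homopolymers(cand, pri, "bayes")$called_length !=
                   cand$true_length)
  expect_equal(sw$curve$errors[sw$curve$weight == 0], ref_err)
  expect_equal(sw$curve$errors[sw$curve$weight == 1], bay_err)
})

test_that("no-variant data minimizes the sweep at W = 0", {
  pri <- default_priors()
  cand <- simulate_candidates(2000, pri, variant_rate = 0, seed = 67)
  sw <- weight_sweep(cand, pri, grid = seq(0, 1, 0.2), seed = 4)
  expect_equal(sw$best_weight, 0)
  expect_equal(min(sw$curve$errors), sw$curve$errors[1])
})

test_that("sweep curve equals a brute-force per-point recount", {
  pri <- default_priors()
  cand <- simulate_candidates(1500, pri, variant_rate = 0.02, seed = 68)
  grid <- c(0, 0.28, 1)
  sw <- weight_sweep(cand, pri, grid = grid, folds = 5, seed = 5)
  fold_id <- withr::with_seed(5L, sample(rep(1:5, length.out = nrow(cand))))
  oracle <- oracle_grid_eval(cand, pri, grid, fold_id)
  expect_equal(sw$curve$errors, oracle$errors)
})

test_that("correct reads rewrites exactly the called runs", {
  pri <- default_priors()
  ref <- simulate_reference(20000, seed = 71)
  smp <- inject_variants(ref, 0.02, seed = 72)
  sim <- simulate_flowgrams(smp, pri, n_reads = 30, read_length = 300,
                            seed = 73)
  # perfect calls leave every read unchanged
  perfect <- dplyr::mutate(sim$truth, called_length = true_length)
  fixed <- correct_reads(sim$reads, perfect)
  expect_equal(fixed$sequence, sim$reads$sequence)

  # a single overcall corrected 5 -> 4 shortens the read by exactly one
  five <- dplyr::filter(sim$truth, true_length == 5)[1, ]
  one_call <- dplyr::mutate(five, called_length = 4L)
  fixed1 <- correct_reads(sim$reads, one_call)
  i <- match(five$read_id, sim$reads$read_id)
  expect_equal(nchar(fixed1$sequence[i]), nchar(sim$reads$sequence[i]) - 1L)
  expect_equal(fixed1$sequence[-i], sim$reads$sequence[-i])

  # random calls match the naive string-rewriting oracle
  calls <- withr::with_seed(74, dplyr::mutate(
    sim$truth, called_length = pmax(true_length +
                                      sample(-1:1, dplyr::n(), TRUE), 1L)
  ))
  fixed2 <- correct_reads(sim$reads, calls)
  for (j in c(1L, 5L, nrow(sim$reads))) {
    cl <- dplyr::filter(calls, read_id == sim$reads$read_id[j])
    expect_identical(
      fixed2$sequence[j],
      oracle_rewrite_read(sim$reads$sequence[j], cl$flow_index,
                          cl$called_length)
    )
  }
})

test_that("calls for nonexistent runs raise a consistency error", {
  reads <- tibble::tibble(read_id = "r1", sequence = "AACCCGT")
  calls <- tibble::tibble(read_id = "r1", flow_index = 10L, called_length = 2L)
  expect_error(correct_reads(reads, calls), "nonexistent run")
  calls2 <- tibble::tibble(read_id = "zz", flow_index = 0L, called_length = 2L)
  expect_error(correct_reads(reads, calls2), "unknown read")
})
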