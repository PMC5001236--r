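#' Simulate a reference sequence with a controlled homopolymer spectrum
#'
#' Builds a random DNA sequence as a chain of homopolymer runs: run lengths
#' are drawn i.i.d. from `spectrum` and each run's nucleotide is drawn from
#' `base_probs` excluding the previous run's nucleotide, so adjacent runs are
#' always distinct. The default base composition enriches A/T runs, the
#' pattern seen in semiconductor sequencing homopolymer profiles.
#'
#' @param length Target sequence length in bp (the last run is truncated to
#'   fit).
#' @param spectrum Named probability vector over run lengths 1..L_max; see
#'   [default_spectrum()].
#' @param base_probs Named probability vector over A, C, G, T.
#' @param seed Optional integer seed; a fixed seed reproduces the sequence
#'   byte-for-byte.
#' @return An `hp_reference`: list with `sequence` (character scalar) and
#'   `loci`, a tibble of every run (`locus` = 1-based start, `nucleotide`,
#'   `length`).
#' @examples
#' ref <- simulate_reference(1000, seed = 1)
#' substr(ref$sequence, 1, 40)
#' @export
simulate_reference <- function(length = 1e5, spectrum = default_spectrum(),
                               base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                               seed = NULL) {
  run_lengths <- as.integer(names(spectrum))
  if (anyNA(run_lengths) || any(run_lengths < 1)) {
    abort("`spectrum` must be named by positive integer run lengths")
  }
  if (any(spectrum < 0) || sum(spectrum) <= 0) {
    abort("`spectrum` must be non-negative with positive total mass")
  }
  spectrum <- spectrum / sum(spectrum)
  base_probs <- base_probs[NUCLEOTIDES] / sum(base_probs[NUCLEOTIDES])

  with_seed_if(seed, {
    mean_len <- sum(run_lengths * spectrum)
    n_guess <- ceiling(length / mean_len * 1.2) + 50L
    lens <- integer(0)
    while (sum(lens) < length) {
      lens <- c(lens, sample(run_lengths, n_guess, TRUE, prob = spectrum))
    }
    n_runs <- which(cumsum(lens) >= length)[1]
    lens <- lens[seq_len(n_runs)]
    # chain nucleotides, excluding the previous run's base at each step
    nts <- character(n_runs)
    nts[1] <- sample(NUCLEOTIDES, 1, prob = base_probs)
    u <- stats::runif(n_runs)
    for (i in seq_len(n_runs)[-1]) {
      p <- base_probs
      p[nts[i - 1]] <- 0
      nts[i] <- NUCLEOTIDES[findInterval(u[i], cumsum(p / sum(p))) + 1L]
    }
    overshoot <- sum(lens) - length
    lens[n_runs] <- lens[n_runs] - overshoot
    if (lens[n_runs] == 0L) {
      lens <- lens[-n_runs]
      nts <- nts[-n_runs]
      n_runs <- n_runs - 1L
    }
    loci <- tibble(
      locus = c(1L, cumsum(lens)[-n_runs] + 1L),
      nucleotide = nts,
      length = lens
    )
    structure(
      list(
        sequence = paste(strrep(nts, lens), collapse = ""),
        loci = loci
      ),
      class = "hp_reference"
    )
  })
}

#' Inject homopolymer variants into a reference
#'
#' Marks each homopolymer locus (run of length >= 2) as a variant with
#' probability `variant_rate`; a variant is a +/-1 length shift ("indel")
#' with probability `indel_fraction`, otherwise a run-nucleotide swap
#' ("substitution", keeping adjacent runs distinct). This plays the role of
#' true inter-individual variation: roughly 1 percent of loci differ from the
#' reference.
#'
#' @param reference An `hp_reference` from [simulate_reference()].
#' @param variant_rate Per-locus variant probability in `[0, 1]`.
#' @param indel_fraction Fraction of variants that are length shifts.
#' @param seed Optional integer seed.
#' @return An `hp_sample`: list with `sequence`, `loci` (tibble: `locus` =
#'   start in the sample sequence, `ref_locus` = start in the reference,
#'   `nucleotide`, `length`, `ref_nucleotide`, `ref_length`, `variant` in
#'   {"none", "indel", "substitution"}), and `variants` (the variant rows).
#' @export
inject_variants <- function(reference, variant_rate = 0.01,
                            indel_fraction = 1, seed = NULL) {
  stopifnot(inherits(reference, "hp_reference"))
  if (variant_rate < 0 || variant_rate > 1 ||
      indel_fraction < 0 || indel_fraction > 1) {
    abort("`variant_rate` and `indel_fraction` must lie in [0, 1]")
  }
  loci <- reference$loci
  n <- nrow(loci)
  with_seed_if(seed, {
    eligible <- loci$length >= 2L
    is_var <- eligible & stats::runif(n) < variant_rate
    is_indel <- is_var & stats::runif(n) < indel_fraction
    is_sub <- is_var & !is_indel

    new_len <- loci$length
    shift <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
    new_len[is_indel] <- loci$length[is_indel] + shift[is_indel]

    new_nt <- loci$nucleotide
    if (any(is_sub)) {
      # exclude the run's own base, the (possibly already substituted)
      # previous run, and the next run's original base so adjacent runs
      # stay distinct
      for (i in which(is_sub)) {
        prev <- if (i > 1) new_nt[i - 1] else ""
        nxt <- if (i < n) loci$nucleotide[i + 1] else ""
        choices <- setdiff(NUCLEOTIDES, c(loci$nucleotide[i], prev, nxt))
        new_nt[i] <- sample(choices, 1)
      }
    }

    sample_loci <- tibble(
      locus = c(1L, cumsum(new_len)[-n] + 1L),
      ref_locus = loci$locus,
      nucleotide = new_nt,
      length = new_len,
      ref_nucleotide = loci$nucleotide,
      ref_length = loci$length,
      variant = dplyr::case_when(
        is_indel ~ "indel",
        is_sub ~ "substitution",
        .default = "none"
      )
    )
    structure(
      list(
        sequence = paste(strrep(new_nt, new_len), collapse = ""),
        loci = sample_loci,
        variants = dplyr::filter(sample_loci, .data$variant != "none")
      ),
      class = "hp_sample"
    )
  })
}

# Draw truncated-at-zero Gaussian voltages (resampling negative draws).
rtrunc_voltage <- function(n, mean, stdev) {
  v <- rnorm(n, mean, stdev)
  neg <- which(v < 0)
  while (length(neg) > 0) {
    v[neg] <- rnorm(length(neg), mean[neg], stdev[neg])
    neg <- neg[v[neg] < 0]
  }
  v
}

#' Draw flow voltages for one model cell
#'
#' Samples voltages from the Gaussian of a single (nucleotide, zone, length)
#' cell of a prior set, truncated at zero (negative draws are resampled).
#'
#' @param n Number of draws.
#' @param priors A [signal_priors()] object.
#' @param nucleotide,zone,length The cell to sample from.
#' @param seed Optional integer seed.
#' @return Numeric vector of voltages.
#' @examples
#' simulate_voltages(5, default_priors(), "A", 1, 4, seed = 1)
#' @export
simulate_voltages <- function(n, priors, nucleotide, zone, length,
                              seed = NULL) {
  stopifnot(inherits(priors, "signal_priors"))
  par <- lookup_gaussian(priors, nucleotide, zone, length)
  with_seed_if(seed, {
    rtrunc_voltage(n, rep(par$mean, n), rep(par$stdev, n))
  })
}

#' Simulate reads and their flowgram from a sample genome
#'
#' Samples reads from the sample sequence and emits one flow per homopolymer
#' run: a voltage drawn from the run's (nucleotide, zone, true length)
#' Gaussian cell, truncated at zero. Reads are snapped to run boundaries
#' (each read starts at a run start and ends at the last complete run inside
#' its window) so every flow corresponds 1:1 to a reference locus. Flow order
#' chemistry (phasing, carry-forward, droop) is not modelled: the signal
#' abstraction is one flow per run.
#'
#' @param sample An `hp_sample` from [inject_variants()] (or an
#'   `hp_reference`, treated as a variant-free sample).
#' @param priors [signal_priors()] providing the emission Gaussians; lengths
#'   outside its range (e.g. single-base runs) are extrapolated.
#' @param n_reads Number of reads.
#' @param read_length Read window length in bp.
#' @param seed Optional integer seed; fixed seeds give byte-identical output.
#' @return List of tibbles: `flowgram` (`read_id`, `flow_index`,
#'   `nucleotide`, `read_position`, `voltage`), `truth` (`read_id`,
#'   `flow_index`, `locus`, `nucleotide`, `true_length`, `ref_nucleotide`,
#'   `ref_length`, `zone`, `variant`), and `reads` (`read_id`, `start`,
#'   `sequence`).
#' @export
simulate_flowgrams <- function(sample, priors = default_priors(),
                               n_reads = 200L, read_length = 300L,
                               seed = NULL) {
  stopifnot(inherits(priors, "signal_priors"))
  if (inherits(sample, "hp_reference")) {
    loci <- dplyr::mutate(
      sample$loci,
      ref_locus = .data$locus, ref_nucleotide = .data$nucleotide,
      ref_length = .data$length, variant = "none"
    )
    sample <- structure(list(sequence = sample$sequence, loci = loci),
                        class = "hp_sample")
  }
  stopifnot(inherits(sample, "hp_sample"))
  loci <- sample$loci
  seq_len_total <- nchar(sample$sequence)
  if (read_length > seq_len_total) {
    abort("`read_length` exceeds the sample sequence length")
  }
  run_start <- loci$locus
  run_end <- loci$locus + loci$length - 1L

  with_seed_if(seed, {
    pos <- sample.int(seq_len_total - read_length + 1L, n_reads,
                      replace = TRUE)
    # snap read start forward to the next run boundary; end at the last
    # complete run inside the window
    first_run <- findInterval(pos - 1L, run_start) + 1L
    last_run <- findInterval(pos + read_length - 1L, run_end)
    keep <- first_run <= last_run & first_run <= nrow(loci)
    first_run <- first_run[keep]
    last_run <- last_run[keep]

    n_runs <- last_run - first_run + 1L
    read_id <- sprintf("read_%05d", seq_along(first_run))
    run_idx <- sequence(n_runs, from = first_run)
    rid <- rep(read_id, n_runs)
    read_start <- rep(run_start[first_run], n_runs)

    truth <- tibble(
      read_id = rid,
      flow_index = sequence(n_runs) - 1L,
      locus = loci$ref_locus[run_idx],
      nucleotide = loci$nucleotide[run_idx],
      true_length = loci$length[run_idx],
      ref_nucleotide = loci$ref_nucleotide[run_idx],
      ref_length = loci$ref_length[run_idx],
      variant = loci$variant[run_idx],
      read_position = run_start[run_idx] - read_start + 1L
    ) |>
      dplyr::mutate(zone = assign_zone(.data$read_position,
                                       priors$zone_scheme))

    par <- lookup_gaussian(priors, truth$nucleotide, truth$zone,
                           truth$true_length)
    voltage <- rtrunc_voltage(nrow(truth), par$mean, par$stdev)

    flowgram <- tibble(
      read_id = truth$read_id,
      flow_index = truth$flow_index,
      nucleotide = truth$nucleotide,
      read_position = truth$read_position,
      voltage = voltage
    )
    reads <- tibble(
      read_id = read_id,
      start = run_start[first_run],
      sequence = substring(sample$sequence, run_start[first_run],
                           run_end[last_run])
    )
    list(
      flowgram = flowgram,
      truth = dplyr::select(truth, "read_id", "flow_index", "locus",
                            "nucleotide", "true_length", "ref_nucleotide",
                            "ref_length", "zone", "variant"),
      reads = reads
    )
  })
}

#' Simulate labelled homopolymer candidates directly
#'
#' Generates candidate-level benchmark data without building a genome:
#' reference lengths are drawn from the prior set's length distribution,
#' variants (+/-1 length shifts at rate `variant_rate`) give the true
#' lengths, and voltages are drawn from the matching Gaussian cells. When
#' `threshold` is set (the default emulates candidate detection), draws are
#' repeated until `n` candidates pass the detection cut.
#'
#' @param n Number of candidates to return.
#' @param priors [signal_priors()] supplying Gaussian cells and the length
#'   prior.
#' @param nucleotides Nucleotides to sample from (uniformly).
#' @param zones Zones to sample from (uniformly); default all zones.
#' @param variant_rate Probability that a locus's true length differs from
#'   the reference by +/-1.
#' @param threshold Detection threshold (strict) applied to voltages;
#'   `NULL` disables it.
#' @param seed Optional integer seed.
#' @return Tibble of candidates: `read_id`, `flow_index`, `nucleotide`,
#'   `read_position`, `zone`, `voltage`, `ref_length`, `true_length`.
#' @export
simulate_candidates <- function(n, priors = default_priors(),
                                nucleotides = NUCLEOTIDES, zones = NULL,
                                variant_rate = 0.01, threshold = 1.5,
                                seed = NULL) {
  stopifnot(inherits(priors, "signal_priors"))
  if (is.null(zones)) zones <- seq_len(priors$zone_scheme$n_zones)
  lengths <- priors$length_prior$length
  probs <- priors$length_prior$prob
  width <- priors$zone_scheme$zone_width

  draw <- function(m) {
    nt <- sample(nucleotides, m, TRUE)
    zn <- sample(zones, m, TRUE)
    ref <- sample(lengths, m, TRUE, prob = probs)
    is_var <- stats::runif(m) < variant_rate
    shift <- ifelse(stats::runif(m) < 0.5, -1L, 1L)
    true <- ifelse(is_var, ref + shift, ref)
    par <- lookup_gaussian(priors, nt, zn, true)
    tibble(
      nucleotide = nt, zone = as.integer(zn),
      read_position = (as.integer(zn) - 1L) * width +
        sample.int(width, m, TRUE),
      voltage = rtrunc_voltage(m, par$mean, par$stdev),
      ref_length = as.integer(ref), true_length = as.integer(true)
    )
  }

  with_seed_if(seed, {
    out <- draw(ceiling(n * 1.15) + 50L)
    if (!is.null(threshold)) {
      out <- dplyr::filter(out, .data$voltage > threshold)
      while (nrow(out) < n) {
        extra <- dplyr::filter(draw(ceiling(n / 2) + 50L),
                               .data$voltage > threshold)
        out <- dplyr::bind_rows(out, extra)
      }
    }
    out <- out[seq_len(n), ]
    dplyr::bind_cols(
      tibble(read_id = sprintf("cand_%06d", seq_len(n)), flow_index = 0L),
      out
    )
  })
}
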