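---
title: "Calling homopolymer lengths from flow signals: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling homopolymer lengths from flow signals: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowcallr)
library(dplyr)
```

## The problem

Semiconductor sequencers (Ion Torrent / Ion Proton) read DNA by flowing one
nucleotide at a time over a well and measuring the voltage released when it
incorporates. A homopolymer — a run of L identical bases — incorporates in a
single flow and ideally produces L times the single-base voltage. In
practice the measured voltage is noisy, and the noise grows with L, so
homopolymer lengths are the dominant error mode of the platform:
over- and undercalls turn into spurious indels at alignment time and mask
real variants.

`flowcallr` implements a per-read statistical treatment of this problem:

1. **Signal model.** For each combination of nucleotide `N` (A/C/G/T),
   read-position zone `Z`, and homopolymer length `L`, the flow voltage `V`
   is modelled as Gaussian: `V | N, Z, L ~ Normal(mean(N,Z,L), sd(N,Z,L))`.
   Zones are fixed-width bins of the position within the read (default four
   75 bp zones; a five-zone 50 bp profile is provided for Proton-style
   reads) because the signal drifts along the read.
2. **Bayesian caller.** For a candidate flow the posterior over lengths is
   `P(L | N, Z, V) ∝ P(V | N, Z, L) · P(L)`, normalized over the modelled
   candidate lengths at fixed `(N, Z)`. `P(L)` is the empirical length
   frequency from training data. The normalizing constant plays the role of
   the marginal voltage probability.
3. **Integrated caller.** Because two genomes differ at only ~1% of
   positions, the reference genome is a strong prior. Each length `L` is
   scored as

   `S(L) = W · ln P(L | N, Z, V) + (1 − W) · Pen(L | ref)`

   where `Pen` is 0 when `L` equals the reference run length (same
   nucleotide), −1 for a same-length nucleotide substitution, and −2 for a
   length mismatch (indel). The called length maximizes `S`. `W ∈ [0, 1]`
   balances signal against reference: `W = 1` is the Bayesian caller,
   `W = 0` copies the reference.
4. **Weight selection.** `W` is chosen by k-fold cross-validation (default
   5) over a grid, minimizing the held-out misclassification rate against
   known lengths.
5. **Baseline.** The nearest-mean caller (a 1-nearest-neighbour rule on the
   cell means) picks `argmin_L |V − mean(N,Z,L)|`; it ignores both the
   length prior and the reference and serves as the comparison floor.

## Candidate detection

A flow is a homopolymer candidate when its voltage strictly exceeds 1.5
incorporation units, so single-base (≈1.0) and empty flows are excluded and
the candidate set starts at L = 2. The strict inequality is deliberate: a
voltage of exactly 1.5 is not a candidate. Candidate lengths are modelled on
[2, 6] by default; the upper bound is configurable, with cells beyond the
fitted data filled by imputation.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| detection threshold | voltage (incorporation units) | 1.5 (strict) | separates L ≥ 2 signals from single-base flows |
| zone profile | bp | 4 × 75 ("torrent"); 5 × 50 ("proton") | signal drift along the read; positions past the last boundary clamp to the last zone |
| length range | bases | [2, 6] | candidate lengths with usable signal separation; sd grows ~linearly with L |
| weight `W` | — | 0.28 (published optimum for A/Z1); optimize per dataset | balances signal vs. reference |
| weight grid | — | 0 to 1, step 0.02 | reported optima are even hundredths |
| penalties | score | 0 / −1 / −2 | match / substitution / indel against the reference |
| `log_floor` | probability | 1e−300 | keeps `W · ln posterior` finite so the penalty term still discriminates when the posterior underflows |
| CV folds | — | 5 | enough resolution at the candidate counts involved without destabilizing fold error |

## The built-in parameter table

`default_priors()` reconstructs a usable signal model from published summary
values: the five A/Z1 Gaussians (means 1.85–5.57, sd 0.14–0.38), the C/Z1
L=4 cell (3.74 / 0.30), G and T at Z1 L=4 (3.68 / 0.24), and the zone drift
of A at L=4 (3.68 / 3.57 / 3.54 / 3.57). Only those anchors were printed;
everything else is filled by the imputation rule below and flagged
`imputed`. The published source gives no standard deviation for the A L=4
cells in zones 2–4, so the non-C L=4 value (0.24) is used there. Anchor
cells carry `n_obs = NA` because the underlying counts were not published.
The table is a reconstruction for simulation and demonstration — on real
data you should fit your own priors with `fit_priors()`.

Its length prior is geometric with ratio 0.5 over lengths 2–6, chosen to
match the simulator's default run-length spectrum conditioned on candidate
lengths; no numeric genome-wide spectrum was available to copy, so this is a
package choice, kept consistent between generator and caller.

## Sparse-cell imputation

Training data never populate all 80 cells. A cell with fewer than two
observations (or zero variance) is imputed as:

* **mean** = `L × slope`, where the per-base slope is a least-squares fit
  through the origin across the populated cells of the same (nucleotide,
  zone) — the physically motivated "L times the single-base signal" line;
* **stdev** = the nearest populated length's stdev in that stratum.

A stratum with no populated cells at all borrows the nearest zone of the
same nucleotide, then the pooled same-zone cells, and as a last resort a
unit slope with sd 0.25. Imputed cells are flagged in memory and in the
serialized JSON, so downstream users can see which parts of the model are
measurement and which are extrapolation.

## Numerical choices

* **Log-space posteriors.** Likelihood × prior is computed as log density +
  log prior and normalized by subtracting the row maximum before
  exponentiating, so posteriors sum to 1 (within 1e−9) even for voltages
  far outside the fitted range; `NaN` is never returned.
* **Natural log** in the integrated score.
* **Tie-breaking.** Argmax ties break toward the larger posterior, then the
  smaller length; nearest-mean ties break toward the smaller length.
  Undercalling is the conservative direction given that length confusion
  grows with L.
* **Degenerate inputs.** Zero-variance fitted cells are imputed rather than
  fitted; voltages are truncated at zero in simulation (negative draws are
  resampled); candidates with a missing reference length fall back to the
  Bayesian call with a warning rather than failing the batch.
* **Standard deviation** uses the n−1 denominator.

## What the simulator emulates — and what it does not

`simulate_reference()` builds a genome as a chain of homopolymer runs with a
configurable run-length spectrum (default: 55% single bases, geometric decay
over 2–6) and adjacent runs always of different nucleotides, with A/T
enrichment in the base composition. `inject_variants()` marks ~1% of
homopolymer loci (runs ≥ 2) as variants, by default all ±1-length shifts —
the event the integrated model must survive, since a pure reference copy
gets every one of them wrong; a fraction can instead be nucleotide
substitutions. `simulate_flowgrams()` samples reads (snapped to run
boundaries so every flow maps 1:1 to a reference locus), assigns zones, and
emits one truncated-Gaussian voltage per run from the configured cell.

Not modelled: flow-order phasing, carry-forward and droop, per-chip
calibration drift, polyclonal wells, quality scores, read errors outside
homopolymer length, and alignment uncertainty (reads come with known loci).
Passing tests on this generator therefore demonstrates the statistical
machinery — prior recovery, posterior calibration, weight selection, the
benefit of reference integration — under the stated noise model; they do
not demonstrate robustness to the chemistry effects above, nor do they
reproduce real-data error magnitudes, which depend on a proprietary
basecaller stack and a real gold standard.

## Problem sizes

The test-suite and acceptance runs use sizes chosen to make sampling error
negligible relative to the tolerances checked: 50,000 draws per Gaussian
cell for parameter recovery (standard error of the mean ≈ 0.0006 at
sd 0.14), 20,000 candidates for the brute-force-equivalence checks, and
100,000 candidates at the 1% variant rate for the method-ordering
comparison (~1,000 variant loci, so ordering margins of several hundred
errors are far outside noise).

## Known limitations

* The reconstructed default table is anchored on one nucleotide/zone
  stratum; other strata are mostly imputed and correspondingly smoother
  than real signal tables would be.
* Lengths outside the modelled range cannot be called; a true L = 7 run is
  at best called 6 (this mirrors the candidate enumeration of the method
  itself).
* The integrated model assumes the read is correctly anchored to the
  reference locus supplying `ref_length`; anchoring errors are outside its
  scope.
* Cross-validated and in-sample weight curves are both reported
  (`optimize_weight()` vs. `weight_sweep()`) because selecting per-cell
  weights on the same data later evaluated is optimistically biased; the
  package makes the distinction explicit rather than hiding it.

## A compact worked example

```{r example, eval = FALSE}
pri <- default_priors()
ref <- simulate_reference(50000, seed = 1)
smp <- inject_variants(ref, variant_rate = 0.01, seed = 2)
sim <- simulate_flowgrams(smp, pri, n_reads = 300, seed = 3)

cand <- detect_candidates(sim$flowgram) |>
  inner_join(select(sim$truth, read_id, flow_index, true_length, ref_length),
             by = c("read_id", "flow_index")) |>
  filter(true_length >= 2, true_length <= 6)

fit <- optimize_weight(cand, pri, seed = 4)
calls <- bind_rows(
  call_homopolymers(cand, pri, "integrated",
                    config = integrated_config(weight = fit$best_weight)),
  call_homopolymers(cand, pri, "bayes"),
  call_homopolymers(cand, pri, "nearest_mean"),
  call_homopolymers(cand, pri, "reference_only")
)
glance(evaluate_calls(calls))
evaluation_table(evaluate_calls(calls), weights = fit$best_weight)
```
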