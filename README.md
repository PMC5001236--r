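# flowcallr

Bayesian and reference-guided homopolymer length calling for semiconductor
sequencing flow signals.

## The problem

Ion Torrent / Ion Proton sequencers measure, for each nucleotide flow, a
voltage roughly proportional to the number of identical bases incorporated.
For a homopolymer of length L the signal is noisy and the noise grows with
L, so homopolymer lengths are the platform's dominant error mode: miscalled
runs become spurious indels at alignment and hide real variants. `flowcallr`
is for people working with flow-space signals (or studying such callers) who
want a transparent, per-read statistical treatment of this problem, plus a
simulator and evaluation harness to benchmark it.

## The model

Flow voltages are modelled per (nucleotide N, read-position zone Z,
homopolymer length L) as Gaussian, `V | N,Z,L ~ Normal(μ_NZL, σ_NZL)`, with
zones binning position along the read (default 4 × 75 bp; a 5 × 50 bp
profile for Proton-style reads). Three callers share this signal model:

* **nearest-mean** (baseline): `argmin_L |V − μ_NZL|`;
* **Bayesian**: `P(L | N,Z,V) ∝ P(V | N,Z,L) · P(L)`, normalized over the
  candidate lengths (default 2–6), computed in log space;
* **integrated**: scores every candidate length against both the signal and
  the reference genome,

  `S(L) = W · ln P(L | N,Z,V) + (1 − W) · Pen(L | ref)`,

  with `Pen = 0` for a perfect match, `−1` for a substitution, `−2` for an
  indel, and calls `L = argmax S(L)`. The weight `W ∈ [0,1]` is selected by
  5-fold cross-validation over a 0.02-step grid.

Since two human genomes differ at only ~1% of positions, the reference term
resolves most signal ambiguity while the Bayesian term preserves true
variants that a pure reference copy would erase.

## Worked example

Simulate a 50 kb genome with 1% homopolymer variants, sequence it, fit
nothing (use the built-in reconstructed parameter table), optimize the
weight, and compare all four callers:

```r
library(flowcallr)
library(dplyr)

pri <- default_priors()
ref <- simulate_reference(50000, seed = 1)
smp <- inject_variants(ref, variant_rate = 0.01, seed = 2)
sim <- simulate_flowgrams(smp, pri, n_reads = 300, seed = 3)

cand <- detect_candidates(sim$flowgram) |>
  inner_join(select(sim$truth, read_id, flow_index, true_length, ref_length),
             by = c("read_id", "flow_index")) |>
  filter(true_length >= 2, true_length <= 6)

fit <- optimize_weight(cand, pri, seed = 4)
fit
#> <weight_fit: best W = 0.26 (5-fold CV on 20739 candidates, CV error 0.0038)>

calls <- bind_rows(
  call_homopolymers(cand, pri, "integrated",
                    config = integrated_config(weight = fit$best_weight)),
  call_homopolymers(cand, pri, "bayes"),
  call_homopolymers(cand, pri, "nearest_mean"),
  call_homopolymers(cand, pri, "reference_only")
)
glance(evaluate_calls(calls))
#> # A tibble: 4 × 4
#>   method         count errors error_percent
#>   <chr>          <int>  <int>         <dbl>
#> 1 bayes          20739   1037         5
#> 2 integrated     20739     79         0.381
#> 3 nearest_mean   20739   1136         5.48
#> 4 reference_only 20739    162         0.781
```

Of the 20,739 detected candidates (voltage > 1.5 incorporation units), the
nearest-mean baseline miscalls 5.48%, the Bayesian caller 5.00%, copying the
reference gets everything except the injected variants wrong (0.78%), and
the integrated caller at the cross-validated weight W = 0.26 miscalls only
0.38% — it fixes the signal errors *and* recovers most variant loci.
Per-(nucleotide, zone) error tables in the standard comparison layout come
from `evaluation_table(evaluate_calls(calls), weights = fit$best_weight)`,
and `autoplot()` methods draw the signal classes, the weight curve and the
method comparison. `tidy()`/`glance()` work on fitted priors, weight fits
and evaluations.

A command-line front end over the same functions ships in
`inst/cli/flowcall` (subcommands `simulate`, `fit-priors`, `call`,
`optimize-weight`, `evaluate`, `correct-reads`).

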