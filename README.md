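# spikesync

Functional network plasticity analysis for multi-electrode array (MEA)
spike-train recordings of cultured neurons — for electrophysiologists and
systems-biology analysts who want to quantify how electrical stimulation
reorganises a network's functional connectivity, and to test those changes
with exact small-sample statistics.

## What it computes

Given per-channel spike timestamps over a trial of duration *T*:

- **Synchrony.** Spike counts in bins of width *w* (default 100 ms);
  sample Pearson correlation *r*ᵢⱼ between all pairs of active channels
  (mean firing rate ≥ 0.1 Hz).
- **Functional graph.** An undirected weighted edge for every pair with
  *r*ᵢⱼ ≥ θ (default 0.3).
- **Subnetworks.** Louvain maximisation of weighted modularity
  *Q* = Σ_c [Σ_in(c)/2m − γ(Σ_tot(c)/2m)²], implemented from scratch with
  deterministic seeded restarts.
- **Network similarity.** Community affiliations written in a fixed
  channel order, canonicalised to a label-permutation-invariant sequence;
  similarity between consecutive trials is 1 − d/n with d the Levenshtein
  edit distance and n the sequence length.
- **Summary indices.** Mean synchrony over active pairs, and the network
  synchronization activity index = (number of functional connections) ×
  (their mean synchrony coefficient).
- **Firing dynamics.** Joint inter-spike-interval (ISI) distributions on
  log-spaced bins, short-interval (≤ 50 ms) pair counts and proportions,
  per-channel and network mean firing rates, fixed-threshold burst
  detection, burst spike rate, and a baseline MFR recovery check.
- **Exact statistics.** Mann–Whitney U and Wilcoxon signed-rank tests with
  enumerated two-sided p (doubled smaller tail) and effect size
  r = |Z|/√N — the conventions that make tiny-sample comparisons honest.
- **Stimulation safety.** Per-phase charge Q = (V/|Z|)·t, geometric charge
  density D = Q/A, and the Shannon criterion k = log₁₀D + log₁₀Q with a
  SAFE/UNSAFE verdict against k ≤ 1.5.

A seeded Markov-modulated Poisson generator with planted community
structure and stimulation-condition effects (`generate_ground_truth()`,
`simulate_trial()`, `generate_disrupt_stabilize_series()`,
`generate_rhythmic_series()`) provides ground-truth data for every stage.

## Worked example

Simulate the eight-trial disrupt/stabilize protocol (control, 3× disrupt,
3× stabilize, control) at the study scale — 60 channels, 3-minute trials —
and run the connectivity pipeline:

```r
library(spikesync)

gt <- generate_ground_truth()   # 60 channels, 4 planted subnetworks
series <- generate_disrupt_stabilize_series(gt, seeds = 1:8)
rep <- run_connectivity_series(series, analysis_config(seed = 1))
rep$trials[, c("trial_id", "paradigm", "n_edges", "mean_edge_weight",
               "n_communities", "similarity_to_prev")]
#> # A tibble: 8 × 6
#>   trial_id    paradigm  n_edges mean_edge_weight n_communities similarity_to_prev
#>   <chr>       <chr>       <int>            <dbl>         <int>              <dbl>
#> 1 control_1   control       377            0.354             4             NA
#> 2 disrupt_2   disrupt      1453            0.344             3              0.3
#> 3 disrupt_3   disrupt      1598            0.351             3              0.533
#> 4 disrupt_4   disrupt      1439            0.342             3              0.5
#> 5 stabilize_5 stabilize     420            0.534             4              0.35
#> 6 stabilize_6 stabilize     420            0.524             4              1
#> 7 stabilize_7 stabilize     420            0.534             4              1
#> 8 control_8   control       344            0.377             4              1
```

Disruptive stimulation floods the network with weak nonspecific
correlations (≈1500 edges at mean weight 0.34) and scrambles the partition
from trial to trial (similarity ≈ 0.3–0.5); stabilizing stimulation prunes
the graph back to the four planted subnetworks (420 strong within-community
edges at weight ≈ 0.53) whose partition repeats exactly (similarity 1).
`glance(rep)` gives the per-paradigm summary; `autoplot(rep)` plots the
trends.

Exact small-sample statistics and the electrode safety report:

```r
tidy(mann_whitney_exact(1:5, 11:15))       # U = 0, p = 0.00794, r = 0.826
tidy(wilcoxon_signed_rank_exact(c(5, 6, 7), c(1, 2, 3)))  # p = 0.25, r = 0.926

safety_report(stim_pulse_spec())
#> # A tibble: 1 × 5
#>   charge_nC density_mC_cm2 shannon_k k_limit verdict
#>       <dbl>          <dbl>     <dbl>   <dbl> <chr>
#> 1      6.67          0.943     0.798     1.5 SAFE
```

A ±300 mV, 200 µs biphasic pulse through a 9 kΩ, 30 µm electrode delivers
6.67 nC per phase at 0.94 mC/cm² — Shannon k ≈ 0.8, well below the 1.5
damage threshold.

See `vignette("network-plasticity-methods")` for the models, parameter
rationale, and the synthetic generator's scope.

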