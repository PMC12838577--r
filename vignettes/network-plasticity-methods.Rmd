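---
title: "Methods: spike-train synchrony, community structure and plasticity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train synchrony, community structure and plasticity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesync)
library(dplyr)
```

spikesync quantifies how electrical stimulation reshapes the functional
network of a cultured neuronal population recorded on a multi-electrode
array (MEA). This vignette describes the models and conventions behind
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where
the underlying experimental literature leaves the details open.

## The analysis model

The pipeline treats each trial as a set of spike trains (one per
electrode channel, timestamps in seconds over a trial of duration $T$,
3 minutes by default) and derives, per trial:

1. **Binned counts.** Spikes are counted in half-open bins
   $[kw, (k+1)w)$ with $w = 0.1$ s by default. The bin width is the
   single most influential tunable: correlations between spike counts
   grow with $w$ because slow co-modulation accumulates while Poisson
   shot noise averages out. Every result records the bin width used.
2. **Active channels.** A channel participates when its mean firing rate
   is at least `min_rate_hz` (default 0.1 Hz, boundary inclusive).
   The experimental figures this mirrors show "only the most active
   sites", without stating the criterion; the threshold is therefore a
   declared configurable, not a recovered constant.
3. **Synchrony matrix.** The sample Pearson correlation of binned counts
   for every active pair. Counts — not raw voltage traces — are the
   standard reading of "correlation between spike signals" for sorted
   spikes. Zero-variance channels yield undefined coefficients, recorded
   as `NA` (never silently zero).
4. **Functional graph.** An undirected weighted edge joins each pair with
   $r \ge$ `edge_threshold` (default 0.3). Negative correlations are not
   functional connections, and no significance filter is applied; the
   threshold is configurable because the reference analysis does not
   state its rule.
5. **Subnetworks.** Louvain modularity maximisation on the thresholded
   graph (weighted modularity, resolution $\gamma = 1$ by default).
6. **Affiliation sequence and similarity.** Community labels are written
   in a fixed lexicographic channel order and canonicalised by first
   appearance (A, B, C, ...), with a reserved symbol for channels
   inactive in that trial. Network similarity between consecutive trials
   is $1 - d/n$ where $d$ is the Levenshtein distance between the two
   canonical sequences and $n$ the (constant) sequence length.

Two summary statistics condense a trial: the **mean synchrony** (average
of all defined active-pair coefficients, not only edges) and the
**network synchronization activity index**, the number of functional
connections times their mean synchrony coefficient.

### Why canonicalisation matters

Raw Louvain labels are arbitrary integers; two identical partitions can
carry permuted labels. Without the first-appearance canonicalisation the
edit distance between trials would be dominated by label permutation
noise and the similarity would be meaningless. With it, the similarity
equals 1 exactly when two trials induce the same partition of the same
active set. Inactive channels keep a dedicated symbol rather than being
dropped so that sequence length — and hence the normalisation — is
constant across the trials of one series.

### Louvain details

Modularity is
$Q = \sum_c \left[\frac{\Sigma_{in}(c)}{2m} - \gamma\left(\frac{\Sigma_{tot}(c)}{2m}\right)^2\right]$
with the usual weighted-degree conventions. The optimiser alternates
local moving (nodes visited in a seed-shuffled order; each node moves to
the neighbouring community with the largest positive gain, computed
incrementally from community degree sums) with aggregation of communities
into super-nodes, until no level improves $Q$. Ties in the gain keep the
current community, otherwise the lowest community label wins, so a run is
fully reproducible given its seed. Because greedy moving can stall in
local optima on small or noisy graphs, `louvain()` runs `n_restarts = 5`
independent visit orders (derived deterministically from the seed) and
returns the best partition; on graphs of up to 8 nodes this matches the
exhaustively enumerated optimum in over 95% of random instances in the
test suite. $Q$ is asserted non-decreasing across passes and the final
value is recomputed independently from the definition.

An edgeless graph has undefined modularity; `louvain()` refuses it. The
series workflows handle that case by assigning every active node its own
community and flagging the trial in the report's `note` column.

## Exact rank statistics

MEA plasticity studies compare tiny samples (3–5 electrodes or trial
pairs), where asymptotic p-values are misleading and effect sizes matter
as much as significance. `mann_whitney_exact()` and
`wilcoxon_signed_rank_exact()` therefore:

- report the min-statistic ($U = \min(U_x, U_y)$;
  $W = \min(W^+, W^-)$);
- compute the exact two-sided p by **doubling the smaller tail** of the
  enumerated null distribution, capped at 1 (for tie-free Mann–Whitney
  via the standard count recurrence; for the signed-rank by convolution
  over the rank weights, equivalent to enumerating all $2^n$ sign
  patterns; under ties the Mann–Whitney p enumerates group assignments
  with mid-ranks);
- report $r = |Z|/\sqrt{N}$ with
  $Z = (S - \mu_S)/\sigma_S$ using the untied variance, **no continuity
  correction and no tie correction** by default.

This convention set is the one under which complete separation at
$n = 5 + 5$ gives $p = 2/252 = 0.008$ and $r = 0.83$, and three
same-sign pairs give $p = 2/8 = 0.25$ and $r = 0.93$ — the worked
examples the package reproduces:

```{r}
tidy(mann_whitney_exact(1:5, 11:15))
tidy(wilcoxon_signed_rank_exact(c(5, 6, 7), c(1, 2, 3)))
```

Continuity and tie corrections are available behind flags for users who
prefer them; they change $Z$ and $r$, not the exact p.

## Stimulation charge safety

For a charge-balanced biphasic pulse the per-phase charge is estimated as
$Q = (V/|Z|)\,t_{phase}$ (scalar impedance magnitude; no equivalent
circuit fitting), the geometric charge density as $D = Q/A$ over the
disc electrode area, and the Shannon criterion as
$k = \log_{10} D\,[\mu C/cm^2] + \log_{10} Q\,[\mu C]$, with damage
empirically associated above $k \approx 1.5$. For the default 300 mV,
200 us, 9 kOhm, 30 um specification this yields $Q = 6.67$ nC and
$D = 0.94$ mC/cm$^2$. Note that $k$ recomputed from those two values is
$\approx 0.80$; reports should quote the computed value, and the safety
verdict depends only on the $k \le 1.5$ bound, which holds with a wide
margin:

```{r}
safety_report(stim_pulse_spec())
```

## The synthetic generator

No public recordings accompany the experimental analyses this package
operationalises, so `spikesync` ships a first-class generator whose
defaults encode the study conditions: 60 channels, 3-minute trials,
community structure in pairwise synchrony, and stimulation effects with
the observed directions.

**Model.** A Markov-modulated Poisson process. Each of $K = 4$
contiguous channel blocks shares a two-state (on/off) continuous-time
Markov "burst" modulator with switching rates
$\lambda_{on} = 0.2\,/s$, $\lambda_{off} = 2\,/s$ (bursts of mean 0.5 s
roughly every 5 s, duty cycle ~9%); a global modulator couples all
channels. Channel $i$ fires as an inhomogeneous Poisson process with
rate
$r_i(t) = b\,\rho\,(1 + a_w \sigma\, m_{c(i)}(t) + a_g\, g(t))$,
where $b = 1$ Hz is the baseline, $\rho$ and $\sigma$ are the
stimulation rate and synchrony multipliers, and spikes are drawn by
thinning against the analytic maximum rate — exact sampling, no time
discretisation. This model was chosen because it produces both
burst-like firing and tunable pairwise synchrony while keeping the mean
rate available in closed form
($E[r_i] = b\rho(1 + (a_w\sigma + a_g)p_{on})$), which the calibration
tests exploit.

**Coupling scale.** The defaults are $a_w = 13$, $a_g = 2$: on-state
rates of roughly 10–15 times baseline, the regime of culture-wide
network bursts. This scale is deliberate. At 1 Hz baseline and 100 ms
bins the expected count per bin is ~0.1, so Poisson shot noise dominates
the bin-count variance; a short analytic calculation gives a
within-community correlation of
$r \approx \frac{(bwa_w)^2 p(1-p)}{bw(1+(a_w+a_g)p) + (bwa_w)^2p(1-p)}$,
which only reaches the 0.3–0.5 range of observed functional connections
when the modulation amplitude is of order ten times baseline. Weak
couplings of order one would leave every pairwise correlation below 0.02
— no pair could ever cross the 0.3 edge threshold and community
recovery would be impossible at any trial length. With the defaults,
within-community correlations sit near 0.37 and planted partitions are
recovered with adjusted Rand index above 0.9 in over 90% of full-length
runs.

**Stimulation effects.** A condition maps to three multipliers (rate,
synchrony amplitude, burst onset rate). Gamma-band stimulation (40 Hz)
raises each at low pulse counts, decaying log-linearly in pulse
repetitions down to a floor; theta-band (7.8 Hz) lowers each by a
constant factor. Gains (rate: $g_{40} = 0.5$, decay 0.4/decade, floor
0.7, $g_{7.8} = 0.3$; synchrony: 0.6/0.5/0.6/0.4; burst:
0.8/0.6/0.6/0.4) are invented and chosen so the two frequencies meet at
10,000 pulses. The 40 Hz curve is additionally clamped at the 7.8 Hz
level, so the absolute between-frequency gap is non-increasing in pulse
count *for any* gain parameterisation — the adaptive-convergence
direction is guaranteed by construction, and the acceptance tests rely
only on directions, never on these invented magnitudes.

**Disrupt/stabilize series.** The eight-trial protocol (control, three
disrupt, three stabilize, control) modifies the ground truth per
paradigm: disrupt scales $a_w$ by 0.2 and raises the global coupling to
$a_g = 12$ (many weak, nonspecific correlations: more edges, lower mean
weight, unstable partitions, low between-trial similarity); stabilize
scales $a_w$ by 1.6 with $a_g = 1$ (fewer, stronger, community-specific
edges and near-identical consecutive partitions).

**What the generator does not emulate.** Trials are conditionally
independent given their condition — the recovery-interval history
effects of real cultures are not modelled. There are no biophysical
neurons, no synaptic plasticity dynamics, no electrode noise or volume
conduction, and no spike-sorting artifacts. Passing tests therefore
demonstrate that the analysis code measures what it claims on data with
known structure; they do not validate biological claims about real
cultures.

## Numerical choices and degenerate inputs

- Bin edges are half-open with a $10^{-9}$ s tolerance on the bin count
  so durations that are exact multiples of the width keep their last bin.
- Joint-ISI histograms use 50 log-spaced bins per axis from 1 ms to
  10 s; out-of-range pairs are counted and reported, never silently
  dropped. The short-interval statistic counts **pairs** with both
  consecutive intervals $\le$ 50 ms by default (tying it to the joint
  distribution's lower-left block); a `mode = "isi"` switch provides the
  simpler single-interval reading.
- Burst detection is the fixed-threshold run method (max intra-burst ISI
  100 ms, min 3 spikes), with parameters always reported alongside
  results; adaptive detectors are out of scope.
- Duplicate (channel, time) rows are deduplicated with a warning; times
  outside $[0, T)$ are errors, not clamps.
- Tie-breaking, seeds and visit orders are deterministic throughout:
  identical inputs, configuration and seed give byte-identical outputs,
  and every written file embeds the configuration hash.

## Problem sizes used in the test suite

Module tests run on reduced problems (12–24 channels, 30–60 s trials)
chosen to exercise every code path quickly; the end-to-end directional
checks run at the full study conditions (60 channels, 180 s trials) with
50 seeded disrupt/stabilize series, 30 seeded rhythmic series and 50
planted-recovery runs — enough seeds for the sign tests to resolve the
directions while keeping the suite comfortably within a coffee break on
one CPU.

## Known limitations

- Louvain is a greedy heuristic; even with restarts it can miss the
  modularity optimum on adversarial graphs. The partition seed is part
  of the result's provenance for this reason.
- Pearson synchrony on binned counts ignores fine spike timing; no
  cross-correlogram or jitter-corrected measures are provided.
- The exact Mann–Whitney path under heavy ties falls back to a normal
  approximation when the permutation space exceeds the enumeration
  budget (a notice is emitted).
- The similarity normalisation and inactive-node handling are declared
  conventions; other choices (dropping inactive nodes, all-pairs
  comparisons) would change absolute similarity values, though not the
  disrupt-vs-stabilize direction.
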