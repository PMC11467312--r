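---
title: "Phase-synchronization and network analysis of two-group EEG studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization and network analysis of two-group EEG studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciplvnet)
```

## The problem this package addresses

Stroke reorganizes the brain's functional networks, and the reorganization
differs between the subacute phase (under six months post-onset) and the
chronic phase. Sensor-space EEG during an attentional Go/No-Go task lets us
quantify that reorganization: phase synchronization between electrode pairs
measures functional coupling, graph metrics summarize the network it forms,
and cluster-level permutation tests compare two groups of patients with
family-wise error control. `ciplvnet` implements that entire chain —
together with a synthetic-data generator whose ground truth is known, so
every stage can be validated end to end.

## The connectivity estimator

For two channels with band-limited instantaneous phases $\varphi_x(t)$ and
$\varphi_y(t)$, let $\Delta\varphi_n(t)$ be their difference on trial $n$.
With $C(t) = \frac{1}{N}\sum_{n=1}^{N} e^{i\,\Delta\varphi_n(t)}$ over $N$
trials, the corrected imaginary phase locking value is

$$\mathrm{ciPLV}(t) \;=\; \frac{\lvert \mathrm{Im}\, C(t)\rvert}
{\sqrt{1 - \mathrm{Re}\, C(t)^2}} \;\in\; [0, 1].$$

Zero-lag synchrony — the signature of volume conduction, where one source
projects instantaneously into several electrodes — contributes only to the
real part and is suppressed; a phase relation that is consistent across
trials at a non-zero lag drives the value toward 1. Taking the absolute
value of the imaginary part makes the measure undirected. The degenerate
case $\mathrm{Re}\,C^2 = 1$ (perfect zero-lag locking) is returned as 0 by
continuity.

Phases come from the analytic signal (FFT construction) of the band-passed
epoch. ciPLV is estimated across trials at each latency and then averaged
over latencies, excluding a guard band of 10% of samples at each epoch edge
where filter and analytic-signal transients concentrate. The aggregation
window is the full epoch minus guards; whether a baseline portion should be
excluded is left configurable because the underlying study design does not
settle it.

A property worth knowing: for perfectly zero-lag-coupled channels the ciPLV
*expectation* collapses to chance scale ($\sim 1/\sqrt{N}$), but the
normalization by $\sqrt{1-\mathrm{Re}\,C^2}$ makes its sampling distribution
roughly a ratio statistic, about $\sqrt{2}$ wider than that of two fully
independent channels. Tests that compare a zero-lag pair against an
independent-pair null band must therefore expect slight exceedances; our
tests assert "chance scale" (an order of magnitude below a truly lagged
pair), not distributional identity.

## Filtering

Band-pass filtering uses a Hamming-windowed FIR with the common published
heuristic: transition width $\min(\max(0.25 f_c, 2\,\mathrm{Hz}),
\text{distance to band edge})$ at each cutoff, order
$\lceil 3.3/(\mathrm{tbw}/f_s)\rceil$ rounded up to even, and the smaller of
the two edge widths (a single linear-phase filter has one transition width).
Application is a single pass with integer group-delay compensation — exactly
zero-phase for symmetric taps, which matters because PLV-type metrics live
on phase. For 800 ms epochs the heuristic order (413 taps for the alpha band
at 250 Hz) exceeds the epoch length; edges are padded by tiled symmetric
reflection so the full order applies. The alternative — capping the order at
the epoch length — widens the transition band to roughly 4 Hz and lets
alpha-band energy leak into the theta filter, which we observed as spurious
theta "coupling" of an alpha-coupled pair; the reflection padding removes
that leakage at the cost of edge artifacts that the guard samples absorb.

Frequency bands are theta (4–7 Hz), alpha (8–12 Hz), beta (15–30 Hz), and
gamma (31–45 Hz).

## Preprocessing

Continuous EDF recordings are epoched into 800 ms windows from 300 ms before
to 500 ms after stimulus onset (half-open sample intervals, 0-based).
Recordings are re-referenced to FCz for connectivity; the reference channel
is then dropped (31 analysis channels from the 32-channel montage), because
an identically-zero channel has no defined phase. Bad channels can be
replaced by spherical-spline interpolation (stiffness $m=4$, 20 Legendre
terms, ridge $10^{-5}$). Artifact screening is a peak-to-peak amplitude
threshold (default 150 µV) — an automated, reproducible stand-in for manual
visual inspection, which cannot be replicated. No ICA, ocular regression, or
notch filtering is attempted.

## Graph metrics

All metrics operate on the full weighted ciPLV matrix; we deliberately avoid
binarization or thresholding, which would add free parameters. Path-based
metrics use edge lengths $1/w$:

* **Global efficiency** $E = \frac{1}{n(n-1)}\sum_{i \ne j} 1/d_{ij}$, with
  disconnected pairs contributing zero.
* **Nodal (local) efficiency** of node $i$: global efficiency of the
  subgraph induced by $i$'s neighbours (0 for degree < 2).
* **Clustering coefficient** (Onnela geometric-mean form):
  $C_i = \frac{1}{k_i(k_i-1)}\sum_{j \ne h}
  (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$ with weights normalized by the
  matrix maximum.
* **Modularity**: Newman's weighted $Q$ with resolution $\gamma$, maximized
  by Louvain with 100 seeded restarts (best $Q$ kept; ties broken by first
  occurrence) — Louvain is stochastic, so restarts and an explicit seed are
  part of the contract.
* **Nodal modularity**: the per-node decomposition
  $Q_i = \frac{1}{2m}\sum_j (w_{ij} - \gamma k_i k_j / 2m)\,
  \delta(c_i, c_j)$, which sums exactly to $Q$. Among the candidate
  "local modularity" definitions (participation indices, module-wise $Q$),
  this is the only one that is exact, parameter-free, and resolved per
  electrode, which is why the package uses it.

## Group inference

Cluster-level permutation testing controls family-wise error over hundreds
of edges or sensors: per-feature pooled two-sample $t$ values; features
exceeding the two-tailed $t$ quantile at `cluster_alpha` (pooled df) are
joined into connected clusters under the feature adjacency — edges are
neighbours when they share a channel; sensors are neighbours under a
Delaunay triangulation of the flattened montage. Positive and negative
supra-threshold features form separate clusters: opposite-sign effects are
distinct phenomena, and letting them share a cluster cancels the mass
$\sum t$. The null distribution is the maximum absolute cluster mass over
group-label permutations (full enumeration when feasible, otherwise
distinct random relabelings), and $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_\mathrm{perm})$.

Two practical notes. First, the default cluster-forming threshold
(two-tailed 0.05) suits spatially extended effects; for *focal* effects a
stricter threshold (for example 0.01) is the appropriate configuration,
because with ~465 edge features and a 12.5% edge-adjacency density, chance
supra-threshold features chain into null clusters whose mass rivals any
single-feature effect. This is the standard power trade-off of
cluster-based inference, and the threshold is an exposed parameter. Second,
when a claim spans several tests (e.g. "nothing appears in either control
band"), its error should be controlled across that family, not per test.

Cohort statistics follow classical conventions: pooled-variance Student $t$
(df $n_1+n_2-2$), Mann–Whitney $U = \min(U_1, U_2)$ with midranks and exact
enumeration for $n_1+n_2 \le 12$ (normal approximation with tie and
continuity correction otherwise), and Pearson $\chi^2$ *without* continuity
correction — the convention that reproduces the reference cohort's published
values. Spearman correlations screen the designated variable for outliers
beyond 3 scaled MADs (constant 1.4826, the normal-consistency choice; the
source convention says only "scaled") before correlating.

## Behavioral scoring

Go/No-Go logs are scored with hit rate and false-alarm rate adjusted at the
boundaries ($1 - 1/2n$ for perfect scores, $1/2n$ for zero counts) so that
$d' = \Phi^{-1}(\mathrm{HR}) - \Phi^{-1}(\mathrm{FAR})$ is always finite. RT
statistics (mean and median both reported; group tests use per-subject
means, since the source convention is ambiguous) are computed over Go hits
only. Responses faster than 100 ms are flagged anticipatory but kept — no RT
cutoff is imposed by default. "Valid" No-Go trials for connectivity are
interpreted as correct rejections.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated.

* **Signal model.** Every channel is $1/f$ background noise (exponent 1 —
  the standard resting-EEG spectral shape; SD 10 µV) plus independent
  band-limited oscillations in theta, alpha, beta, and gamma. Total
  oscillatory amplitude is twice the background SD, split evenly over the
  four bands. That ratio was fixed so that a full-strength, quarter-cycle
  coupled pair yields pipeline ciPLV well above 0.8 at 100 trials — the
  regime the estimator's contract describes — while leaving uncoupled pairs
  at chance; task-state EEG with prominent oscillations sits in this range.
* **Coupling.** A coupling specification names a channel pair, band, phase
  lag, and strength $s \in [0,1]$. The pair's band oscillation becomes
  $(1-s)\,\text{independent} + s\,\text{shared}$, with the second channel's
  shared part rotated by the lag. The shared component has a fresh random
  phase every trial, so only the lag is consistent across trials — the
  structure ciPLV detects and PLV-style measures require. Injection happens
  in signal space before any filtering, so the generator does not
  presuppose the analysis filter.
* **Behavior.** 5 blocks of 60 trials (45 Go / 15 No-Go each,
  pseudo-randomized with at most 3 consecutive No-Go), 300 ms stimuli,
  inter-stimulus intervals from {800, 1000, 1200} ms; responses are
  Bernoulli with the subject's hit/false-alarm probabilities and RTs are
  log-normal.
* **Cohort.** Generated cohorts draw lesion ages per group and derive the
  group label from the 26-week subacute/chronic threshold. The bundled
  reference cohort (27 subjects) preserves its published labels verbatim,
  including one subject whose 25-week lesion age carries a chronic label.
* **Determinism.** Every generator output is a pure function of its
  specification and seed.

What the generator does *not* emulate: realistic ERP waveforms, biophysical
head volume conduction (zero-lag mixing can be constructed explicitly in
tests), eye-blink or muscle artifacts, or electrode drift. Passing tests
therefore demonstrate that the analysis chain recovers known coupling
structure under plausible spectra and noise — not that it is robust to every
artifact class found in clinical recordings.

## Numerical and design choices

* Sampling rate defaults to 250 Hz (not fixed by the study conventions; the
  interchange format carries it explicitly).
* Epoched data travel as a raw little-endian float64 tensor plus a JSON
  sidecar (dimensions, rate, labels, positions, window) — versioned and
  exactly round-trippable. Continuous input uses a minimal EDF+
  implementation (16-bit with per-channel scaling; annotations as TALs)
  written for this package and round-trip tested.
* The montage is an idealized spherical extended 10–20 set of 32 electrodes
  including FCz: the classic outer ring at 72° inclination, midline steps of
  18°, and intermediate electrodes by great-circle interpolation.
* Louvain determinism: restart node orders derive from the caller's seed;
  identical seeds give identical partitions.
* Degenerate inputs error early and descriptively: all-trials-rejected,
  re-referencing to a missing channel, fewer than 2 selected trials,
  zero-weight graphs, zero marginals in 2×2 tables.
* Validation problem sizes (chosen to exercise the estimators meaningfully
  at desk scale): metric oracles on 1000 random graphs of up to 6–8 nodes;
  permutation-test calibration on 500 null datasets of 13 vs 14 subjects ×
  465 edges at 200 permutations; coupling recovery on ten full synthetic
  studies (27 subjects, 32 channels, 75 trials) across three bands.

## Known limitations

* Sensor-space only; no source projection, so interpretation of which
  cortical structures drive an edge is indirect.
* The FIR-plus-analytic-signal phase path is the only spectral estimator
  (no multitaper or wavelet option); very narrow bands on very short epochs
  are limited by the epoch length itself.
* Cluster-based inference has low power for strictly focal effects at the
  default forming threshold (see above); this is a property of the method,
  not of the implementation.
* The Mann–Whitney normal approximation is used above $n_1+n_2=12$; exact
  enumeration beyond that is deliberately avoided for cost.
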