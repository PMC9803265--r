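---
title: "Activity, flexibility and injury resilience of neuronal islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity, flexibility and injury resilience of neuronal islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caislands)
```

## The system and the measurements

caislands analyses small in-vitro cortical circuits — "islands" of a few
hundred neurons confined to a circular adhesion disc (750–1300 µm in
diameter, 50–400 cells/mm², roughly 80% excitatory and 20% inhibitory) and
monitored with a genetically encoded calcium indicator such as GCaMP6f.
Fluorescence transients are a non-invasive proxy for electrical activity;
recordings are typically 3 minutes at 20 frames/s.

The pipeline mirrors how such recordings are analysed in practice:

1. **Imaging** — segment somata from the maximum-intensity projection of
   the binarized stack, register masks across sessions with a rigid
   transform so cells keep their identity, extract per-ROI traces,
   subtract the per-frame background and scale to an interpolated
   baseline: `dff = (F − F_background) / F0`, with F0 a rolling low
   percentile. A quiescent cell sits at `dff = 1`.
2. **Events** — detect calcium transients by correlating trace fragments
   against a library of 128 difference-of-exponential waveforms spanning a
   grid of rise (20–80 ms) and decay (100–400 ms) constants.
3. **Activity** — active population fraction, mean event rate over active
   cells (events/min), and a synchronization index (SI).
4. **Entropy ("flexibility")** — two-state discretization of each cell's
   activity, a first-order transition matrix, and its Shannon entropy
   rate, in [0, 1].
5. **Networks** — binary undirected functional connectivity from
   surrogate-thresholded pairwise correlation; FC density, characteristic
   path length and clustering coefficient referenced to 1000 random
   control graphs of identical size and edge count.
6. **Resilience** — activity-versus-injury curves from sequential
   5-cell microablation, the injury level at 50% and at complete loss of
   activity, and OLS correlations of those thresholds with baseline rate
   and entropy.

Because no public recordings accompany this experimental design, the
package ships a forward simulator — island layouts, spike trains,
fluorescence rendering, and a cascade model for ablation experiments —
so every stage is testable against known ground truth.

## The synchronization index

Traces are z-scored and each pair is scored by the normalized lagged
cross-correlation

$$C_{xy}(\tau) = \frac{1}{N-\tau} \sum_{n=1}^{N-\tau} x_{n+\tau}\, y_n,
\qquad \tau \ge 0,$$

extended symmetrically to negative lags. The pair score is the maximum of
$C_{xy}$ over lags $|\tau| \le 1$ s (the lag bound is `tau_max`), clipped
below at zero; the SI is the mean pair score over all unordered pairs, so
it lies in [0, 1], reaching 1 only for identical traces. The lag search
makes the score tolerant of small propagation delays within a burst; a
zero-lag-only variant is available via `method = "zero_lag"`. Pairs are
symmetrized (the larger of the two directed scores is used), which keeps
the pair matrix symmetric under relabeling. Constant traces carry no
timing information and are excluded with a warning.

## Markov entropy as flexibility

Each cell's event train is discretized at the frame rate: frames within
1 s of an event onset (about one transient duration) are "active", the
rest "inactive". From the 2×2 transition matrix $P$ we report the entropy
rate

$$E = \sum_i \pi_i \, h(P_{i\cdot}), \qquad
h(p) = -\sum_j p_j \log_2 p_j,$$

with $\pi$ the stationary distribution of $P$ and $0 \log 0 = 0$. With two
states E is bounded by [0, 1]: 0 for deterministic dynamics (a rigidly
bursting cell), 1 for fair-coin transitions (a maximally unpredictable
cell). The stationary weighting is the standard entropy rate of a Markov
chain; a plain row-average variant is exposed (`method = "row_mean"`) for
sensitivity checks, since descriptions of this statistic in the
experimental literature are often ambiguous about the weighting. A state
never visited yields a flagged uniform row, so silent cells still produce
a defined (zero) entropy; silent cells are excluded from island means by
default because they are also removed by the active-cell filter.

## Functional connectivity and null referencing

The pair score above is compared, per pair, with the 95th percentile of
scores obtained from 100 circular-shift surrogates: every trace is rotated
by an independent uniform offset of at least 5 s, which preserves each
trace's autocorrelation and event statistics while destroying pairwise
alignment. This gives a per-pair significance threshold with false
positive rate `alpha` (0.05 by default) — on independent traces the
realized FC density is close to `alpha`, which the test suite checks. A
fixed absolute threshold mode exists for sensitivity analyses.

FC density is the undirected edge count over $N(N-1)/2$. (The version of
this formula that sums full node degrees double-counts each edge; we use
the edge-count form, which respects the stated [0, 1] range.)
Characteristic path length excludes unreachable pairs from the mean and
reports their fraction; clustering uses $C_i = 2t_i / (k_i(k_i-1))$ with
$C_i = 0$ for degree < 2. Both are referenced to the mean over 1000
uniform G(n, m) graphs with identical node and edge counts ("same size
and connection density"); a complete graph therefore has scaled metrics
of exactly 1, the signature of the dense, random-like networks formed at
high plating density.

## The synthetic generator: what it emulates, and what not

**Asynchronous regime** (low plating density): independent renewal
processes with an absolute refractory period of 0.5 s and a rate-corrected
exponential waiting time, so the realized mean rate equals the target.
The refractory period encodes the fact that two calcium transients closer
than ~0.5 s are not separable as distinct events by template matching (or
by eye); without it, a generative rate of 12.4 events/min would be
unrecoverable by construction, because ~9% of a pure Poisson train's
events fall inside another event's separability window.

**Bursting regime** (high plating density): population bursts arrive as a
Poisson process; each burst recruits each cell with probability
`participation` and uniform jitter (default 50 ms). At the high-density
event rate of 0.69 events/min a 3-minute recording contains about two
bursts — and with probability $e^{-2.07} \approx 0.13$ none at all, in
which case the island is silent and pair correlation is undefined; such
recordings are flagged and excluded from across-island summaries, as
silent recordings would be in practice.

**Fluorescence**: each event is convolved with a difference-of-exponentials
kernel (rise 50 ms, decay 400 ms, unit peak in dF/F — GCaMP6f-like
kinetics; configurable) on a baseline of 1, with additive Gaussian noise
(default σ = 0.02), optional multiplicative drift and bleaching. Movies
paint somata as 2-D Gaussians at their island positions.

**Cascade model** (for ablation experiments): a discrete-time branching
process on a distance-decay structural graph (50 ms bins). Each
non-refractory cell fires spontaneously with `p_spont` or is recruited
along edges from excitatory neighbours active in the previous bin with
`p_exc`; active inhibitory neighbours multiply the firing probability by
`1 − p_inh_block`. `bicuculline()` scales `p_inh_block` toward 0,
emulating GABA_A blockade (raising the effective E/I ratio increases rate
and synchrony and lowers entropy). Two presets bracket the observed
regimes: `cascade_preset("flexible")` (weak coupling, strong spontaneous
drive — asynchronous, high-entropy, gradual loss of activity under
ablation) and `cascade_preset("rigid")` (strong recurrent coupling,
sparse seeds — synchronous bursts that collapse once random node removal
pushes the circuit below its percolation threshold). The preset
probabilities were chosen once to realize these qualitative contracts;
they are model parameters, not measured quantities.

The simulator is deliberately phenomenological: there is no
conductance-based biophysics, no optics beyond 2-D Gaussians, no
photobleaching–toxicity coupling, and the distance-decay structural rule
is an assumption (the spatial wiring of such cultures is not known), so
passing tests demonstrate that the *pipeline* recovers known ground truth
— not that the generator reproduces every property of living circuits.

## Event detection: design notes

Detection scores every template-start position by the best Pearson
correlation between the z-scored fragment and any library waveform, making
it invariant to transient amplitude. Acceptance is by sequential greedy
matched pursuit: take the best-scoring position at or above `r_min`
(default 0.85), fit the best template's amplitude by least squares,
subtract it, suppress the refractory window (0.5 s), re-score the
neighbourhood on the residual and repeat. Subtraction is what lets a
transient riding on a neighbour's decay be recovered once the neighbour is
accounted for, and removes decay tails that would otherwise match slow
templates. Two guards keep the amplitude-invariant score honest:
a minimum fitted amplitude (`min_amplitude`, default 0.1 dF/F) rejects
tiny residual shapes, and truncated-template scoring covers the last
seconds of the recording so transients that outlast it are still found.
On synthetic islands at default SNR the detector reaches F1 ≥ 0.99 at
12 events/min with zero false positives on pure noise.

## Resilience analysis

The sequential protocol ablates 5 randomly selected surviving cells per
round (random selection avoids biasing by observable activity), up to 75%
of the population by default (tests and simulations may run to 100%).
Curves report the cumulative injured fraction against the fraction of the
*baseline* active population still active — ablated cells count against
activity but stay in the denominator, matching the injured-fraction axis
semantics of microablation experiments. The half-activity threshold
interpolates the first downward crossing of 0.5 linearly between the
bracketing 5-cell steps (a step-function variant is available); complete
silencing uses `epsilon = 0` by default with a configurable tolerance,
since "no activity" is otherwise a visual-inspection criterion. Paired
simulations show the expected ordering: half-activity thresholds precede
silencing thresholds, independent-cell circuits lose activity linearly
(half ≈ 0.5, silencing ≈ 1), and flexible circuits tolerate more injury
than rigid ones before losing half their activity — the
flexibility→resilience direction. The wet-lab threshold values themselves
depend on living-culture dynamics and are deliberately not numeric
targets.

## Worked example

```{r example, eval = FALSE}
library(caislands)

res <- run_pipeline(pipeline_config(
  seed = 1,
  synthetic = list(diameter = 750, cell_density = 150, duration = 60,
                   rate = 12, regime = "asynchronous"),
  network = list(n_surrogate = 50, n_null = 200)))
res$activity
glance(res$entropy)
res$network_metrics
```

## Problem sizes and numerical choices

The examples and tests run islands of 40–150 cells for 60–180 s at
20 fps; surrogate ensembles of 50–100 and null ensembles of 200–1000 are
used depending on how tight the comparison is. These sizes were chosen so
each check is stable at 2–3 Monte-Carlo standard errors. Tolerances
follow the estimator, not the implementation: rate recovery within 10% or
3 SE, entropy within 0.01 at 10^5 chain steps, exact equality where the
result is exact (scaled metrics of complete graphs, active-fraction
bookkeeping). All randomness flows through explicit seeds with derived
per-stage substreams, so identical configuration plus seed reproduces
every artifact bit for bit. Ties in detection are resolved toward the
higher score, then the earlier onset; registration ties resolve toward
the smaller rotation.

## Known limitations

- The segmentation default (global Otsu on the projection) assumes
  reasonably uniform illumination; per-frame adaptive thresholds are
  exposed but not default.
- Registration is rigid (translation + rotation); non-rigid deformation
  and neuropil decontamination are out of scope.
- The SI summarizes a whole recording; it is not windowed in time.
- Entropy uses a two-letter alphabet by design; larger alphabets would
  require a normalization choice that is irrelevant at n = 2.
- The cascade model reproduces regime phenomenology, not biophysics; its
  thresholds (e.g. where collapse occurs) depend on its free parameters
  and should not be read as predictions for living cultures.
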