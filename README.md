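# caislands

Analysis of calcium-imaged neuronal microcircuits: activity, flexibility,
and resilience to microtrauma.

Small in-vitro cortical circuits ("islands" — a few hundred neurons
confined to a circular adhesion disc and expressing a calcium indicator
such as GCaMP6f) are a tractable level of brain architecture for asking
how structure shapes function and how circuits degrade under injury.
`caislands` implements the full analysis chain for such recordings, for
experimentalists and modellers who want a tested, scriptable pipeline
from fluorescence movies (or synthetic equivalents) to circuit-level
statistics:

- **Imaging**: ROI segmentation from the maximum-intensity projection,
  rigid mask registration across sessions, trace extraction, background
  subtraction and baseline normalization
  (`dff = (F − F_background)/F₀`, F₀ a rolling low percentile).
- **Event detection**: calcium transients found by correlating trace
  fragments against a library of 128 spike waveform templates
  (difference-of-exponentials on a rise × decay grid), with sequential
  matched-pursuit acceptance.
- **Activity metrics**: active population fraction; mean event rate over
  active cells (events/min); synchronization index
  `SI = mean over pairs of max_|τ|≤1s C_xy(τ)` where
  `C_xy(τ) = 1/(N−τ) Σ x_{n+τ} y_n` on z-scored traces, clipped to [0, 1].
- **Flexibility**: single-cell Markov entropy — two-state discretization,
  transition matrix `P`, entropy rate `E = Σ_i π_i h(P_i·)` in [0, 1]
  (0 = rigidly predictable, 1 = fair-coin transitions).
- **Functional networks**: binary undirected connectivity from
  surrogate-thresholded pairwise correlation (circular-shift surrogates,
  per-pair 95th-percentile threshold); FC density, characteristic path
  length and clustering coefficient scaled against 1,000 random control
  networks of identical size and edge count.
- **Resilience**: activity-versus-injury curves from sequential 5-cell
  microablation, the injured fraction at 50% and at complete loss of
  activity, and OLS correlation of those thresholds with baseline rate
  and entropy.
- **Forward simulation**: island layouts, asynchronous/bursting spike
  trains, GCaMP-like trace and movie rendering, and a probabilistic
  cascade model on a distance-decay structural graph for simulated
  ablation experiments — so every stage is testable with known ground
  truth and no downloads.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` views for traces,
islands, entropy distributions, networks and resilience curves.

## Worked example

Simulate a low-density-like island (150 cells/mm² on a 750 µm disc,
asynchronous firing at 12 events/min), run the whole pipeline, and read
off the circuit statistics:

```r
library(caislands)

res <- run_pipeline(pipeline_config(
  seed = 1,
  synthetic = list(diameter = 750, cell_density = 150, duration = 60,
                   rate = 12, regime = "asynchronous"),
  network = list(n_surrogate = 50, n_null = 200)))

res$activity
#> # A tibble: 1 × 5
#>   active_fraction event_rate sync_index n_cells n_active
#>             <dbl>      <dbl>      <dbl>   <int>    <int>
#> 1               1       12.5      0.101      66       66

glance(res$entropy)
#> # A tibble: 1 × 3
#>   mean_entropy      se n_cells
#>          <dbl>   <dbl>   <int>
#> 1        0.124 0.00333      66

res$network_metrics
#> # A tibble: 1 × 6
#>   fc_density char_path_raw char_path_scaled clustering_raw clustering_scaled
#>        <dbl>         <dbl>            <dbl>          <dbl>             <dbl>
#> 1     0.0676          2.98             1.02          0.119              1.92
```

All 66 cells are active, the detected rate (12.5 events/min) recovers the
generative 12 events/min, and synchrony is low (SI ≈ 0.10) — the signature
of a flexible, asynchronous circuit. The sparse functional graph has a
scaled path length near 1 (random-like integration). Switching the
generator to the bursting regime flips these: near-zero rate variance,
SI → 1, low entropy, and FC density near 1.

For injury experiments, enable the cascade-driven ablation arm:

```r
res <- run_pipeline(pipeline_config(
  seed = 2,
  synthetic = list(diameter = 900, cell_density = 150, duration = 60),
  injury = list(enabled = TRUE, p_spont = 2e-5, p_exc = 0.3)))
res$resilience_summary        # silencing / half-activity thresholds
autoplot(res$resilience_curve)
```

## Documentation

The methods vignette (`vignettes/island-pipeline.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
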