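---
title: "Models and methods behind svflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svflux)
```

svflux quantifies synaptic vesicle cycling from pHluorin-reporter movies and
ships a synthetic-data generator so the whole pipeline is testable without
external recordings. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic world does and does
not establish.

## The kinetic model of the vesicle cycle

Reporter molecules cycle between an acidic (quenched) vesicular pool and a
bright surface pool `S` (in vesicle-equivalents):

    dS/dt = k_exo(t) * V  -  k_ret(t) * S

* `V` (`pool_size`, default 100) is the releasable pool. It is
  **non-depleting by default**: the releasable pool size could not be
  measured in the system this emulates (alkaline-trapping dequenching fails
  there), so a constant-`V` linear model is the least-committal choice. A
  `finite_pool` option (`flux = k_exo * max(V - S, 0)`) exists but is off by
  default.
* `k_exo(t)` is coupled **piecewise linearly** to calcium around its
  baseline: facilitation `k_exo_basal + k_exo_ca_gain * (ca - baseline)`
  above baseline, proportional suppression `k_exo_basal * ca / baseline`
  below it. The underlying biology is only qualitative (release is
  suppressed with the calcium drop in OFF-type neurons and driven by calcium
  elevation otherwise); piecewise linearity is the simplest monotone
  coupling that reproduces both tonic suppression and stimulus-evoked
  facilitation.
* `k_ret(t)` is a **binary rate switch**: the basal retrieval
  (endocytosis + reacidification) rate `k_ret_basal = 1/18 s⁻¹` jumps to
  `k_ret_fast = 1/8 s⁻¹` for `accel_window` (default 60 s, constrained
  < 70 s) after any sample where calcium exceeds `accel_ca_threshold`. The
  evidence distinguishes only a temporary two-state difference (a basal
  ~18 s time constant, an ~8 s constant at elevated calcium, reverting in
  under 70 s), so a continuous calcium dependence would over-model it. The
  defaults are exactly those two measured time constants.
* Total fluorescence is `fluor_scale * S + dark_offset`; `dark_offset`
  stands for reporter in non-cycling neutral compartments, which brightens
  the baseline without ever changing.

Integration is a fixed-step explicit Euler scheme with ≥ 5 sub-steps per
frame (`dt ≤ 0.04 s` at 5 frames/s). All rates are ≪ 1/dt (`k·dt ≤ 0.005`),
so the discretization bias on fitted time constants is ~0.25% — well inside
every tolerance used; the steady state of the discrete map is exactly
`k_exo V / k_ret` regardless of step size.

## The calcium model

Calcium is phenomenological, in arbitrary units with baseline 1:

* OFF-type (AWC-like): first-order relaxation to `suppressed_level`
  (default 0.2) during a pulse and back to baseline after it, with
  `transition_tau = 0.5 s`; plus an additive post-pulse overshoot whose
  amplitude is a monotone non-decreasing function of pulse duration
  (configurable breakpoint map, default saturating around 2 a.u. at 60 s)
  and which peaks ~1 s after stimulus removal
  (`overshoot_rise_time = 1 s`) and decays with
  `overshoot_decay_tau = 10 s`. If another pulse begins while the overshoot
  is live, the remaining overshoot is quenched with `transition_tau`: odor
  re-application suppresses OFF-type calcium immediately. Without this
  truncation the dual-pulse protocol would carry elevated exocytosis into
  the second pulse and corrupt its decay fit — behavior the recordings do
  not show.
* ON-type (ASH-like): relaxation toward
  `baseline + gain(pulse duration)` during the pulse, and rapid return
  (`transition_tau`) afterwards. Lingering effects of the stimulus on
  retrieval are carried by the acceleration hold window, not by slow
  calcium decay; this mirrors the interpretation that the ON-type neuron's
  fast ~8 s retrieval is the state reached at stimulus-end calcium levels.

There is no absolute calibration between calcium units and exocytosis rate;
defaults were chosen once to reproduce trace shapes (tonic decline during
suppression, fast-then-slow recovery, dual-pulse acceleration), not absolute
amplitudes.

## The imaging scene

`render_movie()` draws each frame as
`background * (1 + bleach_slope * t)` plus Gaussian puncta whose **summed
peak amplitude equals** `fluor_total(t)`, a dim axonal ridge connecting the
puncta (`axon_line_frac`, default 15% of the mean punctum peak — reporter
between synapses is faint but continuous, and segmentation relies on that
continuity), integer random-walk drift, Poisson shot noise, Gaussian read
noise, and clipping to the 14-bit range. Drift steps are integer-rounded so
registration recovery can be exact, and the cumulative walk is reflected at
the bounds beyond which a punctum would leave the field of view, so any seed
yields a valid movie; the recorded trajectory is the walk as applied.

Scene defaults put the reporter well above the autofluorescent background
(puncta peaks in the thousands of counts against a background of ~40–100).
This is deliberately the *favorable* regime: the end-to-end recovery
guarantee (peak ΔF/F within 10% of ground truth) holds there because the
only bias term — background level inside the ROI, which Eq.-style
fluctuation-only correction intentionally does not remove — is a few percent
of `F_o`. With a dim reporter the same pipeline runs but recovery degrades
gracefully as `background / F_o` grows; that regime is exactly why
fluctuation-only background correction exists, and it is not covered by the
10% guarantee.

## Image pipeline choices

* **Registration** is whole-frame integer-shift cross-correlation (FFT)
  against the temporal-mean template, re-expressed relative to frame 1. No
  sub-pixel refinement: the generator drifts by integers, and the original
  workflow also shifted whole pixels. Borders exposed by shifting are
  filled with the frame median; the rectangle of never-filled pixels
  (`valid_box`) is propagated, and trace extraction clips every ROI to it —
  otherwise filled pixels masquerade as background and corrupt the bleach
  fit in long, drifting recordings. Frames shifted beyond 20% of an image
  dimension are flagged for discard (the in-plane analogue of discarding
  z-drift recordings; z is unmodeled).
* **Rolling ball** is the literal grayscale opening by a ball structuring
  element (erosion then dilation with hemispheric heights), floored at 0.
  Default radius 25 px for stand-alone use; the pipeline applies radius 10
  to the *temporal-mean* image only, because masks are its sole consumer
  and per-frame opening would dominate runtime for no analytic gain.
  Boundary convention: the structuring element is truncated at the image
  edge (±Inf padding), and the test-suite oracle uses the same convention.
* **Segmentation** thresholds the smoothed mean image with **Otsu computed
  on the sqrt scale**. Raw-scale Otsu lands between the bright puncta and
  everything else, cutting the axon into disconnected blobs; the sqrt
  transform compresses punctum peaks enough that the dim inter-punctum axon
  joins the foreground class. The largest 4-connected component is kept.
  A fixed threshold and a user-supplied mask remain available as the manual
  path.
* **Background ROIs** are rectangular strips beyond the axon bounding box:
  margin 4 px (fluorescence tails at 1.5 px punctum sigma are < 0.5% of
  peak at that distance), width 3 px, widened laterally by 3 px for better
  counting statistics. "Anterior" is by convention the lower-row-index
  side; `anterior_only = TRUE` implements the rule used for ASH-like
  recordings. Multiple background ROIs combine by unweighted mean.
* Quantification (ROI and background means) always runs on the registered
  **raw** movie; rolling-ball output is never quantified.

## Correction order and ΔF/F

The order is fixed and tested: bleach-detect → bleach-correct (background
only) → fluctuation-only background subtraction → ΔF/F.

* Bleaching is modeled as linear (OLS on time) and flagged only for
  **declines** of ≥ 0.5% of the mean per 2 min. Only the background series
  is ever detrended: this reporter class bleaches negligibly over these
  recordings, while tissue autofluorescence does not — detrending the
  signal would manufacture artifactual rises.
* `BGDelta(t) = BG(t) − min_t BG(t)` is subtracted from the ROI mean. This
  removes shared fluctuations while leaving the (information-free) static
  background pedestal in `F_o`, keeping ΔF/F's denominator away from zero.
* `F_o` is the mean of `F` over a 2 s window ending at the first stimulus
  offset (OFF-type) or onset (ON-type); for multi-pulse ON-type protocols
  the first pulse is always the reference (re-referencing per pulse is not
  done — the original convention references only the first stimulus). If
  `F_o ≤ f_o_floor` (default 10 counts ≈ 5× a typical read-noise SD — the
  published account gives no cutoff, only the instability argument) the
  trial is flagged `low_F_o`, its ΔF/F set to `NA`, and it is excluded from
  fitting.

## Decay fitting and model selection

`fit_decay()` minimizes least squares for
`y(t) = Σᵢ aᵢ e^(−t/τᵢ) + C`, `aᵢ, τᵢ > 0`, `C` free, via `L-BFGS-B` with
positivity bounds, ≥ 5 starts on a log-spaced τ grid spanning frame interval
to 3× the segment length, a parscale matched to the start, and a final
polish restart (L-BFGS-B's "abnormal line-search termination" routinely
fires *at* the optimum; the restart clears it, and residual QC does the real
gating). Time is re-zeroed to the segment start, making fits invariant to
the time origin. `K = 2·n_terms + 1` counts every fitted parameter
including `C`.

Quality control operationalizes "traces that could not be fit or did not
decay are removed": `converged = FALSE` when `r² < 0.2` or the fitted total
amplitude is below 3× the residual SD.

Model order (1–3 terms) is chosen by walking up in complexity and accepting
a more complex model only when `AIC_P` from the AICc difference exceeds
`complexity_threshold = 0.95`. The published analysis reports AIC_P values
but no decision cutoff; 0.95 is this package's choice, biased toward
parsimony, and is exposed as a parameter. Decay epochs come from the
protocol: the stimulus-on phase for OFF-type, the 20 s after offset for
ON-type; dual-pulse comparisons always fit the initial 20 s of each decay so
the two pulses are compared like-for-like.

The time derivative uses a **centered** 3-frame running average before
differencing (whether the original used centered or trailing averages is
unstated; centered is chosen and documented), with output scaled to
% per 200 ms regardless of frame interval.

## Responder classification

"Detectable response" is operationalized as a k·SD rule (default `k_sd = 3`
against the SD of a 2 s pre-stimulus baseline, searching a window from
stimulus onset to 20 s past offset). Note the statistics of a maximum over
several hundred frames: under pure noise this rule still fires in a sizable
minority of trials, so responder *fractions* are only meaningful relative to
a matched null — the test suite compares against an independently simulated
null of the same statistic rather than asserting a fixed false-positive
rate.

## What a green test establishes — and what it does not

The synthetic world emulates: two-pool kinetics with the two measured
retrieval states, stimulus-coupled calcium with duration-dependent
overshoot, punctate axonal geometry with a dim connecting ridge, linear
background bleaching, integer drift, Poisson + read noise, 14-bit clipping.
It does **not** emulate: z-drift, quantal/stochastic single-vesicle fusion,
ultrafast endocytosis timescales, pool depletion (by default), focus or
illumination drift, or a reporter dim enough to sit inside the
autofluorescence band. Pipeline guarantees verified on the simulator
therefore establish algorithmic correctness under the stated model, not
performance on every real recording; in particular the published per-trial
source data are not redistributable here, so the 18 s / 8 s acceptance
values are recomputed by running the full correction + fitting pipeline on
synthetic cohorts whose generative rates are those two published constants —
this validates the measurement chain (it would reveal any bias introduced by
correction, referencing or fitting), not the original measurements.

## Degenerate inputs and tie-breaks

Empty pulse lists are valid protocols (no reference window can be derived:
an explicit one must be supplied). Flat traces fail decay QC rather than
fitting a zero-amplitude exponential. Ties in model selection go to the
simpler model. `aic_probability()` is clamped to the open unit interval
where the logistic saturates in double precision (|Δ| ≳ 1500).
`correct_bleach()` on an unflagged trace is the identity. Backgrounds with
multiple ROIs average before, not after, the minimum in `BGDelta`, so the
minimum of the averaged series is exactly zero.
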