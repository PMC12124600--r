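---
title: "In vivo GnRH-neuron analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vivo GnRH-neuron analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrhephys)
```

GnRH neurons are the final output of the reproductive neural network:
scattered through the rostral preoptic area (rPOA), they drive the
pulsatile and surge modes of luteinizing hormone (LH) secretion that
organise the 4–5 day mouse estrous cycle. Recording them *in vivo* is
hard — their cell bodies are sparse, and a unit picked up on an
extracellular wire is anonymous until proven otherwise. This package
implements the analysis layer for such experiments: it scores the
chemogenetic/pharmacological responses that establish a unit's identity,
profiles basal firing across the cycle, and classifies functional
subtypes from 20-hour overnight recordings. Because raw recordings of
this kind are not publicly deposited, the package pairs every analysis
stage with a synthetic generator that reproduces the statistical
structure the analysis assumes, with ground-truth labels for
parameter-recovery testing.

## Time conventions

All analysis windows are offsets in seconds from session start
(float64); wall-clock anchors live only in the session metadata
(`session_clock`). Mice are housed with lights on 07:00–19:00; basal
sessions run 10:00–12:00, overnight sessions 14:00 until 10:00 the next
day (20 h). Rate bins are half-open `[t, t + delta)` so that a spike on
a boundary belongs to the later bin; this makes the conservation
identity `sum(rates) * delta = n_spikes` exact, which the tests assert.
Voltages are microvolts everywhere, because the detection threshold
convention (64 uV) is stated in microvolts.

## The point-process generator

Each simulated unit is an inhomogeneous Poisson process with intensity

`lambda(t) = base(t) * oscillation(t) * prod_k kernel_k(t)`

sampled by thinning, followed by a 2 ms absolute dead time. Two details
matter:

* **Dead-time compensation.** A Poisson process of intensity `lambda`
  censored by dead time `r` fires at `lambda / (1 + lambda * r)`. The
  sampler therefore rescales the requested profile as
  `lambda = f / (1 - f * r)`, so that configured rates are *observed*
  rates. Without this, a 9.10 Hz target would be recovered at ~8.94 Hz
  and every recovery experiment would carry a built-in ~2% bias.
* **Dead time of 2 ms** keeps waveform insertions non-overlapping when
  a raw trace is synthesised, and approximates a neuronal refractory
  period.

**Stage baselines** default to 5.76 (metestrus), 6.05 (diestrus), 9.10
(proestrus) and 4.55 Hz (estrus) — the reported population means for
2-h morning recordings. Between-recording variability is a
mean-preserving lognormal multiplier with CV 0.1: large enough that
stage summaries exercise a realistic spread, small enough that recovery
experiments measure the estimator rather than cohort luck. Real
cohorts scatter considerably more (reported SEMs of ~1 Hz at n = 11
imply a CV several times larger), driven by between-animal biology the
generator does not model; the jitter here emulates the stability of
repeated recordings from the same neurons.

**The surge envelope** for surge-subtype proestrus sessions is an
absolute piecewise-cosine profile: flat at 8.54 Hz until 15:00, a
smooth monotone rise to 17.12 Hz at midnight, and a fall to 6.59 Hz by
08:00. Cosine segments were chosen over linear ramps to be smooth and
monotone between the anchors; the anchors and rates are the reported
description of the population profile.

**Drug kernels** are multiplicative trapezoids on the baseline:
latency 0, rise 60 s, then a plateau and linear decay. Kiss-10 uses
plateau 600 s / decay 1200 s, matching its transient (~0.5 h) action;
CNO under hM3D(Gq) uses plateau 5400 s, matching its >90 min action.
The Kiss-10 gain defaults to 2.0 (peak tripling of the rate), which
lands simulated excitatory rates near +190%, inside the reported
174–396% range of worked examples; no source states a gain directly.
Under hM4D(Gi), prior CNO scales the second Kiss-10 gain by
`1 + (-0.8) = 0.2`, i.e. an 80% suppression of the response —
comfortably beyond the 40% identification criterion, as in the
reported examples (90.8% and 60% suppression).

**Basal-rhythmic units** oscillate sinusoidally with period 2 h and
amplitude 0.3x baseline on both recording days. Overnight recordings of
non-surge units are described qualitatively as showing "periodic
activity lasting hours" without numbers; these defaults are a stated
choice, not an inference, and both are exposed in `cohort_config()`.

What the generator deliberately does **not** model: LH/hormone
concentrations (only the neural firing consequences), electrode
geometry and volume conduction, waveform drift over 20 h, and
between-animal variance components. Passing recovery tests therefore
demonstrate that the pipeline measures what the generator encodes —
they do not validate the biology of real recordings.

## Identification statistics

The excitatory rate `E = 100 * (r_resp - r_base) / r_base` uses a
30-min baseline immediately preceding the scored injection and is
undefined (an error, and an unclassifiable unit in cohort runs) when
the baseline has no spikes — a ratio with a zero denominator is not a
number, and silently substituting one would manufacture verdicts.
For the second (CNO-containing) score the baseline is re-taken over the
30 min before that injection, so the residual tail of the first
response raises the second baseline slightly; with the default kernel
spacing (injections at 1800 s and 5400 s) the overlap is 60 s of
near-zero envelope and the effect is negligible.

Both dual criteria use strict inequalities at the 40% threshold, since
the defining rule is written as ">40%" throughout. For the Gi model the
first criterion is `E_kiss > 40` by default; the source only says
Kiss-10 must "activate firing", so `require_kiss_excitation = FALSE`
relaxes it to `E_kiss > 0`. This is a flagged assumption; with the
default kernels the two settings agree on every simulated unit.

## Surge-subtype classification

The overnight phenotype is described, not formalised: surge units
"exhibited changes in firing rate over the proestrus-estrus period but
not from diestrus-proestrus morning". The package operationalises it as
an **elevation index** (EI): the maximal mean rate over any contiguous
3-h window of the hourly-binned 20-h session, divided by the
14:00–15:00 anchor-hour rate. The index is a ratio, hence invariant to
uniform rate scaling (asserted as a property test), and is undefined on
a silent anchor hour. A unit is surge-like when `EI_proestrus >= 1.5`
and `EI_diestrus < 1.5`.

The threshold 1.5 sits midway between the two populations the
generator produces: surge units have an envelope peak/baseline ratio of
17.12 / 8.54 ~ 2.0 (hourly binning smooths the observed peak to ~1.95),
while basal-rhythmic units with a 2-h oscillation average out to EI
~0.9–1.3 after 3-h windowing. The 3-h window matches the several-hour
elevation being detected while suppressing single-bin noise; the
anchor hour is the earliest hour of the recording, before the ~15:00
surge onset. All three constants are arguments, not magic numbers.

## Spike detection and sorting

The preprocessing chain is the conventional one for single-wire
extracellular data: a zero-phase (forward–backward) 4th-order
Butterworth high-pass at 300 Hz, an amplitude threshold, trough
alignment, feature extraction, clustering, and cluster QC.

Numerical choices worth stating:

* **Sampling rate** defaults to 30 kHz. No acquisition rate is stated
  in the source material; 30 kHz is inferred from the 1/30 ms quantum
  of the reported waveform durations (0.3667 ms = 11 samples) and is
  configurable.
* **Threshold convention.** Events are negative-going local minima
  below `-theta` — extracellular somatic spikes are trough-dominant.
  Both a fixed `theta = 64` uV and a `2x_noise` mode
  (`theta = 2 * median(|v|) / 0.6745`) are provided, since the source
  describes both and their precedence is not stated; the sorting report
  records which was used.
* **Refractory merge.** Crossings within 1 ms collapse to the single
  largest-amplitude event, processed largest-first so the outcome does
  not depend on scan order.
* **Features.** First three principal components of the mean-centred
  snippets plus peak-to-peak amplitude, trough-to-right-peak width, and
  energy. The wavelet coefficients sometimes used alongside PCA are
  replaced by this explicit triple, since no wavelet family or level is
  specified anywhere; a wavelet option is out of scope.
* **Clustering** is k-means over k in 1..5 on the *raw* feature matrix
  (feature variance is separation signal; standardising inflates
  pure-noise dimensions and invites spurious splits), with k selected
  by average silhouette. Solutions containing a cluster smaller than
  the QC minimum are skipped during selection — they would be discarded
  anyway. A multi-cluster solution must reach silhouette 0.6; splitting
  a single template's noise cloud peaks near 0.5, and genuinely
  distinct templates score >0.9, so 0.6 separates the regimes with
  margin.
* **Cluster QC** discards clusters with fewer than 50 snippets or more
  than 1% of inter-event intervals under 2 ms. These thresholds
  operationalise the qualitative instruction to remove clusters
  "reflecting random variations"; they are not sourced numbers.

## Waveform duration features

`waveform_features()` measures left-peak-to-trough, trough-to-right-peak
and half-width — the time between the two points on the trough lobe at
`trough + (max - trough) / 2`, linearly interpolated between samples.
The half-width is measured on the dominant (trough) lobe; the citation
that defines the feature leaves the lobe unspecified, and the trough
lobe is the only one guaranteed to cross the level on both sides.

`calibrate_template()` inverts this: it builds a piecewise-linear
breakpoint waveform whose peaks and half-amplitude crossings are
breakpoints snapped to the sample grid, so the rendered template
reproduces target durations to within half a sample. At 30 kHz the
targets (0.3667, 0.4, 0.2) ms give exact 0.4 and 0.2 ms features, and
11 samples = 0.36667 ms for the left-peak-to-trough (the target itself
is off-grid by 0.001 sample). Infeasible targets — a half-width
reaching a peak, or breakpoints that collapse onto one grid point —
are errors, not best-effort renders.

## Statistics

Stage comparisons use a classical one-way ANOVA with Tukey HSD
(delegated to `stats::aov`/`stats::TukeyHSD`, and cross-checked in the
tests against a brute-force sums-of-squares oracle). The all-identical
degenerate input returns F = 0 explicitly, since floating-point
round-off otherwise produces a meaningless 0/0.

Hourly profile comparisons use per-timepoint Welch tests with a
hand-written Holm-Sidak step-down adjustment
(`p_adj(i) = 1 - (1 - p(i))^(m - i + 1)` along the sorted order, made
monotone, then unsorted); `stats::p.adjust` offers Holm but not the
Sidak variant. Contrasts are per-timepoint rather than pooled because
the annotated figures mark individual hours. The repeated-measures
omnibus fit is deliberately delegated to `stats::aov` with a subject
error stratum — the bespoke contract here is the contrast/adjustment
layer only. Significance is fixed at p < 0.05.

## Problem sizes used in the shipped experiments

The packaged recovery experiments mirror the recorded cohort sizes: 15
paired 20-h sessions (7 surge / 8 basal) for the subtype fraction, 54
units with 9 responders (Gi) and 43 with 6 (Gq) for identification,
11 proestrus and 12 estrus 2-h recordings for stage baselines, and 14
surge recordings for the hourly profile. The routine test suite runs
the cross-seed subtype-recovery property at 6 seeds and the sorting
recovery on 60-s two-unit traces; these sizes are the package's chosen
balance between statistical resolution and a test suite that stays
pleasant to run.

## Known limitations

* The generator's subtypes are cleanly separated by construction; it
  does not produce the borderline phenotypes (transient bursts near
  lights-off, day-to-day pattern changes within a unit) that real
  recordings show, so classifier performance on real data will be
  worse than the recovery experiments suggest.
* Sorting assumes stationary waveforms and a single wire per unit; no
  drift correction or multi-channel co-registration is attempted.
* The EI classifier requires the full 20-h, 14:00-anchored session
  design; other designs need re-anchoring via its arguments.
* `identify_cohort` treats units with undefined statistics as
  unclassifiable rather than negative, which slightly deflates the
  identified fraction when silent units are common.
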