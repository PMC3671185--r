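---
title: "Quantal analysis of miniature postsynaptic currents with minipsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of miniature postsynaptic currents with minipsc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minipsc)
```

# The problem

Miniature postsynaptic currents — the quantal responses to single-vesicle
release recorded under action-potential block — carry two separable kinds
of information. Their *rate* reports presynaptic function (release sites
and release probability); their *amplitude and kinetics* report the
postsynaptic receptor complement. Peak-scaled non-stationary fluctuation
analysis (NSFA) pushes the postsynaptic side further: from the
trial-to-trial variability of the decay it estimates the unitary channel
current `i` and the number of channels `N` open at the event peak, which
distinguishes "more channels" from "bigger channels" when amplitudes
change — or, as in developmental comparisons of GABAergic signalling,
shows that a frequency phenotype comes with *no* postsynaptic change.

`minipsc` implements the complete desk workflow — detection, kinetics and
quality control, NSFA, tonic-current estimation, network-burst
quantification, and the group statistics — together with a simulator whose
ground truth makes each stage falsifiable.

# The generative model

`simulate_trace()` models a voltage-clamp recording at sampling interval
`dt` (default 0.05 ms, i.e. 20 kHz) as follows. Events arrive as a Poisson
train with rate `rate` (events/s). Event `k` contributes an
open-probability time course

$$p_k(t) = s_k \, p_{peak}\, w(t - t_k), \qquad
  w(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r},$$

with `w` normalised so its sampled maximum is exactly 1, and $s_k$ a
log-normal per-event scale with coefficient of variation `amplitude_cv`
(mean 1, clipped so $s_k p_{peak} \le 1$) representing quantal amplitude
variability. Overlapping events add probabilities, clipped at 1. At every
sample, each of the `n_channels` channels opens independently with
probability $p(t)$ (a Binomial draw) and contributes `unitary_current` pA
of inward current; Gaussian noise of SD `baseline_sigma` and the tonic
offset(s) are added on top.

Independent Bernoulli gating per sample is deliberate: it makes the
variance–mean relation

$$\sigma^2(I) = iI - I^2/N + \sigma_b^2$$

hold *exactly* at every time point, which is precisely the identity NSFA
estimates. Real channel gating is temporally correlated (burst-like), which
colours the noise spectrum but leaves the instantaneous binomial identity
intact; reproducing that correlation is out of scope, and passing the
recovery tests here therefore says nothing about spectral properties of
real recordings.

Compound network bursts (GDP-like events) are phenomenological: each burst
sums `gdp_n_quanta` quantal events whose onsets are exponentially jittered
with time constant `gdp_envelope_tau` after the burst time. No claim of a
mechanistic network model is made — the generator exists so the burst
detector has a ground truth.

## Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `dt` | 0.05 | ms | 20 kHz acquisition |
| `tau_rise` | 0.3 | ms | gives a 10–90% rise of ~0.50 ms, the scale measured for neonatal GABAergic minis |
| `tau_decay` | 8 | ms | weighted decay of the kernel ≈ 9.1 ms, matching reported values |
| `n_channels` | 25 | — | reported channel counts ~22–26 |
| `unitary_current` | 2.5 | pA | reported unitary currents 2–2.6 pA |
| `p_peak` | 0.5 | — | plausible peak open probability; keeps mean peaks ~31 pA and the clipping warning silent at the default CV |
| `amplitude_cv` | 0.2 | — | typical quantal CV |
| `baseline_sigma` | 2 | pA | typical whole-cell noise |

One global seeded RNG drives each `simulate_trace()` call; identical seed
and configuration reproduce the trace bit for bit.

The simulator does **not** apply the 2 kHz acquisition low-pass filter to
its output: filtering would partially average the per-sample Bernoulli
noise and break the exact variance identity above. Consequences of that
choice are flagged below where they matter.

# Event detection

`detect()` slides a difference-of-exponentials template (default
τ~r~ = 0.5 ms, τ~d~ = 8 ms, 40 ms long, 2 ms baseline pad) along the trace
one sample at a time. At each offset the window is least-squares fitted by
`s·T + c`; the detection criterion is the Clements–Bekkers statistic
`DC = s / SE(s)`, where `SE(s)` is the regression standard error of the
fitted scale. `DC` is dimensionless, hence invariant to multiplying the
trace by a gain or adding an offset (both are tested properties).

Two practical details matter more than the textbook description:

- **Hysteresis.** Along the decay of a large event the criterion stays
  elevated for tens of milliseconds (a smooth decay correlates well with
  the long template), so taking every local maximum above threshold
  retriggers heavily. The detector instead accepts one event per criterion
  excursion above `rearm_fraction × threshold` (default 0.5 × 4) that
  reaches the threshold, at the excursion's maximum; a refractory period
  (default 5 ms, larger criterion wins) is applied on top.
- **Onset refinement.** The criterion argmax localises the template start;
  the reported onset is the last pre-peak baseline crossing. The peak used
  for this walk-back is found on a 0.25 ms boxcar-smoothed magnitude
  (single raw noise spikes later in the decay would otherwise masquerade
  as the peak), while the crossing itself is refined on the raw samples so
  the smoothing cannot smear it earlier.

The criterion threshold (4.0), refractory, template length and re-arm
fraction are configuration, not constants; the acquisition software used
in published work does not document its internal equivalents, so these
defaults are this package's own and are surfaced in `detection_params()`
and `build_template()`.

# Event kinetics and quality control

`measure_event()` takes the baseline as the mean over `baseline_window`
(default 5 ms) before the onset, the peak as the raw extreme of the
baseline-subtracted current within `peak_search` (default 10 ms), the
10–90% rise time from linearly interpolated crossings (first upward 90%
crossing; last 10% crossing before it — the other pairings are
noise-inflated), and the charge as the trapezoidal integral from onset to
the first *sustained* post-peak return to within one baseline SD of
baseline (0.25 ms-smoothed magnitude staying below for ≥ 0.5 ms; a single
noisy sample must not truncate the integral), capped at `charge_window`
(default 100 ms). The weighted decay is charge divided by amplitude.

QC flags rather than drops: rise times above `max_rise_qc` (1 ms —
electrotonically filtered events), below `min_rise_qc` (0.1 ms — faster
than the acquisition filter permits, hence noise artefacts), non-positive
charge, and baselines overlapping the previous event's integration window.

Two measurement biases are worth knowing about on synthetic data. First,
the raw-extreme amplitude carries the extreme-value bias of unfiltered
white noise (on the default simulator, tens of percent at high channel
noise), which deflates weighted decays in noisy runs; real band-limited
recordings are much less affected, and the noiseless oracles in the test
suite are exact. Second, that same bias couples measured rise time to
amplitude, which is why the `rise_vs_amp` member of the stability screen
(below) can reject stationary synthetic recordings once hundreds of events
are pooled.

# Peak-scaled NSFA

`stability_screen()` applies the standard admission test before pooling:
Spearman rank correlations of amplitude, rise and decay against event
number (time stability), plus rise-vs-amplitude and rise-vs-decay
(electrotonic filtering). All five p-values above `alpha` (default 0.05)
pass. Constant series (all ranks tied) have undefined ρ and are treated as
stable with a warning. On long stationary synthetic recordings the
`rise_vs_amp` test detects the measurement coupling described above; the
alignment step therefore accepts an `override` flag and the screen's
report is meant to be read, not used as a hard gate, on synthetic data.

`align_and_average()` aligns each event at its point of steepest rise —
the maximum of the 0.25 ms-smoothed derivative, refined to sub-sample
precision by parabolic interpolation — and extracts a window (default
−5 to +50 ms). The applied shift is rounded to the sample grid: fractional
resampling by linear interpolation shrinks white-noise variance by up to a
third (the average of $(1-f)^2 + f^2$ over fractional shifts $f$), which
was measured to bias the fitted background variance from 4.0 down to
2.6 pA² and the unitary current by −40%. Integer shifts keep the noise
process intact at the cost of ±half-sample alignment jitter, which is
negligible over a 0.3 ms rise.

`peak_scaled_nsfa()` scales the ensemble mean to each event's response at
the mean's peak and subtracts, accumulates the across-event variance of
the differences over the decay, bins it against the mean current in 50
equal-width amplitude bins (equal-occupancy available), and fits the
parabola by weighted least squares, reporting `i`, `N`, σ²~b~, the 3×3
parameter covariance, and γ = i/(E~m~ − E~rev~) in pS.

Numerical choices, each of which was validated against ground truth:

- **Windowed peak scaling** (`scale_window`, default ±0.5 ms). Scaling by
  the single peak sample injects that sample's noise variance into the
  difference waveforms as a spurious $+(I/I_{pk})^2\sigma^2(pk)$ term —
  for the default conditions that term almost exactly cancels the
  $-I^2/N$ curvature, making `N` unidentifiable. Averaging the scale over
  ±0.5 ms divides the spurious term by the window length; recovery of `N`
  then lands within a few percent.
- **Decay phase only, starting past the scale window.** Samples inside
  the scale window have part of their variance absorbed by the scaling
  itself; the rising phase is excluded because latency jitter violates
  the binomial model there.
- **Bin occupancy and weights.** At 20 kHz a 50-bin decay leaves only a
  handful of time points in the highest-amplitude bins; they carry the
  curvature and must not be discarded, so the default occupancy floor is
  2 points. Weights are `count / (2·σ⁴)` — the inverse large-sample
  variance of a sample variance — with σ⁴ taken from the previous fit
  pass (3 iterations) so sparse bins do not receive erratic weights from
  their own noisy variance estimates.
- **Degenerate fits** (no downward curvature, non-positive `i`, or too
  few populated bins) raise a condition of class `nsfa_fit_error`
  carrying the variance–mean table for inspection.
- `N` is reported as a real number; channel counts estimated from
  variance curvature are not integers.
- The identities σ²(0) = σ²~b~, σ²(iN) = σ²~b~ and apex excess variance
  i²N/4 hold algebraically for the fitted parabola and are asserted after
  every successful fit in the test suite (`nsfa_parabola()`).

At the validation scale used throughout (300 events, `i` = 2.5 pA,
`N` = 25, σ~b~ = 2 pA, CV 0.2, ten seeds), the full pipeline — simulate,
detect, QC, screen, align, fit — recovers the median unitary current
within ~3% and the median channel count within ~8%.

# Tonic currents and network events

`tonic_holding()` builds an all-point histogram per 10-s window (bin width
max(0.2 pA, Freedman–Diaconis)) and fits a Gaussian to the event-free side
of the mode — for inward synaptic events, the less-negative side — whose
peak is the holding current. One-sided fitting is what keeps the estimate
within ~0.1 pA even when frequent inward events skew the histogram.
Windows drifting more than `drift_limit` (2 pA) linearly, or whose fit
fails, are flagged and excluded. `drug_shift()` is the stable-window mean
difference, outward positive, and recovers injected offset steps (e.g.
the picrotoxin-revealed tonic current, or the two-step transporter-block /
channel-block protocol) to within the noise of the window means.

`detect_gdps()` low-passes the trace (2nd-order zero-phase Butterworth,
default 20 Hz), thresholds excursions at `threshold_sd` (4) robust SDs of
the filtered signal lasting ≥ `min_duration` (100 ms), extends each
excursion to its surrounding baseline crossings so the measured charge
covers the full burst, and merges excursions closer than `merge_gap`
(200 ms — a burst's quanta can briefly dip the filtered current back to
baseline). All GDP detector parameters are this package's own choices; the
source literature names no algorithm for burst identification.

# Group statistics

Pooled per-event values feed the distribution-level tools —
`cumulative_curve()` (probability k/n at the k-th order statistic) and
`ks_compare()` (two-sample Kolmogorov–Smirnov; exact p for small samples,
asymptotic otherwise) — because cumulative probability plots are built
from pooled events. Per-cell means feed `group_tests()` — unpaired
Student's t for two groups; one-way ANOVA with the classic pooled-variance
Bonferroni post test for more — because the field's `n` is cells, not
events. All tests are two-sided at α = 0.05. Whether pooled events or
per-cell medians should feed the K–S comparison is not documented in the
source workflow; pooling is the default here and per-cell summaries can
always be passed explicitly.

# Validation scales and limitations

The test suite validates at sizes chosen to make each check statistically
meaningful while keeping a full run in the low minutes: parameter recovery
over ten seeded 160-s pipelines; detector sensitivity at a 5× noise
operating point over hundreds of events and false positives over 20 × 100 s
of pure noise; K–S power at n = 200 per group over 100 seeds; Bonferroni
family-wise error over 200 null seeds.

Known limitations:

- The simulator's white (uncorrelated) channel gating and unfiltered
  output are idealisations; they are what make the variance identity exact
  and the oracles sharp, but amplitude measures on synthetic noisy traces
  carry an extreme-value bias that band-limited real data would not show
  at the same magnitude.
- Overlapping events are not deconvolved; they are flagged by QC and
  excluded from ensembles.
- ABF (vendor binary) reading is not implemented; traces enter as JSON
  bundles or two-column CSV.
- The GDP generator and detector are phenomenological; burst counts and
  charges are meaningful relative to the generator, not as a network
  model.
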