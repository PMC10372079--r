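---
title: "Methods: fractal-normalised HFO detection, phase synchrony and directed coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal-normalised HFO detection, phase synchrony and directed coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hfosync` analyses drug-induced high-frequency oscillations (HFOs,
~110–180 Hz) in multi-structure rodent LFP recordings: spectral detection
against the fractal background, zero-lag phase-synchrony and
phase-inversion mapping, spike entrainment, firing-rate modulation,
head-twitch detection, and spectral Granger causality. This vignette states
the models, the parameters that matter, the synthetic-data conditions used
for validation, and the numerical choices made where the design was open.

## Session model and epochs

A session holds channels × samples LFP in microvolts at `fs_lfp` Hz,
channel metadata (anatomical structure, hemisphere, electrode bundle,
stereotaxic coordinates), sorted spike units with mean waveforms, an
optional 3-axis head accelerometer in g, and drug metadata. All times are
seconds from recording start (float64); the injection time is stored
explicitly. The analysis epochs default to the recording convention of a
60-min baseline followed by injection: baseline −35 to −5 min, drug +30 to
+60 min relative to injection, both configurable. Epoch slicing keeps the
absolute start time of the slice in a `t0` attribute, which makes slicing
idempotent and lets spectral windows carry absolute centre times.

The on-disk container is a plain-text directory (`meta.json`,
`channels.csv`, `lfp.csv`, `accel.csv`, `units.json`) with the hierarchical
blocks documented in `?write_session`; round trips are lossless to 15
significant digits. Vendor formats (Neuralynx NCS, OpenEphys continuous)
are out of scope; adapters can populate the same structure.

Bipolar derivation pairs all unique same-structure electrodes
(lower channel id minus higher). The sign convention is arbitrary but
consistent; downstream quantities use power and phase-difference magnitudes,
so only consistency matters. Bipolar referencing cancels common-mode
(distant, volume-conducted) signal, which is why HFOs surviving it indicate
locally generated currents.

## IRASA and the rhythmicity spectrum

Spectrograms use 50%-overlapping 8-s windows (0.125 Hz grid), mean-detrended
and Hanning-tapered. For each window the fractal (arrhythmic) PSD is
estimated by irregular resampling: for each factor `h` in
{1.10, 1.15, …, 1.90}, the signal is resampled by `h` and by `1/h` and the
geometric mean `sqrt(S_h(f) · S_{1/h}(f))` is taken; a power-law spectrum is
invariant under this operation while rhythmic peaks are displaced to `f·h`
and `f/h` and suppressed by the median over `h`. Rhythmicity is then
`S_dB(f) = 10·log10(S(f)/S_fractal(f))` ("dB_fractal"): 0 dB means no
excess over the fractal background, and the measure is invariant to
amplitude scaling of the signal.

Two numerical choices matter here:

* **Resampling is exact FFT (sinc) resampling** — spectrum truncation as an
  ideal anti-alias filter, zero-padding as an ideal interpolator. Cubic
  spline and windowed-FIR polyphase resampling both attenuate frequencies
  approaching Nyquist enough to bias the fractal estimate low by >1 dB at
  the top of the analysis band; the FFT method is their ideal-filter limit
  and shows no measurable bias (the flatness property below).
* **The h-resampled PSDs are smoothed ~1 Hz across frequency before the
  geometric mean.** A single-taper periodogram value is exponentially
  distributed, and `E[sqrt(AB)] < sqrt(E[A]E[B])` biases the fractal
  estimate low by ~1.4 dB for raw periodograms. The fractal component is
  smooth by definition, so a short running mean across frequency is
  principled and removes the bias; the total PSD `S` is never smoothed, so
  peak localisation keeps the native 0.125 Hz grid.

The analysis band is capped at `fs/(2·max(h))` so all resampled spectra are
defined. Averaged spectra combine `S` and `S_fractal` in the linear power
domain across windows and recompute `S_dB` from the means. On 600 s of pure
1/f² noise the median |S_dB| over 20–200 Hz is ~0.4 dB, and an added 150 Hz
rhythm is localised to the exact grid frequency.

## HFO detection and prevalence

Each (structure-averaged) windowed rhythmicity spectrum is fitted over
70–200 Hz with a Gaussian peak on a linear trend:

y(f) = a1·exp(−((f − a2)/a3)²) + a4·f + a5

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). The fit band is
wider than the admissible peak range (90–170 Hz) so the linear term has
leverage; it is configurable. Initialisation puts `a2` at the largest
trend-corrected value inside 90–170 Hz, the trend from a line through the
band edges, `a3 = 5` Hz; five multi-starts jitter `a2` by {0, −10, +10, −5,
+5} Hz and the best residual sum of squares wins (deterministic, no RNG). A
window is a detection when all of: R² > 0.2, 2 < a1 < 100 dB,
90 < a2 < 170 Hz, 1 < a3 < 20 Hz, −1 < a4 < 1, −10 < a5 < 10 — strict
inequalities, treated as the operative definition and configurable. The
median of `a2` over detected windows defines the recording's HFO frequency
and seeds the narrowband phase analysis.

Detection rates per (session, structure, condition) are classified:
*persistent* when >1/3 of sessions exceed a 0.9 rate; else *prevalent* when
>1/3 exceed 0.5; else *absent* when <5% of sessions exceed 0.05; else
*occasional*. "Absent" is evaluated after the first two so that
"occasional" is exactly the remainder class. Structure-averaged spectra
(pairs averaged before fitting) are the default detection input; per-pair
fitting is available.

## Instantaneous phase and amplitude

Monopolar channels are filtered with a 64th-order Hamming-windowed FIR
bandpass at the median HFO frequency ±5 Hz, applied forwards and backwards
for exact zero phase, then Hilbert transformed (FFT construction). The
phase convention puts the oscillation **trough at 0** (a cosine peak maps
to π), implemented by adding π to the analytic argument. Note that at this
filter order the transition band, not the ±5 Hz design band, determines the
effective bandwidth; this is inherited from the method's stated filter and
is what lets ~50 ms envelopes through.

Amplitude autocorrelations (60-s windows, averaged; channels admitted only
when their median amplitude exceeds 15 µV) summarise spindle length as the
FWHM of the central peak, interpolated at the half-maximum crossing.
Amplitude cross-correlations between channel pairs are summarised by their
peak value. Pairwise phase statistics are circular summaries of
`φ_i − φ_j`; by default samples are gated to times when both channels
exceed their own median amplitude (suppresses noise-phase samples; turn the
gate off for the literal whole-period estimate). A pair is *phase inverted*
when |Δφ| > 3π/4 and κ > 1. Structure-level lag maps take all pairs linking
a structure to the reference structure, drop pairs with resultant length
below 0.5 (unstable estimates), orient the sign so positive means the
structure leads, and report the median with a Wilcoxon signed-rank test
against zero.

Circular statistics use the arg/modulus of the mean resultant; κ comes from
the piecewise Best–Fisher inversion (branches at r = 0.53 and 0.85, capped
at 10³), with no small-sample bias correction (flagged here: reported κ of
small samples are slightly inflated). The Rayleigh p-value uses the
standard finite-n corrected approximation. Angles always wrap to (−π, π],
ties at ±π resolving to +π.

## Spike analysis

Rates are binned at 10 s and z-scored by the baseline mean and SD; units
with zero baseline SD are excluded with a reason code. Per-unit modulation
is a Wilcoxon rank-sum test on the binned counts at α = 0.01 (up/down by
the direction of the median difference); population-level excess of
modulated units is a binomial tail test at the per-tail chance level α/2.

Waveform features — valley width and peak width as interpolated FWHM, and
peak-to-valley time — feed a fuzzy k-means (k = 2, fuzzifier m = 2, z-scored
features, 10 restarts with fixed seeds, best objective kept). Units with
maximum membership ≤ 0.75 are unclassified ("X"); the narrow-spiking
cluster (smaller mean peak-to-valley) is the putative interneuron class.
One caveat the tests encode: when the data contain no real cluster
structure, z-scoring inflates whatever jitter exists, and the fuzzy split
still labels points near its arbitrary centres confidently — abstention
rises sharply but does not reach 100%.

Spike phases are evaluated on all same-structure channels *except the
unit's own electrode* (spike waveforms leak into the local LFP and would
bias the phase estimate); the per-spike phase is the circular mean across
eligible channels (per-channel mode available). Fits use the von Mises
moment estimator; entrainment is Rayleigh p < 0.001; fits with κ > 0.1 are
marked includable for strength summaries. The minimum spike count defaults
to 50 (unstated in the source method; configurable).

The Bhattacharyya distance between population-modulation clusters uses the
Gaussian closed form from sample moments,
`D_B = (1/8)(μa−μb)ᵀΣ̄⁻¹(μa−μb) + (1/2)·ln(|Σ̄|/√(|Σa||Σb|))`.

## Head-twitch detection

The mediolateral acceleration is resampled to 200 Hz (anti-aliased), a
100th-order FIR bandpass 8–32 Hz is applied forwards and backwards,
rectified, and convolved with a unit-area Gaussian (σ = 50 ms, truncated at
±4σ; unit area keeps the index in g). Peaks above 0.4 g are picked greedily
in descending height with a 1-s dead time, so twin events closer than 1 s
merge into the larger one. Detector evaluation uses greedy one-to-one
matching within ±0.2 s; both per-detection and per-minute false-positive
rates can be derived from the returned counts, since the natural
denominator is ambiguous.

A consequence of unit-area smoothing worth stating: the index peak of a
burst is bounded by (integral of |bandpassed burst|) × (kernel peak), so a
0.8 g burst must last ≳150 ms to cross the 0.4 g threshold at all. The
synthetic twitch default is therefore a 300 ms Hanning-windowed 15 Hz burst
at 0.8 g — within the reported range of head-twitch durations — rather than
a shorter burst that no unit-area detector at this threshold could see.

## Spectral Granger causality

Bipolar pairs are fitted with a bivariate VAR of order 5 on 500-ms windows
pooled as trials: each window is linearly detrended and contributes only
regression rows whose lags stay inside the window, and one coefficient set
is estimated from all rows by least squares (the pooled-trials convention;
single-window fitting is a trivial restriction). The residual covariance
comes from the pooled residuals. Geweke's measure is computed from the
transfer function `H(f) = (I − Σ_k A_k e^{−2πifk/fs})⁻¹`:

f_{x→y}(f) = ln( S_yy / (S_yy − (Σ_xx − Σ_xy²/Σ_yy)·|H_yx(f)|²) )

on a 1 Hz grid, both directions, after a stability check (companion
spectral radius < 1). Peaks are local maxima on the analytic spectrum with
no smoothing; only the highest is analysed, retained when it reaches 0.2.
Band summaries report the median qualifying peak height per directed
structure pair (missing when no pair qualifies), plus mean causality in
the HFO band (HFO frequency ±10 Hz) and the gamma band (25–75 Hz). Signals
are analysed at 1 kHz so a 5th-order model can express ~150 Hz structure
within 500-ms windows; the rate is configurable. Only bivariate causality
is implemented; conditional multivariate GC is out of scope.

## The synthetic-data generator

`gen_session()` emulates the statistical structure the analysis assumes,
with full ground truth. Conditions and defaults:

* **Sampling**: LFP 2000 Hz (the offline LFP rate of the acquisition
  system emulated; at 1000 Hz the 64-tap narrowband filter smears amplitude
  envelopes by ~17 ms SD, visibly broadening spindle-length estimates).
  Sessions default to 120 min with injection at 60 min.
* **Background**: 1/f² fractal noise at 5000 µV²/Hz (1 Hz), i.e. ~0.3
  µV²/Hz at 130 Hz and a total SD of ~300 µV — typical rodent LFP. Power
  below 0.1 Hz is flattened. Gamma is band-limited 30–80 Hz noise at 3 µV
  RMS (8 µV in the amphetamine preset, which has no HFO).
* **HFO**: carrier 127 Hz (5-HT2A preset) or 143 Hz (NMDA preset), with a
  shared Ornstein–Uhlenbeck frequency wander (SD 3 Hz, τ = 2 s) that
  produces cross-structure frequency co-modulation by construction. The
  envelope is a train of Gaussian bumps at 12 spindles/s;
  `envelope_fwhm = 50 ms` is the spindle length in its *operational* sense
  — the FWHM of the envelope autocorrelation — so the bump SD is
  `fwhm/(2.355·√2)` (a literal 50 ms bump would put the autocorrelation
  FWHM at ≥71 ms by construction). Amplitude 80 µV represents channels
  with clear HFOs (median analytic amplitude ~18 µV, above the 15 µV
  inclusion screen). Spindle onsets are thinned to 5% before the
  injection, making baseline HFOs sporadic and drug-epoch HFOs persistent.
  Per-electrode coupling gains are spread evenly over [0.6, 1.4] within a
  structure — electrodes sample the local dipole at distinct depths — which
  guarantees that bipolar derivation retains the local HFO instead of
  cancelling it. Envelopes are shared exactly within a structure and mixed
  with a common component across structures so their correlation equals
  the configured ρ (default 0.8). Per-channel phase lags, plus π for
  channels listed as inverted, define the ground-truth lag map.
  Theta-periodic envelope modulation is not generated (it was a
  some-electrodes observation; the autocorrelation machinery detects it
  when present, as the tests show with a constructed 7 Hz modulation).
* **Spikes**: inhomogeneous Poisson by thinning with a 1-ms dead time, rate
  = base_rate × envelope gating × von Mises gain
  `exp(κ·cos(φ−μ))/I₀(κ)` against the channel's true trough-zero phase, so
  the realised phase distribution is von Mises with the configured (μ, κ)
  in expectation and entrained firing happens when the oscillation is
  present. Defaults μ = −2 rad (≈2 rad before the trough), κ = 0.3.
  Class-specific multiplicative rate factors apply after the injection
  (NMDA preset: PC ×0.6, IN ×1.6). Waveform templates are negative-first
  with narrow (IN) or broad (PC) widths and 5% parameter jitter.
* **Accelerometer**: 1/f colored noise at 0.1 g SD per axis; twitches are
  300-ms Hanning-windowed 15 Hz bursts at 0.8 g on the mediolateral axis,
  placed ≥2 s apart after the injection (1/min in the 5-HT2A preset).

What the generator does *not* emulate: biophysical HFO generation,
non-sinusoidal oscillation shape, behavioural state transitions, electrode
drift, spike-sorting errors, or volume-conducted far fields beyond the
common-mode term. Passing tests therefore demonstrate that the estimators
recover known ground truth under the assumed signal model — not that the
model captures every property of in-vivo data.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use scaled recordings chosen to
keep every property measurable with comfortable statistical margins:
600 s of 1/f² noise for spectral flatness; 100 replicates for peak-model
recovery at 0.5 dB noise; 300-s eight-channel sessions for phase-lag maps;
20–25-min sessions for detection rates, entrainment (≈5000 spikes per
unit) and head-twitch detection (20 events); 10⁴ replicates for the
Rayleigh and Wilcoxon calibrations; 10⁵ exact-moment samples for the
Bhattacharyya closed forms; and 60 s of VAR simulation for Granger
direction and the analytic-oracle comparison. Epoch windows scale with the
session (e.g. drug = +1 to +11 min for a 20-min session); the defaults
remain the full-length convention.

## Known limitations

* κ estimates are not bias-corrected for small n.
* The detector's strict-inequality criteria mean a parameter landing
  exactly on a printed bound does not detect; this is the operative
  reading of the published bounds.
* Granger causality is bivariate; common-input effects between two
  structures driven by a third are not resolved.
* The pipeline treats hemispheres pooled per structure by default; the
  channel table retains hemisphere labels so split analyses remain
  possible.
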