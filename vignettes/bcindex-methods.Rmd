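---
title: "Methods: resting-EEG individualization parameters for BCI users"
author: "bcindex developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-EEG individualization parameters for BCI users}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcindex)
```

## The problem

Motor-imagery brain-computer interfaces (BCIs) decode the
desynchronization of sensorimotor alpha/beta rhythms. Users differ
substantially in both *where in frequency* their rhythms sit and *how
much* rhythm they have to modulate; a fraction of users cannot control a
motor-imagery BCI at all. Two pre-training parameters address this:

1. the **individual alpha frequency (IAF)**, used to center narrow,
   subject-specific alpha bands instead of the fixed 8–12 Hz convention;
2. a **neurophysiological aptitude predictor**, a scalar that quantifies
   how far the resting spectrum at the central electrodes rises above
   its aperiodic background — larger values indicate a stronger
   sensorimotor rhythm and a better prognosis for motor-imagery control.

`bcindex` computes both from two ~3-minute resting recordings
(eyes closed, EC, and eyes open, EO), and optionally validates the IAF
against a cardiac-derived theoretical value.

## Spectral substrate

All paths start from Welch power spectral densities with **4-second
epochs** (0.25 Hz resolution at the typical 128 Hz sample rate), Hann
taper, 50 % overlap, per-epoch constant detrending, density scaling
(µV²/Hz), with any trailing partial epoch discarded. Only the epoch
length is dictated by the estimation procedure itself; taper, overlap
and detrending follow common EEG practice and are exposed as
configuration (`welch.*` keys). Density scaling is used so that the
power-law term of the spectral model keeps a stable meaning across
sample rates. The implementation was checked bin-by-bin against an
independent Welch implementation (`scipy.signal.welch`) and against the
closed-form variance of a sinusoid (Parseval).

## IAF from EC−EO reactivity

Occipital alpha power is strongly enhanced by eye closure. For each of
the occipital channels O1 and O2 the package forms the raw difference
spectrum PSD(EC) − PSD(EO) and takes the frequency of its maximum
inside the search band (default 7–14 Hz; the band is configurable
because resting alpha peaks occasionally sit at its edges). The IAF is
the **arithmetic mean of the per-channel peak frequencies** — peak
*frequencies*, never amplitudes — and the two individualized alpha
sub-bands are (IAF−2, IAF) and (IAF, IAF+2) Hz, each exactly 2 Hz wide,
following the recommendation to individualize alpha within narrow
~2 Hz bands.

**Validity.** An IAF only makes sense when the recording actually shows
alpha reactivity. A necessary condition is a strictly positive EC−EO
difference at the peak; but because the *maximum* of a noisy difference
spectrum over ~29 bins is positive almost surely even with no
systematic reactivity, positivity alone never rejects anything. We
therefore additionally require the positive peak to **dominate the
largest negative excursion** within the search band: a pure-noise
difference spectrum is sign-symmetric, so this rejects roughly half the
channels per run when there is no reactivity, while a genuine alpha
bump passes easily. An invalid result carries `iaf_hz = NA` and a
diagnostic naming the offending channel — never a silent 0. Ties at the
peak break toward the lower frequency, deterministically. An optional
3-bin moving average of the difference spectrum (`iaf.smooth`) is off
by default.

## The aptitude predictor

The EO spectrum at C3 and C4 is fitted over 2–35 Hz (excluding DC/drift
below and line noise above; the band is configurable) with

$$P(x) \;=\; k_1 \;+\; A_2\,x^{k_2} \;+\;
  \frac{A_3}{\sigma\sqrt{2\pi}}\,
  e^{-(x-\mu)^2/2\sigma^2}
  \;\left[+\; \frac{A_{3b}}{\sigma_b\sqrt{2\pi}}\,
  e^{-(x-\mu_b)^2/2\sigma_b^2}\right],$$

a constant floor plus aperiodic power law plus one Gaussian
probability-density peak for the alpha (mu) rhythm and, by default, a
second one for its beta harmonic (`two_peaks = TRUE`; the beta center
is initialized at twice the alpha center and bounded to 15–30 Hz).
The fit is bounded nonlinear least squares on **linear power** (the
model is stated on linear power; a dB option exists via `log_power`),
run with `stats::nlminb` under the bounds $k_1 \in [0, \max P]$,
$A_2 \ge 0$, $k_2 \in [-3, 0]$, $\mu \in [7, 14]$ (or IAF ± 2 when an
IAF is available — the pipeline passes a valid IAF automatically),
$\sigma \in [0.25, 4]$ Hz. Four starts are tried: the data-driven
initialization, two with the alpha center jittered ±1 Hz, and a
*peakless* start ($A_3 = 0$) so that a spectrum with no rhythmic peak
is fitted honestly by the power law alone. The best (lowest-SSE)
solution wins; `converged` reflects the optimizer status and optimizer
failure on all starts yields `converged = FALSE` rather than an error.

The **primary index** is $\max(\text{model} - \text{power law})$ over
the fit band; for a single noiseless Gaussian peak this equals
$A_3/(\sigma\sqrt{2\pi})$, which the tests verify to 4 significant
figures. When the fit did not converge, or the fitted model degenerates
onto the power law (primary index below `degenerate_tol` — default 1 %
— of the in-band PSD maximum), the **fallback index**
$\max(\text{PSD} - \text{power law})$, floored at 0, is reported
instead, and the method actually used (`model_minus_powerlaw` vs
`psd_minus_powerlaw`) is always recorded in the report. The degeneracy
threshold is our decision; the original behavior it emulates (a fitted
model visually overlapping the power law) was described but never
quantified.

Per-channel indices for C3 and C4 are the primary outputs; the reported
`combined` value is their plain mean and is labeled as plumbing, not as
part of the method.

## Cardiac validation path

A harmonic brain–body coupling model ties the centers of the canonical
EEG bands to the cardiac frequency $s$ (Hz):
$f_d(i) = s \cdot 2^i$, with $i = 1..5$ giving the delta, theta, alpha,
beta and gamma centers; $i = 3$ (i.e. $8s$) is the **theoretical IAF**.
At $s = 1.25$ Hz (75 bpm) the series is 2.5, 5, 10, 20, 40 Hz.

The chain: the single-lead ECG is zero-phase high-pass filtered at
0.1 Hz; QRS complexes are detected with the Pan–Tompkins algorithm
(5–15 Hz band-pass, five-point derivative, squaring, 150 ms
moving-window integration, adaptive signal/noise thresholds with a
200 ms refractory period, 360 ms T-wave slope discrimination, and
missed-beat search-back at 1.66× the running RR average — the original
algorithm's constants, all exposed as arguments); NN intervals outside
0.3–2.0 s (30–200 bpm) are discarded as artifacts (our cleaning rule;
the number of discards is reported); the surviving intervals are
averaged and inverted to give $s$; and $f_d(3)$ is the theoretical IAF.

All filtering in the package is zero-phase and FFT-domain with
raised-cosine transition bands. This choice (over forward–backward IIR
filtering) keeps R-peak timing exactly unbiased and avoids hand-rolled
filter design; its edge effects are circular-wraparound at the very
ends of the record, negligible for the ≥ 10 s traces the preprocessor
accepts.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable offline; they are
seeded and bit-reproducible, and restore the caller's RNG state.

* **EEG pairs** (`generate_eeg_pair`): each channel is
  $1/f^{\beta}$-shaped Gaussian noise (β = 1, SD 5 µV) plus a
  band-limited alpha oscillation plus white sensor noise (SD 1 µV).
  The alpha component is white noise shaped by a **Gaussian spectral
  profile** (FWHM = 2 Hz) — not a pure sinusoid, so the EC−EO bump has
  realistic width, and not a flat-top band-pass, whose plateau would
  put the spectral argmax anywhere in the passband rather than at the
  center, which no physiological alpha peak does. Occipital channels
  are reactive (alpha SD 4 µV EC vs 1 µV EO, giving a reactivity peak
  an order of magnitude above the background, comfortably above the
  SNR ≥ 3 regime the recovery tests assume); C3/C4 carry a
  non-reactive 11 Hz sensorimotor peak (SD 2.5 µV). Default length
  180 s at 128 Hz, the 3-minute resting protocol.
* **Model PSDs** (`sample_model_psd`): direct evaluation of the
  spectral model with optional multiplicative Gaussian noise, for fit
  and recovery testing.
* **ECG** (`generate_ecg`): a morphological beat template (narrow R
  spike with Q/S deflections, smaller P and T bumps) at a fixed rate
  with optional Gaussian timing jitter, returning ground-truth R-peak
  times for scoring. It is morphological, not biophysical.

None of the generators simulate eye blinks, muscle artifact, electrode
drift, volume conduction, or non-stationary alpha. A green test
therefore establishes that the algorithms are implemented correctly on
signals with the assumed statistical structure — not that they are
robust to real-world artifacts, which the tool (like the procedure it
implements) expects to have been handled upstream.

## Numerical choices and degenerate inputs

* Welch requires an integer epoch in samples and at least two epochs;
  violations are errors with the required minimum stated.
* PSD grids are never resampled: IAF estimation refuses mismatched
  grids outright.
* The fit requires ≥ 20 bins in band and a non-zero PSD; an all-zero
  channel is a data error, while optimizer failure is a recorded
  non-convergence.
* `which.max` tie-breaking makes every peak pick deterministic (lowest
  frequency wins).
* Reports are byte-identical for identical inputs and configuration;
  figures are excluded from that guarantee.
* MAT-file and EDF/BDF input are not supported (delimited text only);
  a `.mat` path is rejected with a pointer to the text format.

## Known limitations

* The IAF method needs genuine EC/EO reactivity; low-alpha subjects
  yield `valid = FALSE`, by design, and the predictor then runs without
  an IAF-informed initialization.
* The predictor's correlation with real BCI performance cannot be
  established from synthetic data and is not claimed anywhere in this
  package; the acceptance surface covers the computation, not the
  clinical claim.
* The cardiac path assumes sinus rhythm; arrhythmia handling and HRV
  analysis are out of scope.
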