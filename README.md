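# bcindex

Resting-EEG individualization parameters for brain-computer-interface
(BCI) users: the **individual alpha frequency (IAF)** and a
**neurophysiological predictor** of motor-imagery BCI aptitude, with an
optional ECG-based validation of the IAF.

## Who this is for

Motor-imagery BCIs decode the event-related desynchronization of
sensorimotor alpha/beta rhythms, but users differ in where their
rhythms sit in frequency and in how much rhythm they have to modulate —
some cannot control such a BCI at all ("BCI illiteracy"). Before
investing in training, two parameters computed from a few minutes of
resting EEG help individualize the system and triage users:

1. **IAF** — from paired eyes-closed (EC) / eyes-open (EO) recordings,
   the peak of the occipital (O1, O2) reactivity spectrum
   PSD(EC) − PSD(EO), averaged over the two channels. It centers the
   two individualized alpha sub-bands (IAF−2, IAF) and (IAF, IAF+2) Hz.
2. **Predictor** — the EO spectrum at C3 and C4 is fitted with

   P(x) = k₁ + A₂·x^k₂ + A₃/(σ√2π)·exp(−(x−μ)²/2σ²) [+ beta peak],

   a constant + aperiodic power law + Gaussian peak(s), and the index
   is max(model − power law) over the fit band. If the fitted model
   degenerates onto the power law (or the fit fails), the fallback
   max(PSD − power law) is reported instead, and the method used is
   recorded. Larger index ⇒ stronger sensorimotor rhythm ⇒ better
   aptitude prognosis.
3. **Cardiac validation (optional)** — from a single-lead ECG:
   high-pass 0.1 Hz, Pan-Tompkins QRS detection, NN intervals averaged
   and inverted to the cardiac frequency s, and the harmonic structure
   f_d(i) = s·2^i evaluated at i = 3 gives a theoretical IAF (8·s) to
   compare with the empirical one. At s = 1.25 Hz (75 bpm) the series
   f_d(1..5) is 2.5, 5, 10, 20, 40 Hz — the canonical band centers.

Seeded synthetic generators (EC/EO EEG with reactive alpha, model-based
PSDs, morphological ECG) make the whole pipeline testable offline.

## Worked example

```r
library(bcindex)

pair <- generate_eeg_pair(synth_eeg_config(seed = 42))   # 180 s EC/EO at 128 Hz
ecg  <- generate_ecg(duration_s = 120, sample_rate_hz = 128, bpm = 75)

report <- run_pipeline(pair$eo, pair$ec, ecg = ecg$signal, out_dir = "out")
print(report)
#> <bci_report>
#> <bci_iaf> IAF = 10.38 Hz (peaks: O1 10.50, O2 10.25); bands 8.38-10.38 / 10.38-12.38 Hz
#> <bci_predictor>
#>   C3: 3.759 (model_minus_powerlaw)
#>   C4: 4.274 (model_minus_powerlaw)
#>   combined (mean): 4.016
#> <bci_cardiac> 150 R peaks, s = 1.250 Hz (75 bpm), theoretical IAF = 10.00 Hz
```

Reading the output: the generator placed a reactive alpha bump at
10.25 Hz, and the per-channel reactivity peaks (10.50 and 10.25 Hz)
average to an IAF of 10.38 Hz — within one 0.25 Hz frequency bin of the
truth — from which the two 2-Hz alpha sub-bands follow. Both central
channels were fitted successfully (`model_minus_powerlaw`, no
fallback), with indices ≈ 3.8–4.3 µV²/Hz of peak elevation above the
aperiodic background. The 75 bpm ECG gives a cardiac frequency of
1.25 Hz and hence a theoretical IAF of 8 × 1.25 = 10 Hz, consistent
with the empirical estimate. `out/` now contains `report.json`,
`iaf.png` and `predictor.png`.

The same run from the shell, using delimited-text recordings:

```sh
Rscript -e 'bcindex::bcindex_main()' synth --out demo --seed 42 --duration 180
Rscript -e 'bcindex::bcindex_main()' run --eo demo/synthetic_eo.txt \
    --ec demo/synthetic_ec.txt --fs 128 --ecg demo/synthetic_ecg.txt --out demo/out
```

Input files are numeric delimited text (comma, tab or whitespace;
channels in rows or columns — the longer axis is taken as time), with
an optional header row of channel labels; headerless 64-row files get
the shipped BioSemi 10/10 labels, and `--fs` supplies the sample rate.
All tunables (Welch epoch, IAF search band, fit band, degeneracy
threshold, NN plausibility window, ...) live in a flat key = value
config file; see `inst/extdata/default_config.toml`.

## Scope notes

EDF/BDF and MAT input, artifact rejection, re-referencing, event-related
IAF methods, and any claim of validated correlation between the index
and real-user BCI performance are out of scope. See
`vignettes/bcindex-methods.Rmd` for the full methods account.
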