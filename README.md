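# pulseHHT

Hilbert–Huang analysis and random-forest recognition of arterial
pressure-pulse waveforms.

Radial-pulse recordings are short, nonstationary, quasi-periodic pressure
signals. Fourier and wavelet descriptions of them impose fixed bases; the
Hilbert–Huang approach instead decomposes each recording adaptively and
asks, band by band, how much energy and how much irregularity the signal
carries. pulseHHT packages that pipeline for researchers comparing two
cohorts of pulse recordings (e.g. a patient group against controls):

1. **EMD** — from-scratch empirical mode decomposition by cubic-spline
   envelope sifting (mirror boundary extension, Cauchy stopping rule),
   yielding intrinsic mode functions `c_i(t)` with
   `s(t) = Σ c_i(t) + r_n(t)` exact to floating point.
2. **Hilbert traces** — per-mode analytic signals
   `z_i(t) = c_i(t) + j ĉ_i(t) = a_i(t) e^{jφ_i(t)}`, instantaneous
   frequency `w(t) = dφ/dt / 2π`, and a binned Hilbert spectrum `H(w, t)`.
3. **Features** — 7-level vectors of normalized mode energy
   `E'_i = E_i / Σ_j E_j`, `E_i = ∫ c_i(t)² dt`, and of per-mode sample
   entropy `SampEn(m, r, N) = −ln(A^m(r) / B^m(r))` with `m = 2`,
   `r = 0.2 · sd` (Chebyshev distance, self-matches excluded).
4. **Statistics** — Mann–Whitney rank-sum comparison of every level
   between cohorts (mean ranks, two-sided p), with the interference-prone
   entropy levels 1–2 excluded by default.
5. **Recognition** — a 500-tree random forest
   (`mtry = ⌊√m_all⌋`, unpruned, bootstrap resampling) evaluated by
   repeated stratified cross-validation over three feature vectors —
   entropy, energy, and their combination — reporting per-group and pooled
   recognition rates as mean ± sd.

Clinical data are not shipped. A first-class synthetic generator produces
labelled two-cohort data sets (default design: 225 CHD-like vs 117
normal-like subjects, 60 s at 720 Hz) whose designed group contrasts have
the direction and magnitude the analysis is meant to detect; see the
methods vignette (`vignettes/pulse-hht-methods.Rmd`) for the waveform model
and effect mechanism.

## Worked example

```r
library(pulseHHT)

cfgs <- defaultCohortConfigs(durationS = 6, fsHz = 720, nChd = 40, nNormal = 24)
recs <- generateCohorts(cfgs$chd, cfgs$normal)
recs[[1]]
#> PulseRecording 'CHD_001' (CHD_like): 4320 samples @ 720 Hz (6.0 s)

features <- pulseFeatures(recs, maxPoints = 2000)   # EMD + 7+7 features per subject
featureRankTables(features)$energy
#> Rank-sum comparison of IMF energy (CHD_like n=40 vs normal_like n=24)
#>   IMF1   meanRank A    24.88  B    45.21  p 2.41e-05 ***
#>   IMF2   meanRank A    27.30  B    41.17  p 0.00401 **
#>   IMF3   meanRank A    28.98  B    38.38  p 0.0514
#>   IMF4   meanRank A    28.75  B    38.75  p 0.0382 *
#>   IMF5   meanRank A    27.38  B    41.04  p 0.00457 **
#>   IMF6   meanRank A    29.60  B    37.33  p 0.109
#>   IMF7   meanRank A    29.93  B    36.79  p 0.155

report <- evaluateFeatureSets(features, forestConfig(seed = 1, nRepeats = 3))
report
#> RecognitionReport: CHD_like n=40, normal_like n=24 (stratified 5-fold x 3 repeats, 500 trees)
#>   CHD_like     sampen 91.67±10.21  energy 94.17±8.00  combined 93.33±9.29
#>   normal_like  sampen 85.00±14.27  energy 79.33±22.19  combined 82.33±19.90
#>   average      sampen 89.15±8.68  energy 88.55±8.35  combined 89.15±8.18
#>   OOB reference: sampen 87.50  energy 89.06  combined 87.50
```

Reading the output: group A is the CHD-like cohort, B the normal-like one;
a higher mean rank means that group's normalized energy at that level tends
to be larger. At this demonstration size (40 + 24 subjects) only some
levels reach significance; at the full 225 + 117 design every energy level
and entropy levels 3–6 separate at p < 0.001 with the normal-like group on
top, and the combined feature vector outperforms either single family.
Recognition rates are percentages of held-out subjects assigned their true
cohort; `average` pools both groups.

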