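# clickpam

Detection, description and species classification of odontocete
echolocation clicks from single-hydrophone passive acoustic monitoring
(PAM) recordings.

Sympatric dolphin populations — here the model system is Indian Ocean
humpback (*Sousa plumbea*) and Indo-Pacific bottlenose (*Tursiops
aduncus*) dolphins sharing a shallow bay — can only be monitored
acoustically at species level if their clicks can be told apart.
`clickpam` implements the complete analysis chain for that question, for
bioacousticians working with calibrated recorder data (e.g. SoundTrap at
576 kHz, full scale 173 dB re 1 μPa):

1. **Audio**: mono WAV in/out with full-scale pressure calibration;
   zero-phase 4th-order Butterworth band-pass (10–200 kHz).
2. **Click detection**: a spectral energy detector — 5 ms segments,
   Welch spectra (Hanning, 576-point FFT, 50% overlap), a segment is a
   click candidate when ≥ 13% of the 15–95 kHz bins exceed a robust
   per-recording noise floor by 15 dB; false positives are screened by
   spectral peak (< 20 kHz) and clipping (> 80% full scale).
3. **Train selection**: grouping by time gap; qualification (≥ 8 clicks,
   mean inter-click interval in (10 ms, 0.1 s), ≥ 10 dB above
   background); per-session cap at 2 × group size; highest-amplitude
   click per train as the on-axis surrogate.
4. **Click parameters** (32-point window on the envelope peak, spectrum
   interpolated ×10 to 1.8 kHz bins): −10 dB duration D₋₁₀dB; peak
   frequency F_P; centroid frequency F_C = Σf·S(f)/ΣS(f); lower −3 dB
   and −10 dB frequencies F_L3, F_L10; −3 dB and −10 dB bandwidths;
   RMS bandwidth BW_RMS = √(Σ(f−F_C)²·S(f)/ΣS(f)).
5. **Statistics**: per-species median (5th–95th percentile) summaries;
   two-sided Mann-Whitney U comparisons; KS/Levene distribution checks.
6. **Classification**: random forest on all eight parameters
   (n_tree = 3000, m_try = ⌊√8⌋ = 2), out-of-bag (OOB)
   correct-classification rates reported as the median with 5th/95th
   quantiles over 100 repeated fits, per-class chance baselines
   (class priors), and permutation importance ranking.
7. **Simulation**: ground-truthed Gabor click trains in band-limited
   noise with snapping-shrimp-like clutter, and reference-matched
   synthetic feature tables, so the whole pipeline is testable against
   closed forms with no recordings.

## Worked example

The numbered scripts under `analysis/` run the pipeline as a narrative:
`01_simulate_scene.R` renders a two-species encounter (12 trains, 17 s,
plus snapping-shrimp clutter) to `scratch/scene.wav`,
`02_detect_clicks.R` detects clicks, `03_select_trains_extract_features.R`
qualifies trains and extracts parameters, `04_species_statistics.R` and
`05_classify_species.R` produce the statistical tables. Outputs land in
`results/`. What they print (abridged):

```
$ Rscript analysis/02_detect_clicks.R
Detected 129 candidates (0 rejected as false positives)
Recall against ground truth: 97.5% of 120 clicks

$ Rscript analysis/03_select_trains_extract_features.R
14 trains, 12 qualified (rejections: too_few_clicks)
Capped at 2 x group size (12): 12 selected
   species      train_id duration_us peak_khz centroid_khz
1        A session1_t001        15.5     88.2         87.8
...
7        B session1_t008        16.7     70.2         69.9
```

The two isolated shrimp impulses that survive detection fail train
qualification (`too_few_clicks`), and the recovered peak/centroid
frequencies separate the 95 kHz species A from the 72 kHz species B.

On the synthetic reference table (35 + 92 clicks matched to the two
species' published medians and 5–95% ranges):

```
$ Rscript analysis/05_classify_species.R
Random forest (3000 trees, m_try 2, 100 repeats, repeats quantiles)
Overall OOB correct rate: 67.7% (5th-95th: 66.1%-69.3%)
  S. plumbea     17.1% (14.3%-20.0%), chance 27.6%, n = 35
  T. aduncus     87.5% (85.9%-89.1%), chance 72.4%, n = 92
Importance (mean decrease in accuracy): lower10_khz > duration_us > ...
Expected OOB fraction at n = 127: 36.6%
```

Read this as the method's qualitative signature: the majority species is
classified well above its prior, the minority species sits near its
prior (majority voting with unweighted, overlapping classes), the
overall rate is well above the 50% two-class chance level, and the lower
−10 dB frequency carries the most classification power. The vignette
(`vignettes/clickpam-methods.Rmd`) discusses why absolute rates on a
marginal-matched synthetic table sit a few points below what correlated
real clicks support.

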