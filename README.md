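# hrvload

Heart rate variability (HRV) analysis for dual-task studies that cross
**cognitive load** (n-back working-memory task, 1/2/3-back) with
**physical load** (isotonic contraction at none/medium/high resistance).
The package implements the complete measurement and analysis chain and a
synthetic-data layer that makes every stage testable end to end without
any subject recordings:

- **Synthesis** — n-back trial sequences with exact target counts and
  run schedules; RR interval series from an integral pulse frequency
  modulation (IPFM) model with controllable LF (~0.1 Hz) and HF
  (~0.25 Hz) oscillatory power; single-lead ECG with powerline, EMG and
  baseline-wander noise; behavioral response logs and NASA-TLX responses
  whose distributions shift with the load condition; full n-subject
  within-subject study datasets with counterbalanced task order.
- **ECG processing** — median-filter + moving-average denoising,
  difference-threshold QRS detection (differentiate → square →
  integrate → adaptive threshold), RR extraction, and outlier screening
  by the median ± 3 scaled-MAD rule with linear interpolation.
- **HRV features** — meanHR, SDNN, NN50, pNN50, RMSSD; Burg
  autoregressive power spectrum of the resampled tachogram with VLF
  (0.003–0.040 Hz), LF (0.040–0.150 Hz) and HF (0.150–0.400 Hz) band
  powers, Total, LF/HF, and normalized powers nLF = LF/(LF+HF),
  nHF = HF/(LF+HF). A Welch periodogram serves as an independent
  cross-check estimator.
- **Task-load scoring** — weighted NASA-TLX total (selection-frequency
  ranks mapped to weights 1/21 … 6/21, tie-safe, weights summing to 1)
  and n-back performance (MRT, SDRT, maxRT, minRT, CNR, MNR, WNR).
- **Statistics** — assumption-gated repeated-measures comparisons
  (Shapiro–Wilk gate: rmANOVA + paired t, else Friedman + Wilcoxon
  signed-rank), Spearman correlations of HRV with workload and RT per
  physical-load stratum, and a three-stage study-level analysis runner.

## Worked example

Generate five minutes of autonomically modulated RR intervals, render
them as a noisy ECG, and run the full recovery chain back to HRV
features:

```r
library(hrvload)

rr <- gen_rr_series(autonomic_params(seed = 42), duration_s = 300)
rr
#> <rr_series> 352 intervals over 298.9 s; mean RR 849.3 ms; 0 replaced

ecg <- gen_ecg(rr, fs = 256,
               noise = noise_spec(powerline_amp = 25, emg_amp = 20,
                                  baseline_amp = 150, seed = 43))
ecg
#> <ecg_record> ECG: 76785 samples @ 256 Hz (299.9 s), 353 annotated beats

feats <- hrv_features(ecg_to_rr(ecg))
round(feats, 3)
#>   meanHR   SDNN NN50  pNN50  RMSSD   aVLF     aLF     aHF   aTotal LF_HF   nLF   nHF
#> 1 70.793 38.484   88 25.071 41.863 25.977 609.797 710.329 1346.103 0.858 0.462 0.538
```

Despite mains interference, EMG noise and baseline wander, the detector
recovers all 353 beats and the feature set matches the generator: ~70.6
bpm from the 850 ms mean RR, RMSSD ≈ √2 × 20 ms jitter + modulation, and
near-equal LF and HF power from the symmetric modulation amplitudes
(nHF ≈ 0.54).

A small synthetic study, then the physical-load contrast on the
normalized HF power within the 2-back condition:

```r
ds <- gen_study_dataset(8, seed = 1, duration_s = 300)
ft <- study_feature_table(ds)
compare_repeated(ft[ft$cl == 2, ], "nHF", "pl")
#>   feature factor       contrast     test statistic  p_value n direction
#> 1     nHF     pl        omnibus  rmANOVA     56.38 2.00e-07 8        NA
#> 2     nHF     pl medium vs none paired_t     -5.82 6.51e-04 8        -1
#> 3     nHF     pl   high vs none paired_t    -10.35 1.71e-05 8        -1
#> 4     nHF     pl high vs medium paired_t    -5.16 1.32e-03 8        -1
```

The planted effect (HF modulation suppressed as physical load rises) is
recovered with the expected negative direction in every pairwise
contrast. `run_study_analysis()` chains the full three-stage analysis;
`run_pipeline()` runs synthesis → features → analysis end to end and
writes CSV/JSON/YAML artifacts. A thin command-line front end is in
`inst/cli/hrvdt.R`.

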