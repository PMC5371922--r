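# pcgkit

Automated screening of newborn heart sounds. `pcgkit` implements an
end-to-end phonocardiogram (PCG) analysis pipeline that takes raw
stethoscope audio and decides whether a recording contains an innocent
murmur (benign, e.g. a transiently patent ductus arteriosus) or a
pathological one (a structural defect needing follow-up):

1. **De-noising** — 3rd-order Butterworth band-pass, 20–100 Hz, applied
   zero-phase, isolating the band where S1 and S2 carry their energy.
2. **Segmentation** — the envelope of a complex Gaussian (Gabor) wavelet
   transform, `psi(u) = C e^{-i w u} e^{-u^2}`, peaks at S1/S2; peaks are kept
   above a normalized threshold of 0.1 and localized at zero-crossings of the
   envelope's first difference. Because a newborn's systole (S1→S2) is
   shorter than its diastole (S2→next S1), the alternating short/long
   inter-peak intervals label the peaks and cut the signal into cardiac
   cycles.
3. **Cycle selection** — dynamic time warping (DTW) with the three-neighbour
   recursion `D(i,j) = |a_i − b_j| + min(D(i−1,j), D(i,j−1), D(i−1,j−1))`
   (Sakoe-Chiba or Itakura constraints available) scores cycle similarity;
   a greedy medoid cover reduces the recording to the fewest representative
   cycles whose per-step DTW distance to the cycles they stand for is
   below 0.005.
4. **Features** — per representative cycle: maximum amplitude, sum of
   positive area, variance, Shannon energy `−mean(x² ln x²)`, and four
   summary scalars each from the direct (FFT-based) bispectrum
   `B(f1,f2) = E[X(f1) X(f2) X*(f1+f2)]` and from the diagonal slice of a
   pseudo Wigner bispectrum — a 12-dimensional descriptor per recording.
5. **Classification** — soft-margin linear SVM (`min |w|²/2` s.t.
   `y_i(w'x_i − b) ≥ 1`, labels +1 = healthy, −1 = pathological) evaluated by
   stratified 8-fold cross-validation: confusion matrix, accuracy, ROC, AUC.

Because clinical newborn PCG collections are rarely shareable, the package
ships a seeded synthetic PCG simulator (`generate_recording()`,
`generate_dataset()`) that renders S1/S2 as Gaussian-windowed tones at
newborn heart rates with ground-truth event times, optional
innocent/pathological murmur bursts and calibrated noise — so every stage of
the pipeline is testable end to end.

## Worked example

```r
library(pcgkit)

g <- generate_recording(synth_config(murmur_kind = "pathological_systolic",
                                     murmur_relative_amplitude = 0.6,
                                     noise_snr_db = 15, seed = 7))
g$recording
#> <pcg_recording> synthetic: 24000 samples @ 4000 Hz (6.00 s), label=pathological

seg <- segment_recording(bandpass_filter(g$recording))
head(seg$events, 4)
#>   time_s kind
#> 1 0.1000   S1
#> 2 0.2750   S2
#> 3 0.5370   S1
#> 4 0.6145   S2
```

The first S1 is detected at 0.100 s — exactly where the simulator placed it —
and the S1→S2 interval (~0.175 s) is the systole. Fourteen cycles are cut;
with heart-rate jitter and 15 dB noise no two cycles fall within the strict
0.005 DTW threshold of each other, so each remains its own representative
(on noise-free input a single cycle represents the whole recording).
Features and a cross-validated evaluation of a small simulated cohort:

```r
fv <- extract_features(select_representatives(seg$cycles), seg$cycles)
round(fv[1:4], 4)
#>     max_amplitude sum_positive_area          variance    shannon_energy
#>            0.9896           83.8079            0.0546            0.0553

cfg <- pipeline_config(simulate = list(n_normal = 10, n_pathological = 10),
                       synth = synth_config(murmur_relative_amplitude = 0.6,
                                            noise_snr_db = 15),
                       output_dir = tempfile(), k = 4, seed = 42)
res <- run_pipeline(cfg)
res$report
#> Cross-validated evaluation
#>               predicted
#> actual         normal pathological
#>   normal           10            0
#>   pathological      0           10
#> accuracy: 100.0%  (normal 100.0%, pathological 100.0%)
#> AUC: 1.000
```

The confusion matrix counts out-of-fold predictions (rows actual, columns
predicted); accuracy is `100 × trace / total` and AUC is the area under the
pooled decision-value ROC — 1.0 means the two simulated classes separate
perfectly.

A command-line wrapper lives at `inst/cli/pcgkit.R`
(`simulate | denoise | segment | run-all`), e.g.

```sh
Rscript inst/cli/pcgkit.R simulate --n-normal 10 --n-pathological 10 --seed 1 --out-dir pcg_sim
Rscript inst/cli/pcgkit.R run-all --n-normal 58 --n-pathological 58 --seed 42 --out-dir pcg_run
```

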