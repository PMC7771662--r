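# arksim

Segmented cine cardiac MRI collects the k-space data of one heart-phase
image over several heartbeats. Fixed radial schedules — golden-angle
increments or random view angles — cannot react to the rhythm that is
actually unfolding, so the views collated into a frame from different
heartbeats land unevenly around the half-circle and the image inherits
streak artifacts. `arksim` is a desk-scale simulator and analysis toolkit
for the alternative: a closed-loop ("autonomous") controller that, at every
repetition time (TR), looks at the live ECG, finds prior moments of the
same cardiac phase by normalized cross-correlation, collates the radial
views acquired at those moments together with the current half-shot, and
acquires the next view along the bisector of the largest angular gap of
that frame.

The package is aimed at MRI pulse-sequence and reconstruction researchers
who want to study closed-loop view ordering without scanner hardware: every
component of the loop — ECG synthesis, phase matching, view selection,
trajectory quality metrics, and a demonstration reconstruction — is an
ordinary R function operating on plain data structures.

## What it computes

* **Synthetic ECG** (`rhythm_spec()`, `generate_ecg()`): a seeded
  sum-of-Gaussians P-Q-R-S-T beat model with controllable mean RR interval,
  beat-to-beat variability, ectopic beats with compensatory pauses,
  baseline wander and noise; sampled at 400 Hz and resampled to the TR grid
  (`resample_to_tr()`).
* **Phase matching** (`cross_correlate()`, `find_phase_matches()`,
  `phase_match_series()`): Pearson correlation of the trailing 300 ms ECG
  window against the full history; local maxima above a score threshold
  become the matched heartbeats whose views are collated into the current
  frame.
* **The controller** (`run_acquisition()`): per TR, collate the frame
  (`collate_frame_views()`) and bisect its largest angular gap
  (`next_angle_bisect()`), with golden-angle training until matches are
  available; golden, random and equispaced comparator schedules share the
  same interface. A segmentation scheme with `N_q` shots and `N_s`
  segments per shot yields `N_theta = N_s (N_q - 1) + N_s / 2` views per
  frame, because only half of the current shot has happened.
* **Sampling-quality metrics** (`uniformity()`, `uniformity_series()`,
  `psf_2d()`, `psf_profile_and_ratio()`, `compare_trajectories()`): the
  angular uniformity statistic
  `U = sum_k CS(k) / sum_k CS_ideal(k)`, where `CS` is the cumulative sum
  of the ascending-sorted adjacent-angle differences and the ideal is the
  equal-gap distribution `pi / N`; and the point-spread-function main-lobe
  signal ratio `sum_{|x| <= tau} s(x) / sum_x s(x)` of the radially
  averaged PSF, with `tau` at the first zero crossing. `nyquist_views()`
  and `reduced_fov()` give the classical radial sampling bounds
  `N_theta >= N_r pi / 2` and `FOV_reduced = N_theta / (2 pi N_r) * FOV`.
* **Demonstration reconstruction** (`cardiac_phantom()`,
  `phantom_kspace()`, `reconstruct_frame()`, `ventricular_projection()`):
  an analytic dynamic ellipse phantom, sampled along any view log and
  reconstructed by density-compensated adjoint gridding, for qualitative
  streak comparisons and M-mode-style motion maps.

## Worked example

```r
library(arksim)

ecg <- generate_ecg(rhythm_spec(rr_mean = 1.0, rr_sd = 0.05, seed = 1),
                    duration = 90, fs = 400)
scheme <- segmentation_scheme(n_shots = 1, n_segments = 54, tr = 2.8e-3)

arks   <- run_acquisition(ecg, scheme, "arks")
golden <- run_acquisition(ecg, scheme, "golden")

compare_trajectories(list(golden = golden, arks = arks), scheme)
#> <trajectory_report> N_theta=27 (N_q=1 x N_s=54)
#>          mode n_frames mean_uniformity_pct sd_uniformity_pct psf_ratio_pct
#> golden golden    31428            83.01731          1.046274            NA
#> arks     arks    31428            96.48787          1.049898            NA
#>        rel_uniformity_vs_golden_pct
#> golden                      0.00000
#> arks                       16.22621
```

The report says: over the 31,428 sliding frames of 27 views each, the
golden-angle schedule fills the half-circle at 83.0% of the equal-gap
ideal, while the closed loop — which keeps bisecting the largest gap of
its own trailing frame — reaches 96.5%, a 16% relative improvement on the
same ECG. Random schedules sit near 51% for this frame size.

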