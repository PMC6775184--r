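# fingerflex

Continuous finger joint-angle decoding from a high-density (96-channel)
surface-EMG array wrapped around the forearm.

## The problem

Finger flexor and extensor muscles are small and lie deep in the forearm,
so conventional single-sensor EMG depends critically on electrode placement
— and on anatomy that, for amputees, may be unknown. An electrode array
covering the whole forearm sidesteps placement: every muscle projects onto
some subset of the grid, and the best signal per finger can be identified
computationally after the recording. `fingerflex` implements that pipeline
for R users working on myoelectric control, EMG signal processing, or
musculoskeletal modelling:

* preprocessing of the raw array (common average reference, zero-phase
  5–200 Hz band-pass, anti-aliased downsampling, rectified 3 Hz-low-pass
  envelopes with calibration-offset removal);
* ICA source separation with electrode-grid topology heuristics (motion-
  noise and detached-sensor flags) and correlation-based selection of one
  flexor and one extensor signal per finger — for independent components
  and, in parallel, for raw channels restricted to an anatomical mask;
* two decoding models per finger; in the musculoskeletal equilibrium-point
  model (MSM) an antagonist muscle pair generates torque

  τ = Σₙ aₙ (k₀,ₙ + k₁,ₙ uₙ)(l₀,ₙ + l₁,ₙ uₙ − aₙ θ),  n ∈ {flexor, extensor},

  and the decoded angle is the equilibrium θ_eq = Σ aₙKₙLₙ / Σ aₙ²Kₙ at
  which τ = 0 (fitted by constrained multi-start least squares); the
  linear regression model (LRM) is θ̂ = β₀ + β₁u_flex + β₂u_ext;
* ground-truth construction from the protocol trigger and the normalized
  finger displacement, θ_f = T_dir · NRMSD_f with T_dir = 2.094 rad
  (flexion), −0.523 rad (extension), 0 (rest);
* evaluation protocols reporting Pearson correlation (CC) and RMSE per
  subject × finger × method, with a paired t-test contrasting the IC route
  against the raw-channel route;
* a synthetic array-EMG generator with fully known ground truth (muscle
  activations, mixing matrix, joint angles) emulating the acquisition:
  2 s flexion/rest/extension/rest phases, 6-motion train experiments,
  10-cycle mixed test experiments, 96 channels at 2048 Hz, line
  interference, sensor noise at a configurable SNR, motion artifacts, and
  crosstalk between adjacent fingers.

See `vignettes/decoding-methods.Rmd` for the models, assumptions and
design decisions in full.

## Worked example

Simulate two subjects at a reduced acquisition rate, run the train→test
protocol for all four methods, and summarize:

```r
library(fingerflex)

cfg <- sim_config(seed = 11, n_subjects = 2, fs_raw = 512,
                  motions_per_train_exp = 2, train_exps_per_finger = 1,
                  test_exps = 2, cycles_per_test_exp = 5,
                  snr_db = 10, crosstalk = 0.1)
opt <- pipeline_options(fs_proc = 128, ica_components = 16,
                        fit_fs = 16, restarts = 4)
tab <- run_protocol(cfg, protocol = "A", options = opt)
aggregate(cbind(cc, rmse_deg) ~ method, tab, mean)
```

```
   method        cc rmse_deg
1 LRM-EMG 0.9321863 7.224877
2 LRM-ICA 0.9688939 5.256306
3 MSM-EMG 0.9602606 5.775246
4 MSM-ICA 0.9746505 4.697686
```

Each row averages the per-subject, per-finger Pearson correlation and RMSE
(degrees) between the decoded and ground-truth angle on held-out test
experiments. Two patterns matter: the musculoskeletal model beats the
linear baseline, and for either model the ICA-selected sources beat the
best raw channel — ICA unmixes overlapping muscles and suppresses noise
that any single electrode necessarily picks up. A paired comparison:

```r
compare_ic_emg(tab, "MSM")[c("mean_diff", "t", "df", "p_two_sided")]
```

```
$mean_diff
[1] 0.01438993

$t
[1] 2.147533

$df
[1] 9

$p_two_sided
[1] 0.06027814
```

With only two simulated subjects (10 paired finger values) the positive
IC−EMG difference is not yet significant at α = 0.05; the 10-subject run
in the test suite (harder conditions, 5 dB SNR) yields a clearly
significant advantage.

The generator's defaults (`sim_config()`) reproduce the full study
conditions — 10 subjects, 25 train experiments each at 2048 Hz — which is
gigabytes of signal; the reduced rates above exercise the identical code
path in minutes.

## Command line

A thin CLI wraps the package for shell use:

```sh
Rscript inst/cli/fingerflex.R simulate --config cfg.yaml --out data/
Rscript inst/cli/fingerflex.R run --config cfg.yaml --out results/ --protocols A,B
```

`cfg.yaml` may set any `sim_config()` field; outputs are delimited tables
with YAML sidecars (recordings), TSV schedules and evaluation tables, and
a provenance stamp (seed, config hash, package version).
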