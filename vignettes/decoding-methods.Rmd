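---
title: "Decoding finger angles from a forearm EMG array: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger angles from a forearm EMG array: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Controlling a prosthetic hand finger-by-finger requires a continuous
estimate of each finger's joint angle from muscle activity. The finger
flexors and extensors are small and lie deep in the forearm, so the
classical approach — placing one bipolar EMG sensor over each muscle of
interest — depends heavily on operator skill and fails outright when the
anatomy is unusual (e.g. after amputation). A high-density array that wraps
the whole forearm removes the placement problem: every muscle projects onto
*some* subset of the 96 electrodes, and the right signal can be found after
the fact, by computation.

`fingerflex` implements that computation end to end:

1. **Preprocessing** — common average reference, zero-phase 5–200 Hz
   band-pass, downsampling to a processing rate, rectified 3 Hz-low-pass
   envelopes.
2. **Source separation** — ICA over the array, electrode-grid topology
   heuristics to reject artifact components, and correlation-based
   selection of one flexor and one extensor signal per finger (both for
   independent components and for raw channels restricted to an anatomical
   mask).
3. **Decoding** — two models per finger: a musculoskeletal equilibrium-point
   model (MSM) and a linear regression model (LRM).
4. **Evaluation** — Pearson correlation and RMSE against a trigger-based
   ground-truth trajectory, under two train/test protocols, with a paired
   t-test comparing the IC route against the raw-channel route.
5. **Simulation** — a synthetic array-EMG generator with known ground truth
   that makes every stage testable without human recordings.

# Ground truth: trigger × normalized displacement

The experimental protocol instructs one finger at a time to flex for 2 s,
rest 2 s, extend 2 s, rest 2 s. A camera-based tracker yields per-finger
joint positions; the package reduces them to a *normalized RMS
displacement* from the calibration pose,

$$\mathrm{NRMSD}_f(t) \;=\; \min\!\Big(1,\;
  \frac{1}{L_f}\sqrt{\tfrac{1}{J}\textstyle\sum_j \lVert p_{f,j}(t) - c_{f,j}\rVert^2}\Big),$$

and signs it with the protocol trigger to produce the ground-truth angle

$$\theta_f(t) = T_{dir}(t)\cdot \mathrm{NRMSD}_f(t),\qquad
T_{dir} = \begin{cases} 2.094\ \mathrm{rad} & \text{flexion}\\
0 & \text{rest}\\ -0.523\ \mathrm{rad} & \text{extension.}\end{cases}$$

The reference pose $c$ is the mean pose over the calibration segment and
$L_f$ the recorded finger length; both are free choices of this package
(robust and directly testable), since only the formula's shape is fixed by
the protocol. The trajectory is then median-filtered (0.5 s window — our
choice; wide enough to kill single-frame tracker glitches at typical camera
rates, narrow relative to the 2 s phases) and low-pass filtered at 1 Hz,
both zero-phase.

# The musculoskeletal equilibrium-point model

Each finger joint is modelled as an antagonist pair of spring-like muscles
with activation-dependent stiffness and rest length. Muscle $n \in \{1 =
\text{flexor}, 2 = \text{extensor}\}$ with moment arm $a_n$ ($a_1 > 0$,
$a_2 < 0$) contributes torque, and the joint torque is

$$\tau = \sum_{n=1}^{2} a_n\,(k_{0,n} + k_{1,n} u_n)\,
        (l_{0,n} + l_{1,n} u_n - a_n\theta),$$

with all $k$, $l$ parameters positive. The predicted angle is the
*equilibrium point* where the torques balance ($\tau = 0$):

$$\theta^{eq}(u_1, u_2) \;=\;
 \frac{\sum_n a_n K_n L_n}{\sum_n a_n^2 K_n},
 \qquad K_n = k_{0,n} + k_{1,n}u_n,\quad L_n = l_{0,n} + l_{1,n}u_n.$$

Note the squared moment arms in the denominator: this is the exact root of
the torque equation above, which we verified independently by bisection.
A stiffness-weighted form without the square (which appears in parts of the
literature on this model family) is *not* a root of the same torque
expression and can have a vanishing denominator; the implementation
therefore uses the exact root, so that
`msm_torque(u, msm_equilibrium(u)) == 0` holds to machine precision — a
property the test suite checks over a thousand random parameter draws.

**Identifiability.** $\theta^{eq}$ is invariant under a common rescaling of
all four stiffness constants, so the fit pins $k_{0,1} = 1$. Fitted
parameter values are consequently only defined up to this normalization;
predictions are unaffected, and only predictions are evaluated.

**Fitting.** Parameters are estimated by least squares between
$\theta^{eq}(u)$ and the ground-truth angle. The sign and positivity
constraints are enforced structurally by optimizing log-parameters
($k, l, a_1 = e^{x}$, $a_2 = -e^{x}$), which turns the constrained problem
into a smooth unconstrained one. Levenberg–Marquardt is restarted from 10
seeded log-uniform draws in $[e^{-2}, e^{2}]$ plus a unit start, and the
best training RMSE wins. On noiseless synthetic data this recovers held-out
predictions with correlation ≥ 0.99 and RMSE ≤ 0.02 rad.

# The linear regression model

$$\hat\theta_f = \beta_0 + \beta_1 u_{flex} + \beta_2 u_{ext}$$

fitted by ordinary least squares; a rank-deficient design (e.g. identical
flexor and extensor inputs) falls back to the minimum-norm solution and is
flagged. The LRM is the simple baseline a practitioner unfamiliar with
musculoskeletal modelling would reach for.

# ICA and signal selection

The array mixes every muscle into many electrodes; ICA inverts that mixing
under the assumption of statistically independent, non-Gaussian sources.
The implementation whitens by SVD (retaining the subspace that explains
$1 - 10^{-6}$ of the variance, or a user-set component count) and runs
symmetric fixed-point ICA with the log-cosh contrast — a standard
single-model, super-Gaussian algorithm of the FastICA/extended-Infomax
class, deterministic for a given seed. Separation quality is validated with
the Amari index against the known mixing of simulated data (≤ 0.15 on
3–6 sources; typical values are below 0.02).

Component vetting mimics what a human does with topology plots, as
automated heuristics on the mixing weights placed at the electrode grid
coordinates:

* **motion-noise flag** — more than half the array carries ≥ 50% of the
  peak weight ("large area" pattern);
* **detached-sensor flag** — the dominant electrode has an adjacent
  neighbour of opposite sign at ≥ 50% of its weight.

For each finger and direction the candidate components are ranked by the
absolute Pearson correlation between their envelope and the
direction-specific half-wave-rectified target ($\max(\theta_f, 0)$ for
flexion, $\max(-\theta_f, 0)$ for extension); the top 16 are reported and
the best unflagged candidate is selected (ties to the lower component
index). Using envelopes rather than raw activations, and rectified
direction-specific targets, makes the flexor/extensor assignment
well-defined; the raw-channel route uses exactly the same criterion but
restricts candidates to the anatomical mask (ties to the lower grid row,
then column). The mask ships as data, not code: a contiguous 4-row × 2-column
electrode block per finger per panel, ordered Thumb→Pinky along the
panel axis, since no published electrode coordinates exist for the muscle
regions.

ICA is fitted once per subject on the concatenation of all of that
subject's experiments. Selection, by contrast, only ever uses the
experiments that the current protocol designates for fitting.

# Preprocessing choices

All filters are 4th-order Butterworth applied forward–backward
(zero-phase), so envelopes stay time-aligned with the kinematics — a
requirement for correlation-based selection. The filter family and order
are not dictated by the decoding problem; they are standard EMG practice
and have a directly testable frequency response. Filtering operates about
the series mean with odd-reflection padding, which makes constant signals
exact fixed points and keeps edge transients inside the padded region.
Envelopes are full-wave rectified, low-passed at 3 Hz, clamped at zero
(removing tiny filter undershoot so $u \ge 0$ always holds), and offset-
corrected by subtracting the mean envelope of the rest-only calibration
segment. Downsampling applies a zero-phase anti-alias low-pass at 80% of
the new Nyquist frequency before evaluating on the new time grid.

The pipeline order is fixed: re-reference → band-pass → resample → ICA →
envelope. Whether re-referencing precedes band-passing is immaterial for
the average reference (both are linear), and the package fixes this order.

# The synthetic generator

The generator reproduces the statistical and temporal structure of the
study conditions with known ground truth:

* **Protocol** — 2 s phases, 6 motions per train experiment (8 s each),
  25 train experiments per subject (5 per finger, Thumb→Pinky), test
  experiments of 10 cycles sweeping all fingers twice, a 4 s calibration
  rest at the start of every experiment; 96 channels at 2048 Hz by default.
* **Activations** — raised-cosine trapezoids of the instructed muscle per
  phase (peak jittered by up to 10%), a resting baseline of 0.02, and a
  configurable fraction (default 0.1) of each burst leaking into adjacent
  fingers, emulating the mechanical interconnection between finger muscles.
* **Angles** — per-subject muscle parameters are drawn randomly and their
  length constants solved so that the equilibrium angle is 0 at rest and
  reaches the trigger-consistent peaks (≈ 2.094 rad flexion, ≈ −0.523 rad
  extension) at full activation. The published range-of-motion figures for
  this task are not unit-consistent with the trigger constants, so the
  generator follows the trigger values; the simulated angles *are* the
  equilibrium of the true parameters, which is what makes parameter-recovery
  tests meaningful.
* **EMG** — each muscle source is its activation envelope times an
  independent unit-RMS 20–250 Hz noise carrier (independent carriers make
  the ICA model hold by construction); sources spread onto their panel's
  electrodes as a spatial Gaussian (σ = 1.5 grid units) centred on the
  finger's mask block; channels add line interference (50 Hz, relative
  amplitude 0.1), white sensor noise scaled to a configurable
  source-to-noise ratio (default 10 dB, the middle of the SNR range
  reported for array systems), and low-frequency (< 5 Hz) motion-artifact
  bursts during movement, common to the array with per-channel gains
  (default relative level 0.5).

**What the generator does not emulate:** motor-unit firing statistics,
conduction velocity and electrode-skin impedance variation, non-stationary
muscle movement under the skin, camera tracking failures, and genuinely
nonlinear activation-to-angle relationships beyond the equilibrium model
itself. Passing tests therefore demonstrate the pipeline's correctness and
its behaviour under controlled mixing/noise/crosstalk — not human-subject
performance levels.

# Evaluation protocols

* **Protocol A** — per finger, fit on that finger's single-finger train
  experiments; evaluate on all mixed-finger test experiments.
* **Protocol B** — fit on exactly one mixed test experiment; evaluate on
  the remaining test experiments (the minimal-training regime relevant to
  prosthetic fitting sessions).

Both protocols run all four method combinations (MSM/LRM × ICA/EMG). CC
uses the sample (n−1) definition; RMSE is reported in degrees, since
angles span ±120° and degree-scale errors are the field's convention. The
IC-vs-EMG comparison pairs per-(subject, finger) CC values of the same
model and applies a two-sided paired t-test at α = 0.05, with no
multiple-comparison correction (matching standard practice for this
two-condition contrast).

Protocol A could alternatively be defined with the variables estimated
from test data; the package keeps the strict train → test definition
because it makes the data provenance unambiguous, and Protocol B already
covers the fit-on-test-data regime.

# Numerical and scale choices

Angles are radians everywhere internally; degrees appear only in reports.
Envelopes and targets are decimated to `fit_fs` (default 25 Hz) before
model fitting and evaluation — the envelopes are band-limited to ~3 Hz, so
this loses nothing while making the nonlinear fits fast. The test suite
and the bundled analyses run the generator at reduced acquisition rates
(512 Hz), reduced experiment counts, a 128 Hz processing rate, 16 retained
ICA components and 16 Hz fitting rate; these sizes were chosen so a full
10-subject analysis completes in minutes on a laptop while exercising
every stage at the study's structural defaults (96 channels, 2 s phases,
Thumb→Pinky ordering). The directional IC-vs-EMG comparison uses 10
subjects at 5 dB SNR with overlapping spatial mixing — the regime where
source separation should pay off — and asserts only the sign of the mean
CC difference, not its magnitude.

Degenerate inputs are contracts, not crashes: constant-input fits are
flagged, zero-variance correlations return flagged missing values, ICA
non-convergence (e.g. Gaussian sources) returns a flagged partial result,
and rank-deficient regressions return the minimum-norm solution with a
collinearity flag.

# Known limitations

* The raw-channel route selects a single best electrode per muscle rather
  than averaging the masked region; with dense arrays and correlation-based
  selection the single-electrode variant is better defined and was kept.
* EDF/BDF input is not implemented (no text-safe backend); recordings
  interchange as delimited tables with YAML sidecars.
* The equilibrium model is single-joint per finger and has no activation
  dynamics (no first-order lag), no gravity and no external load.
* Human inspection of topology plots is replaced by two heuristics; they
  are deliberately conservative and can be bypassed by supplying explicit
  component choices.
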