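---
title: "Navigator-based dynamic off-resonance correction for SMS-EPI: model, simulation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigator-based dynamic off-resonance correction for SMS-EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(smsb0)
```

## The problem

Accelerated EPI of awake, behaving animals suffers from dynamic B0
off-resonance: body, limb and jaw motion outside the head perturbs the main
field inside the brain from one frame to the next. Beyond geometric
distortion, these perturbations break the correspondence between the
functional frames and the calibration data that simultaneous multi-slice
(SMS) and in-plane GRAPPA reconstructions rely on.

This package implements, on fully synthetic data, a correction that uses the
EPI phase-correction navigators — three non-phase-encoded readouts acquired
every frame — to estimate a per-frame, spatially *linear* field perturbation
and undo it in raw k-space before reconstruction.

## Signal model

The field perturbation at frame $t$ is modelled as

$$\Delta f_t(x, y) = c_0(t) + c_x(t)\,x + c_y(t)\,y \quad [\mathrm{Hz}],$$

with $x$ (readout) and $y$ (phase-encode) in FOV units. Phase accrued up to
the echo time TE turns the linear terms into a net k-space translation and
the constant term into a global phase:

$$\varphi_0 = 2\pi c_0 \mathrm{TE}, \qquad
  \Delta k_x = c_x \mathrm{TE}, \qquad \Delta k_y = c_y \mathrm{TE},$$

in grid units ($\Delta k = 1/\mathrm{FOV}$). Per frame the package estimates
and inverts exactly these three numbers:

1. **Nyquist ghost parameters** $(\theta_0, \theta_1)$ from the
   opposite-polarity navigator pairs (magnitude-weighted linear phase fit of
   odd $\times$ conj(even) in projection space).
2. **$\varphi_0$ and $\Delta k_x$** from the phase of
   $P_t(x)\,\overline{P_{\mathrm{ref}}(x)}$, where $P$ are ghost-corrected
   navigator projections; the readout is fully sampled, so this translation
   can be inverted exactly by a projection-space phase ramp.
3. **$\Delta k_y$** by a 1-D search: $\Delta k_y = -\arg\min_\delta
   \lVert W^{\delta} P_{\mathrm{ref}} - P_t \rVert^2$, where $W$ is the
   GRAPPA shift operator described below. A coarse grid (step 0.05) is
   refined by golden section to 0.005 grid units. After the search,
   $\varphi_0$ and $\Delta k_x$ are refit against the $\delta$-shifted
   reference: a phase-encode translation moves the object's intrinsic
   k-space phase into the comparison (a bias of roughly
   $2\pi \bar y\, \Delta k_y$ on $\varphi_0$) which the refit removes.

The reference is frame 1's navigators (the timeline's zero state) by
default; the calibration navigators can be chosen instead.

### The GRAPPA shift operator

The phase-encode direction is undersampled (R = 2) and collapsed over slices
(MB = 2), so a fractional $k_y$ translation cannot be applied by a Fourier
ramp. Instead a coil-coupling operator $W$ is trained on the fully sampled
calibration data to map every line onto its $k_y + 1$ neighbour; fractional
powers $W^{\delta} = V \Lambda^{\delta} V^{-1}$ (principal branch) realise
sub-grid shifts.

Numerical choices, all config-exposed:

* The operator is stored in hybrid $(x, k_y)$ space, where it reduces to one
  $C \times C$ matrix per readout position. The default fit is an
  unconstrained per-position ridge regression (`width = NULL`); a classical
  k-space tap parameterisation (`width = 3` etc.) is available. The
  per-position fit measured better one-step residuals and clearly better
  end-to-end behaviour than 3- to 9-tap variants, which is why it is the
  default.
* Training stacks the slices' calibration data, so by linearity the operator
  shifts any linear combination of the slices — including CAIPI-phased
  collapsed frames and the plain-sum navigators — consistently.
* Eigenvalue magnitudes are floored at `lam_floor = 0.25` (phases kept, and
  the operator matrices are rebuilt from the floored spectrum). The ridge
  fit annihilates coil directions the calibration cannot predict; without
  the floor, *negative* fractional powers would amplify measurement noise in
  those directions by up to $|\lambda|^{-1.5} \sim 10^2$. With the floor the
  gain of any $|\delta| \le 1.5$ power is at most $0.25^{-1.5} \approx 8$,
  the exact power semigroup $W^aW^b = W^{a+b}$ is preserved to machine
  precision, and the one-step prediction residual is essentially unchanged
  (the floored directions carry almost no signal).
* Readout positions with (numerically) no object signal get the identity.
* The 1-D $\Delta k_y$ search is significance-gated: if the best objective
  does not improve on $\delta = 0$ by more than 1% (relative), the estimate
  snaps to zero. Identical navigators therefore give an exact zero and the
  correction provably does nothing on unperturbed data.

### Reconstruction chain

Both arms share: per-frame Nyquist ghost correction (estimated from that
frame's navigators), the dynamic zeroth-order phase correction
$e^{-i\varphi_0}$, split-slice (leak-block) SMS unaliasing, in-plane GRAPPA
completion, inverse Fourier transform, and root-sum-of-squares coil
combination. The *corrected* arm additionally applies the first-order
correction ($\Delta k_x$ by exact projection ramp, $\Delta k_y$ by
$W^{+\Delta k_y}$) before unaliasing — the single code-path difference
between the arms, asserted by a test.

Split-slice kernels are trained on synthetically collapsed, CAIPI-encoded
calibration data with the leak-block objective (each kernel must null the
other slice of its group). The CAIPI convention is the standard blipped
pattern for MB = 2 / R = 2: slice 2 of a group gets phase $e^{i\pi m}$ on
acquired line $m$; kernels target the encoded slice and the phase is removed
after unaliasing. All kernels use circular k-space indexing (the spectrum of
a discrete image is exactly periodic).

## What the generator emulates

* **Geometry**: 64 x 64 matrix, 4 slices in 2 SMS groups, 8 coils, MB = 2,
  R = 2 — a desk-scale version of a 120 mm FOV / 42-slice / 15-channel
  protocol. TE/TR = 25.4/1282 ms are the protocol values; the echo spacing
  (0.6 ms) is a convention because no sequence timing diagram exists.
* **Phantom**: piecewise-smooth ellipse with seeded texture, ventricle-like
  inclusions and smooth phase; per-slice geometry varies so slice supports
  differ (making slice leakage measurable). Eight named ROI masks (seven
  shell sectors plus a deep region) stand in for anatomical ROIs.
* **Coils**: Gaussian lobes on a ring with strong low-order phase,
  normalised to unit mean root-sum-of-squares over the object. The lobe
  width (0.28-0.38 FOV) was chosen for solid parallel-imaging encoding;
  smoother coils degrade every kernel in the chain.
* **Field timelines**: "smooth" (low-pass-filtered noise; body-motion-like
  drift), "step" (posture changes), "spikes" (isolated events, e.g.
  responses or licking; positions shared across coefficients). Default
  amplitudes (10, 15, 15) Hz give max $|\Delta k| \approx 0.38$ grid units
  at TE. Frame 1 is always the zero reference.
* **Task**: offers every ~12 s; go-cue 3-4 s after the offer; responses
  within 1 s of the cue on a fraction `p_respond` of trials (a session is
  guaranteed to contain both trial types, otherwise the motor-response
  regressor is unidentifiable); outcome 3.5-4.5 s after the response;
  3.5-4.5 s intertrial intervals. BOLD: 2% peak amplitude in a posterior
  "offer" blob and an anterior "motor" blob, double-gamma HRF with a 3 s
  peak (no published parameter set exists for macaque cortex, so the shape
  is a knob).
* **Noise**: white complex Gaussian, default sigma = 0.006, calibrated to
  give coil-combined object tSNR of about 30 at default geometry;
  calibration scans use sigma/4 (an averaged acquisition).
* **Navigator timing**: the three navigator echoes are *centred on TE*. With
  navigators placed before the echo train (the more literal sequence
  layout), linear phase accrual means they sense only ~60% of the net
  translation at TE, which contradicts both the translate-mode identities
  and the unit-slope tracking this estimator is meant to have. Centring them
  at TE is the convention that makes navigator-sensed phase equal the net
  translation; equivalently, one may read it as the estimator rescaling its
  navigator phases from navigator time to TE under the linear-accrual model.

Two acquisition modes exist per frame: **physics** (per-line phase accrual
$e^{i 2\pi \Delta f(r) t_n}$ with the line's acquisition time $t_n$ — the
honest model, including within-train distortion the correction cannot fix)
and **translate** (the idealised net-translation model the estimator
assumes; exact, used for oracle tests).

What the generator does *not* model: T2* decay across the train, ramp
sampling, partial Fourier, through-slice dephasing, physiological noise, and
— importantly — any through-slice (z) field component, so both slices of an
SMS group always see the *same* in-plane perturbation.

## Analysis chain

Image quality: bias vs the single-band reference (per-voxel temporal mean
minus reference, normalised by mean reference intensity), temporal CoV and
tSNR maps, ROI summaries, paired across-session Wilcoxon comparisons with
Benjamini-Hochberg FDR, histograms, and a ground-truth slice-leakage proxy
(energy in each slice's partner-only zone).

Activation: high-pass filtering by DCT-basis projection (3-dB at 100 s; a
brick-wall projection, so slow drift is removed completely and the task band
is untouched), in-plane Gaussian smoothing with an exact-Gaussian transfer
function (3 mm FWHM; through-slice smoothing is omitted with only 4
slices), a voxelwise GLM with intercept + offer + action_onset +
motor_response + outcome (0.1 s boxcars convolved with the HRF, amplitudes
one, no orthogonalisation), AR(1) prewhitening by Cochrane-Orcutt refit,
t-to-z via log tail probabilities, face-connected cluster thresholding at
z = 3.1 with a null-simulation extent calibration (Gaussian-field p-values
are not implemented), a one-sample-t second level (a deliberate
simplification of mixed-effects session-level inference; both arms face the
same inference), and 10-fold split-half reliability (voxelwise correlation
of half z-maps within ROIs, plus the absolute difference of ROI-mean z as
baseline bias). z-maps are capped at |z| = 40; degenerate zero-variance
voxels at the second level are set to the cap and flagged.

## Problem sizes

Unit tests run at N = 64, C = 8 (single frames or a handful of frames); the
multi-session evaluations use 10 sessions of T = 120 frames with 10 trials
each, which keeps a full study in the minutes range on one CPU. The same
configuration is used by `scripts/acceptance.R`.

## A worked example

```{r example}
library(smsb0)

cfg <- run_config(n_frames = 120, sigma = 0.006, n_trials = 10)
ses <- simulate_session(cfg, seed = 1)
ops <- train_recon_operators(ses$calibration, config_protocol(cfg))
est <- estimate_session(ses, ops)
plot_estimates(est, ses$truth$timeline, te = cfg$te)

rec_c <- reconstruct_session(ses, ops, est, "corrected")
rec_u <- reconstruct_session(ses, ops, est, "uncorrected")
qc <- qc_report(rec_c, rec_u, ses$calibration, ses$truth$phantom$masks)
qc$medians

study <- run_study(cfg, n_sessions = 10, seed = 100)
study
report_markdown(study, "study_report.md")
```

## What the synthetic validation does and does not show

The estimator itself validates cleanly: injected perturbations over the full
search range are recovered to ~0.003 rad / grid units noiselessly and with
RMSE well under 0.05 grid units at tSNR 30; the physics-mode estimates track
the true net translation with unit slope; correcting a translate-mode frame
with the truth restores the zero-field k-space to within 2%; and the
correction is exactly inert on unperturbed sessions.

At the image-magnitude level, however, this simulation world is kinder to
the *uncorrected* arm than an awake in vivo experiment is. With a purely
in-plane linear field, lattice-indexed CAIPI and periodic k-space, a net
k-space translation of the collapsed data is almost invisible to the
magnitude reconstruction: the GRAPPA and split-slice kernels are (up to
their finite-fit error) translation-equivariant, so the uncorrected
translation emerges as a pure image phase ramp. The measurable uncorrected
penalty is a ~15% inflation of the reference bias and a ~1% temporal
artifact CoV, while the coil-space fractional-shift correction carries model
error and noise gain of similar size. On the default ensemble the corrected
arm consistently wins on bias against the single-band reference, but loses
on temporal CoV/tSNR (and on measures downstream of temporal noise: GLM
suprathreshold counts and split-half correlation), with the size of the loss
depending mainly on the sign of the field drift (negative phase-encode
shifts require negative operator powers, which amplify noise in contractive
coil directions despite the eigenvalue floor).

The mechanism that makes uncorrected reconstructions fail badly in vivo —
through-slice field components giving the two slices of an SMS group
*different* perturbations, which genuinely breaks slice separation and
causes the half-FOV aliasing this correction is known for suppressing — is
outside this package's 2-D field model by design. Extending the generator
and estimator with a per-slice differential term is the natural next step if
the goal is to reproduce the in vivo effect sizes rather than to validate
the estimation/correction machinery.

## Known limitations

* 2-D in-plane field model only (see above); first-order spatial terms only.
* The net-translation model ignores within-train phase evolution; physics
  mode quantifies that residual (the translate/physics agreement is ~5% at
  $|\Delta k| \le 0.3$).
* The second level is a one-sample t, not a mixed-effects model.
* The session container is an R-native serialized file, not a hierarchical
  binary container; it round-trips bit-exactly within R.
* Cluster inference uses simulation-calibrated extents, not random-field
  theory.
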