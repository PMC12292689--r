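---
title: "Methods: synergy tensors, the CMFI, and the key–finger–exoskeleton model"
author: "pianosynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy tensors, the CMFI, and the key–finger–exoskeleton model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pianosynergy)
```

This vignette is the package's own account of the science it implements:
what each stage assumes, which parameters matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design choices
were settled.

## 1. From raw sEMG to the frequency × time × space tensor

Surface EMG is modeled as an amplitude-modulated stochastic interference
pattern: a slowly varying, non-negative activation envelope multiplying a
broadband carrier whose energy sits roughly between 20 and 150 Hz. The
preprocessing chain (`preprocess()`) therefore resamples to the 400 Hz
analysis rate with polyphase anti-aliasing (plus an explicit zero-phase
8th-order low-pass at 0.45× the target rate, because the polyphase FIR's
transition band alone lets near-Nyquist tones leak through), band-passes
20–150 Hz with a 4th-order zero-phase Butterworth, optionally notches mains,
and removes residual DC. Zero-phase filtering matters because the temporal
factors extracted later are compared across sessions; a phase-shifted
pipeline would bias those comparisons.

Each channel is then transformed with a complex Morlet wavelet
$\psi(t) = \sigma^{-1/2}\pi^{-1/4} e^{j\omega_0 t} e^{-t^2/(2\sigma^2)}$,
in L2 normalization, with $\sigma = 1$ in the wavelet's natural units and
$\omega_0 = 2\pi f_c$, $f_c = 0.849$. Integer scales $a = 1,\dots,30$ map to
frequencies $f = f_c \cdot F_s / a$, i.e. 339.6 Hz down to 11.3 Hz at
400 Hz. Two caveats are deliberate and documented rather than hidden:

* The scale map is a *per-scale* reading of the conventional
  centre-frequency relation; with 30 integer scales the axis does not reach
  below 11.3 Hz, so the lowest part of the nominal 0–150 Hz band is
  represented only by the widest wavelet. Both the scale count and $f_c$ are
  configurable (`wavelet_config()`).
* Convolution uses zero padding with the central segment retained — the
  simplest fully reproducible edge dialect. Edge samples within one wavelet
  length of the boundary are attenuated accordingly.

**Magnitudes and smoothing.** A complex spectrogram cannot enter a
non-negative factorization, so the tensor holds CWT magnitudes. Raw
magnitudes of a stochastic carrier are Rayleigh-distributed pointwise with a
coefficient of variation of $\sqrt{4/\pi - 1} \approx 0.52$ *regardless of
the envelope*, which caps the FIT of any low-rank model near
$\pi/4 \approx 0.785$. What a synergy model can and should represent is the
time–frequency *envelope*, so `build_emg_tensor()` applies a moving-average
over 0.4 s (default `smooth_s`) to each scale row before stacking. The
window is chosen to sit below the duration of a key-press activation burst
(so temporal structure survives) while averaging several correlation lengths
of the magnitude fluctuation (so the Rayleigh noise shrinks). Because the
smoothing is linear in time it maps a CP-rank-R envelope to a CP-rank-R
envelope — it changes no ranks, only noise. Set `smooth_s = 0` for raw
magnitudes.

## 2. Non-negative CP factorization and the synergy count

`cp_als()` fits $E \approx \sum_{r=1}^{R} F_r \circ T_r \circ S_r$ by
alternating least squares over the mode unfoldings, in the update order
spatial → frequency → temporal. Each mode update solves the unconstrained
least-squares problem against the Khatri–Rao design and clips negative
entries to zero. Clipping can, rarely, *raise* the residual (we observed
this on the first sweep from random initializations, where the temporal-mode
clip overshoots); a monotonicity safeguard therefore rejects any such update
and substitutes one exact column-wise non-negative coordinate-descent pass,
which provably cannot increase the residual. Consequently the residual is
non-increasing from the initialization onward, and the returned model never
fits worse than its random start.

Numerical choices: absolute-valued Gaussian initialization, 5 restarts (best
FIT kept, per-restart FITs retained for the selection rule), convergence at
a FIT change below `1e-5` or 200 sweeps, Gram systems solved with an SVD
pseudo-inverse fallback for rank-deficient components, and the
identification convention that frequency and spatial columns are unit-norm
with scale absorbed into the temporal factor. An all-zero tensor is assigned
FIT 1 (its trivial reconstruction is exact). FIT itself is implemented as
the relative-error form $1 - \|X-Y\|_F^2/\|X\|_F^2$: the only reading that
stays in $[0,1]$ and equals 1 exactly at perfect reconstruction.

`select_rank()` applies the stopping rule: the smallest rank whose mean FIT
over restarts reaches 0.90 while the gain from one extra synergy is at most
2 percentage points; if no rank qualifies, the argmax-FIT rank is returned
flagged. The mean is over *restarts* — the alternative (over subjects) is a
cohort-level statistic this toolkit does not own.

**Identifiability.** CP uniqueness needs factor diversity (Kruskal:
$k_F + k_T + k_S \ge 2R + 2$). When every synergy rides the same carrier
band the frequency factors are nearly collinear ($k_F = 1$), so uniqueness
rests entirely on the temporal and spatial factors. This is not an artifact
of the generator — real forearm sEMG channels share their spectral band too
— and it is why the generator's activation bursts are short and mostly
disjoint (see §5): with heavily overlapping activations the "true" synergies
are simply not recoverable by *any* method, which is worth knowing before
interpreting patient data.

## 3. Similarity-based rehabilitation assessment

`compare_synergies()` fixes component pairs once, by exhaustive search over
injective assignments maximizing summed spatial Pearson correlation, then
reuses that pairing for the frequency and temporal domains. Matching in one
domain and reporting in all three avoids cherry-picking a favourable pairing
per domain. Temporal factors of unequal length are linearly resampled to the
reference length. Correlations are reported signed (not clamped), and they
are invariant to per-component positive rescaling, so the normalization
convention does not leak into the scores. Rank mismatches pair up to the
smaller rank and report the surplus components as unpaired — the increase in
synergy count during recovery is itself a finding, not an error.

## 4. The fatigue stack: features, DMWCM, CMFI

Features are extracted on 1 s windows with 50% overlap — at 400 Hz this is
the shortest window giving a usable Welch median-frequency estimate while
keeping the index responsive. Per window and muscle:

* **RMS** — quadratic mean (rises with fatigue as recruitment grows);
* **MF** — the frequency splitting the Welch PSD (Hann segments of up to
  256 samples, 50% inner overlap) into equal-power halves, located by linear
  interpolation of the cumulative-power crossing (falls as conduction
  velocity drops);
* **PE** — permutation entropy of order 4, delay 1, normalized by
  $\log 4!$, ties broken by position (falls as the signal grows regular);
  degenerate windows (constant, monotone) give 0;
* **FD** — Higuchi fractal dimension with $k_{max} = 8$ (falls as waveform
  complexity drops); flat windows give 1.

`normalize_features()` maps each feature per muscle into $[0,1]$ and aligns
direction with fatigue: $rf = \mathrm{minmax}(RMS)$ and
$mf, pf, ff = 1 - \mathrm{minmax}(\cdot)$. Whether the decreasing features
should be inverted before weighting is not dictated by the index's
definition; without inversion a convex combination of oppositely-trending
terms cancels, so inversion is adopted and documented. Recording min–max is
the default; a baseline-relative mode (anchored at the first windows'
mean) is provided for online use where the final range is unknown.

The single-muscle index is the convex combination
$I^{FMI}_i = T_R rf_i + T_M mf_i + T_P pf_i + T_F ff_i$ with equal default
weights; `calibrate_weights()` re-estimates them by non-negative least
squares of an external fatigue reference on the channel-averaged features
(renormalized to sum 1, with fallbacks to equal weights on rank-deficient or
degenerate designs).

The multi-muscle combination follows the dominant-mode construction: rank-2
NMF (multiplicative updates, monotone objective) of the rectified,
0.125 s-smoothed envelope yields muscle weights `W` and activations `H`; per
sample the dominant mode is the argmax activation (ties to the lower index);
per feature window the dominant mode is the within-window majority vote —
the windowed features and the sample-level modes must share a time base,
and majority voting is the least-structured way to get there. The DMWCM
column for a window is the dominant mode's muscle-weight column renormalized
to sum 1, making $CMFI = \sum_i s^{main}_i I^{FMI}_i$ a convex combination
bounded in $[0,1]$; without that renormalization the index would inherit the
arbitrary scale of the factorization. Rest prompting uses hysteresis: the
flag raises when the CMFI reaches the threshold (default 0.7) and clears
only below the resume level (default 0.6), preventing chatter around the
threshold. Both levels are configuration, not physiology; no canonical
threshold value exists.

## 5. What the synthetic generator emulates — and what it does not

`generate_synergy_emg()` implements the amplitude-cascade model: channel
$i$ is $\sum_r W_{ir} H_r(t) \, c_i(t) + \varepsilon(t)$ with unit-variance
Gaussian carriers band-passed to 20–150 Hz, multiplicative envelopes, and
white sensor noise. Activation waveforms are sums of short Gaussian bursts
(0.1–0.22 s wide, staggered across components, peak 1) — the tempo of
single key presses — generated by `make_activation_waveforms()`. The burst
design is what keeps the ground truth identifiable (§2): wide overlapping
activations would make recovery impossible in principle, not merely hard.

`generate_fatigue_emg()` drives all "decreasing" features with one
mechanism: a time-varying first-order low-pass whose cutoff tracks the MF
ramp compresses the spectrum toward low frequencies (lowering MF, PE and
FD together), and a slow 6 Hz deterministic component scaled by the PE/FD
ramps adds regularity. The local RMS (1 s moving window) is normalized out
before the RMS ramp is applied as an explicit amplitude profile — otherwise
the low-pass gain change would confound the programmed amplitude trend. The
programmed fatigue level returned alongside the recording is the linear
ramp in $[0,1]$.

What passing tests on this generator shows: the pipeline recovers known
low-rank structure at realistic noise, the synergy-count rule finds the
generating rank, and the CMFI tracks a monotone fatigue progression. What it
does not show: robustness to electrode shift, motion artifact,
non-stationary cross-talk, motor-unit firing statistics, or inter-subject
variability — none of which the generator attempts to model. MF/PE/FD ramp
multipliers are targets of *direction and ordering*, not calibrated
magnitudes; only the RMS ramp is reproduced quantitatively.

## 6. The key–finger–exoskeleton simulator

The finger is a planar (sagittal, flexion–extension) chain of rigid
phalanges — three links for index through little finger, two for the thumb —
with uniform-rod inertias from cylinder-approximated phalanx masses. The
coupled dynamics

$$[M_f + M_e]\ddot\theta + [C_f + C_e]\dot\theta + K_s(\theta - \theta_{eq})
 = \tau_m + \tau_e - J_k^\top (k_s x_k + b_s \dot x_k)$$

are integrated with fixed-step RK4 at 1 ms. Design readings worth stating:

* The exoskeleton's two torque descriptions are reconciled by treating the
  structural stiffness $K_s$ about the gravity-compensated equilibrium as
  the device's *passive* dynamics and the PD law as its *active* drive on
  the right-hand side; a single symbol cannot be both.
* $M_e$ (reflected actuator/linkage inertia, defaults
  $2\!\times\!10^{-4}/10^{-4}/5\!\times\!10^{-5}$ kg m²) is part of the
  plant: phalanx inertias alone are $\sim\!10^{-6}$ kg m², which would make
  the PD derivative term stiffer than an explicit integrator can follow —
  and no physical drive is inertia-free.
* Hill curves are the standard phenomenological forms the torque product
  needs but does not define: Gaussian force–length
  $f_l(\tilde l) = e^{-((\tilde l - 1)/0.45)^2}$ and a hyperbolic
  concentric / saturating eccentric force–velocity with $a_f = 0.25$,
  plateau 1.4; both equal 1 at the operating point, so the isometric limit
  reduces to $F_{max} r_m(\theta)$ exactly. Moment arms come from the
  virtual-work identity $r_m = \partial l_{mt}/\partial\theta$ by central
  difference (exact for the linear tendon-excursion models used by
  default).
* Key contact is one-sided and friction-free: the spring–damper engages
  only while the fingertip penetrates the contact plane, with compression
  equal to the penetration depth.
* Coriolis terms come from Christoffel symbols with central-difference
  $\partial M/\partial\theta$; the passive system (no activation, no drive)
  is dissipative to integrator tolerance, and halving the step shrinks the
  end-state error at 4th order — both are tested invariants.

The per-joint assistive force is $F_a = \tau_m / d_{joint}$ with
$d_{joint}$ the distance from the robot's force application point to the
joint's instantaneous centre (defaults: half the link lengths). The garbled
distinction between the tendon force and its per-joint distribution is
resolved by computing $F_a$ per joint from that joint's torque only.

## 7. Problem sizes and limitations

The validation suite runs on desk-scale synthetic conditions chosen once:
3 s (1200-sample) synergy recordings for tensor work, 40–180 s fatigue
sessions, 5 random seeds and 5 restarts where a statistic is aggregated, and
a 200-restart box-constrained quasi-Newton oracle on 4×6×3 tensors as the
independent check on CP-ALS. Known limitations: single-band carriers make
frequency factors uninformative for component separation (real data may
differ); the CWT frequency axis is coarse below ~20 Hz; NMF/NTF solutions
are local optima mitigated but not eliminated by restarts; the simulator is
planar, friction-free and gravity-free, and its gains are illustrative — it
predicts interaction forces for plausible parameter sets rather than
reproducing any specific device's calibration.
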