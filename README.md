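# pianosynergy

Muscle-synergy analysis, real-time fatigue monitoring and hand biomechanics
for piano-based upper-limb rehabilitation.

Piano-playing occupational therapy engages stroke patients in a task that
demands fast, finely coordinated finger muscle activity. Evaluating that
therapy objectively needs three computational pieces that this package
provides as one toolkit:

1. **3-D muscle-synergy extraction.** Multichannel surface EMG (forearm
   montage ED, FDS, ECU, FCU) is mapped channel-by-channel through a complex
   Morlet continuous wavelet transform and stacked into a non-negative
   *frequency x time x space* tensor `E`. Non-negative CP (CP-ALS)
   factorization decomposes it as

   `E ≈ Σ_r F_r ∘ T_r ∘ S_r,  F, T, S ≥ 0`

   where `S_r` are muscle weights, `T_r` activation-scaling waveforms and
   `F_r` frequency profiles. Reconstruction quality is scored by
   `FIT = 1 − ‖E − Ê‖²_F / ‖E‖²_F`, and the number of synergies is the
   smallest rank with mean FIT ≥ 0.90 whose FIT gain from one more synergy
   is ≤ 2 percentage points. A 2-D NMF path (`E ≈ W H`) is included for the
   fatigue pipeline.

2. **Rehabilitation assessment.** A subject's factors are matched to a
   reference (healthy) model by optimal spatial-correlation assignment, and
   per-pair Pearson correlations are reported in the spatial, frequency and
   temporal domains.

3. **Comprehensive Muscle Fatigue Index (CMFI).** Per 1-s window and muscle,
   four fatigue features are extracted — RMS amplitude, median frequency
   (MF), permutation entropy (PE) and Higuchi fractal dimension (FD) —
   normalized to `[0, 1]` with fatigue-aligned direction, and combined as
   `I_FMI = T_R·rf + T_M·mf + T_P·pf + T_F·ff`. The momentarily dominant
   synergy mode (from the NMF activations) selects a muscle-weight column
   (the DMWCM), and `CMFI(t) = Σ_i s_i(t)·I_FMI_i(t)` with hysteresis-based
   rest prompting when a threshold is crossed. Weights are calibratable by
   non-negative least squares against a fatigue reference.

4. **Key–finger–exoskeleton forward simulation.** A planar multi-link finger
   presses a spring–damper key (`F = k_s x_k + b_s ẋ_k`) while a PD-driven
   exoskeleton (`τ_e = K_p(θ_d − θ) + K_d(θ̇_d − θ̇)`) assists; muscle
   torques follow a Hill-type model
   (`τ_m = F_max · f_l(l̃) · f_v(ṽ) · α · r_m(θ)`) with virtual-work moment
   arms (`r_m = ∂l_mt/∂θ`), integrated by fixed-step RK4.

Because no recordings are deposited, the package ships a first-class
synthetic-data module: sEMG with a known low-rank synergy structure
(band-limited carriers amplitude-modulated by burst-like activations) and
fatigue sessions whose windowed RMS rises while MF, PE and FD fall along
programmed ramps — so every downstream stage is testable against ground
truth.

## Worked example

```r
library(pianosynergy)

# a 3 s, 4-channel recording with 3 known synergies
truth  <- default_synergy_truth(seed = 7)
rec    <- generate_synergy_emg(truth)
tensor <- build_emg_tensor(rec, wavelet_config())
sel    <- select_rank(tensor, r_max = 6, restarts = 5, seed = 1)
model  <- sel$models[[sel$rank]]
glance(model)
#> # A tibble: 1 × 5
#>    rank   fit mean_restart_fit n_iter converged
#>   <int> <dbl>            <dbl>  <int> <lgl>
#> 1     3 0.974            0.974     39 TRUE

# the recovered muscle weights match the generator
match_components(model, list(S = truth$muscle_weights))
#> # A tibble: 3 × 3
#>   subject reference spatial_r
#>     <int>     <int>     <dbl>
#> 1       1         3     0.992
#> 2       2         1     0.998
#> 3       3         2     0.994
```

The rank was selected by the FIT rule (mean FIT 0.974 ≥ 0.90 at rank 3, with
a gain of only 0.6 points from a fourth synergy), and each recovered muscle
weight vector correlates above 0.99 with the generating one.

```r
# a 60 s fatigue session and its CMFI trajectory
ses    <- generate_fatigue_emg(fatigue_program(duration_s = 60, seed = 11))
series <- cmfi_pipeline(ses$recording, seed = 11)
glance(series)
#> # A tibble: 1 × 5
#>   n_windows max_cmfi mean_cmfi prop_rest threshold
#>       <int>    <dbl>     <dbl>     <dbl>     <dbl>
#> 1       119    0.770     0.472     0.109       0.7
```

The CMFI climbs with the programmed fatigue ramp and crosses the 0.7 rest
threshold near the end of the session (11% of windows flagged).
`autoplot(series)`, `autoplot(model)` and `autoplot(tensor)` draw the
corresponding figures; `tidy()` returns long tibbles for your own plots.

A command-line wrapper covering the same stages
(`synth`, `tensorize`, `decompose`, `assess`, `fatigue`, `simulate`) is
installed at `system.file("cli", "pianosynergy.R", package = "pianosynergy")`.

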