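# somatoprf

Voxel-wise population receptive field (pRF) mapping of the hand
representation in somatosensory cortex, for fMRI experiments that
stimulate a 4 × 4 grid of sites — four digits (D2–D5) × four
proximal–distal (PD) locations along each digit (tip to base) — with
travelling-wave (phase-encoded) vibrotactile protocols.

Phase-encoded mapping alone yields each voxel's *preferred* location;
pRF modelling additionally estimates receptive field *size and shape*.
`somatoprf` implements the full analysis chain and a synthetic-data
generator with known ground truth, so every stage is testable without
access to scanner data.

## What it computes

**Stimulus model.** Binary time × 16-site stimulus descriptions for
three travelling-wave paradigms (between-digit, within-digit, diagonal;
4 s per stimulation line, 16 s or 28 s cycles, 12 cycles, TR 2 s;
forward and reverse runs; run-aware concatenation).

**Four pRF model families**, fitted per voxel by grid-search-initialised,
bounded Levenberg–Marquardt nonlinear least squares, each including five
HRF parameters:

| family | weights | fitted parameters |
|---|---|---|
| `gaussian2d` | w(d,pd) = exp[−(d₀−d)²/2σ_d² − (pd₀−pd)²/2σ_pd²] | 9 |
| `gaussian1d_bd` | four scaled Gaussians over digits, one per PD row | 16 |
| `gaussian1d_wd` | four scaled Gaussians over PD, one per digit | 16 |
| `unconstrained` | one free weight per site (fit ceiling) | 21 |

Fits report r², adjusted r² (maps thresholded at adjusted r² > 0) and
the least-squares AIC n·log(rss/n) + 2k.

**Travelling-wave reference analysis.** Coherence, phase and amplitude
of the stimulus-frequency Fourier component, with forward/time-flipped
reverse averaging to cancel the haemodynamic delay; exact p-values
p = (1−c²)^(K−1) under Gaussian noise; Hommel (stagewise Bonferroni)
correction across voxels; phase binned into four digit/PD labels.

**Evaluation, coverage and ROI statistics.** Dice label-agreement
matrices between TW and pRF maps; AIC preference matrices across
families; pRF coverage maps (bicubic 4×4→20×20 upsampling, Laplace-PDE
extrapolation to 60×60, PCA summarisation with equal subject weighting,
integer-shift peak alignment); ROI aggregation of pRF sizes by PD
location or area band with one-way ANOVA + Tukey HSD.

**Synthetic generator.** Ground-truth somatotopic patches (smooth D2→D5
gradient, mirrored tip–base gradients across four area-like bands,
band-dependent and elongated pRF sizes) and complete simulated sessions
(forward model + drift + white or AR(1) noise), plus recovery scoring.

## Worked example

Simulate a small session at temporal SNR 50, run the travelling-wave
analysis, fit the 2D Gaussian family, and score recovery against the
ground truth:

```r
library(somatoprf)

patch <- generate_patch(nx = 6, ny = 6, seed = 42)    # 36 voxels
cfg   <- simulation_config(noise_sd = 2, seed = 1)    # tSNR 50
sim   <- simulate_session(patch, cfg)                 # 912 volumes
Y     <- preprocess_timeseries(sim$Y, tr = 2, runs = sim$seq$runs)

tw   <- tw_analysis(Y, sim$seq, paradigm = "between")
head(tw, 3)
#>   voxel coherence     phase amplitude        p_raw  p_corrected label
#> 1     1 0.8917108 0.9808345  3.890557 2.119506e-32 6.358517e-31     1
#> 2     2 0.8809979 1.3528709  4.074753 1.251329e-30 3.253454e-29     2
#> 3     3 0.8521204 2.3685828  3.315596 1.344493e-26 2.016740e-25     2

fits <- fit_patch(Y, "gaussian2d", sim$seq)
rec  <- score_recovery(patch, fits)
print(rec$per_parameter, digits = 3)
#>   parameter     bias  rmse correlation median_abs_error
#> 1        d0  0.01557 0.174       0.985           0.0498
#> 2       pd0 -0.00195 0.138       0.990           0.0500
#> 3   sigma_d -0.02883 0.173       0.918           0.0979
#> 4  sigma_pd -0.00410 0.151       0.970           0.0859
rec$dice_digit
#> [1] 0.941
```

Reading the output: each voxel's TW `coherence` measures how strongly it
follows the travelling wave (here far above the 0.3 mapping threshold),
its `phase` encodes the preferred digit, and `label` is the discretised
digit assignment. The recovery table shows the 2D Gaussian fits locate
pRF centres to ≈0.05 grid units (median) at this noise level, with
size estimates correlating > 0.9 with the planted truth; the fitted
digit map agrees with the ground-truth map at Dice 0.94.

The whole pipeline (simulate → preprocess → TW → fit all families →
Dice/AIC → coverage → ROI report) runs from one call:

```r
run_pipeline(pipeline_config(seed = 1, nx = 12, ny = 12), "my_run")
```

or from a shell via the thin wrapper `inst/cli/prf-pipeline.R` with a
YAML configuration. Every stage writes TSV artefacts and a JSON
manifest recording the seed and thresholds.

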