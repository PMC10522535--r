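---
title: "Two-dimensional pRF mapping of the hand representation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional pRF mapping of the hand representation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatoprf)
```

# The problem

Phase-encoded ("travelling wave") fMRI mapping of primary somatosensory
cortex recovers each voxel's *preferred* stimulus location on the hand but
says nothing about how much of the skin surface drives the voxel. The
population receptive field (pRF) framework fills that gap: a generative
model of the voxel response as a weighted sum over stimulation sites,
whose fitted parameters give both a preferred location and a receptive
field *size* along each axis of the stimulus space.

`somatoprf` implements this analysis for a 4 x 4 vibrotactile grid:
four digits (D2--D5) by four proximal--distal (PD) sites along each digit
(PD1 = tip to PD4 = base), 16 sites in all. Because no public data set
accompanies the protocol, the package ships a first-class synthetic
generator that produces complete sessions with known ground truth, and
every stage of the analysis is validated against it.

# Stimulus model

Three travelling-wave paradigms sweep "lines" of the grid, each line ON
for 4 s:

* **between-digit** -- the four digit columns in succession (16 s cycles),
* **within-digit** -- the four PD rows in succession (16 s cycles),
* **diagonal** -- the seven anti-diagonals of the grid, ordered from the
  (D2, PD1) corner (28 s cycles).

At TR 2 s and 12 cycles a between/within run spans 96 volumes and a
diagonal run 168. Reverse runs are the time-reversed forward sweep. The
stimulus description is a binary time-points x 16 matrix; sessions are
concatenations of runs with recorded boundaries, and no convolution or
filtering operation ever crosses a boundary. The anti-diagonal
orientation and the site linear index (`site = (digit-1)*4 + pd`) are
conventions chosen for determinism; the physical grid fixes neither.

# pRF model families

Four families describe the site weights $w$ of a voxel:

* **2D Gaussian** (9 fitted parameters):
  $w(d, pd) = \exp\!\left[-\frac{(d_0-d)^2}{2\sigma_d^2}
  -\frac{(pd_0-pd)^2}{2\sigma_{pd}^2}\right]$.
  The centre $(d_0, pd_0)$ is the preferred location; $\sigma_d$ and
  $\sigma_{pd}$ are the between- and within-digit pRF sizes in grid units
  (FWHM $\approx 2.355\,\sigma$). The Gaussian carries no scale factor of
  its own: overall response amplitude lives in the HRF amplitude
  parameter, which keeps the parameter count at 4 spatial + 5 HRF.
* **1D between-digit** (16 parameters): four independently scaled
  Gaussian profiles over digits, one per PD row,
  $g(d)_{pd} = k_{pd}\exp[-(d_0-d)^2/2\sigma_d^2]$, with the PD1 row's
  scale fixed to 1 (the freed amplitude again lives in the HRF), so
  4 centres + 4 sizes + 3 scales + 5 HRF.
* **1D within-digit** (16 parameters): the orthogonal construction, one
  profile per digit, the D2 profile's scale fixed to 1.
* **unconstrained** (21 parameters): one free weight per site, no shape
  constraint. It serves as the fitting ceiling; a pRF size is not defined
  for it.

The preferred location of a fitted 1D model is read off the profile with
the largest scale factor (ties break to the lowest index, with a
warning); for the unconstrained model it is the argmax site.

A note on the 2D equation: the printed source equation for this family
carries a sign and subscript anomaly (the minus applied to one term only,
and the size subscripts swapped between the axes). The package implements
the standard separable Gaussian above -- the only form consistent with
the two 1D families and with the model's visualisation -- and treats the
printed form as a typographical slip.

# Haemodynamic response

The neural prediction $S w$ (stimulus matrix times weights) is convolved
run-wise with a five-parameter double-gamma HRF: peak delay, undershoot
delay, a shared dispersion, undershoot:peak ratio, and amplitude. Each
lobe is written in unit-peak form
$(t/t_p)^{t_p/\delta} e^{-(t-t_p)/\delta}$ so the delay parameters are
exactly the lobe modes and the amplitude scales the kernel linearly.
Defaults: 5 s peak, 15 s undershoot, 1 s dispersion, ratio 0.15. The
exact parameterisation of the kernel is a free choice here -- any smooth
five-parameter unimodal-with-undershoot kernel preserving linearity fits
the design -- and the HRF parameters are re-fit per voxel and per family,
consistent with the per-family parameter totals of 9/16/16/21.

# Preprocessing and fitting

Raw series are converted per run to percent signal change: the run mean
is recorded, an intercept, linear trend and discrete-cosine components
below 0.01 Hz are projected out, and the residual is scaled by
100/mean. Crucially, the *same* projection is applied to every model
prediction inside the optimiser (`run_projector()`): model and data see
identical filtering, which is what makes noiseless synthetic voxels
recoverable to solver tolerance rather than merely approximately.

Fitting is nonlinear least squares per voxel:

1. **Grid search** (`grid_search_init()`): centres on the integer lattice
   1..4, sigmas in {0.5, 1, 2}, HRF at canonical values, response scale
   solved linearly. For the 1D families the four profile scales are
   solved by OLS at each lattice point; for the unconstrained family the
   16 weights are solved directly by OLS. Ties break to the lowest
   lattice index.
2. **Levenberg--Marquardt refinement** (`minpack.lm::nls.lm`) of all
   parameters under box bounds: centres in [0.5, 4.5] grid units (the
   stated constraint of the protocol), sigmas in [0.1, 10] (a guard
   against degenerate spike/flat fits; the source states bounds only for
   the centres), HRF parameters in physiologically sensible boxes.
   Stopping: relative tolerances 1e-8, at most 100 iterations. A fit
   that fails to improve on its start returns the start with
   `converged = FALSE`, so the final residual never exceeds the
   grid-search minimum. If a fitted centre lands exactly on a bound --
   the signature of a boundary local minimum, which happens for broad
   receptive fields centred near the grid edge -- the fit is retried
   from wide-sigma and then narrow-sigma starts and the best solution
   kept.

Fit quality is summarised by $r^2$, adjusted
$r^2 = 1-(1-r^2)(n-1)/(n-p-1)$ (maps are conventionally thresholded at
adjusted $r^2 > 0$), and the least-squares AIC
$n\log(\mathrm{rss}/n) + 2k$ with $k$ the family's total parameter
count.

# Travelling-wave reference analysis

The Fourier analysis extracts, per voxel, the DFT component at the
stimulation frequency (the 12th harmonic of a run). Phase follows the
delay convention -- $\cos(\omega t - \phi)$ returns $\phi$ -- so later
preferred epochs mean larger phase. Forward and time-flipped reverse
runs are circularly shifted by the haemodynamic lag (default 2 TR) and
averaged, which cancels the HRF delay from the phase estimate to first
order.

Coherence is the stimulus-frequency amplitude divided by the root sum of
squared amplitudes over all frequencies *strictly between* DC and
Nyquist. Excluding the Nyquist bin is deliberate: with $K$ complex bins
of equal variance under white Gaussian noise, squared coherence is
exactly Beta(1, K-1) and the p-value $(1-c^2)^{K-1}$ is exact; the real
Nyquist bin of an even-length series would perturb this. The
Monte-Carlo type-I error at $\alpha = 0.05$ is verified in the test
suite at 10,000 replicates.

P-values are corrected across voxels with Hommel's stagewise-Bonferroni
procedure (`stats::p.adjust(method = "hommel")`), which the tests verify
against an exhaustive closed-testing oracle (Simes local tests over all
subsets) for up to six hypotheses. One consequence worth noting: a set
of *identical* p-values is left unchanged by the procedure, because the
Simes combination of equal p-values is that p-value itself.

Phases are discretised into four contiguous half-open bins of width
$\pi/2$. Each stimulation line's ON block occupies the first samples of
its quarter-cycle, so the discrete epoch phases sit at
$(k-1)\pi/2 + \pi/8$; the default bin offset of $-\pi/8$ centres them in
their bins. Broadly tuned voxels at the edge digits (D2, D5) show a
systematic inward phase compression -- their weight mass extends past
the edge of the grid, pulling the response phase toward the centre of
the sweep -- which is a property of phase encoding itself, not of the
implementation, and is the main source of travelling-wave/pRF label
disagreement on synthetic data.

# Map comparison

Continuous preferred locations are rounded to the nearest grid integer
before comparison (the discretisation rule is a package choice). Dice
coefficients $2|A\cap B|/(|A|+|B|)$ are computed per label and as the
full 4 x 4 label-pair matrix. Family comparison uses the AIC preference
matrix: entry (A, B) is the percentage of voxels with
$\mathrm{AIC}_A < \mathrm{AIC}_B$, ties split evenly, diagonal reported
as 50, so complementary entries always sum to 100.

# Coverage maps

Per ROI, each voxel's native 4 x 4 weight grid is

1. upsampled to 20 x 20 by separable natural-cubic-spline (bicubic)
   interpolation, which reproduces the native values at coinciding
   sample positions;
2. placed centrally in a 60 x 60 frame whose surround is filled by
   solving the discrete Laplace equation (known block as Dirichlet data,
   zero-flux at the frame edge). Filled values obey the maximum
   principle and the sparse Cholesky factorisation is cached and reused
   across voxels;
3. summarised by PCA across voxels: maps are reconstructed from the
   first 3 components, averaged within subject, then across subjects
   with equal weight so that no subject dominates through voxel count.
   Whether the PCA pools voxels across subjects (the default) or is
   computed per subject first is exposed as a flag, since either reading
   of the procedure is defensible;
4. optionally peak-aligned before averaging: integer shifts only (no
   resampling, so the operation is exactly invertible on the common
   support), out-of-frame cells dropped and the average count-normalised.

Coverage "width" is reported as the weighted second moment of the map
around its centre of mass, computed on the central 20 x 20 block -- the
extrapolated surround is synthetic fill and would dilute contrasts.

# ROI aggregation and group statistics

Voxels passing adjusted $r^2 > 0$ are aggregated into 16 ROIs per
scheme -- functionally (PD location x digit) or anatomically (area band
x digit) -- as subject-wise means, which are the observational units for
one-way ANOVA with Tukey HSD pairwise comparisons (`stats::aov`,
`stats::TukeyHSD`). ROI volumes are voxel counts times the voxel volume
(1.953125 mm^3 for 1.25 mm isotropic voxels).

# The synthetic generator

`generate_patch()` plants the qualitative structure the analysis is
meant to recover:

* a smooth digit gradient D2 to D5 along one lattice axis;
* mirrored tip-base-tip PD gradients across four parallel area bands,
  emulating the representation reversals at areal borders (3a/3b/1/2);
* band-dependent pRF sizes (multipliers 1.0/0.85/1.15/1.5 for the
  3a/3b/1/2-like bands: the area-2-like band widest, 3b narrowest);
* elongated pRFs, $\sigma_{pd} = 1.5\,\sigma_d$ by default;
* sizes growing 50% from D2 to D5 and from tip to base;
* Gaussian centre jitter of 0.1 grid units.

The baseline size of 0.7 grid units and the response amplitude of 2%
signal change are typical of high-field digit mapping. Noise is white
Gaussian in raw units on a baseline of 100, so `noise_sd = 2` gives
temporal SNR 50; an AR(1) option (suggested value 0.3) adds realistic
autocorrelation and a per-run linear drift option exercises the
detrending. The generated response is expressed as percent signal change
about each run's mean, so the raw run mean equals the baseline exactly
and the percent-signal-change conversion is exact rather than
approximate -- without this, a per-run gain mismatch of order 1% leaks
into every fit.

What the generator does *not* emulate: cortical geometry (the patch is a
flat lattice, not a mesh), spatial noise correlations, physiological
noise spectra, motion, distortion, and the thermal-noise structure that
denoising leaves behind in real 7T data. Passing tests therefore show
that the estimator chain is correct and well calibrated under its own
assumptions, not that those assumptions exhaust real data.

# Problem sizes and runtime choices

The validation surfaces use a 40 x 40 patch (1600 voxels, full session
protocol of 912 volumes) for 2D-Gaussian parameter recovery at tSNR 50,
and a 16 x 16 patch with one forward/reverse pair per paradigm (720
volumes) for the four-family pipeline comparisons. These sizes give
stable statistics (recovery medians, Dice matrices, AIC preferences)
while keeping a full test run on one CPU in the minutes range.

# Known limitations

* With only four samples per axis, sigma above ~2 grid units is weakly
  identified; bounds, not data, then determine the estimate.
* Edge-of-grid centres inherit the phase-compression and truncation
  biases described above; recovery is best for interior voxels.
* The unconstrained family shares its amplitude between the HRF and the
  16 weights; the product is identifiable, the factors individually are
  not (the reported weights absorb an arbitrary positive scale).
* Difference-of-Gaussians and compressive-nonlinearity pRF variants are
  out of scope.
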