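---
title: "Modelling and estimating brain extracellular-space parameters from tracer MRI"
author: "ecstracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and estimating brain extracellular-space parameters from tracer MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecstracer)
```

## The model

A paramagnetic tracer (e.g. Gd-DTPA) injected into brain parenchyma spreads
through the extracellular space (ECS) by hindered diffusion and is removed
by interstitial-fluid drainage and metabolism. Because the tracer shortens
the T1 of tissue water, its concentration is visible as signal enhancement
in T1-weighted MRI, and the space-time pattern of that enhancement carries
the ECS parameters. The tissue-level model is the anisotropic
diffusion--clearance equation

$$\frac{\partial C}{\partial t}
  = D_x \frac{\partial^2 C}{\partial x^2}
  + D_y \frac{\partial^2 C}{\partial y^2}
  + D_z \frac{\partial^2 C}{\partial z^2}
  - kC + \frac{Q}{\alpha}\,\delta,$$

where $C$ is the tracer concentration at a voxel, $D_x, D_y, D_z$ are the
effective (hindered) diffusion coefficients, $k$ is a first-order clearance
rate, $Q$ the injected amount, and $\alpha$ the ECS volume fraction: the
tracer is confined to the extracellular fraction of each voxel, so the
source concentration is amplified by $1/\alpha$. For a free medium and an
instantaneous point bolus the solution is the anisotropic heat kernel with
exponential decay,

$$C(\mathbf r, t) = \frac{Q/\alpha}
  {8 (\pi t)^{3/2} \sqrt{D_x D_y D_z}}
  \exp\!\Big(-\sum_i \frac{r_i^2}{4 D_i t} - kt\Big),$$

implemented in `pointSourceConcentration()` / `evaluateField()`. Four
summary parameters are reported per study (`ECSResult`): the scalar
effective diffusion coefficient $D^*$ (geometric mean of the axis
coefficients), the clearance coefficient $k'$, the half-life $T_{1/2}$ of
the region-of-interest enhancement curve, and the volume fraction $\alpha$
recovered from the fitted amplitude $A = Q/\alpha$.

### Assumptions

* homogeneous, anisotropic-but-axis-aligned medium: no spatially varying
  $D$ or $k$, no compartments, no vascular input function;
* instantaneous bolus by default. A 2 µl infusion lasts minutes while the
  observation horizon is 240 min, so the convolution correction (supported
  via `SourceBolus(duration = ...)`) is negligible for the study design
  emulated here;
* linear concentration-to-enhancement mapping by default (valid at small
  concentrations); a saturating spoiled-gradient-echo relaxivity mode is
  provided for realism studies;
* magnitude (Rician) noise with spatially constant $\sigma$.

## Units

Internal units are mm and minutes: $D$ in mm²/min, $k$ in 1/min. Reported
ECS diffusivities are conventionally displayed on a $10^4 \times$ mm²/s
scale, so an internal $D = 0.0185$ mm²/min prints as $3.09$;
`internalToReportedD()` / `reportedToInternalD()` convert (the factor is
configurable). The same display convention is applied to $k'$ when a
reporting-scale value is requested. These display scalings are labelling
conventions only; all computation is in internal units. Note that a single
linear scale cannot simultaneously reproduce tabulated $k'$ values and
tabulated half-lives ($T_{1/2} = \ln 2 / k$ at the whole-domain level);
the simulation presets therefore treat the tabulated $k'$ column as an
opaque reported scale and derive the physical clearance rate from the
half-life column, which preserves the sign structure of every group
contrast.

## Forward solvers

The analytic kernel is the primary forward model (it is what the estimator
fits). An independent finite-difference solver (`solveFD()`) cross-checks
it and supports boundary studies:

* **implicit** (default): operator-split, locally one-dimensional sweeps.
  With constant coefficients the axis operators commute, so splitting
  introduces no additional error order; each sweep solves a tridiagonal
  system by the Thomas algorithm. The spatial stencil is the compact
  fourth-order Crandall/Douglas form by default (`spatialOrder = 4`),
  which keeps far-field ("deep tail") relative errors small at practical
  voxel sizes; `spatialOrder = 2` gives classic Crank--Nicolson.
  Unconditionally stable; default $\Delta t = 0.5$ min.
* **explicit** forward-time central-space, with the stability bound
  $\Delta t \le 1 / (2\sum_i D_i / h_i^2)$ enforced before integration.

The clearance term is applied exactly per step ($e^{-k\Delta t}$). With
no-flux boundaries and $k = 0$ both schemes conserve the discrete mass
exactly. The point source is represented by the exact analytic kernel at a
warmup time at which its standard deviation spans `warmupVoxels` (default
3) voxels: a grid delta does not converge to the Green's function at early
times, while the warmup start is exact. The default no-flux boundary on a
domain several diffusion lengths wide emulates an effectively infinite
medium.

## Synthetic studies and cohorts

`makeAnimal()` composes the forward model, the signal model and the noise
model into a 4D study with attached ground truth; `makeGroupDataset()`
draws per-animal truths from group-level (mean, SD) designs.
`defaultDesigns()` provides sham-like, PD-like (6-OHDA-lesioned), NST-like
and ST-like (lesioned + subthalamic deep-brain stimulation) presets whose
reporting-scale means and SDs equal the reference rows in
`referenceECSSummaries()`; each sampled animal's physical truth is
$D = $ `reportedToInternalD(D*)`, $k = \ln 2 / T_{1/2}$, $\alpha$ from the
percent column, truncated to physical ranges by resampling.

Default study conditions (chosen once, as the simulated analogue of the
emulated rat experiment):

* grid: $48^3$ voxels of 0.5 mm (a 24 mm cube, rat-brain scale, matching
  the acquisition voxel size), injection at the center;
* injection: 2 µl of 10 mM tracer, i.e. $Q = 20$ nmol;
* schedule: baseline plus scans at 15, 30, 60, 90, 120, 180, 240 min (the
  published design states the 240-min horizon and the ~5 min scan length
  but not every time point; this schedule is this package's choice);
* noise: Rician at peak SNR 20 (the SD is anchored to the maximum
  noiseless enhancement over the whole series).

What the generator does **not** emulate: anatomy (no tissue/CSF
boundaries, no heterogeneous compartments), partial-volume effects beyond
voxel averaging, motion, B0/B1 inhomogeneity, or the lesion biology
itself (groups differ only through their parameter presets). Passing
recovery tests on these phantoms therefore demonstrates correctness of
the estimator under the stated model, not robustness to everything real
data can do.

## Parameter estimation

`fitDiffusionModel()` fits the closed-form kernel to voxel × time data by
Levenberg--Marquardt under box constraints
($D \in [10^{-4}, 1]$ mm²/min, $k \in [0, 0.2]$ /min, $A > 0$), starting
from spatial-moment estimates (`momentsInit()`: per-axis variance growth
$\mathrm{Var}_i(t) = 2 D_i t + c_i$ and log total-signal decay). The
isotropic single-$D$ fit is the default, matching the single reported
$D^*$; the per-axis fit is available.

For noiseless or Gaussian-noise data the objective is plain least squares
on baseline-subtracted enhancement over informative voxels (peak
enhancement above 3 baseline-noise SDs). For **Rician** data that
objective is biased twice over: the magnitude noise floor inflates weak
signals (so the fitted decay is too fast), and selecting voxels by their
own noisy peak preferentially retains upward excursions. The Rician path
therefore

1. selects voxels where the *initial model's* predicted peak exceeds
   `predFloor` (default 0.2) noise SDs -- selection on the model, not on
   each voxel's own noise, is unbiased;
2. fits the exact second-moment relation $E[S^2] = s^2 + 2\sigma^2$:
   residuals $(S^2 - 2\sigma^2) - \mathrm{pred}^2$ have mean zero at the
   true parameters at any SNR;
3. applies iteratively reweighted least squares with weights
   $1/\sqrt{\mathrm{Var}(S^2)}$ frozen between rounds (weights that move
   within an optimization step would let the optimizer trade variance for
   fit).

At peak SNR 20 under the default design this attains median absolute
relative errors of roughly 1% ($D$), 7% ($k$) and 1.5% ($\alpha$),
close to the Cramér--Rao bound for $k$ (~6%).

### Half-life

$T_{1/2}$ is measured on the ROI mean-enhancement curve: time from the
curve's global peak to the first crossing of half the peak, log-linearly
interpolated (exact for exponentials); crossings never reached within the
schedule give a right-censored result, and with noisy multiple crossings
the first one after the global peak is used. For Rician studies the curve
is built from bias-corrected amplitudes
$\sqrt{\max(S^2 - 2\hat\sigma^2, 0)}$. The model-implied whole-domain
half-life $\ln 2 / \hat k$ is reported alongside (`ThalfModel`); the two
agree for whole-domain totals but differ for local ROIs, where diffusive
escape shortens the measured value.

The default ROI is a 4 mm-radius sphere at the injection site
(`sphereROI()`). The radius matters: diffusive escape shortens $T_{1/2}$
more for faster-diffusing (PD-like) tracers while slower clearance
lengthens it, and near a ~3 mm radius the two effects cancel between the
sham-like and PD-like presets. At 4 mm the clearance ordering of the
presets is preserved, while the region remains local at rat-brain scale.

## Decs/ADCe mapping

`computeLocalDMap()` produces the voxelwise map of the local diffusion
parameter by a windowed fit: for each informative voxel, the window
(default radius 2 voxels) × all post-injection times is fitted for (local
$D$, amplitude) with $k$ held at the study-level estimate. Voxels failing
the informative criterion are masked as NA, never zero-filled.
`renderContour2D()` and `renderWireframe3D()` follow the Decs-mapping
display convention -- lowest value blue, highest red, with surface height
encoding the parameter and the contour plot on the bottom plane -- and are
pure functions of their inputs (byte-identical re-renders).

## Group statistics

The statistics layer operates on printed-style summaries (label, mean, SD,
n) as well as raw values. `anovaFromSummary()` computes the one-way ANOVA
exactly as raw data with those moments would
($SS_B = \sum n_i(\bar x_i - \bar x)^2$, $SS_W = \sum (n_i - 1) s_i^2$);
`momentMatchedSample()` constructs raw data with exactly stated moments,
which is how the two pathways are proven equivalent in the tests.
`posthocPooled()` uses the pooled within-group mean square and its full
error degrees of freedom -- the ANOVA-consistent pairwise form -- with
Benjamini--Hochberg adjustment across the family of reported contrasts
(the published tables report ANOVA-then-FDR without defining the family;
all pairwise contrasts per endpoint is this package's choice).
`welchTFromSummary()` is provided as the unequal-variance alternative, and
`pearsonCor()` wraps the Pearson test. One caution recorded here because
it is easy to assume otherwise: BH adjustment is *not* idempotent in
general, so re-adjusting already-adjusted p-values is an error in an
analysis pipeline.

## Numerical choices and degenerate inputs

* Fit tolerances: LM `ftol = ptol = 1e-10`, at most 150 iterations;
  non-convergence is flagged on the result, never silent.
* All-zero studies, empty ROI masks, too-few time points, non-positive
  amplitudes and out-of-range probabilities are errors, not warnings.
* Voxel caps (default 4000) keep fits at desk scale; the highest-signal
  (noiseless path) or nearest (Rician path) voxels are kept
  deterministically.
* Seeds: every stochastic routine either takes a seed or documents that
  it draws from the caller's stream; seeded draws restore the caller's
  RNG state.
* Validation sizes: the finite-difference cross-checks in the test-suite
  run on $64^3$ grids at 0.25 mm over the full 240-min horizon; recovery
  Monte-Carlos use 20 seeds at the default design, and the cohort
  sign-reproduction study uses 40 repetitions of n = 6 cohorts on a
  $32^3$ grid. These sizes were chosen as the package's own desk-scale
  validation conditions.

## Known limitations

* The estimator assumes the point-source free-space kernel; real data
  with strong boundary effects (ventricles, tissue interfaces) violate
  this and would need the FD forward model in the loop.
* $\alpha$ is identified only through the amplitude $Q/\alpha$ and
  therefore requires a calibrated enhancement-concentration relation
  (known $\kappa$ or relaxivity); with a long-TR MPRAGE-style sequence at
  TR = 1.5 s the relaxivity-mode enhancement saturates at ~1.4%, so the
  inversion pathway needs a short-TR spoiled-gradient regime instead.
* The measured ROI half-life is an operational quantity: it depends on
  the ROI radius and, at low SNR, on the residual noise floor. The
  model-implied $\ln 2/\hat k$ is the cleaner clearance summary and both
  are reported.
* No registration, motion or partial-volume correction.
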