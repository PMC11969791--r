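# ecstracer

Tracer-based MRI quantification of the brain extracellular space (ECS) in R.

A paramagnetic tracer (such as Gd-DTPA) injected into brain tissue spreads
through the extracellular space by hindered diffusion and is removed by
interstitial-fluid drainage; because it shortens T1, its concentration is
visible as signal enhancement in T1-weighted MRI. From a 4D enhancement
series this package estimates the four standard ECS parameters — the
effective diffusion coefficient D\*, the clearance coefficient k′, the
tracer half-life T½, and the ECS volume fraction α — the quantities used to
compare, e.g., sham, 6-OHDA-lesioned (PD-model) and deep-brain-stimulated
rat groups. It is aimed at researchers who want the full measurement chain
— forward model, simulated studies with known ground truth, estimator,
voxelwise Decs/ADCe mapping, and group statistics — testable offline on
synthetic data.

## The model

The tissue-level model is the anisotropic diffusion–clearance equation

∂C/∂t = Dx ∂²C/∂x² + Dy ∂²C/∂y² + Dz ∂²C/∂z² − kC + (Q/α)·δ,

whose free-space point-bolus solution is the anisotropic heat kernel with
exponential decay,

C(r, t) = (Q/α) · [8(πt)^{3/2} √(DxDyDz)]⁻¹ · exp(−Σᵢ rᵢ²/(4Dᵢt) − kt).

The package provides this closed form (the estimator's forward model), an
independent finite-difference solver (operator-split implicit, compact
fourth-order in space; explicit scheme with enforced stability bound) for
cross-validation, a T1 signal and Rician noise layer, nonlinear
least-squares estimation of (D, k, A = Q/α) with a Rician-unbiased
second-moment objective, and a summary-statistics ANOVA/FDR layer that
works directly on printed (mean ± SD, n) tables.

## Worked example

Simulate one animal with known ground truth and recover its parameters:

```r
library(ecstracer)

truth <- DiffusionParams(0.02, k = 0.008, alpha = 0.18)   # mm^2/min, 1/min
study <- makeAnimal(truth, grid = Grid3D(48, 0.5),        # 24 mm cube
                    noise = NoiseModel("rician", NA), peakSNR = 20,
                    seed = 7)
fitDiffusionModel(study)
```

```
ECSResult (tracer-based ECS parameter fit)
  D*    : 0.01997 mm^2/min (3.33 reporting units)
  k'    : 0.008023 /min (1.34 reporting units)
  T1/2  : 19.89 min (model ln2/k = 86.39 min)
  alpha : 17.93 %
  fit   : RSS 1.549e+04, R^2 0.4709, converged
```

D\*, k′ and α recover the truth (0.02, 0.008, 18%) to well under 1% at
peak SNR 20. `T1/2` is the operational half-life of the measured
4-mm-sphere ROI curve — shortened by diffusive escape from the ROI —
while `ln2/k` is the model-implied whole-domain half-life; both are
reported. The R² is taken over all model-selected voxels, many of which
are deliberately near the noise floor (they carry clearance
information), so values well below 1 are expected for noisy studies.

Group-level statistics straight from a printed table:

```r
g <- groupSummary(c("sham", "pd", "nst", "st"),
                  mean = c(3.09, 4.21, 4.12, 3.74),
                  sd   = c(0.08, 0.13, 0.19, 0.27), n = 6)
anovaFromSummary(g)
#         F df1 df2            p
# 1 47.0325   3  20 3.031224e-09
posthocPooled(g, pairs = list(c(2, 1)))
#   groupA groupB        t df            p   p_adjusted
# 1     pd   sham 10.66667 20 1.057335e-09 1.057335e-09
```

A shell interface covers the same pipeline:
`./exec/ecstracer simulate --design sham --seed 1 --out d/`,
then `fit`, `map` and `stats` subcommands (`--help` for usage).

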