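Package: ecstracer
Title: Tracer-Based MRI Quantification of Brain Extracellular Space
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and inverse estimation for tracer-based
    magnetic resonance imaging of the brain extracellular space (ECS).
    Implements the anisotropic diffusion-clearance equation for an injected
    paramagnetic tracer (analytic free-space Green's function and a finite
    difference solver), T1-weighted signal enhancement with Rician noise,
    synthetic tracer-study and cohort generators with known ground truth,
    nonlinear least-squares estimation of the ECS parameter quartet
    (effective diffusion coefficient D*, clearance coefficient k', half-life
    T1/2 and volume fraction alpha), voxelwise diffusion-parameter
    (Decs/ADCe) mapping with 2D contour and 3D wireframe rendering, and a
    group-statistics layer (summary-statistics one-way ANOVA, pooled and
    Welch pairwise contrasts with Benjamini-Hochberg false discovery rate
    control, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    RNifti,
    minpack.lm,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'group-stats.R'
    'signal-model.R'
    'forward-model.R'
    'estimation.R'
    'decs-mapping.R'
    'reference-tables.R'
    'synthetic-data.R'
    'io.R'
    'cli.R'
    'fd-solver.R'
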