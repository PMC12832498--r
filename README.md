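# structura

Structure-guided restoration of degraded 2-D grayscale images, aimed at
scientists working with blurred, noisy, sensor-distorted image data
(microscopy fields, scanned sections, screening images) who know — or can
model — how the degradation happened and want a reproducible, fully
inspectable reconstruction pipeline with no training data and no GPU.

## The model

An observation `y` is modeled as

    y = G(H(x)) + ε,        ε = ε_G + ε_S

where `x` is the latent image in [0, 1], `H` is a blur operator (a single
normalized kernel, or a *kernel field* with a distinct point-spread function
per pixel), `G` an optional monotone sensor map `v ↦ clip(v^γ)`, `ε_G`
Gaussian noise with possibly spatially varying σ, and `ε_S` sparse impulse
outliers. A variant mixes the blurred latent with a dominant-noise image
through an attention map: `y = α ⊙ H(x) + (1 − α) ⊙ η`.

Reconstruction runs a *progressive structure-guided optimizer*: iterative
minimization of

    J_t(x) = Σ_i ω_i^t (y_i − H(x)_i)² + λ Σ_{(i,j)∈E_t} w_ij^t (x_i − x_j)²

where the per-pixel weights `ω^t` come from a confidence map
`C_t(i) = exp(−(y_i − H(x_t)_i)²/σ²)` thresholded into reliable/uncertain
regions, and the regularizer is a graph Laplacian over a k-nearest-neighbor
pixel-similarity graph built from learned features of the current iterate.
Every `K = 5` iterations the graph, confidence map and thresholds are
restructured; steps use backtracking line search (the objective never
increases), a decaying unsharp sharpening correction, and a diminishing
residual-energy stopping rule. Dynamic per-pixel filtering (softmax-
normalized content-adaptive kernels with attention gating), multiscale
refinement and uncertainty-aware correction are available as standalone
building blocks.

A synthetic phantom generator (edges + textures + ridges, four frozen
degradation scenarios) makes everything testable offline with known ground
truth.

## Worked example

```r
library(structura)

sc  <- make_scenario("uniform_blur_gauss")   # 64x64 phantom, 5x5 Gaussian
sim <- simulate_scenario(sc)                 # blur sigma = 1, noise sigma = 0.02

image_metrics(sim$y, sim$x_true)$psnr_db
#> [1] 26.60736

res <- run_psgo(sim$y, sc$spec, psgo_schedules(), seed = 0)
res
#> psgo_result: 60 iterations
#>   final J = 1.3475, residual energy = 1.31294

image_metrics(res$x_hat, sim$x_true)$psnr_db
#> [1] 29.10263
```

The degraded observation starts at 26.6 dB PSNR against the ground-truth
phantom; sixty optimizer iterations raise it to 29.1 dB (+2.5 dB). The
returned trace logs, per iteration, the objective before/after the step, the
residual energy, the fraction of pixels currently deemed reliable, and the
step size and confidence threshold in force.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/structura simulate    --scenario uniform_blur_gauss --outdir sim/
Rscript inst/scripts/structura reconstruct --input sim/y.png --config run.toml \
                                           --output xhat.png --log trace.csv --seed 0
Rscript inst/scripts/structura evaluate    --input xhat.png --reference sim/x_true.png
```

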