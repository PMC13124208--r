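# mndpipe

Motor neuron diseases (MND) — ALS, primary lateral sclerosis (PLS),
progressive bulbar palsy (PBP) and progressive muscular atrophy (PMA) —
overlap clinically with many other neuromuscular disorders, and imaging
findings such as the hypointense "motor band" along the precentral gyri are
subtle. `mndpipe` is an R implementation of a five-stage pipeline for
classifying 2-D multimodal brain images (MRI, CT, PET, DTI) into the five
categories *normal / ALS / PLS / PBP / PMA*, aimed at researchers who want a
tested, fully seeded, CPU-sized reference implementation of each stage:

1. **ADHE** — adaptive dynamic histogram equalization for MRI/CT: Gaussian
   smoothing of the 256-bin histogram, mode detection, partitioning at the
   cuts between consecutive modes with grouped medians
   `L_m + ((N/2 − F_{m−1})/f_m)·C`, and per-partition equalization with
   count-proportional dynamic range allocation.
2. **ETVB** — a total-variation-style speckle denoiser for PET/DTI in which
   the TV regularizer is replaced by a bilateral term
   `ũ(k) = Σ_p G_c(‖p−k‖) G_s(|u(p)−u(k)|) u(p) / Σ_p G_c G_s`, solved in the
   log domain (multiplicative speckle `f = T·η` becomes additive) by the
   damped fixed point `u ← (f/σ_fu² + λũ(u)) / (1/σ_fu² + λ)`.
3. **Res4Net-CBAM** — a four-block residual network with convolutional block
   attention (channel attention `M_c = σ(MLP(avgpool)+MLP(maxpool))`, spatial
   attention `M_s = σ(conv₇ₓ₇[avgmap; maxmap])`) exporting a 32-dim
   penultimate feature vector per image; convolutions are im2col + BLAS in
   C++, the backward pass is hand-derived and finite-difference verified.
4. **Dove swarm optimization** — a grid swarm with bound-anchored corner
   initialization, learning rate `η(t) = 0.1(1 − t/T)`, satisfaction dynamics
   `S_j ← λS_j + exp(f_j − f_best)` and moves
   `w_j ← w_j + ηβ_j(w_ds − w_j)`,
   `β_j = ((S_ds−S_j)/S_ds)(1 − ‖w_j−w_ds‖/maxDistance)`; wrapped as a binary
   feature selector (threshold 0.5, CV-accuracy-minus-sparsity fitness).
5. **DBN** — stacked restricted Boltzmann machines (energy
   `A(v,h) = −vᵀWh − bᵀv − cᵀh`, CD-1 pretraining) fine-tuned with a softmax
   head; exact partition functions of toy RBMs are available by enumeration
   for verification.

Because clinical MND image collections are rarely shareable, the package
ships a parametric phantom generator (`make_phantom()`, `make_dataset()`)
that emulates the intensity, texture, and noise structure each stage
assumes — elliptical brains with class-dependent cortical bands, modality
profiles, low-contrast regimes, and multiplicative speckle — so the entire
pipeline is testable end to end. See the vignette
(`vignettes/mnd-imaging-pipeline.Rmd`) for the models and design rationale.

## Worked example

```r
library(mndpipe)

# a speckled PET phantom of the ALS class, and its clean counterpart
clean <- make_phantom(phantom_spec("ALS", "PET", seed = 7))
noisy <- make_phantom(phantom_spec("ALS", "PET", speckle_sigma = 0.3, seed = 7))
den <- etvb_denoise(noisy, tvbf_params())
psnr(noisy, clean)      # 20.00 dB
psnr(den$image, clean)  # 23.55 dB after 12 fixed-point iterations

# a low-contrast MRI phantom before/after equalization
low <- make_phantom(phantom_spec("PLS", "MRI", contrast = 0.2,
                                 additive_sigma = 0.02, seed = 3))
sd(low); sd(adhe(low))  # 0.069 -> 0.287
```

The full pipeline — simulate 100 phantoms, preprocess by modality, train the
extractor on a stratified 60/20/20 split, select features with the swarm,
classify with the DBN, and score the held-out test images:

```r
res <- run_pipeline(pipeline_config(seed = 101))
res
#> <pipeline_result>
#>   test accuracy 0.950, macro-F1 0.949 (n = 20)
```

`res$report` holds per-class precision/recall/F1; artifacts (features.csv,
mask.json, predictions.csv, report.json, manifest.csv) are written to the
output directory and MD5-hashed, and identical config + seed reruns are
hash-identical. A thin command-line front end lives at `inst/cli/mndpipe`
(`mndpipe simulate ...`, `mndpipe preprocess --method adhe IN OUT`,
`mndpipe run --config cfg.yaml`).

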