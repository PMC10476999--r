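# ldctloss

Hybrid patch/frequency losses for low-dose CT denoising, with a
self-contained synthetic testbed: an analytic abdomen phantom generator, a
projection-domain low-dose simulator (Radon transform, Poisson counting
noise, filtered back-projection), a small residual CNN trainer with
hand-written gradients, image-quality metrics, and a command-line driver.
Everything is base R plus a small Rcpp/Armadillo kernel for the
convolutions — no deep-learning framework is required.

## The problem

Reducing the X-ray dose of a CT scan reduces the photon count reaching the
detector, and the resulting quantum noise degrades the reconstructed image.
Learned denoisers map a low-dose CT (LDCT) image to an estimate of its
normal-dose counterpart (NDCT). Networks trained with a plain mean-absolute
error (MAE) objective treat every region of the image and every spatial
frequency equally, so they under-weight small high-error regions (lesions,
organ boundaries) and tend to over-smooth fine texture. This package
implements a hybrid objective that addresses both effects and provides the
scaffolding needed to study it end to end on synthetic data.

## The loss

For a generated image `G` and target `T` of the same shape:

**Adaptive weighted patch loss (WPLoss).** Partition the pair into `N`
non-overlapping patches on an `r × c` grid (default 4 × 4). With per-patch
mean absolute errors `l_i`, the weights are

    w_i = clamp( l_i / median(l) , 0.25 , 4 )

and the loss is `L_WP = Σ_i w_i · l_i`. Patches that are currently harder
to reconstruct get up to 4× the gradient signal; weights are treated as
constants during backpropagation (they scale, but are not differentiated).
If all patch errors are zero, all weights are 1.

**High-frequency loss (HFLoss).** Let `H(x)` be an ideal high-pass filter
applied in the 2-D DFT domain, keeping frequencies with centered normalized
radius `ρ = sqrt((u/m)² + (v/n)²) > r0` (default `r0 = 0.1`; the DC bin is
always removed, and a Gaussian-profile variant is available). The loss is
the mean absolute difference of the filtered images,

    L_HF = mean | H(G) − H(T) | ,

which penalizes exactly the fine detail that MAE-style objectives smooth
away.

**Hybrid.** `L = α1 · L_WP + α2 · L_HF` with `α1 = α2 = 1` by default. The
loss is positively 1-homogeneous, its two components are reported
separately in a `loss_report` object, and `hybrid_loss_grad()` returns the
exact analytic gradient (verified against central finite differences with
the patch weights frozen, per the backpropagation contract above).

## Worked example

Simulate a quarter-dose scan of a synthetic abdomen phantom and score the
loss between the low-dose image and its clean target:

```r
library(ldctloss)

phantom <- generate_phantom(phantom_spec(size = 64, seed = 12))   # HU image
ldct <- simulate_ldct(phantom,
                      dose_model(N0 = 1e5, dose_fraction = 0.25, seed = 99),
                      n_angles = 90)

psnr(ldct$pixels, phantom$pixels)
#> [1] 28.39548
ssim(ldct$pixels, phantom$pixels, data_range = 3000)
#> [1] 0.8682043

stats <- compute_normalization_stats(list(phantom))
g <- normalize_ct(ldct, stats)$pixels
t <- normalize_ct(phantom, stats)$pixels
hybrid_loss(g, t, hybrid_config())
#> <loss_report wp=1.1805 hf=0.0706335 hybrid=1.25113 (alpha1=1, alpha2=1)>
```

Train the small residual CNN on a 30-pair synthetic dataset (about a minute
on a laptop) and denoise a held-out test image:

```r
dir <- file.path(tempdir(), "readme-data")
generate_dataset(30, dir, spec = phantom_spec(size = 64),
                 dose = dose_model(N0 = 1e5, dose_fraction = 0.25),
                 master_seed = 7, n_angles = 90)
data <- load_dataset(dir)

fit <- train_denoiser(data, train_config(loss = "hybrid", epochs = 25,
                                         learning_rate = 1e-3, batch_size = 1,
                                         seed = 3))
fit
#> Residual CT denoiser (4 conv layers, 16 channels), loss = hybrid
#>   trained 25 epochs, final train loss 0.480522
#>   final validation PSNR 37.48 dB, SSIM 0.9766

pair <- data$test[[1]]
den <- denoise(fit, pair$ldct)
c(ldct = psnr(pair$ldct$pixels, pair$ndct$pixels),
  denoised = psnr(den$pixels, pair$ndct$pixels))
#>     ldct denoised
#> 28.44064 37.15515
```

`train_denoiser()` returns a classed `ldct_denoiser` object with `print`,
`summary`, `coef`, `predict` and `plot` methods, and `ablation_run()`
repeats the training across loss variants (`mae`, `wp`, `hf`, `hybrid`) and
tabulates test-set PSNR/SSIM against the noisy-input baseline.

A command-line driver exposing the same pipeline (dataset generation,
simulation, training, evaluation, ablation) is installed at
`inst/cli/ldctloss`; run it with no arguments for usage.

## Documentation

The methods vignette (`vignettes/hybrid-loss-methods.Rmd`) describes the
model, the simulator's assumptions and numerical choices, the phantom
generator, and known limitations.

## License

MIT (see `LICENSE`).
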