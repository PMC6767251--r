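# silact — sinogram inpainting for ultra-limited-angle CT

CT reconstruction solves the discrete imaging model **g = A u**: the
sinogram `g` holds line integrals of the attenuation image `u` along the
rays encoded in the system matrix `A`. When the scanner can only cover a
narrow arc — less than 90° of the 180° a complete parallel scan needs — a
contiguous block of sinogram rows is missing and the problem becomes
severely ill-posed: filtered back-projection (FBP) and even
total-variation-regularised iterative reconstruction (SART-TV) leave heavy
directional artifacts. `silact` is for researchers studying this
*ultra-limited-angle* regime.

The package implements a sinogram-domain remedy end to end:

* a Siddon ray-driven **projector** for parallel and fan beam with an
  exact adjoint, Ram–Lak **FBP**, and **SART-TV**
  (view-sequential SART sweeps alternated with adaptive-step TV descent,
  defaults α = 0.01, α_s = 0.95, 15 iterations × 10 TV steps);
* a **synthetic phantom / paired-dataset generator** reproducing the
  published recipe: images rescaled to [0, 0.255], 512-view/512-bin
  sinograms over 180° normalised to [0, 1], Gaussian noise of variance
  2·10⁻⁶, and five 120° deletion windows (1°–120°, …, 61°–180°; 341 of
  512 views each);
* a **conditional GAN** that inpaints the deleted block: a U-Net generator
  (stride-2 4×4 convolutions, channels 64/128/256 then 512, mirrored
  decoder with skip connections) against a five-layer patch discriminator,
  trained with the joint objective

  `L = L_cGAN + λ₁·L_sino + λ₂·L_recon`,  λ₁ = 120, λ₂ = 10⁻⁵,

  where `L_sino` is the sinogram-domain L1 error and `L_recon` is the L1
  error between FBP reconstructions, back-propagated through the package's
  own differentiable FBP (its gradient is the FBP adjoint, since FBP is
  linear). The conv/transposed-conv layers, batch norm, dropout and Adam
  are implemented in the package on single-precision im2col/GEMM kernels,
  so desk-scale models train on a CPU;
* **metrics** (RMSE, NMAD, PSNR, SSIM), an end-to-end pipeline, a λ₁/λ₂
  grid-search harness, and a `silact` command-line tool (in `exec/`).

## Worked example

```r
library(silact)
grid    <- image_grid(128, 128, pixel_size = 1)
geom    <- scan_geometry("parallel", n_views = 180, n_bins = 128, bin_size = 1)
phantom <- make_phantom("random_ellipses", grid, seed = 5)
sino    <- forward_project(phantom, geom, grid)          # g = A u
limited <- make_limited_angle(sino, deletion_window(46, 120))
sum(!limited$valid_mask)                                 # 120 of 180 views deleted

full_fbp <- filtered_back_project(sino, grid)
full_stv <- sart_tv(sino, grid, recon_params(15, 10, 0.01, 0.95))
lim_stv  <- sart_tv(limited, grid, recon_params(50, 15, 0.01, 0.95))
rmse(phantom, full_fbp)   # 0.0201  (discretisation error of analytic FBP)
rmse(phantom, full_stv)   # 0.0015  (complete data: SART-TV ~13x better)
rmse(phantom, lim_stv)    # 0.0684  (only 60 degrees measured)
psnr(phantom, lim_stv)    # 24.79 dB
```

With complete data SART-TV is excellent; deleting a 120° block degrades it
by a factor ~45 even with 50 iterations — the gap the inpainting network
is trained to close. The full loop at desk scale (40 phantoms × 5 windows
= 200 training pairs of 64×64 sinograms, depth-6 generator, 30 epochs,
roughly 15 CPU-minutes):

```r
pl <- run_pipeline(smoke_profile(), seed = 1)
pl$summary
#             method  psnr    rmse   nmad   ssim
#                FBP 17.84 0.03313 1.3786 0.1455
#            SART-TV 24.03 0.01642 0.4615 0.7446
#       SI-GAN + FBP 21.11 0.02309 0.9050 0.3392
#   SI-GAN + SART-TV 21.34 0.02248 0.7390 0.4863
colMeans(pl$sino_stats[, c("mae_zero_fill", "mae_inpainted")])
# mae_zero_fill mae_inpainted
#       0.2033        0.0714
```

Read this honestly: in the *sinogram domain* the trained model recovers
the deleted 120° block to a third of the zero-fill error on held-out
phantoms. In the *image domain*, at this miniature scale the limited-angle
SART-TV baseline still wins — piecewise-constant ellipse phantoms are the
ideal case for a TV prior, and 40 distinct training phantoms cap the
generator's held-out accuracy. Reconstructing the *true* complete sinogram
with the same 15-iteration SART-TV reaches PSNR ≈ 50 on these phantoms, so
the pipeline has ample headroom; the image-domain advantage of inpainting
reported for clinical data emerges with training diversity and resolution
far beyond a CPU smoke run. The methods vignette
(`vignettes/sinogram-inpainting.Rmd`) discusses this in detail.

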