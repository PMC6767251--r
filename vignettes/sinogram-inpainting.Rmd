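---
title: "Sinogram inpainting for ultra-limited-angle CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sinogram inpainting for ultra-limited-angle CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silact)
```

## The problem

X-ray CT reconstructs an attenuation image $u$ from line integrals
$g = A u$, where each row of the system matrix $A$ holds the exact
intersection lengths of one detector ray with the pixel grid. When the
gantry can only sweep a narrow arc — less than 90° of the 180° a parallel
(or short-scan fan) acquisition needs — a contiguous block of sinogram rows
is missing, $A$ acquires a large effective null space, and both analytic
(filtered back-projection, FBP) and regularised iterative methods
(SART-TV) produce images dominated by directional blur in the missing
orientation. We call this the ultra-limited-angle problem.

This package implements a sinogram-domain answer: a conditional GAN is
trained on paired (limited-angle, complete) sinograms to *inpaint* the
missing angular block, after which a classical method reconstructs the
estimated complete sinogram. The novelty relative to a plain image-to-image
GAN is a joint objective that penalises errors both in the sinogram domain
and — through a differentiable FBP — in the reconstructed image domain.

## The imaging model

`siddon_trace()` computes exact ray/pixel intersection lengths (the rows of
$A$), and `forward_project()` / `back_project()` apply $A$ and $A^T$ with
the identical traversal, so the pair is adjoint to machine precision — a
property the test suite verifies against a densely materialised $A$.
Parallel and flat-detector fan geometries are supported; view angles are
$\theta_k = k \cdot 180°/n_{\text{views}}$ on the half-open interval
$[0°, 180°)$, and detector bins are centred symmetrically about the
projection of the rotation centre.

FBP is realised as Ram–Lak ramp filtering in the frequency domain (views
zero-padded to the next power of two at least $2 n_{\text{bins}}$ to
suppress interperiod convolution; no apodisation window) followed by
back-projection with angular weight $\pi/n_{\text{views}}$ and the
discretisation factor $\Delta s / h^2$ that makes the Siddon adjoint
approximate the continuous back-projection integral. For fan mode a cosine
pre-weighting is applied and the ramp uses the bin spacing magnified to the
rotation centre; this is the standard flat-detector approximation (the
distance-dependent back-projection weight is omitted), which is adequate
here because FBP only serves as a training-loss operator and a baseline.
One wording caveat: the ramp is routinely described as "smoothing" the
projections before back-projection; as a frequency response it is the ideal
$|\omega|$ high-pass, and that is what is implemented.

Because FBP is linear, its Jacobian is itself; the adjoint
$\phi^T = c\,C F A$ (`fbp_adjoint()`) propagates image-domain gradients
back to the sinogram domain exactly, which the tests confirm against
central finite differences.

## Synthetic study conditions

Clinical slices are out of scope, so `make_phantom()` supplies the
canonical 10-ellipse head phantom and seeded random compositions of 5–12
ellipses as stand-ins. Dataset construction mirrors the published recipe:

1. every image is min–max rescaled to $[0, 0.255]$;
2. its sinogram is simulated by the ray-driven projector and min–max
   normalised to $[0, 1]$ (the scale is kept for later de-normalisation);
3. zero-mean Gaussian noise of variance $2 \times 10^{-6}$ is added — on
   the normalised scale, where that variance is meaningful;
4. for each of the five deletion windows starting at 1°, 16°, 31°, 46° and
   61° (each spanning 120°, i.e. 341 of 512 views), the window is
   zero-filled and the view mask set false, giving five 60°-scan training
   pairs per image. 1000 images × 5 windows = 5000 pairs at full scale.

The view-index mapping treats the printed degree labels as 1-based:
a window starting at $s°$ deletes `round(n_views · span/180)` views
beginning at index $\lfloor (s-1) \cdot n_\text{views}/180 \rfloor$, which
reproduces the printed counts (341 deleted views for 120°, 284 for 100°).
Deleted views are zero-filled (the value the network sees) and tracked by
an explicit mask, so measured data are never altered — bit-exactness of the
measured block is asserted in the tests. What the phantoms do not emulate:
anatomical texture, detector physics (scatter, beam hardening, blur), and
the "hard-to-penetrate direction" placement of missing angles in the real
test sets; window placement is therefore a configurable knob defaulting to
the mid-range 46°–165° position for held-out evaluation.

## The networks

The generator is a U-Net: a `depth`-level encoder of stride-2 4×4
convolutions with leaky-rectifier slope 0.2 and channels
64, 128, 256, then 512 for the remaining levels (nine levels at the full
512×512 scale), mirrored by stride-2 4×4 transposed convolutions with skip
connections, so each decoder level sees twice the channels of its encoder
partner. Choices the architecture description leaves open were resolved as
follows and are configurable:

* batch normalisation on all but the first encoder and last decoder layer
  (the image-to-image cGAN convention);
* plain rectifiers in the decoder and a sigmoid output to keep estimated
  sinograms in $[0, 1]$;
* the printed nine-deconvolution decoder ends at 64 channels, so a final
  1×1 convolution projects to the 1-channel sinogram;
* the noise input $z$ has no stated mechanism; the default is dropout
  (rate 0.5) in the first three decoder layers, active during training,
  with shape-preserving additive bottleneck noise ("channel") and "none"
  as alternatives.

The discriminator is the printed five-layer patch design — 4×4 kernels,
channels 64/128/256/512/1, strides 2/2/2/1/1, rectifier activations and a
final sigmoid — applied to the channel-concatenated (conditioning,
candidate) pair; its output is an $N \times N$ map of per-patch
probabilities whose arithmetic mean is the decision. `count_parameters()`
prints the exact per-layer ledger; the literal printed architecture totals
76.78M trainable scalars against the published headline figure of 87.833M.
Since bias, normalisation and output-head choices are unstated, the ledger
is logged rather than forced to agree.

## Training

The objective is
$L = L_{cGAN} + \lambda_1 L_{sino} + \lambda_2 L_{recon}$ with
$\lambda_1 = 120$ and $\lambda_2 = 10^{-5}$: the adversarial term, the
sinogram-domain mean absolute error, and the image-domain mean absolute
error between FBPs of the estimated and true sinograms, back-propagated
through the package's own differentiable FBP. Optimisation is alternating
Adam ($\beta_1 = 0.5$, $\beta_2 = 0.999$), learning rate 0.002 held for the
first half of training then decayed linearly towards zero. Two deliberate
deviations from the literal min–max statement, both standard practice and
both selectable: the generator minimises the non-saturating
$-\log D(x, G(x,z))$ rather than $\log(1 - D)$, and its adversarial
gradient is taken through the discriminator state *before* that batch's
discriminator update (a simultaneous-style step that also saves a forward
pass). Probabilities are clamped away from 0/1 by $10^{-7}$ inside the
logs. Non-finite losses abort training with a diagnostic rather than
continuing silently.

The layers run as single-precision im2col/GEMM kernels with weights, Adam
moments and gradients resident in a float parameter store, which is what
makes CPU training of the desk-scale model practical; training is
deterministic for a fixed seed, and a same-seed rerun reproduces the loss
history exactly.

At inference, `inpaint()` runs the generator deterministically (noise off),
clips to $[0, 1]$, and by default pastes the measured views back
bit-exactly, so only the deleted block is synthesised — whether to paste is
exposed because the published procedure does not say.

## Reconstruction

`sart_tv()` alternates one SART sweep with a block of TV descent steps.
The SART sweep is the classic view-sequential update: for each measured
view, row-normalised residuals are accumulated with intersection-length
weights, divided by the per-pixel weight sum, and applied immediately
(relaxation 1 by default; the factor is unstated in the source method and
exposed). The TV stage performs `tv_steps` normalised-gradient descent
steps on the anisotropic total variation (forward differences, reflective
boundary, $\varepsilon = 10^{-8}$ smoothing at the kink), with step length
$\alpha \cdot \lVert \Delta u_{\text{SART}} \rVert$ decayed by $\alpha_s$
after each step — the adaptive-steepest-descent convention. $\alpha$ is
reset at every outer iteration; the published phrase "after each
computation" is ambiguous between per-step and per-iteration decay, and
per-step decay within the block was adopted. Non-negativity is projected
after each outer iteration. Published constants: 15 iterations with 10 TV
steps, $\alpha = 0.01$, $\alpha_s = 0.95$ for estimated sinograms; 50
iterations with 15 TV steps for limited-angle baselines.

One numerical note: on very coarse systems (a handful of detector bins
barely covering the grid) the view-sequential sweep can admit spurious
fixed points because the per-view update is an approximate, not exact,
projection; with detector sampling at or below the pixel pitch — every
configuration the package ships — the tests show convergence to the unique
least-squares solution of a full-rank consistent system to machine
precision.

## Desk-scale study sizes and what they show

CPU-tractable sizes are used throughout the tests: the functional smoke
test trains the depth-6 generator on 200 pairs of 64×64 parallel-beam
sinograms (40 phantoms × 5 windows) for 30 epochs at batch 8 with the
published loss weights, then evaluates held-out phantoms deleted at the
46°–165° window. The suite asserts two things at this scale: that
inpainting beats the zero-fill baseline in the deleted block (it does,
robustly — held-out masked MAE roughly 0.04–0.12 against 0.17–0.24), and
that inpainting + SART-TV beats limited-angle SART-TV on RMSE, NMAD, PSNR
and SSIM, the ordering reported for clinical data. The second assertion
does *not* hold under these conditions and the test documents that
honestly: piecewise-constant random-ellipse phantoms are exactly the model
class total-variation regularisation is ideal for, so the limited-angle
SART-TV baseline is far stronger here than on anatomy, while the
generator's held-out accuracy is capped by the 40 distinct training
phantoms the 200-pair budget affords. Reconstructing the *true* complete
sinogram with the same 15-iteration SART-TV reaches PSNR ≈ 50 on these
phantoms — the pipeline itself has ample headroom — and at train-level
inpainting error the GAN route already wins PSNR/RMSE/NMAD (though not
SSIM, which penalises the GAN's residual texture on smooth phantoms).
Closing the remaining gap is a matter of training-set diversity and scale,
not of the machinery tested here; the published clinical metric values
came from 1000 slices at 512×512 and roughly 60 GPU-hours of training.
The full-scale profile (`paper_profile()`) carries those settings for
completeness.

## Metrics

`rmse()`, `nmad()`, `psnr()` and `ssim()` follow the standard definitions;
the PSNR peak is the reference image's actual maximum (the literal reading
of the published formula) rather than a fixed dynamic range, and SSIM uses
the standard 11×11 Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$,
$K_2 = 0.03$) with data range $\max(f_{\text{Ref}})$, averaged over valid
window positions. Metrics are computed over the full image; identical
images report PSNR as `Inf`. `lambda_grid_search()` retrains one model per
$(\lambda_1, \lambda_2)$ cell and scores held-out sinogram RMSE, the
harness behind the weight-selection heatmap.

## Known limitations

* 2D only; no cone-beam, scatter, beam hardening or detector blur.
* Fan-beam FBP uses the cosine-weighted approximation described above.
* The phantom generator does not imitate anatomy; transfer of the smoke
  results to clinical data is explicitly not claimed.
* HDF5 dataset bundles are replaced by a plain directory bundle (float
  TIFF + JSON metadata).
* Desk-scale GAN training, while deterministic, is single-threaded CPU
  code; the full 512×512, 400-epoch profile is not practical without
  accelerator hardware.
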