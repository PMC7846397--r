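---
title: "Reference-driven wavelet-sparsity deep image prior: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-driven wavelet-sparsity deep image prior: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

Accelerated MRI acquires only a subset of k-space: the measurement is
$\mathbf{y} = F_u \mathbf{I}_t$, where $F_u$ is the Fourier transform
restricted to an undersampling mask $U$ and $\mathbf{I}_t$ is the target
image. Recovering $\mathbf{I}_t$ from $\mathbf{y}$ is underdetermined, so a
prior is needed. The *deep image prior* (DIP) observes that the inductive
bias of an untrained convolutional network is itself a usable image prior:
fit a randomly initialised network $f(\theta \mid \mathbf{z})$, with fixed
noise input $\mathbf{z}$, to the single measurement by

$$\hat\theta = \arg\min_\theta \; \lVert \mathbf{y} - F_u f(\theta \mid
\mathbf{z}) \rVert_2^2 ,$$

and take $f(\hat\theta \mid \mathbf{z})$ as the reconstruction. No training
data or pre-trained weights enter anywhere; the network is re-fitted per
scan.

This package implements a strengthened variant that injects two further
priors:

1. **Structure**: the network input is not noise but a previously acquired
   high-resolution *reference image* $\mathbf{I}_r$ with similar anatomy, so
   structural detail flows into the output from iteration one.
2. **Sparsity**: the output is encouraged to be sparse in an orthonormal
   wavelet basis $\Psi$ through an $\ell_1$ penalty,

$$\hat\theta = \arg\min_\theta \;
\lVert \mathbf{y} - F_u f(\theta \mid \mathbf{I}_r) \rVert_2^2
+ \lambda \lVert \Psi f(\theta \mid \mathbf{I}_r) \rVert_1 .$$

Introducing $\alpha = \Psi f(\theta \mid \mathbf{I}_r)$ and a scaled
multiplier $\mu$ turns this into a constrained problem solved by ADMM, with
penalty parameter $\rho$:

* **theta step** — `theta_update()`: `sub_it` Adam steps on
  $\lVert \mathbf{y} - F_u f(\theta \mid \mathbf{I}_r)\rVert_2^2 +
  \tfrac{\rho}{2}\lVert \alpha^{k-1} - \Psi f(\theta \mid \mathbf{I}_r) -
  \mu^{k-1}\rVert_2^2$;
* **alpha step** — `alpha_update()`: the closed-form minimiser
  $\alpha^k = S_{\lambda/\rho}(\Psi f(\hat\theta^k \mid \mathbf{I}_r) +
  \mu^{k-1})$, with $S_\kappa$ the elementwise soft-thresholding operator;
* **mu step** — `mu_update()`: dual ascent on the splitting constraint,
  $\mu^k = \mu^{k-1} + \Psi f(\hat\theta^k \mid \mathbf{I}_r) - \alpha^k$.

After `max_it` cycles the network output is the raw reconstruction
(`recon_pre_correction`). A final **data-correction** step
(`data_correction()`) replaces its Fourier samples on $U$ by the acquired
$\mathbf{y}$, so that all measured data are preserved exactly and residual
error is confined to unmeasured k-space.

## Numerical conventions

**Fourier scaling.** `fourier()` is unitary (division by $n$), so Parseval
holds exactly and the magnitudes of $\lambda$ and $\rho$ transfer across
image sizes. Masks and spectra are stored DC-centred.

**Real image model, complex k-space.** Inputs are real magnitude images in
$[0,1]$; $\mathbf{y}$ is complex. The squared residual norm sums real and
imaginary parts. Displayed images are magnitudes of complex inverses.

**Data correction and its invariants.** The corrected k-space
$\mathbf{y}_{cor}$ is not Hermitian, so its inverse image is complex and a
magnitude image alone cannot reproduce $\mathbf{y}$ under $F$. The returned
image therefore carries `attr(, "kspace")` (the corrected spectrum) and
`attr(, "complex")` (the complex image); a second `data_correction()` call
reuses the complex channel. This makes the correction exactly idempotent and
keeps the projection property ($F(\text{result}) = \mathbf{y}$ on $U$) at
machine precision while the user-facing pixels stay the magnitude
convention.

**Wavelet transform.** Only the Haar family is provided: with periodic
boundary handling on power-of-two grids it is exactly orthonormal, its
adjoint equals its inverse (needed inside the theta-step gradient), and it
matches the published training settings (decomposition level 6 for 256 x 256
scans, 8 for 512 x 512). The $\ell_1$ penalty is applied to *all*
coefficients including the approximation band — the objective is written
without exclusions, and at depth 6-8 the approximation band is a negligible
fraction of coefficients.

**Network.** The hourglass encoder-decoder follows the published
configuration: per depth, a stride-2 conv + BN + LeakyReLU followed by a
stride-1 conv + BN + LeakyReLU on the way down; 1 x 1 conv skip branches; on
the way up bilinear 2x upsampling, concatenation with the skip feature, and
conv + BN + LeakyReLU; a 1 x 1 conv head with a sigmoid keeps outputs in
$[0,1]$. Unstated details follow common DIP practice and are fixed here:
LeakyReLU slope 0.1, reflection padding, skip branches at every depth fed
from the feature entering each encoder block, noise-input amplitude 0.1 for
the DIP baseline, and normalisation always using the current input's
statistics (a single-image batch), which makes every forward pass a pure
function of parameters and input — the basis of the bit-reproducibility
guarantee. There is no torch backend in this environment; convolution,
batch-norm, upsampling and their exact backward passes are implemented in
compiled code and verified against central finite differences.

**Dual-update sign.** With the augmented-Lagrangian penalty
$\tfrac{\rho}{2}\lVert\alpha - \Psi f - \mu\rVert^2$ and the thresholding
step $S_{\lambda/\rho}(\Psi f + \mu)$, this is scaled-dual ADMM with
multiplier $\nu = -\rho\,\mu$, and the consistent dual ascent is
$\mu \mathrel{+}= \Psi f - \alpha$. The opposite sign (which does appear in
print in this literature) satisfies
$\mu_{new} \approx 2\mu - \kappa\,\mathrm{sign}(\cdot)$, a positive feedback
that doubles the splitting residual $\lVert\alpha - \Psi f\rVert$ every
outer cycle instead of driving it to zero — empirically the reconstruction
survives (the theta step only ever feels the bounded residual
$-\kappa\,\mathrm{sign}$), but $\alpha$ and $\mu$ diverge and the
constraint is never approached. The package implements the convergent sign;
the feasibility-trend test in the suite is what caught the difference.

**Optimisation.** The published settings give only a learning rate (0.01),
iteration counts (`MaxIt` 50, `SubIt` 100) and $(\rho, \lambda) = (0.05,
10^{-4})$ (with $\rho = 0.07$ for the 512 x 512 group). Adam is used for the
theta step, as in standard DIP implementations, and its state persists
across outer ADMM iterations to avoid restart shocks. The inner stopping
rule is a fixed `sub_it` count. $\alpha^0 = \Psi f(\theta^0 \mid
\mathbf{I}_r)$ and $\mu^0 = 0$, so the proximity term starts at zero.

**Divergence guard.** The theta step tracks the best objective seen in the
inner loop and rolls back to those parameters if the final objective is
worse, so the inner objective never ends above its starting value (a
stronger guarantee than the nominal "no more than +5%" contract); a
non-finite loss raises an error naming the iteration. This choice keeps long
runs alive instead of aborting them, without masking real divergence, which
still surfaces as a non-finite loss.

**DIP baseline fairness.** The baseline uses `max_it * sub_it` plain Adam
steps on the fidelity loss — the same gradient-step budget as the ADMM
method — and the identical data-correction step afterwards.

## The phantom world

The in vivo scans used in the original experiments are not publicly
deposited, so the package ships a seeded generator of reference/target pairs
(`generate_pair()`): a skull ring plus `n_ellipses` random interior ellipses,
lightly smoothed, background exactly zero. The target jitters every
ellipse's centre/axes by up to `deformation` (default 0.05), intensities by
up to `contrast_shift` (default 0.1), and adds smooth random texture
(`texture_amp`, default 0.05) *to the target only*, so the reference never
leaks target-specific detail. The defaults were chosen once as a plausible
"same patient, earlier scan" similarity level and are exposed in the
configuration; `deformation` acts as a monotone structural-similarity dial.

These phantoms are noiseless, piecewise-smooth and strongly
wavelet-compressible. A green comparative test on them establishes that the
implementation realises the method's mechanism (structural prior + sparsity
+ data consistency beats DIP beats zero-filling); it does not establish
clinical image quality, robustness to acquisition noise, or the published
absolute metric values, which depend on the undeposited scans.

## Scaled-down testing preset

Full-scale settings (depth-6 network, 50 x 100 iterations, 256 x 256) are
CPU-hostile. The `"desk"` preset (`desk_admm_config()`) fixes: 128 x 128
images, depth-4 network with halved filter counts (16, 16, 32, 64; skips 8),
`MaxIt` 10, `SubIt` 50, all other values unchanged. All outputs carry a
`scale` label so desk results are never mistaken for full-scale ones. The
comparative acceptance tests run this preset on three seeded pairs at 30%
Cartesian sampling.

## Metrics

`rel_err()` is $\lVert\hat{x}-x\rVert_2 / \lVert x\rVert_2$. `psnr()` uses
the squared-error form $10\log_{10}(\mathrm{MAX}_x^2/\mathrm{MSE})$ with
$\mathrm{MAX}_x$ the largest ground-truth value (the printed source formula
omits the square on the error term, which would not be a PSNR; the standard
form is implemented). `ssim()` is the single global-statistics form with
constants $c_1 = 0.01$, $c_2 = 0.03$ exactly as published; because no
sliding window is described for it, the global form is the default and a
conventional 11 x 11 Gaussian-window variant is available via
`windowed = TRUE`.

## Known limitations

* Single-coil, on-grid Cartesian/radial/variable-density simulation only: no
  NUFFT, coil sensitivities, or acquisition noise models.
* Only the Haar wavelet; no biorthogonal or shift-invariant transforms.
* The radial mask meets its requested rate by trimming the outermost points
  of the final spoke — visually a marginally shorter last spoke.
* Whether Cartesian masks sample rows or columns was unstated; full rows
  (phase-encoding lines) are sampled.
* The reference is assumed registered to the target; no motion or
  registration error model.
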