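# rwsdip

Per-scan reconstruction of undersampled MR images with a reference-driven,
wavelet-sparsity constrained deep image prior — no training data, no
pre-trained weights.

## The problem

Accelerated MRI measures only a fraction of k-space: `y = F_u I_t`, where
`F_u` is the Fourier transform restricted to a sampling mask `U`. Recovering
the target image `I_t` is an underdetermined inverse problem. The *deep
image prior* (DIP) regularises it with the inductive bias of an untrained
CNN, fitted per scan to the single measurement. This package strengthens DIP
with two extra priors that clinical workflows can actually supply:

* **structure** — a previously acquired high-resolution reference image
  `I_r` of similar anatomy is used as the network input instead of noise;
* **sparsity** — an l1 penalty on the wavelet coefficients of the output,

```
min_theta  || y - F_u f(theta | I_r) ||_2^2  +  lambda || Psi f(theta | I_r) ||_1
```

solved by ADMM: `sub_it` Adam steps on the network (`theta_update`), a
closed-form soft-thresholding update of the wavelet code
`alpha^k = S_{lambda/rho}(Psi f + mu)` (`alpha_update`), and a dual ascent
`mu^k = mu + alpha - Psi f` (`mu_update`). After `max_it` cycles, a k-space
**data-correction** step re-inserts every acquired sample, so measured data
are preserved exactly and residual error is confined to unmeasured k-space.

The package also provides the zero-filling and traditional noise-input DIP
baselines (with identical gradient-step budget and the same correction step,
for fair comparison), Cartesian / radial / variable-density mask generators,
a seeded ellipse-phantom generator of reference/target pairs, RelErr / PSNR /
SSIM metrics, and an experiment runner for comparison, convergence and
parameter-sweep protocols. The hourglass network (conv + BN + LeakyReLU,
stride-2 downsampling, bilinear upsampling, 1x1-conv skip connections,
sigmoid head) and its exact backpropagation are implemented natively in
compiled code; everything is seeded and bit-reproducible.

## Worked example

```r
library(rwsdip)

pair <- generate_pair(phantom_pair_config(n = 64, seed = 1))  # reference + target
mask <- make_cartesian_mask(64, rate = 0.3, seed = 1)         # 30% phase-encoding lines
y    <- undersample(pair$target, mask)                        # simulated acquisition

cfg <- admm_config(max_it = 5, sub_it = 40, wavelet_level = 5,
                   net_spec = network_spec(depth_L = 3, n_d = c(8, 16, 32),
                                           n_s = rep(4, 3)),
                   seed = 1)

zf  <- zero_fill(y)
rws <- rws_dip_reconstruct(y, pair$reference, cfg, truth = pair$target)

metric_report(zf, pair$target)
metric_report(rws$recon_final, pair$target)
```

This prints (64 x 64 phantom, 30% Cartesian, reduced network):

```
zero-fill : RelErr 30.55%  PSNR  19.20 dB  SSIM 0.9225
rws-dip   : RelErr  5.22%  PSNR  34.54 dB  SSIM 0.9981
```

i.e. the reference-driven reconstruction cuts the relative l2 error about
six-fold over zero-filling and recovers structure almost perfectly
(SSIM near 1). `rws$history` holds per-ADMM-iteration objective and metric
values; `rws$recon_final` carries the corrected complex k-space as an
attribute, on which `F(result) == y` holds at every acquired location.

At the scaled-down "desk" preset (128 x 128, depth-4 network, 10 x 50
iterations, 3 phantom pairs, 30% Cartesian) the full comparison produced by
`run_experiment()` gives mean RelErr 28.5% / 4.5% / 2.7% and mean PSNR
21.0 / 37.1 / 41.3 dB for zero-filling / DIP / reference-driven DIP — the
same ordering on every metric that full-scale in vivo experiments report.

## Command line

A thin CLI over the same functions lives at `inst/cli/rwsdip.R`:

```sh
Rscript inst/cli/rwsdip.R phantom --n 128 --seed 1 --out-dir ph/
Rscript inst/cli/rwsdip.R mask --scheme cartesian --n 128 --rate 0.3 --out mask.h5
Rscript inst/cli/rwsdip.R acquire --image ph/target.png --mask mask.h5 --out k.h5
Rscript inst/cli/rwsdip.R recon --method rws_dip --kspace k.h5 \
        --reference ph/reference.png --truth ph/target.png --out-dir out/
```

`experiment` and `sweep` verbs drive `run_experiment()` /
`sweep_parameters()` from a YAML plan.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes an end-to-end seeded pipeline — phantom pair generation, Cartesian
undersampling, zero-filling and the reference-driven ADMM reconstruction —
prints the resulting RelErr / PSNR / SSIM, and writes the JSON summary to
`--out`.

## Further reading

`vignettes/rwsdip-methods.Rmd` documents the model, every numerical
convention (Fourier scaling, the complex channel behind data correction, BN
statistics, the divergence guard), what the phantom generator does and does
not emulate, and known limitations.
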