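# fdpr — feature-domain phase retrieval for computational microscopy

Phase retrieval recovers a complex optical wavefront (amplitude *and*
phase) from intensity-only camera frames. Classical solvers minimize the
pixel-wise difference between model-predicted and observed intensities,
which makes them fragile against everything real microscopes do to images:
uneven illumination, vignetting (half-bright/half-dark frames under oblique
LEDs), shot and read noise, and unknown pupil aberrations.

`fdpr` implements **feature-domain phase retrieval**: the regression is run
on extracted image features instead of raw pixels,

```
L(x, A_k) = sum_n D( Theta_S(I_n_obs), Theta_S(|A_n x|^2) )
            + alpha ||x - C(x)||^2 + sum_k beta_k ||A_k - C(A_k)||^2
```

where `x` is the unknown wavefront, `A_n` the (factorized, linear) forward
propagator of exposure `n`, `S` an intensity scaling, `Theta` a linear
feature extractor (first-order gradients or multi-level bior2.2 wavelet
detail bands), `D` a distance (charbonnier/l2), and `C` plug-and-play
refinement operators (amplitude thresholds, TV, guided filter, Hessian
curvature penalties) applied through an extended hybrid-input-output
constraint block. Optimization is Wirtinger gradient descent accelerated by
Adam or YOGI. The package ships:

* forward models for Fourier ptychographic microscopy (FPM), lensless coded
  ptychography, and inline holography, each as an operator chain with exact
  adjoints;
* the feature extractors, the loss, the Wirtinger engine and the constraint
  block (`fd_solve()`, returning a classed fit with `print`, `summary`,
  `coef`, `fitted`, `residuals`, `plot` methods);
* classical pixel-domain baselines: Gerchberg–Saxton, ePIE, EPRY, mPIE;
* synthetic phantoms and dataset generators (USAF-1951 targets, Zernike
  pupil screens, LED-array stacks with vignetting and Poisson+Gaussian
  noise, coded scan series, inline holograms) with bit-exact regeneration
  from their truth records;
* image-quality metrics: blind noise level, RMS contrast, PSNR, SSIM,
  USAF line widths, Abbe resolution.

## Worked example: vignetting-robust FPM

```r
library(fdpr)

# a 64 px test object behind a 9 x 9 LED array, NA 0.1 objective
kv  <- led_grid_kvectors(9, 1800, 50000, 0.532)
sys <- fpm_system(c(64, 64), objective_na = 0.1, wavelength_um = 0.532,
                  object_pitch_um = 0.5, led_kvectors = kv,
                  downsample_factor = 2)
obj <- phantom_cell_blobs(c(64, 64), 15, c(0.5, 1), c(0, 1), seed = 2)

# oblique frames lose half their light; 1% read noise
deg <- degradation_spec("half_plane", vignette_strength = 1,
                        poisson_photons = Inf, gaussian_sigma = 0.01,
                        seed = 11)
sim <- simulate_fpm_dataset(Mod(obj), Arg(obj), sys, degrade = deg)

fit <- fd_solve(sim$observation, fdpr_model_fpm(sys, learn_pupil = FALSE),
                feature_extractor_spec("gradient"), loss_spec("charbonnier"),
                config = solver_config("adam", c(object = 0.02),
                                       iterations = 300, seed = 7))
print(fit)
#> <fdpr_fit> fpm, 81 frame(s), gradient features, charbonnier distance
#>   300 iteration(s); best loss 7794.37 at iteration 300

ep <- epry_fpm(sim$observation, sys, baseline_config("epry", iterations = 50))
ta <- Mod(sim$truth$object) / mean(Mod(sim$truth$object))
na <- function(x) Mod(x) / mean(Mod(x))
psnr(na(recovered_object(fit)), ta)   # 29.95 dB  (feature-domain)
psnr(na(ep$object), ta)               # 14.95 dB  (pixel-domain EPRY)
```

The feature-domain fit is ~15 dB better than EPRY on the same vignetted
stack: the half-plane shadow perturbs raw pixels enormously but leaves edge
features nearly untouched, so the feature-domain likelihood simply ignores
it. With clean frames the same solver drives the feature loss below 1e-4 of
its initial value.

Blind aberration recovery (unknown pupil phase up to several pi
peak-to-valley) is packaged as `fd_blind_fpm(observation, sys)`; see the
vignette for the study conditions and the identifiability caveats.

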