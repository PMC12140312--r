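---
title: "Feature-domain phase retrieval: model, solver and study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-domain phase retrieval: model, solver and study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdpr)
```

## The inverse problem

Phase retrieval recovers a complex wavefront $x$ (amplitude and phase) from
intensity-only measurements. Each exposure $n$ of an optical system applies a
known *linear* propagator $A_n$ to $x$ and records
$I_n^{\mathrm{obs}} \approx |A_n x|^2$. The $A_n$ factorize into elementary
linear stages (spectrum shifts, crops, pupil masks, Fourier transforms,
angular-spectrum transfers, element-wise masks), each carrying an exact
adjoint; every chain in this package passes a dot-product test
$\langle A u, v\rangle = \langle u, A^H v\rangle$ to $10^{-10}$ relative.

Classical solvers compare predictions and observations pixel by pixel.
This package instead minimizes a **feature-domain** loss

$$
L(x, A_k) \;=\; \sum_{n=1}^{N}
  D\!\big(\Theta_S(I_n^{\mathrm{obs}}),\, \Theta_S(|A_n x|^2)\big)
\;+\; \alpha\,\lVert x - C(x)\rVert_2^2
\;+\; \sum_k \beta_k\,\lVert A_k - C(A_k)\rVert_2^2 ,
$$

where $S$ is a pixel-wise intensity scaling, $\Theta$ a linear feature
extractor, $D$ a distance, and $C$ arbitrary plug-and-play refinement
operators with penalty weights $\alpha, \beta_k$. The rationale: image
*features* (edges, wavelet detail coefficients) are far more stable than raw
pixels under the degradations that plague real acquisitions — uneven
illumination, vignetting, mixed Poisson–Gaussian noise — so a likelihood
formed on features is robust to exactly the corruptions that break
pixel-domain least squares. Empirically (and reproduced by the test suite),
the first-level wavelet detail histograms of very differently degraded
frames are all symmetric about zero, while the raw-pixel histograms differ
pairwise; a smooth polynomial background that changes pixel energy by more
than 50% moves detail-band energy by less than 5%.

The penalty norm is implemented as squared $\ell_2$ ($p = 2$ in
`constraint_spec()`); the `norm_order` field is retained so other readings
remain expressible.

## Components

**Intensity scaling $S$** — `sqrt` (default, $\sqrt{I + \varepsilon}$,
$\varepsilon = 10^{-9}$): amplitude-like and approximately
variance-stabilizing for shot noise; `identity` and `log1p` are selectable.
Both sides of the loss pass through the same $S$ and $\Theta$.

**Feature extractors $\Theta$** — all linear with exact adjoints (the
gradient engine needs $\Theta^T$):

* `gradient`: horizontal/vertical forward differences with replicate
  boundary (central differences selectable). Used for blind aberration
  recovery, where edge sharpness is the signal that drives the pupil fit.
* `wavelet`: multi-level bior2.2 (CDF 5/3) decomposition, five levels by
  default, implemented by lifting with whole-point symmetric extension.
  Lifting makes the inverse exact to machine precision and the adjoint a
  short chain of scatter-adds; the tests verify the coefficients against an
  independent direct filter-bank convolution.
* `identity`: reduces the engine to pixel-domain least squares (the
  classical baseline behavior, useful for head-to-head comparisons).

**Distances $D$** — `charbonnier` (default, $\sqrt{r^2+\varepsilon^2}-
\varepsilon$, $\varepsilon = 10^{-3}$) as the differentiable surrogate of
$\ell_1$; `l2`; exact `l1` is accepted for loss evaluation but rejected by
the gradient engine because it is non-differentiable at zero.

**Wirtinger gradients** — the loss is real-valued over complex parameters;
the engine returns $g = 2\,\partial L/\partial \bar p$, the direction that
satisfies $L(p - t g) = L(p) - t\lVert g\rVert^2 + o(t)$. The returned
gradients match central finite differences to $10^{-4}$ relative on random
coordinates (tested).

**Optimizers** — Adam (default), YOGI (additive second-moment update
$v \leftarrow v - (1-\beta_2)\,\mathrm{sign}(v - |g|^2)\,|g|^2$, which
forgets curvature more slowly and damps oscillation in the strongly
non-convex holographic setting), and plain SGD with momentum. Complex
parameters track first moments on the complex gradient and second moments on
its squared modulus. The solver returns the best-loss iterate rather than
the last one, because adaptive optimizers oscillate before convergence.

**Constraint block** — each `constraint_spec()` names a refinement operator
(amplitude thresholds, total-variation denoising by Chambolle dual
iterations, the guided filter, hard support masks, or any user function),
a target parameter group, a component (complex values, amplitude, or phase)
and a mode. In *penalty* mode the block adds $2w\,(u - C(u))$ to the
target's gradient with $C$ treated as fixed (no gradient through $C$); in
*replace* mode it projects $u \leftarrow C(u)$ at a configurable cadence.
The exact refinement schedule of the constraint block is an open design
point in the source material; both realizations are provided and recorded
in the fit object, with the penalty form as default.

## Forward models

* **Fourier ptychographic microscopy (FPM)**: the object is parametrized by
  its high-resolution DC-centered spectrum. Frame $n$ crops a low-resolution
  window displaced by the LED wave-vector (quantized to integer pixels;
  sub-pixel shifts change the operator and are out of scope), applies the
  pupil, inverse-Fourier transforms, and scales so a unit object yields unit
  mean intensity. LED wave-vectors follow planar array geometry,
  $k_n = (x_n, y_n) / (\lambda\sqrt{x_n^2 + y_n^2 + h^2})$.
* **Coded ptychography**: the sample, shifted laterally by integer pixels
  (circular shifts on a grid equal to the pattern grid — a periodic
  idealization of the real rotation-based scan, which is out of scope),
  propagates a distance $d_1$ to a fixed binary-phase coded mask and a
  further $d_2$ to the sensor.
* **Inline holography**: a single angular-spectrum propagation. The
  transfer function uses the exact non-paraxial phase
  $\exp(i 2\pi z \sqrt{1-(\lambda f)^2}/\lambda)$ with a hard evanescent
  cutoff and no Fresnel approximation, since lensless distances are small.

All transforms are orthonormal and DC-centered on even grids, so every
unitary stage is its own adjoint-inverse and the pupil/shift masks are
symmetric around the center pixel.

## Identifiability

A global object phase is never recoverable. In blind joint
object-plus-pupil FPM recovery two further gauges exist: (i) a linear pupil
phase (tip/tilt) trades exactly against an object translation, and (ii) for
a symmetric LED set, conjugate-flipping both the object spectrum and the
pupil reproduces every frame exactly (verified numerically to $10^{-15}$).
Comparisons against ground truth therefore remove piston/tip/tilt over the
pupil disk and score the better of the solution and its conjugate twin.

One practical subtlety deserves emphasis: the tilt gauge routinely settles
several radians per pixel away from zero (an object translation of a few
pixels), so the wrapped phase difference between recovered and true pupil
looks like uniform noise, and a least-squares plane fit on wrapped phases
does **not** remove it. `pupil_phase_rms()` instead locates the tilt by a
coarse-to-fine search maximizing the amplitude-weighted phasor
concentration $|\sum w\, e^{i(\Delta\phi - a x - b y)}|$, which is immune
to wrapping, then reports the weighted RMS of the wrapped residual. A
scale factor between pupil and object amplitudes is likewise a gauge; the
pupil amplitude is clamped at 1.5 because an unbounded joint fit is
degenerate with the object amplitude.

## Blind aberration recovery: what the study conditions are

`fd_blind_fpm()` packages the recipe used for blind large-aberration
recovery: gradient features, sqrt scaling, charbonnier distance, Adam with
learning rates 0.02 (object spectrum) and 0.05 (pupil), 400 iterations, the
ideal-disk pupil as starting point. The desk-scale study conditions are a
64 px object at 0.5 um pitch, a 15 x 15 LED grid (1.8 mm pitch, 100 mm
height, so adjacent LEDs step the pupil by about one spectrum pixel —
generous ptychographic overlap), objective NA 0.1 at 0.532 um, and pupil
phase screens drawn from the first 15 OSA/ANSI Zernike modes (piston
excluded), rescaled to an exact peak-to-valley target. Success is a
pupil-phase RMS error below 0.5 rad after piston/tip/tilt removal.

At this miniature scale the NA disk spans only about 6 pixels in radius,
so a 6-pi screen has wrapped phase steps exceeding pi between some
neighboring pupil pixels — a considerably harsher discretization than a
full-scale bench system, where the same peak-to-valley spreads over tens
of pixels. The recipe nevertheless recovers screens of 6-pi and 8-pi
peak-to-valley across random draws, provided the evaluation removes the
(frequently multi-wrap) tilt gauge as described above. The acceptance
sweep reports the largest peak-to-valley at which all tested screens
succeed.

## Synthetic data and what it does not emulate

`simulate_fpm_dataset()`, `simulate_inline_hologram()` and
`simulate_coded_dataset()` generate every modality with a ground-truth
record sufficient to regenerate the frames bit-exactly (tested). The
degradation pipeline applies, in fixed order: a vignette mask (half-plane,
or a circular window displacing linearly with illumination angle — the
model behind the half-bright/half-dark oblique frames), a smooth
multiplicative polynomial background, Poisson shot noise (default $10^4$
photons per pixel at full scale) and additive Gaussian read noise (default
1% of full scale), then a clamp at zero. The generators do not model
partial coherence, sensor MTF, readout artifacts, thick samples or
continuous scan geometry; passing tests therefore demonstrate correctness
of the algorithms under the stated image-formation model, not performance
on any particular laboratory dataset.

Defaults chosen where the source material is silent: vignette strength 1
(fully dark half), guided filter radius 8 px with regularization 0.04
(stronger smoothing erases fine structure — tunable), TV via 20 Chambolle
dual iterations at step 0.248, ePIE/EPRY step sizes 1, EPRY pupil support
confined to the NA disk dilated by 10%, mPIE momentum 0.7.

## Numerical choices

Even grid dimensions only (fftshift is then an involution); orthonormal
FFTs; integer-pixel spectrum shifts; charbonnier smoothing $10^{-3}$;
divergence aborts when the loss exceeds $10^6$ times its initial value;
optional relative-loss stopping tolerance (disabled by default, fixed
iteration budgets preferred for reproducibility); all solver randomness
(LED mini-batching) derives from a single integer seed, and identical
configurations produce bitwise-identical traces (tested).

Problem sizes in the test-suite and acceptance runs — 32-128 px grids,
9-225 frames, hundreds of iterations — were chosen as the package's
desk-scale study conditions: large enough that every mechanism (vignetting
robustness orderings, aberration recovery, twin-image suppression) is
exercised, small enough that the whole suite reruns from scratch in
minutes.

## Known limitations

The guided filter is not a
projection, so "apply twice equals apply once" holds only approximately;
the tests check monotone roughness decrease instead. Exact $\ell_1$ loss
gradients are not provided (use charbonnier). Multi-wavelength runs are
per-channel independent.
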