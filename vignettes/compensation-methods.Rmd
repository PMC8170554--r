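---
title: "Covariate compensation of circumpapillary RNFL thickness profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate compensation of circumpapillary RNFL thickness profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spectral-domain OCT measures the thickness of the retinal nerve fiber layer
(RNFL) on a 3.4-mm circle around the optic disc, typically at 768 equally
spaced angular positions.  The resulting TSNIT profile (temporal, superior,
nasal, inferior, temporal) is double-humped: the superotemporal and
inferotemporal axon bundles form two peaks roughly 70 degrees either side
of the temporal horizontal.  Glaucoma destroys retinal ganglion cell axons,
preferentially in those arcuate bundles, so a standard detector flags an
eye when a stretch of consecutive profile points falls below a one-sided
95% normative limit built from healthy eyes.

The trouble is that healthy profiles also vary systematically with
demographics and ocular geometry: thickness declines with age at roughly
0.3% per year; longer (more myopic) eyes are thinner and their bundle
peaks converge temporally; the disc-fovea axis rotates and stretches the
whole pattern.  Those covariate effects inflate the normative band and, in
long eyes, masquerade as disease.  `rnflcomp` implements a two-phase
compensation that removes the covariate-attributable deformation before
detection, plus the simulation and evaluation machinery needed to exercise
the whole pipeline end to end on synthetic cohorts.

## Phase 1: the age-slope field

For healthy eyes the age effect is modeled per angular position, in the
log domain:

$$\log y_{n,i} \;=\; \mu_i \;-\; \rho_i\,(a_n - a_\mathrm{ref}) \;+\;
\varepsilon_{n,i},$$

where $\rho_i$ is the relative loss rate per year at position $i$.  The
field $\rho$ is estimated by penalized least squares with a circular
second-difference penalty
$\lambda \sum_i (\rho_{i-1} - 2\rho_i + \rho_{i+1})^2$ (indices mod $P$),
expressing that neighboring points on the scan circle are supplied by
overlapping axon bundles and cannot lose tissue at wildly different rates.
With the intercepts profiled out, the stationarity conditions form one
sparse circulant-structured linear system that is solved exactly — there
is no iterative optimization and no tuning beyond $\lambda$.  One step of
iterative refinement follows the solve because at very large $\lambda$ the
system becomes ill-conditioned and the raw solution carries visible
residual ripple.

Choices worth making explicit:

* **Multiplicative, not additive.**  The age effect on thickness is
  proportional (a fraction per year), so compensation multiplies by
  $\exp(\rho_i\,(a - a_\mathrm{ref}))$.  This also makes the transform
  exactly invertible by mirroring the age about the reference.
* **Log floor at 1 µm.**  A thickness of 0 µm is legal input (severe
  atrophy); values are floored at 1 µm before the log so the fit is
  defined everywhere.
* **Defaults.**  `reference_age` defaults to the training-cohort mean age;
  `smoothing_lambda` defaults to $10\,n$.  With realistic training sizes
  the fit is insensitive to $\lambda$ over several orders of magnitude
  because the true field is already smooth.

## Phase 2a: the scale/shift network

Axial length, disc-fovea distance, disc-fovea angle and gender act on the
profile mostly as a *global deformation*: a vertical scaling and a
horizontal rotation of the pattern around the scan circle.  A small fully
connected network (4 → 16 → 16 → 2, tanh hidden layers) maps the
standardized covariates to a per-eye log scale $s$ and circular shift
$\delta$ (in index units); compensation applies the inverse,
$c_{n,i} = e^{-s_n}\, \tilde y_n(i + \delta_n)$, with circular linear
interpolation.  Training minimizes the across-subject per-point variance
of the compensated profiles on the normative cohort — if the deformation
is covariate-driven, removing it must make healthy profiles more alike.

The variance objective has a well-known degeneracy: a component of $s$ or
$\delta$ *shared by every eye* is either invisible to it (a common
rotation permutes the variance across positions) or actively rewarded (a
common down-scaling shrinks all variance without removing any structure).
Three design elements deal with this:

* the applied outputs are centered on their batch mean, which projects the
  common component out exactly; the training means are frozen into the
  model and used as fixed offsets at prediction time;
* a penalty $\gamma\,[(\overline{s}/s_\mathrm{max})^2 +
  (\overline{\delta}/\delta_\mathrm{max})^2]$ on the raw output means
  (default $\gamma = 10$) keeps the network away from tanh saturation;
* outputs are bounded, $|s| \le 1$ and $|\delta| \le P/8$, so no
  parameter setting can collapse the profiles.

The variance term is normalized by the input variance, making the loss
dimensionless and the optimizer settings independent of profile units.
Optimization is deterministic full-batch gradient descent with an Armijo
backtracking line search (the step grows 1.5× after every accepted step
and halves on rejection), so the loss trajectory is non-increasing by
construction; the default budget is 600 iterations with early stop at a
relative change of $10^{-8}$.  Initialization is Glorot-uniform with the
output layer scaled by 0.01: training must start next to the identity
transform, because an eye initialized with a large random shift sits
outside the attraction basin of its true displacement (the classic local
minimum of registration problems).  The loss and its exact gradient in
$(s, \delta)$ are computed in compiled code (`src/fcn_loss.cpp`); the
interpolation is piecewise linear, so the gradient is exact almost
everywhere.

A global shift plus a smooth residual stage (below) was chosen over a
per-point warp: the deformation the covariates induce is low-dimensional,
and giving the network per-point freedom at this stage would let it
absorb disease-like local structure.  Any residual per-point flexibility
is deliberately delegated to the next stage, which is linear, heavily
shrunk, and conditioned on covariates only.

## Phase 2b: the residual radial basis function network

What the global deformation cannot capture — peaks that change width or
relative height with ocular geometry — is modeled as a smooth per-point
residual field conditioned on the covariates:

$$r_i(x) \;=\; \sum_{k=1}^{K}\sum_{m=1}^{M} v_{km}\,\varphi_k(x)\,\psi_m(i),$$

with $\varphi_k$ Gaussian kernels in standardized covariate space
($K = 24$ centers from k-means, shared bandwidth equal to the median
inter-center distance) and $\psi_m$ circular Gaussians over the angular
positions ($M = 24$ equally spaced centers, width 1.5× their spacing — so
the field is smooth on the circle by construction).  The coefficients are
the exact ridge least-squares solution; because the design is a Kronecker
product of the covariate and angular Gram matrices, one eigendecomposition
of each gives the solution for every ridge value at negligible cost.

The ridge is selected by 5-fold cross-validation **over eyes**.  The fold
unit matters and is easy to get wrong: residual profile variance is
dominated by per-eye individual variation (whole rows move together), so
pointwise criteria such as GCV — which count $n \times P$ independent
observations — under-penalize badly and let the field memorize sampling
noise of the training cohort.  Validated per eye, the selector behaves the
way one wants at both extremes: on noise-free planted structure it picks a
light penalty and recovers the field almost exactly, while on realistic
noisy cohorts it shrinks hard.

The compensated profile is the Phase-2a output minus $\hat r(x)$, clipped
at 0 µm.  With all network weights zero the full pipeline reduces exactly
to the Phase-1 output, and at the reference covariates a null-trained
compensator is the identity — these invariants are tested.

## Detection and evaluation

The detector is deliberately simple and fixed across arms: build the
per-point one-sided 95% lower limit from reference normals (empirical 5th
percentile with the type-7 interpolated order statistic by default;
`mean − 1.645·SD` as an alternative), and score an eye by the maximum
length of a *circular* run of consecutive points strictly below the limit
(a run may wrap across the temporal origin; a point exactly on the bound
counts as not below).  Sweeping the integer run length gives the ROC; the
AUROC is computed by midrank Mann–Whitney, identical to the trapezoidal
area over the operating points, with ties counted ½.

Limits for the original arm come from the original training normals and
for the compensated arm from the *compensated* training normals; they are
never refit on validation data.  Axial-length subgroups take the
$\lceil f n \rceil$ longest eyes (ties broken by eye id), both labels
retained, so subgroup AUROCs compare glaucoma against normals within the
long-eyed stratum.

## The synthetic cohort generator

No suitable per-eye dataset with all five covariates is publicly
deposited, so the package ships a generator whose defaults emulate a
population-based cohort; the defaults are fixed study conditions, not
tuning knobs.

* **Template.**  Baseline 75 µm, two 55 µm circular-Gaussian peaks at
  ±70° (width 25°), 15 µm nasal elevation — a noise-free reference
  profile with mean thickness close to the ~102 µm of healthy eyes.
* **Covariate marginals.**  Truncated Gaussians with the means, SDs and
  ranges of a large population-based study (normals: age 62.3 (8.9) y, AL
  23.18 (0.96) mm, DFD 4.88 (0.27) mm, DFA 7.59 (3.4)°, 43.4% male;
  glaucoma: 69.4 (9.3), 23.77 (1.27), 5.41 (0.82), 8.16 (4.36), 54.3%).
  The age truncation at the 50-year inclusion bound is asymmetric and
  raises the realized mean by about 1.5 years; we accept this rather than
  distort the pre-truncation parameters.
* **Effect sizes.**  Age 0.3%/yr (the literature value); axial length
  1.5%/mm vertical thinning and 6°/mm temporal peak convergence; whole
  profile rotation of 2° per degree of disc-fovea angle; −1%/mm for
  disc-fovea distance; 2% male–female offset; 6 µm i.i.d. measurement
  noise.  The AL and DFA couplings have no published point estimates;
  they were set — once — so that the uncompensated detector degrades
  visibly in long eyes while healthy mean thickness stays on target,
  which is the regime the method exists for.
* **Individual variability.**  A per-eye log-normal thickness factor
  (SD 0.10) reproduces the ~11 µm between-eye SD of mean RNFLT in healthy
  populations.  This is the irreducible part of the normative band: no
  covariate model can remove it, and without it synthetic detection would
  be unrealistically easy.
* **Glaucoma.**  One arcuate wedge defect per eye (center ±50–90°, width
  20–45°, cosine-tapered depth 0.1–0.7) plus diffuse thinning
  `0.4·Beta(1, 3)` — mostly mild disease with a tail of severe loss, as
  population-based recruitment produces — calibrated so the glaucomatous
  mean RNFLT lands near 85 (17) µm against 102 (11) µm for normals.

What the generator does **not** model: spatially correlated segmentation
error, retinal vessels, peripapillary atrophy optics, or OCT speckle.
Synthetic detection is therefore somewhat easier than clinical reality
(overall AUROCs run high), and passing tests demonstrate correctness of
the machinery and the *ordering* of effects — compensation helps, and
helps most in long eyes — not clinical performance levels.

## Conventions and numerical details

* Index 0 of a profile is the temporal horizontal position, indices
  increasing superiorly (TSNIT unrolling).  Vendor exports do not
  document their origin; this convention only fixes plot orientation and
  the meaning of the simulator's peak angles, never a computation.
* Profile length $P$ is a configuration value read from the data
  (default 768); every algorithm is written for general $P$, and most
  tests run at $P$ between 16 and 256.
* Fractional shifts use circular *linear* interpolation; higher-order
  schemes were rejected so that shift-related oracle checks stay exact on
  piecewise-linear cases and integer shifts remain pure re-indexings.
* Cohort CSVs are written with `%.17g`, so a write/read round trip is
  bit-exact.
* Seeds: one master seed fans out to per-stage seeds through a fixed
  integer map (`derive_seed`), so stages can be rerun in isolation and
  the whole pipeline is reproducible from one integer.

## Problem sizes used by the test-suite

The default experiment — 2223 training normals, 254 + 254 validation eyes
at $P = 768$ — trains in about two minutes on one core; the suite runs it
once and reuses the result.  Parameter-recovery tests use 500 eyes at
$P = 256$ (rotation) and $P = 96$ (residual field); the variance
monotonicity check trains at a reduced 150-iteration budget across five
seeds, which is sufficient because monotonicity is a structural property
of the optimizer and the closed-form fits, not of the budget.

## Known limitations

* Compensation is trained on normals only and extrapolates for covariate
  combinations outside the normative range (e.g. very long glaucomatous
  eyes); the bounded network outputs keep the extrapolation tame but not
  principled.
* Removing covariate effects also removes the covariate *confound* from
  detection: glaucomatous eyes are on average older and longer, and part
  of an uncompensated detector's apparent separation rides on exactly
  that.  On synthetic cohorts the removable deformation outweighs the
  lost confound, but the balance depends on the population.
* The run-length detector ignores the depth of a defect below the limit;
  eyes with deep but very focal loss score the same as shallow dips of
  equal extent.
* Effect sizes for the disc-fovea geometry are plausible placeholders,
  not estimates from data.
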