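---
title: "Spatiotemporal shape trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal shape trajectories: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapetraj)
```

# The problem

In autosomal-dominant neurodegenerative disease, subcortical structures
such as the thalamus change shape years before symptoms appear. Given one
surface mesh per subject per hemisphere, each labelled with the subject's
estimated years to expected symptom onset (EYO) and covariates (mutation
carrier status, sex, site, family), `shapetraj` asks *when* and *where*
the shapes of carriers start to deviate from those of non-carrier
relatives. Volume summaries discard localisation; vertex-wise tests pay a
heavy multiplicity price. The package instead analyses the *deformations*
linking each subject to a population-average shape trajectory, reduced to
a small number of cluster-level descriptors.

# Model

## Shapes as varifolds

A triangulated surface is represented as a varifold: a sum of weighted
point masses at triangle centres $c_k$ carrying the unnormalised area
normals $\tau_k$ ($\|\tau_k\|$ = triangle area). Two surfaces are compared
through the kernel inner product

$$\langle [A],[B]\rangle \;=\; \sum_{k,l}
  e^{-\|c_k - c_l\|^2/\lambda_W^2}\,
  \frac{(\tau_k\cdot\tau_l)^2}{\|\tau_k\|\|\tau_l\|},$$

a Gaussian spatial kernel times a squared-cosine directional kernel. The
squared dot product makes the representation orientation-free (winding
conventions never matter) and correspondence-free (no point matching).
The squared distance
$d^2 = \langle A,A\rangle - 2\langle A,B\rangle + \langle B,B\rangle$
is the data term of every matching problem in the package.

An important practical property: the varifold metric responds strongly to
displacement along the surface normal and only weakly to tangential
sliding (which changes the shape only at second order). Any effect one
wants the pipeline to detect must therefore have a normal-displacement
footprint; the synthetic generator (below) is designed around this.

## Deformations: control points and momenta

Deformations are flows of smooth velocity fields
$v(x) = \sum_p K_V(x, x_p)\,\alpha_p$, parametrised by momenta $\alpha_p$
on a regular control-point grid, with a Gaussian kernel
$K_V(x,y) = e^{-\|x-y\|^2/\lambda_V^2}$ (no factor 2 in the denominator —
both kernels use the same convention). Optimal flows are geodesics,
obtained by integrating the Hamiltonian system

$$\dot x_p = \sum_q K(x_p,x_q)\alpha_q, \qquad
  \dot\alpha_p = -\sum_q (\alpha_p\cdot\alpha_q)\nabla_1 K(x_p,x_q)$$

from $t=0$ to $1$ (geodesic shooting). The kinetic energy
$\sum_{p,q}(\alpha_p\cdot\alpha_q)K(x_p,x_q)$ is conserved along exact
geodesics, which provides the package's core integration diagnostic: with
the default 11 RK4 steps the relative drift is far below $10^{-5}$ and
shrinks sixteen-fold when the step count doubles, as fourth-order
integration should.

Registration minimises
$J(\alpha) = d^2([\phi_\alpha(S)],[T]) + \gamma \|v\|^2_V$ with a
limited-memory BFGS iteration under Armijo backtracking. Gradients are the
*discrete adjoint* of the RK4 scheme — exact derivatives of the discretised
objective, verified against central finite differences at $10^{-3}$
relative or better. This avoids the mismatch a continuous adjoint
introduces at coarse step counts.

## The pipeline

1. **Bilateral mean.** Left meshes are mirrored about the cohort
   mid-sagittal plane (estimated as the mean x coordinate of all meshes;
   configurable) and each pair is averaged by registering one joint
   deformation $\chi$ toward a mean $S$ and updating $S$ as the vertex-wise
   average of the two flowed sides. The update subtracts the net
   translation of the flow: the joint functional is invariant under
   translating $\chi$ and $S$ together, and without fixing this gauge the
   alternating scheme converges to the kinetically optimal centre only at
   rate $2/(2+\gamma)$ per round. One round is the default; with nearly
   coincident sides further rounds refine little, and with distant sides
   they can degrade the mean (a single smooth field cannot move two
   overlapping copies independently, so re-registration to an averaged
   shape squeezes it).
2. **Baseline.** The iterative centroid of the 10 subjects furthest from
   onset: a sequential pass in seeded random order, flowing the running
   centroid $1/(j+1)$ of the way along the geodesic to the next shape.
   The result depends mildly on the ordering; the seed is recorded and
   `centroid_order_variability()` reports the spread.
3. **Geodesic regression.** One geodesic $(B_0, \beta_0)$ is fitted
   through all subject means, with EYO mapped affinely to the geodesic
   parameter $[0,1]$ and discretised onto $T=30$ snapshots (about one per
   two years over a 60-year span). Each subject's data term is evaluated
   at its nearest grid time; the baseline anchors at the earliest EYO.
4. **Residuals.** Each subject is registered from its trajectory snapshot,
   yielding initial momenta $\alpha_i(0)$ at the snapshot's control
   points. Residual registrations reuse the trajectory's kernels and
   $\gamma$.
5. **Parallel transport.** The residual momenta are carried to the
   baseline space along the reversed geodesic with Jacobi fields: at each
   grid interval the transported vector is read off a central difference
   of two perturbed exponentials, converted from a velocity reading back
   to momenta through the kernel matrix. Central (not one-sided)
   differences give $O(\varepsilon^2)$ accuracy; stepping one interval at
   a time keeps the finite-$\varepsilon$ error uniform across subjects
   regardless of their position on the time axis. Parallel transport is an
   isometry; the discrete scheme preserves the kinetic norm to well within
   2%.
6. **Clustering.** The trajectory parametrisation is grouped into $K=10$
   clusters from the similarity
   $s(p,q) = -5\|x_p-x_q\|^2 + 2(\cos(\beta_p,\beta_q)+1)
   - \big|\|\beta_p\|^2-\|\beta_q\|^2\big|$, using a spectral embedding of
   the affinity $e^{s/\tau}$ and discretisation-based label extraction
   restarted many times (3000 by default), keeping the labelling with the
   lowest embedding-space inertia.
7. **Descriptors and statistics.** Per subject and cluster, the mean
   transported momentum $\nu_{i,k}$ is reduced to an amplitude
   $|\nu_{i,k}|$ and an orientation scalar (first principal component of
   the three direction angles across subjects). Each descriptor is
   modelled as
   `value ~ group * EYO + sex + site + (1 | family)` (REML), with Wald
   tests: T1 jointly tests the carrier main effect and the
   carrier-by-EYO interaction (df 2), T2 the interaction alone (df 1),
   Bonferroni-corrected over the $2K$ tests; descriptors surviving
   correction are followed up with the contrast
   $b_{\text{carrier}} + b_{\text{interaction}}\cdot t$ every 5 years from
   EYO $-20$ to $+10$, Bonferroni-corrected over the 7 grid times. Age is
   not a covariate: in onset-anchored cohorts it is nearly collinear with
   EYO.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_v` | 11 mm | deformation kernel width; about half a thalamus length, sets the control grid spacing |
| `lambda_w` | 5 mm | varifold kernel width; ~2 voxels, balances sensitivity and segmentation-noise robustness |
| `gamma` | 0.1 | regularity/data trade-off in all matching functionals |
| `n_steps` | 11 | RK4 steps per geodesic |
| `T` | 30 | trajectory snapshots over the observed EYO span |
| `K` | 10 | clusters; a balance between multiplicity and spatial specificity |
| `n_init` | 3000 | clustering restarts (a few tens suffice on well-separated problems) |
| `eyo_grid` | −20 … +10 by 5 | grid of the time-resolved Wald tests |

Open choices resolved here, for the record: the varifold inner product is
the Gaussian × squared-cosine construction (the directional kernel is not
pinned down by the distance functional alone); similarity distances are
divided by `lambda_v` before squaring (with raw mm distances on an 11 mm
grid the positional term dwarfs the others; a raw mode is available);
the similarity-to-affinity map is $e^{s/\tau}$ with $\tau$ the
interquartile range of the off-diagonal similarities (scale-free, and
planted-partition recovery is insensitive to $\tau$ within a factor of 4);
orientation PCA is fitted per cluster across subjects; subjects snap to
the nearest of the $T$ grid times; the at-EYO contrast reuses the single
model fit rather than refitting per time point.

# The synthetic cohort generator

Real genetic-FTD imaging cohorts cannot be redistributed, so validation
runs on a generator with exact ground truth: ~200 subjects (carrier
fraction 113/211), EYO uniform on $[-40, 20]$, 60 families, 5 sites, and
thalamus-scale ellipsoid meshes (semi-axes 11×7×6 mm; icosphere
subdivision 3, 642 vertices, by default). A fixed anterior-pole momentum
field defines the ground-truth trajectory (a few mm of anterior
displacement over the span, the scale of real atrophy). Carriers past
`divergence_onset` (−10 EYO) additionally carry a residual deformation in
an anterior-superior patch whose **direction rotates** with EYO at a rate
of 0.5°/year on a 45° cone around the local surface normal, at fixed
amplitude. The rate is calibrated so the planted group effect sits in the
marginal-detection regime (omnibus Wald chi-square of a few tens, first
corrected detection at or just after onset) rather than being
overwhelming — the regime in which such analyses operate in practice. The cone construction matters: the varifold data term sees
mostly normal displacement, so rotating the direction *through* the
normal would change the observable amplitude and contaminate the
amplitude descriptor. On the cone the normal component is constant — a
pure orientation effect, with surface displacements of a couple of mm
(matching the magnitude of reported cluster deformations). Family- and
subject-level momentum noise (tied to `noise_sd`) and vertex jitter
(0.15 mm) model biological and segmentation variability.

What the generator does **not** emulate: real anatomy (ellipsoids, not
thalami), segmentation-error spatial structure, scanner effects beyond a
site intercept, or longitudinal within-subject correlation. Passing tests
therefore demonstrate that the estimation machinery recovers known
effects of realistic magnitude under idealised geometry — not that the
pipeline's power generalises to arbitrary real data.

# Numerical choices and degenerate inputs

* Integration: fixed-step RK4; divergence (non-finite states) raises an
  error naming the step rather than silently continuing.
* Optimisation: L-BFGS (memory 7) with Armijo backtracking; accepted
  objective values are non-increasing by construction; non-convergence
  within the iteration budget returns the best iterate with a warning.
* Transport $\varepsilon$: default $10^{-3}\,\|\beta_0\|/\|\theta\|$ per
  step; an $\varepsilon$ below machine noise errors out with guidance. A
  zero-momentum segment transports by the identity exactly.
* Degenerate triangles (area below $10^{-12}$ mm²) are dropped at mesh
  validation; an all-degenerate mesh is an error. Zero momentum vectors
  get cosine 0 in the similarity and neutral angles $(\pi/2,\pi/2,\pi/2)$
  in the orientation descriptor.
* Clustering with $K=n$ returns singletons directly (the only valid
  partition). Discretisation restarts that produce an empty cluster are
  discarded; if every restart does, a k-means fallback is used with a
  warning.
* The mixed model falls back to fixed effects (with a warning) when fewer
  than two families are present or the mixed fit fails.

# Problem sizes used in the tests

The shipped tests and the acceptance script run the whole pipeline at
reduced scale: icosphere subdivision 1–2 (42/162 vertices — the package's
own choice of desk-scale problem sizes), registration
iteration caps of 12–60, 50 clustering restarts, and 15–30 trajectory
time points. Inverse-crime recoveries (registering a shape deformed by
known momenta, regressing snapshots sampled from a known geodesic) verify
the estimation machinery at sub-0.3 mm vertex RMS at these sizes.

# Known limitations

* The earliest *detectable* divergence time is a property of the linear
  mixed model, not only of the data: a hinge-shaped true effect fitted by
  a linear interaction yields a nonzero fitted contrast before the true
  onset, so with a strong planted effect the first significant grid time
  can precede the onset. The generator's default effect size is chosen in
  the regime where detection first appears at or just after onset —
  mirroring how marginal such detections are in practice.
* The iterative centroid is ordering-dependent by construction; the
  ordering is seeded and reported, not averaged out.
* One pass of the bilateral mean assumes the two (mirrored) sides share
  connectivity, as mirrored bilateral pairs do; heterogeneous meshes
  would need a correspondence-free mean, which the package does not
  implement.
* No subject-specific longitudinal trajectories: each subject contributes
  one time point, and the analysis is cross-sectional along EYO.
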