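---
title: "Egg volume from a partial range-camera point cloud: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg volume from a partial range-camera point cloud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggfit)
```

## The problem

A single static range camera looking down at an egg sees roughly one half
of the shell. Volume estimators that need a closed surface (convex hull,
alpha shapes, voxelization) fail on such partial coverage. The approach
implemented here fits a *parametric implicit surface* whose volume is known
in closed form, so the unobserved half is supplied by the model rather than
by the data. The cost of that choice is that everything rests on the model
being a good description of real eggs, and on the estimation being honest
about what a half shell can and cannot determine.

## Shape model

The 2D egg outline is the quartic curve
$(X^2+Y^2)^2 = aX^3 + (a-b)XY^2$ with major-axis length $a > 0$ and a
second parameter $b \ge 0$ controlling elongation and asymmetry. A regular
chicken egg has $b/a \approx 0.7$; the package treats $b/a \in [0.63,
0.77]$ (10% around 0.7) as the "realistic egg" band, which later gates the
shear-model selection. At $b = 0$ the curve is a circle of diameter $a$.

Solving for the squared cross-section radius at axial station $t \in
[0, a]$ gives a quadratic in $r^2$ whose larger root is the physical
profile (`radius_profile()`); the radius vanishes at both ends of the axis.
Revolving the profile yields the 3D surface; all three spatial variants
(major axis near sensor X, Y or Z) share the implicit condition
$F = (s^2+r^2)^2 - as^3 - (a-b)sr^2$ with $s$ the axial and $r$ the
transverse coordinate. Since eggs lie flat, only the two horizontal
variants are ever fitted; the vertical one exists for completeness and for
generator use.

### Closed-form volume

The solid-of-revolution volume $\pi\int_0^a r^2\,dt$ has a closed form
usually written with $1/b$ and $1/b^2$ factors. Binomial expansion shows
those singular factors cancel *identically* — not only in the $b \to 0$
limit — leaving

$$V = \frac{\pi}{2}\left(\frac{a^3}{3} - \frac{a^2b}{3} + \frac{ab^2}{6}
  - \frac{b^3}{30}\right),$$

which the package uses for every $b$, including $b=0$ where it reduces to
the sphere volume $\pi a^3/6$. A unit test confirms numerical equality
with the unsimplified expression and with adaptive quadrature of the
radius profile. $V$ depends on $(a, b)$ only, so pose and shear errors
affect the volume only through their correlation with the shape estimates;
$\sigma_V$ follows by first-order propagation using the analytic partials
$\partial V/\partial a = \frac{\pi}{2}(a^2 - \frac{2ab}{3} +
\frac{b^2}{6})$ and $\partial V/\partial b = \frac{\pi}{2}(-\frac{a^2}{3}
+ \frac{ab}{3} - \frac{b^2}{10})$. For regular shapes with $a > 3$ cm,
$|\partial V/\partial a| > |\partial V/\partial b|$: the major-axis length
dominates the volume budget, which is why capture geometries that shorten
the observed axis degrade the volume most.

## Units and conventions

Geometry is in meters internally (range cameras report meters); the
reporting layer prints cm and mL ($1\,\mathrm{m}^3 = 10^6$ mL). Angles are
radians internally and degrees at every user surface. Rotations are
right-handed elementary rotations (positive = counter-clockwise looking
down the axis toward the origin), applied in each model's stated order;
the source never states handedness, so the single convention is used
consistently by the generator, the fitter and the initialization — all
tests are closed under it. The shear correction $X' = X - Sh_x Z$,
$Y' = Y - Sh_y Z$ is applied after the rigid transform to object space and
replaces $X, Y$ everywhere in the condition equation; the generator applies
the exact inverse distortion, so fitted coefficients are directly
comparable to generator truth.

## Estimation

Each point contributes one implicit condition $F(x; \theta) = 0$, with
both the parameters $\theta$ (7 without shear, 9 with) and the
observations uncertain: a Gauss–Helmert adjustment
$A\hat\delta + B\hat v + w = 0$ with $Q = \sigma_{obs}^2 I$ and
$\sigma_{obs} = 1$ mm by default (the working precision of the intended
sensor class). $B$ is block-diagonal with one $1\times3$ row per point, so
$BQB^\top$ is diagonal and the normal equations reduce to gradient-weighted
least squares. All partials are analytic (the model is a quartic
polynomial) and are verified against central finite differences in the
test suite.

Numerical choices that experience forced:

* **Step control.** The classical undamped iteration oscillates along the
  strongly correlated pose/shear ridge on noisy data. Each step is
  therefore Levenberg–Marquardt-damped, and accepted only if it decreases
  the *exact* orthogonal-distance objective $v^\top Q^{-1}v$, evaluated by
  Newton-projecting every point onto the current surface. First-order
  (Sampson) weighting alone is not a safe merit function here: it has
  spurious minima at near-spherical, heavily sheared shapes whose true
  geometric misfit is larger — the exact objective rejects those.
* **Tip singularity.** The surface gradient vanishes at the egg tip (the
  object-space origin), so a data point there yields a zero row in $B$ and
  no linearized information; such rows are excluded from that iteration's
  normal equations.
* **Convergence.** Corrections are tested per unit: $10^{-9}$ m for
  positions and shape, $10^{-8}$ for angles (rad) and shear, cap 50
  iterations. Non-convergence — including a singular normal matrix from
  degenerate capture geometry — is reported in the result, never raised,
  so batch runs can tabulate "no solution" cases.
* **Covariance.** The parameter covariance is the a-posteriori-scaled
  inverse normal matrix, $\hat\sigma_0^2(A^\top(BQB^\top)^{-1}A)^{-1}$,
  $\hat\sigma_0^2 = v^\top Q^{-1}v/(n-u)$, so $\sigma_V$ reflects the
  actual residual level rather than the a-priori 1 mm.

### Shear or not

Two fits are run (`shear = "auto"`): the shear model is kept only when it
converged, reduced the weighted SSE, *and* left $b/a$ inside the realistic
band $[0.63, 0.77]$. The band matters: on half-shell data the shear
coefficients trade off against the pose angles along a long, shallow
likelihood valley, and the unconstrained optimum can wander to strongly
sheared, implausible shapes at 1 mm noise. This is a property of the data,
not of the optimizer — the wandered optima genuinely have lower geometric
SSE — and it is why shear coefficients are *not* precision-recoverable at
1 mm noise (formal $\sigma_{Sh}$ is 0.02–0.07 there). The tests assert
exact shear recovery on noise-free data, a ±0.005 band at 0.02 mm noise
(the linear regime), and the selection rule's behavior at 1 mm.

### Tip-end ambiguity

The half-shell silhouette is nearly symmetric, so the initialization's tip
may land on either end of the axis. `estimate_egg_volume()` fits from both
the primary and the mirrored initial guess and keeps the lower-SSE
converged solution; on noise-free data the correct orientation wins by
many orders of magnitude.

## Initialization

A 4th-order implicit model needs good starting values. Following the
capture geometry (the egg always lies tilted on the stage, up to ~20°):

1. the **top point** (minimum range) anchors a 2D translation;
2. the **in-plane alignment angle** $\theta \in [0°, 180°]$ minimizes the
   rotated Y-width of the XY projection. The width function has several
   local minima, so a 0.05° scan brackets the global one before Brent
   refinement; $\theta$ also selects Model II (axis within 45° of X;
   boundary 45° → Model I, 135° → Model II) versus Model I;
3. half the aligned Y-width approximates the **mid-body radius** $r_s$;
4. a **sphere fit with $r_s$ fixed** (Gauss–Newton on the center only)
   gives a stable egg center — left free, the sphere balloons to the full
   axis length;
5. the **tip** is the point farthest from the center among those within
   the 10th percentile of distances from the aligned major axis (the
   percentile gate makes the informal "near the axis but far from the
   center" criterion deterministic);
6. the tip–center line gives the axis direction, hence the two pose
   angles by elevation/azimuth trigonometry; $a_0$ is the aligned axis
   extent and $b_0 = 0.7a_0$.

The tip–center direction carries a systematic tilt of a few degrees (the
constrained sphere center of a *half* shell is biased along the viewing
direction), and the tip is quantized by the pixel pitch. Both are
harmless: the contract of the initialization is that the Gauss–Helmert
fit converges from it, which the suite verifies at 100% over random
noise-free poses with tilt up to 20°.

## Segmentation

From a full frame: (i) a metric center window (default 0.30 m edge,
half-open bounds, centered on the boresight) isolates egg plus nearby
stage; (ii) Otsu's threshold on the raw integer intensity histogram
separates the bright shell from the dark stage — computed on integer
counts for bit-exact reproducibility, ties broken toward the smallest
threshold; (iii) a robust depth-surface filter removes range outliers.

The filter fits a bivariate quadratic $z = p(x, y)$ by MM-estimation
(`MASS::rlm`): an S-estimator start resists the high-leverage
configurations that bright stage speckle at the window edge creates, where
a plain IRLS from least squares is silently corrupted. Points beyond 20
robust scales ($1.4826 \times$ MAD) are discarded and the fit repeated to
a fixed point. The multiplier is deliberately loose: no polynomial depth
surface can follow the steep shell rim, so smooth model mismatch alone
reaches 12+ scales on a clean shell, while genuine depth outliers (mixed
pixels, multipath, displaced stage returns) sit ~50 scales out. A tight
classical $3\times$ MAD rule would shave ~20% of good rim points off every
clean shell.

## The synthetic generator

The generator replaces the sensor hardware and defines the conditions the
tests run under: exact surface sampling (uniform axial stations and
azimuths through the radius profile), visibility by outward-normal
orientation toward the sensor — exact for a convex body, no ray casting
needed — resampling to one point per angular pixel (0.0024 rad pitch on a
424 × 512 grid, nearest return per cell), forward shear distortion,
isotropic Gaussian point noise (default $\sigma = 1$ mm), and intensities
drawn around a bright-shell / dark-stage contrast (200 vs 30 gray levels)
with optional Gaussian intensity noise. Default capture distance is
0.74 m; egg presets are chicken ($a = 6$ cm), duck (7 cm) and quail
(3 cm), each with $b = 0.7a$. Side-on captures (axis near the image
plane) emulate the favourable geometry; tilting the axis ~45° out of the
image plane emulates end-on captures, which foreshorten the observed axis
and demonstrably inflate $\sigma_V$ or break the shear fit.

What the generator does *not* emulate: physically based time-of-flight
error (multipath, intensity-dependent range bias, temperature drift) —
only its shear-like aggregate; surface BRDF effects on intensity; partial
occlusion by other objects. Passing tests therefore show correctness of
the estimation machinery under the stated noise model, not sensor-level
fidelity on real hardware.

## Problem sizes used by the suite

Default scenes yield 550–700 shell points (matching the point counts the
capture geometry produces at 0.74 m). The acceptance-style tests run 100
noise-free random captures for exact recovery, 20 noisy replicates for
the 5% volume check, 5 matched capture-geometry pairs, and 100-histogram /
100-shape sweeps for the threshold and quadrature oracles; the full suite
completes in under two minutes on one core.

## Known limitations

* Shear coefficients are weakly identifiable from a half shell at 1 mm
  noise (see above); their value is in absorbing distortion for the
  volume, not as calibration estimates.
* End-on captures can converge to an answer with honest but large
  $\sigma_V$; users should prefer side-on geometry and treat the reported
  sigma as the quality gate.
* The model family assumes a circular cross-section and the specific
  quartic outline; elliptical cross-sections and other outline families
  are out of scope.
* The volume rests entirely on the model for the unseen half; a shape
  outside the family (double-yolk, deformed shells) will fit poorly and
  should be caught by the SSE and the $b/a$ band, not by the volume.
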