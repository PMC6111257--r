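# eggfit

Egg volume estimation from a single range-camera view of roughly half the
eggshell.

Measuring egg volume matters to the poultry industry (grading, quality) and
to ornithology, but contact methods risk cracking shells and water
displacement is slow. A low-cost time-of-flight range camera placed above
the egg sees only about half of the shell, which rules out mesh-based
volume estimation (convex hull, alpha shapes). `eggfit` instead fits an
implicit parametric egg-surface model to the partial point cloud and
computes the volume in closed form from the fitted shape parameters.

## The model

The egg outline in 2D is the two-parameter curve

```
(X² + Y²)² = aX³ + (a − b)XY²
```

where `a` is the major-axis length and `b` controls elongation; `b/a ≈ 0.7`
for a regular chicken egg, and `b = 0` gives a circle. Revolving the curve
about its major axis gives an implicit 3D surface. Placing that surface in
sensor space adds the tip position `(Xc, Yc, Zc)` and two rotation angles
(three model variants cover a major axis near the sensor X, Y or Z axis;
only the two horizontal variants are fitted, since an egg lies flat).
Range-camera distortion is absorbed by two optional back-shear terms
`X′ = X − Shx·Z`, `Y′ = Y − Shy·Z` applied in object space.

All parameters — shape, pose and optional shear — are estimated
simultaneously by a Gauss–Helmert least-squares adjustment
(`A δ + B v + w = 0`, one implicit condition per point, isotropic 1 mm
observation precision), with Levenberg–Marquardt step control on the exact
orthogonal-distance objective. The volume then follows from the shape
parameters alone:

```
V = π/2 · (a³/3 − a²b/3 + ab²/6 − b³/30)
```

with its standard deviation by first-order propagation of the `(a, b)`
covariance. Around the fitter sit an intensity-based segmentation stage
(metric center window, Otsu threshold on the infrared intensities, a
leverage-robust polynomial depth-surface filter), an automatic
initial-value pipeline (top point, in-plane alignment by width
minimization, constrained-radius sphere fit, tip search), and a synthetic
range-camera scene generator with exact ground truth.

## Worked example

```r
library(eggfit)

# simulate a capture: chicken egg, sensor 0.74 m above, 1 mm point noise
spec <- scene_spec(shape = egg_preset("chicken"), tilt_deg = 8, seed = 7,
                   noise_sigma = 0.001, intensity_sigma = 5)
frame <- render_scene(spec)
egg <- extract_egg(frame)           # center window + Otsu + robust filter
fit <- estimate_egg_volume(egg)     # init + Gauss-Helmert + shear choice
print(fit)
#> <egg_fit> Model II + shear, 651 points, 32 iterations, converged
#>   a = 6.03 cm, b = 4.52 cm (b/a = 0.750), SSE = 629, dof = 642
#>   V = 56.15 +/- 0.99 mL
egg_volume(spec$shape) * 1e6        # generator truth
#> [1] 57.75881
```

The printed `a` and `b` are the estimated shape parameters in cm, `V` the
closed-form volume in mL with its propagated standard deviation; here the
estimate is within 2.8% of the generating truth (1.6 propagated sigmas). A direct volume check:

```r
egg_volume(egg_shape(6.76, 5.49))   # duck-egg parameters, cm -> mL
#> [1] 75.06447
```

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/eggfit simulate --seed 1 --scene --out scene.xyz
Rscript inst/cli/eggfit segment  --in scene.xyz --out egg.xyz
Rscript inst/cli/eggfit fit      --in egg.xyz --out result.json
Rscript inst/cli/eggfit volume   --a 6.76 --b 5.49
```

Exit codes: 0 success, 1 usage error, 2 fit did not converge.

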