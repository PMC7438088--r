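---
title: "Models and methods in cellosmo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cellosmo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellosmo)
```

This vignette is the package's own account of the models it implements,
the numerical choices behind them, and what its synthetic-data tests do
and do not demonstrate about real data.

## The osmotic volume-response model

A round cell in a bath of nonpermeating solute (NaCl at room temperature,
where active volume recovery is absent) exchanges water across its
membrane at a rate set by the osmotic pressure difference:

$$\frac{dV}{dt} = A(V)\, L_p\, R\theta\, (c_i - c_e),$$

where $A(V) = 3V/a = 4\pi a^2$ is the surface area of a sphere of volume
$V$, $L_p$ the hydraulic permeability (m³/(N·s)), $R\theta$ the thermal
pressure scale, and $c_i, c_e$ the intra- and extracellular osmolarities.
Because the solute does not permeate, the intracellular molar amount
$n_i$ is constant and $c_i = n_i / (\phi_i V)$ with the osmotically
active water fraction

$$\phi_i = 1 - (1 - \phi_{ir})\frac{V_r}{V};$$

the subscript $r$ marks the reference state at the start of each loading
step. Setting $dV/dt \to 0$ gives the closed-form equilibrium

$$\frac{V_\infty}{V_r} = 1 - \phi_{ir} + \phi_{ir}\,\frac{c_{er}}{c_e},$$

which both seeds the fit ($\phi_{ir}$ from the plateau) and serves as an
independent oracle for the integrator (the simulated plateau must match
it to 0.1% across $\phi_{ir} \in \{0, .25, .5, .75, 1\}$ and both step
directions, which the test suite checks).

Assumptions worth stating: the cell is a sphere at all times; the
inactive volume $(1-\phi_{ir})V_r$ is incompressible and fixed; membrane
transport is purely osmotic (no mechanical tension term); temperature is
constant. Units follow the convention 1 mOsm/liter ≡ 1 mol/m³, so
$R\theta c$ is a pressure in Pa with $R = 8.314$ J/(mol·K) and
$\theta = 295.15$ K (room temperature, configurable via
`modelConstants()`).

### Key parameters

| parameter | units | default | role |
|---|---|---|---|
| $L_p$ | m³/(N·s) | fit; bounds $[10^{-16}, 10^{-11}]$ | water transport rate |
| $\phi_{ir}$ | – | fit; bounds $[0, 1]$ | osmotically active fraction |
| $\theta$ | K | 295.15 | bath temperature |
| sampling | s | 2 (0.5 Hz) | trace sampling interval |
| protocol | mOsm/liter | 333 → 466 → 333, 300 s each | loading steps |

### Numerical choices

*Integration.* `deSolve::ode` (lsoda, adaptive, stiff-capable) with
relative tolerance $10^{-8}$; residuals are evaluated exactly at the
measured time points. The active water volume $V - V_{\rm solid}$ is
floored at $10^{-6} V_r$ inside the right-hand side so adaptive trial
steps cannot cross the singular state where the cell would be all solid;
a cell generated with $\phi_{ir} = 0$ has $n_i = 0$ and cannot change
volume at all, which is handled as an exact constant trace.

*Fitting.* Each labeled step is fitted independently by
Levenberg–Marquardt (`minpack.lm::nls.lm`) on normalized volume. The
parameter vector is $(\log_{10} L_p,\ \phi_{ir},\ s)$: $L_p$ on a log
scale for conditioning, and $s$ a reference-volume nuisance scale bounded
within ±20% of the first sample. The scale matters: anchoring $V_r$ to
the single first measurement of a step propagates that sample's noise as
a *systematic* offset on every residual, and because a global scale on
$V(t)/V_r$ is nearly collinear with $\phi_{ir}$ (and partially with
$L_p$), a 1% radius error on the reference alone can shift the fitted
$L_p$ by tens of percent. With the scale free, the early-transient
samples pin the reference collectively. $\phi_{ir}$ is initialized from
the equilibrium plateau, and $L_p$ from a coarse profile scan over
$\log_{10} L_p \in [-14.5, -12]$ (step 0.5) so the local optimizer
starts in the right basin even on noisy traces. Fits whose parameters
stop at a box bound are flagged (`lp_at_bound`, `phir_at_bound`).

*Choice of jointly fitting $\phi_{ir}$.* Fixing $\phi_{ir}$ at the
plateau estimate and fitting $L_p$ alone is the main design alternative.
The joint fit was chosen because the plateau estimator uses only the
terminal window (throwing away information), fails entirely when a step
is truncated before equilibrium, and propagates its own noise into
$L_p$ invisibly; the joint fit degrades gracefully and reports its own
diagnostics. The plateau estimate survives as the initializer and as
`estimatePhirFromEquilibrium()` for direct use.

*Equilibration criterion.* A step "has plateaued" when the volume changes
by less than 5% (relative) over the final 30 s; $V_\infty$ is the mean
over that window. Both thresholds are arguments. The same rule doubles as
the burst/no-plateau QC flag: cells that lyse under hypo-osmotic load
drift or jump instead of plateauing. Fits with $R^2 < 0.8$ are flagged
`low_r2`; flags are reported, not silently dropped, so exclusion policy
stays with the caller.

*Reference reset.* In multi-step protocols the reference state resets at
each step boundary: the boundary sample carries the next step's label, so
the first sample of a step is the pre-step volume. A consequence worth
knowing: the second step's $\phi_{ir}$ is the *re-referenced* fraction
$1 - (1 - \phi_{ir})V_r/V_1$, not the original one — e.g. a cell
generated with $\phi_{ir} = 0.6$ that shrinks to 82.9% of its volume
enters the swelling step with $\phi_{ir}' = 0.517$.

### Identifiability under measurement noise

The hyperosmotic transient has amplitude ≈17% of $V_r$ with a time
constant of 60–90 s for typical cells. The information this carries about
$L_p$ is modest: with white multiplicative radius noise of CV $\sigma_a$
per frame at 0.5 Hz, a profile-likelihood analysis (and the package's own
Monte-Carlo tests) put the per-cell standard error of $\ln L_p$ near
$6\sigma_a$. At the sub-pixel accuracy the segmentation stage actually
delivers (≈0.25 px on a 45 px cell, $\sigma_a \approx 0.5\%$), per-cell
$L_p$ is recovered to a few percent and group means are unbiased. At
$\sigma_a = 5\%$ per frame, however, $L_p$ is essentially unidentifiable
per cell — the likelihood is flat over an order of magnitude, fits pile
up at the box bounds, and every fit fails the $R^2$ QC rule. The
generators accept any noise level, and the test suite deliberately
includes a case documenting that heavy noise produces *flagged* fits
rather than quietly wrong numbers. This is a physical information limit
of the assay geometry, not an optimizer artifact.

## Hertz microindentation

Spherical-tip indentation of an elastic half-space:
$F = \tfrac{4}{3}\,\tfrac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}$, with
$\nu = 0.5$ (incompressible cell; configurable) and $R = 3$ μm. For a
candidate contact point $z_0$ the model is linear in the prefactor and
baseline, so `fitHertz()` grid-searches $z_0$ (201 candidates) with a
linear least-squares solve at each, then refines $(z_0, k, b)$ jointly by
Levenberg–Marquardt. Curves with no detectable contact — best slope
non-positive, or no decisive improvement over a flat baseline — return a
non-converged flag instead of a number. The fitted range can be
restricted to a fraction of the maximum indentation (`fitFraction`) to
respect thin-sample validity; no bottom-effect (substrate) correction is
applied. Noiseless round trips recover $E$ and contact offsets to well
under 0.5% and 5 nm respectively, and the mean bias under 5%-of-peak
force noise stays below 2% (both tested).

## Morphometry

*Segmentation.* Background subtraction (median), Gaussian smoothing
(σ = 1 px), a global Otsu threshold refined to the midpoint of the
foreground/background plateau levels, hole filling, connected components,
and a distance-map watershed to split touching cells; border-touching
objects are dropped. The plateau levels are sampled away from the edge
ring (erode/dilate with a 5 px disc) because class means computed from
the raw threshold are dragged by edge pixels, biasing the boundary off
the half-height of the edge profile. With the refinement, measured disk
radii are accurate to <0.25 px across radii 10–60 px (tested), which at
0.2 μm/px is what makes 0.1 μm-level population radius comparisons
possible.

*Circularity.* The isoperimetric quotient $4\pi A / P^2$, computed on a
simplified polygon fitted to the traced object boundary
(Douglas–Peucker, tolerance 1 px), with $A$ the polygon's shoelace area.
Computing both $A$ and $P$ from the same polygon makes the quotient
internally consistent and removes the rasterization staircase: axis-
aligned and rotated squares score $\pi/4$ essentially exactly, large
disks ≥0.99. Chain-code corner-correction estimators
(Vossepoel–Smeulders) were evaluated and rejected: their weights assume
isotropically oriented boundaries and overshoot the quotient by 4–10% on
squares. Reported *perimeters* add the half-pixel boundary offset
($P_{\rm poly} + \pi$, the convex Minkowski term), since the traced
polygon runs through pixel centers. Reported group circularity follows
the convention of normalizing to the untreated-group mean.

*Other features.* Equivalent radius $a = \sqrt{A/\pi}$ from pixel area;
spherical volume $(4/3)\pi a^3$; aspect ratio from image-moment ellipse
axes; tracking by greedy nearest-centroid linking with a 10 px/frame gate
(cells are attached and near-stationary); focus scoring by variance of
the Laplacian; marker intensity as total in-mask intensity per μm²,
optionally normalized to a control mean; nuclear colocalization as the
Fisher z-transform $\operatorname{atanh}(\rho)$ of the in-mask Pearson
correlation between marker and nuclear channels (correlations are capped
at $1 - 10^{-6}$ so identical channels give a large finite score). The
default single-cell gates (area 80–1500 μm², aspect ≤ 1.4) separate
fragments, single round cells, and fused doublets cleanly in the
synthetic sets; on real cytometry data they would need re-tuning per
instrument.

## The synthetic-data generators

The generators emulate the *statistical structure* of the study's
treatment groups, not instrument physics:

- `groupPresets()` hard-codes only group means/SDs that are printed in
  the source results text; quantities shown only in figures are `NA` and
  must be user-supplied. The active water fraction truth defaults to 0.6
  for every group (per-group values are not printed numerically) — a
  placeholder, flagged as such here and in reports.
- `samplePopulation()` draws truncated-normal truths (physical bounds:
  $L_p > 0$, $E > 0$, radius > 0, $\phi_{ir} \in [0,1]$); the normal
  family is a modeling choice, not a published fact.
- `makeVolumeTraces()` applies white multiplicative radius noise per
  frame. Real segmentation noise is approximately white at this level but
  real traces also carry drift, bursts and focus excursions that the
  generator omits.
- `renderFrameSequence()` draws soft-edged (logistic, 1.5 px) bright
  disks on a noisy background. It exercises segmentation, tracking and
  morphometry; it does not emulate DIC shear shadows, halos, or
  out-of-focus light.
- `makeForceCurves()` and `makeChannelPair()` are exact forward models of
  the corresponding fits plus additive Gaussian noise.

Passing the recovery tests therefore shows the *estimation machinery* is
correct and unbiased under the stated noise models; it does not validate
the segmentation against real DIC images or the Hertz model against real
(viscoelastic, substrate-coupled) cells.

## Statistics

Cell-level feature distributions are compared with the two-sample
Kolmogorov–Smirnov test; biophysical group comparisons use two-tailed
Student t tests (equal variances, Welch available via `varEqual`), and
designs with more than two groups use one-way ANOVA followed by Fisher
LSD pairwise tests with the pooled residual mean square and no
family-wise correction (the LSD convention). Null-calibration tests run
at $n = 200$ per sample for the KS statistic because the exact
small-sample KS test is discretely conservative (measured type-I error
≈0.03–0.045 at $n = 50$) — a property of the test, not of the
implementation. Cross-system normalization multiplies a second imaging
system's measurements by the ratio of untreated-control means so the
controls coincide exactly. Scaling relationships are ordinary least
squares across treatment-group means (not per-cell values); with five
groups the regression of hyperosmotic $L_p$ on relative circularity gives
slope −14.1 ×10⁻¹⁴ m³/(N·s) per circularity unit and $R^2 = 0.93$ (see
the README example, computed by the package).

## Problem sizes used by the test suite

Chosen to make the suite informative yet quick on a single CPU: recovery
grids of 9 $(L_p, \phi_{ir})$ combinations; 100-replicate Monte-Carlo
recovery studies with 12 cells each; 200-cell radius-recovery populations
rendered in 512 px fields of 6 cells; 1000-replicate null calibrations
for KS and ANOVA; 200-replicate power checks. The full suite runs in a
few minutes.

## Known limitations

- The volume model ignores membrane tension, transporter activity and
  solute permeation; it is a passive, room-temperature description.
- $\phi_{ir}$ group truths are placeholders (0.6) pending numeric values.
- The Hertz fit assumes a linear-elastic half-space; thin, adherent or
  viscoelastic cells violate this, and no substrate correction is made.
- The imaging generator's realism bounds what image-analysis tests can
  claim (see above).
- Per-cell $L_p$ precision is information-limited by the transient's
  size and duration; group-level inference should weight or filter by
  the reported QC flags.
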