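---
title: "Quantifying nodule size and depth from instrumented palpation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nodule size and depth from instrumented palpation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A stiff nodule embedded in soft tissue — the clinically important case is a
prostate tumour palpated through the rectal wall — changes the reaction
force measured when a probe is pressed into the tissue surface. The
difficulty is that the effect of nodule **size** and nodule **depth** on the
force feedback is coupled: a small shallow nodule and a large deep one can
produce essentially the same force at a single indentation depth, so
single-depth palpation cannot determine both. `palpquant` implements a
decoupling strategy: probe at *several* indentation depths, reduce each
force-vs-position profile to the second derivative of a spline fit at the
nodule position, and invert each of those curvature values against a
precomputed finite-element calibration library. Each indentation depth then
constrains a *curve* of (depth, diameter) combinations, and the curves from
different indentation depths intersect at the true nodule parameters.

## The forward model

The tissue block is a 2D **plane-strain** rectangle (coordinates: x along
the palpated top surface, y positive downward), fully fixed along its
bottom edge — the configuration of a sample resting on a rigid test
platform — with traction-free lateral edges. The probe is the circular
cross-section (radius 5 mm) of a 10-mm spherical-tip indenter, treated as a
rigid body in frictionless contact. Loading is quasi-static and
displacement-controlled; every reported force is per millimetre of
out-of-plane thickness (N/mm). Only relative and derivative quantities
enter the inversion, so the plane-strain normalization cancels between
library and measurement.

Both tissues are hyperelastic. The healthy matrix uses a second-order Ogden
energy in the isochoric principal stretches,

$$\Psi = \sum_{i=1}^{2} \frac{2\mu_i}{\alpha_i^2}
  \left(\bar\lambda_1^{\alpha_i} + \bar\lambda_2^{\alpha_i} +
        \bar\lambda_3^{\alpha_i} - 3\right),$$

with the prostate-mimicking parameters $\mu_1 = 0.02119$ MPa,
$\alpha_1 = 2.244$, $\mu_2 = -0.01120$ MPa, $\alpha_2 = -1.081$
(`ogden_healthy_tissue()`); the nodule doubles every $\mu_i$
(`ogden_cancerous_nodule()`), giving the conservative 2:1 stiffness
contrast between cancerous and healthy tissue. Note the "$-3$" in each
deviatoric term: without it the energy would not vanish in the reference
configuration, which is required of a strain-energy density; the package
includes it deliberately. Gelatin phantom gels use the one-parameter
incompressible neo-Hookean model $\Psi = C_1(\bar I - 3)$, which is the
exact one-term Ogden material with $\mu = 2C_1$, $\alpha = 2$; under
incompressibility $E = 6C_1$, so the fitted constants
$C_1 = 4.6898\times10^{-3}$ and $6.5872\times10^{-3}$ MPa correspond to
28.1 and 39.5 kPa.

The small-strain modulus implied by the Ogden parameters is
$E = 3\sum_i\mu_i \approx 30$ kPa rather than the 20 kPa these parameters
nominally represent; the parameters were fitted over the large-strain range
relevant for deep indentation, and the package takes them as given rather
than re-deriving them. The tests therefore assert the tangent against
$3\sum\mu_i$, not against the 20/40 kPa labels.

### Discretization and solver

The mesh is a structured "crossed-triangle" grid: each quadrilateral cell is
split into four constant-strain triangles around a centre node. The surface
is resolved at half the nominal `mesh_size` in x everywhere (the probe can
land anywhere), and rows are graded in y — `mesh_size/2` in the
contact-affected band near the surface, `mesh_size` in the middle,
about `1.7 * mesh_size` at depth. Elements are labelled healthy / cancerous
/ interface-mixture by the position of their centroid relative to the
nodule geometry.

Incompressibility is enforced by a volumetric penalty on the *cell-averaged*
volume ratio (mean dilatation over each four-triangle quartet), the standard
locking mitigation for linear triangles. The default penalty bulk modulus
is $200\,\mu_0$, corresponding to a Poisson ratio of about 0.4975 — inside
the 0.49–0.5 range reported for prostate tissue. A stiffer penalty of
$1000\,\mu_0$ changes the peak force by under 1% but makes the Newton
tangent indefinite at intermediate iterates and roughly quadruples solve
time, so 0.4975 is the default and `penalty_factor` is exposed for
near-incompressibility studies.

Contact comes in two interchangeable modes. The default,
`mode = "displacement"`, moves every surface node inside the geometric
overlap onto the indenter arc, prescribing only the vertical component —
the horizontal dof stays free, which is what frictionless contact means for
a nodal discretization. `mode = "penalty"` is true frictionless nodal
penalty contact against the analytic rigid circle. The two agree within a
few percent (asserted at 3% in the tests); the displacement mode is several
times faster and is used for library construction.

Each indentation is solved quasi-statically in (by default) 10 equal
displacement increments with a full Newton iteration per increment.
Globalization is by backtracking line search on the total potential energy
(the assembled residual is the exact gradient of the assembled energy, so
Armijo descent is well defined) plus a Levenberg-style diagonal shift
whenever the simplicial LDL' factorization reports negative pivots.
Increments that still fail are bisected recursively. Convergence is
declared at a residual norm below $10^{-8}$ of the reaction-force scale.
Because the material is elastic, the response is path independent: a sweep
over indentation depths 1/5/10 mm is computed as one continuation solve per
position whose increment schedule passes exactly through the requested
depths, which is identical to (and three times cheaper than) solving each
depth from the undeformed state. Each probe *position* is still solved from
an undeformed configuration, mirroring the relaxation protocol of a real
measurement.

## Profile analysis

`second_derivative()` fits a cubic spline through *all* points of a force
profile and differentiates it analytically. With `smoothing = "auto"` a
smoothing spline is used and its parameter chosen by generalized
cross-validation — the right default for noisy measurements. With
`smoothing = 0` an exact interpolating cubic spline is used instead, which
reproduces polynomials up to cubic order exactly; this is the appropriate
setting for noiseless simulated profiles and is what the calibration
pipeline uses, because library and measurement must be reduced by the
*identical* analysis for the inversion to be consistent. Positions within
one indenter radius of the domain edges are flagged unreliable by
`curvature_profile()`.

`localize_nodule()` returns the position where the force differs most from
a healthy-background baseline, with ties broken toward the centre of the
probed line. The detection floor defaults to three times the baseline's
residual spread about a GCV spline — zero for a noiseless baseline, about
$3\sigma$ for a noisy one — so identical profiles yield a clean "no nodule"
signal.

One caveat worth stating plainly: the homogeneous block's profile has
substantial curvature of its own (the force decays toward the domain
edges), of the same order as the nodule's contribution at shallow
indentation. The raw second derivative is therefore *not* a
nodule-specific signal in absolute terms; it is the comparison against a
library computed under the identical protocol that makes it informative.

## Calibration library and inversion

`build_library()` runs the forward model for circular nodules over a grid
of centre depths and diameters, for every indentation depth in the
protocol, storing the spline second derivative at the nodule position
(the nodule is centred under the probed line's midpoint; lateral position
is handled by localization, and the library is translation-invariant by
symmetry). Two empirical monotonicities make the inversion well posed, and
are asserted in the tests: at fixed depth the value moves strictly
monotonically with diameter, and the diameter effect weakens as the nodule
sits deeper.

`invert_to_curve()` maps one measured second derivative to a diameter at
every tabulated depth by shape-preserving monotone (Fritsch–Carlson)
interpolation along the diameter axis; depths where the measurement falls
outside the tabulated range are omitted, library rows that are not strictly
monotone in diameter (a deep nodule probed too shallowly for its signal to
exceed the mesh resolution) are skipped with a warning, and a fully
out-of-range measurement yields an explicit empty-curve signal. The
`quantify_profiles()` wrapper drops such uninformative indentation depths
and intersects the remaining curves, requiring at least two. Depth conventions:
library circles are indexed by their *centre* depth (unambiguous for
circles); phantoms specified by top-face depth are converted with
`depth_center = depth_top + height/2`.

`intersect_curves()` joins each curve's points linearly across the library
depths and searches for the point minimizing the sum of squared distances
to all curves, in coordinates normalized by the spans the curves cover so
that depth (tens of mm) and diameter (mm to tens of mm) contribute
comparably. A grid scan seeds Nelder–Mead refinements of every local
minimum; all candidates are reported ranked by residual, the best is
`chosen`, and a configurable residual ceiling converts mutually
inconsistent measurements into an error instead of a silent bad answer.
When the truth lies on the library grid and the measurement comes from the
same forward model, every curve passes exactly through the true point and
the recovered residual is numerically zero — the closed-loop exactness the
acceptance tests assert. For irregular nodules the result is summarized as
an equivalent circle (2D, $R = \sqrt{A/\pi}$) or sphere
($R = (3V/4\pi)^{1/3}$).

## Synthetic phantoms

`reference_configurations()` bundles the study conditions used throughout:
the two in-silico worked examples (16 mm circle at 30 mm depth; 30 mm
circle at 45 mm depth; 100 × 100 mm domain, 40 probe sites, indentation
depths 1/5/10 mm), five nodule-geometry sensitivity cases (two
intersecting-circle variants of 10 and 15 mm diameter, an irregular
polygon, a diffuse-boundary annulus of 20/30 mm inner/outer diameter, and
a 12.5 × 25 mm rectangle), and the 2D mid-section of a gelatin tissue
phantom (100 × 31 mm block, 20 × 12 mm rectangular nodule with its top
face 10 mm below the surface, 28.1/39.5 kPa gels, depths 2/4/6 mm at five
sites, 20 mm apart).

Choices the geometry descriptions leave open are fixed once and recorded in
the bundle metadata: intersecting circles are placed side by side at the
nodule depth with a centre offset equal to the mean radius (so they
genuinely intersect); the irregular outline is a fixed synthetic polygon of
roughly 15 mm extent; the diffuse annulus's shell takes the arithmetic mean
of the healthy and cancerous moduli (a "mixture of both tissues" with no
stated mixing law); the 3D gelatin phantom is represented by its 2D
mid-section, consistent with the calibration models being 2D — closed-loop
tests on it therefore validate the pipeline, not the 3D-to-2D reduction.

`synth_measurement()` perturbs a forward sweep with the two error sources a
real instrument exhibits: zero-mean Gaussian force noise scaled by the
per-profile maximum, and a contact-point-finding error applied as a random
per-site indentation-depth offset (bounded by ±0.5 mm, re-evaluated
through a monotone local force–depth interpolant). Everything is
reproducible from the seed, and zero noise returns the simulation
unchanged, bit for bit.

## Material identification

`fit_neo_hookean()` identifies $C_1$ from indentation force data by damped
(Levenberg–Marquardt) least squares over all depths and positions,
delegating to `minpack.lm::nls.lm` with a finite-difference Jacobian,
parameter tolerance $10^{-8}$ and at most 200 iterations. Because the
incompressible neo-Hookean response is exactly linear in $C_1$, the
objective is quadratic and the closed loop recovers a generating constant
essentially exactly; the per-point relative errors
$|F_{sim}-F_{meas}|/F_{meas}$ are reported alongside the implied modulus.

## Problem sizes and numerical defaults

The worked examples and tests run at deliberate desk scale, chosen once:
calibration libraries of 3 depths × 4 diameters at `mesh_size = 6` mm with
13 probe sites (a library builds in about 2.5 minutes on one core; the
full closed loop in about 3.5), property checks at `mesh_size = 8`, mesh
convergence compared against `mesh_size = 3`. Newton tolerance $10^{-8}$,
10 increments per indentation, contact penalty $1000\,\mu_0$ per node
(the resulting force is within 0.3% of a 20× stiffer penalty)
(penetration well under 1% of the indentation depth), library
interpolation monotone cubic, intersection grid 101 × 101 with
Nelder–Mead refinement to $10^{-14}$ relative.

## What passing tests do and do not show

The closed-loop validations generate the "measurement" from the same
forward model that builds the library. They demonstrate that the
localization, curvature reduction, inversion and intersection machinery is
internally consistent, exactly invertible on the grid, and robust to the
modelled noise — not that the 2D model reproduces any particular physical
phantom. Friction, viscoelasticity (rate dependence and relaxation),
3D geometry, multiple nodules, and heterogeneous background stiffness are
all outside the model; the quasi-static elastic treatment is justified
only for slow indentation with adequate relaxation time. The stiffness
contrast is fixed at 2:1 — the inversion estimates geometry, not modulus.
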