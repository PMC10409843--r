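---
title: "Coronary bending FSI: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary bending FSI: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corofsi)
```

## What the package models

Coronary arteries are not static conduits: every heartbeat they distend
under the pressure pulse and bend with the moving myocardium. Both effects
alter the wall shear stress (WSS) environment of the endothelium — the
time-averaged WSS (TAWSS), its multidirectionality (transverse shear
stress, tSS) and its oscillatory character (OSI) — and the cyclic strain
state of the wall. `corofsi` implements an artery-specific, reduced-order
fluid–structure interaction (FSI) pipeline to quantify these effects and to
compare three simulation arms on identical boundary conditions:

1. `cfd_rigid` — pulsatile flow in the rigid imaged geometry;
2. `fsi_no_bending` — distensible pre-stressed wall, no bulk motion;
3. `fsi_bending` — distensible wall plus the measured (or synthesised)
   diastole-to-systole bending motion.

Everything lives on one structured lumen parameterisation: axial station
`i` (proximal at station 0, after an inlet flow-development extension that
is excluded from all outputs) by circumferential angle `theta_j`, with
`theta = 0` anchored to the inner curvature — the myocardial side — at the
station of maximum curvature. Opened-and-flattened metric maps, histograms
and summary statistics are then exact re-indexings of this grid.

## Vessel geometry and kinematics

A centreline is an ordered 3D polyline with cumulative arc length.
`build_tube()` extrudes a circular cross-section of per-station radius
along it using rotation-minimising (parallel-transport) frames; Frenet
frames are deliberately avoided because they flip at inflection points of
realistic coronary centrelines. Since no convention exists for where to cut
a vessel open for flattened maps, the package fixes the cut line at the
inner-curvature generator and propagates it by transport.

Bending motion is derived from a diastole/systole centreline pair:
`compute_bending_vectors()` resamples both to a common station count at
equal normalised arc length and takes the pointwise difference. The
normalisation absorbs any systolic change of vessel length — a known
limitation of centreline-pair kinematics, shared with the imaging it
emulates. The displacement is applied to the wall over a contiguous
inner-curvature patch covering 30% of the circumference by default (the
epicardial embedding of proximal segments; ~50% is more representative of
mid/distal segments and is available via `patch_fraction`), with all nodes
of one ring sharing one vector, and to the full circumference of the
perivascular outer surface.

The bending amplitude over the cycle is a smoothed asymmetric sawtooth:
zero at diastole (t = 0), one at systole, linear in between. The blending
at both extrema uses monotone cubic Hermite segments with zero slope at the
extremum. This choice — rather than, say, convolution smoothing — keeps
A(diastole) = 0 and A(systole) = 1 *exact*, guarantees A in [0, 1] for
every admissible smoothing width (Fritsch–Carlson monotonicity), and makes
dA/dt continuous and periodic, so no displacement-rate impulse is applied
when the vessel reverses direction. The default smoothing half-width is 5%
of the period. The exact waveform shape beyond these constraints is not
observable from the endpoint conditions and is not asserted anywhere.

The bending metric, `bending_derivative()`, is the spatial derivative of
the magnitude of the inlet-normalised displacement field, by central
differences on the station grid with no additional smoothing: zero
identifies rigid translation, non-zero values local bending. The same
inlet-normalisation defines which part of the motion the pipeline treats as
*deforming*: a pure translation carries the contained blood and the
surrounding tissue with it and is dynamically inert in the quasi-static
limit, so only the translation-removed component drives the patch
distension constraint and the motion-induced shear closure. The
`assign_to_wall()` displacement field itself always carries the full
vectors.

## Wall mechanics

The wall is a three-term Ogden hyperelastic solid in deviatoric principal
stretches,

$$W = \sum_{i=1}^{3} \frac{2\mu_i}{\alpha_i^2}
      \left(\lambda_1^{\alpha_i} + \lambda_2^{\alpha_i} +
            \lambda_3^{\alpha_i} - 3\right),$$

with defaults fitted to porcine coronary inflation data:
`mu = (6.8991, 10.0284, 3.9691) kPa`, `alpha = (8.5782, 0.0003, 8.5782)`,
and volumetric parameter `D1 = 9.57e-4 kPa^-1`. The initial moduli are
`mu0 = sum(mu_i) ~ 20.9 kPa` and `K0 = 2/D1 ~ 2090 kPa`, a bulk-to-shear
ratio of 100, i.e. a near-incompressible Poisson's ratio of 0.495.
Near-incompressibility is enforced through this volumetric penalty, not a
Lagrange multiplier. The exponent `alpha_2 = 3e-4` is numerically
degenerate in the naive formulas; all constitutive kernels switch to a
series expansion in `alpha` below |alpha| < 1e-2 (accurate to ~1e-8
relative at the threshold), and the small-exponent limit of a term's
uniaxial stress is `3 mu log(lambda)`.

Because the wall thickness (190–250 µm) is an order of magnitude below the
lumen radius, the wall is discretised as a membrane on the (station, ring
node) grid rather than as 3D continuum finite elements: per ring, a
Laplace-type circumferential balance with the Ogden tangent response,
circumferential smoothing between neighbouring nodes (coefficient
`coupling_c`, default 1, scaled by `mu0 h / (R dtheta)^2`), an elastic
foundation representing the perivascular tissue, and hard radial
constraints on bending-patch nodes. The perivascular support (linear
elastic, E = 10 kPa, nu = 0.05 — soft enough not to restrict distension) is
reduced to a foundation stiffness `E / t_support` with a default support
thickness of 2 mm; its role is to prevent unphysical drift, and when the
bending displacement is applied to its full outer circumference the whole
ring follows the imposed motion. If that full-ring loading is disabled, the
imposed translation is transmitted around the ring by a screened-Laplace
equation and decays with circumferential distance from the patch. End
stations are axially constrained (fixed axial stretch) but radially free,
mirroring rigid sliding end planes.

### Pre-stress

The imaged diastolic geometry is already loaded by axial stretch and
diastolic pressure. `backward_incremental_prestress()` recovers the
unloaded reference and the in vivo stress state with the backward
incremental (BI) method: the axial traction is ramped 0 → 100 kPa in 10
increments (the resulting axial stretch is held thereafter), then pressure
is ramped 0 → 80 mmHg in 12 increments with the ends axially constrained;
after each increment the computed displacement is subtracted from the
reference radius so that the fully loaded configuration converges to the
imaged one. A final fixed-point polish at full load tightens the recovery
below 1e-5 relative; the test suite asserts 0.1%. With the default
coefficients the axial phase yields an axial stretch of ~1.5 under our
membrane boundary conditions; the uniaxial evaluation is reported, not
asserted, since the stretch equivalent to a given traction depends strongly
on the lateral boundary conditions.

Cyclic strains are logarithmic, relative to the diastolic pre-stressed
state, and reported as the signed extreme over the cycle in percent:
circumferential from the ring radius ratio, axial from the change in
distance between axially adjacent nodes (which is what makes bending-driven
inner/outer-curvature shortening and lengthening visible), and radial from
near-incompressibility, `e_r = -(e_c + e_a)`, which also produces the
expected axial/radial anticorrelation.

## Blood flow

Blood is laminar, incompressible and shear-thinning, with Carreau
viscosity

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \left[1 + (\lambda_t \dot\gamma)^a\right]^{(n-1)/a},$$

with `lambda_t = 3.313 s`, `n = 0.3568`, `a = 2`, density 1050 kg/m^3, and
plateau viscosities `mu_0 = 0.056 Pa s`, `mu_inf = 0.00345 Pa s` (the
standard whole-blood values; both endpoints are configurable and all limit
checks compare against the configured values). The inlet velocity waveform
is imposed as a parabolic profile with the waveform value as the centreline
maximum; an inlet extension of 1.5 inlet diameters is prepended for flow
development and stripped from every output.

The 3D finite-volume problem is replaced by a radially resolved quasi-1D
solver: per station, the unsteady axisymmetric axial momentum equation is
integrated on a radial grid (default 33 points) with the pressure gradient
entering as a Lagrange multiplier that enforces the station flow. Station
flows follow from mass conservation with the wall-storage term,
`Q(s,t) = Q_in(t) - int_0^s dA/dt ds'`; the storage derivative is computed
spectrally with a low-pass at a quarter of the Nyquist band, which is exact
for the smooth periodic area signals involved and keeps the FSI coupling
loop from amplifying grid-frequency noise. Pressure is integrated backward
from the outlet waveform. Time stepping uses a theta-scheme with
`theta = 0.6` by default: pure Crank–Nicolson (0.5) leaves an undamped
grid-frequency oscillation on stiff radial modes when the wall moves, while
theta = 0.6 damps it and still resolves an analytic pulsatile (Womersley)
profile at Womersley number 3 to ~0.1% relative L2 with 200 steps/cycle.
Carreau self-consistency in the shear rate is handled by one Picard
correction per step (the steady solver iterates to tolerance). Wall shear
is evaluated from a second-order one-sided gradient, which is exact for the
parabolic steady profile.

Azimuthal structure is restored by closures on top of the axisymmetric
base shear `tau_0(s, t)`:

* a curvature (Dean) modulation `tau_ax = tau_0 (1 - c_d delta cos theta)`
  with `delta = R_lumen / R_curvature` and `c_d = 1.5` by default, raising
  shear on the outer curvature, plus a transverse secondary-flow component
  `c_s delta tau_0 sin(theta) tanh(De/50)` (`c_s = 0.5`); and
* a Stokes-layer transverse shear proportional to the deforming part of
  the lateral wall velocity, `sqrt(rho mu_w omega) v_tangential`
  (coefficient `c_b = 1`).

The literature the azimuthal closure condenses reports the inner/outer
asymmetry qualitatively but no secondary-flow structure is printed for this
configuration, so all three coefficients are explicitly free parameters of
the reduced model; the straight-tube limit (`delta -> 0`, no motion)
recovers the axisymmetric solution identically, and the WSS vector is
tangent to the lumen surface by construction.

## Coupling and the three arms

FSI arms initialise with BI pre-stress, then iterate coupling cycles: a
quasi-static wall pass (per station and time step: axisymmetric membrane
inflation, or the ring solve with patch constraints when bending deforms
the station) followed by a flow pass on the updated lumen, exchanging the
pressure field with under-relaxation 0.5. Wall inertia is neglected —
appropriate at coronary scales where the wall response time is far below
the cycle period. The loop stops when the ring-mean diameter field and the
TAWSS map change by less than `periodicity_tol` (default 1e-3, max-norm
relative) between consecutive cycles; with the damped theta-scheme this
takes 3–4 cycles. The rigid arm is a single flow solve on the static
geometry. All arms consume identical boundary-condition waveforms.

## Shear metrics and statistics

On the converged cycle (uniform periodic grid, so all time integrals are
exact periodic trapezoids, i.e. plain means):

* `TAWSS = mean_t |tau|`;
* `OSI = 0.5 (1 - |mean_t tau| / mean_t |tau|)`, clamped to [0, 0.5] and
  defined as 0 where the shear vanishes over the whole cycle;
* `tSS = mean_t |tau . (n x s_mean)|` with `s_mean` the unit cycle-mean
  shear direction — defined as 0 where the mean vector vanishes (at that
  exact degenerate point the transverse direction is undefined; any
  arbitrarily small asymmetry restores the generic definition, which the
  tests exercise with a non-uniformly rotating shear history).

Summaries use median and quartiles with the type-7 linear-interpolation
quantile rule (the convention must be fixed somewhere; type 7 is R's
default and is asserted in the tests). Distribution comparisons between
arms use Kruskal–Wallis plus pairwise rank-sum tests for unpaired shear
metrics and paired Wilcoxon signed-rank tests for strain fields on a
common grid, all Bonferroni-multiplied by the number of pairwise
comparisons and capped at 1.

## Synthetic data: what it does and does not emulate

`make_artery_preset()` provides LAD-, LCx- and RCA-like cases: tapered
gently curved tubes (e.g. LAD: 45 mm long, radius 1.7 → 1.0 mm), the
branch-specific uniform wall thickness (LAD 250 µm; LCx/RCA 190 µm), and a
motion composition over the three empirical coronary motion classes —
translation, bend (smooth curvature change) and lever (rotation about the
proximal end). The LAD and RCA presets are bend-dominant and the LCx
translation-dominant, and peak displacements are a few mm, matching the
qualitative phenotypes reported for these branches. Waveforms are sums of
raised cosines on one R-R interval (period 1 s by default, since
subject-specific heart rates are not available): a two-phase velocity
waveform, diastolic-dominant for the left system, and a pressure waveform
riding on an 80 mmHg diastolic baseline (the pre-stress reference) up to
120 mmHg. Optional Gaussian noise followed by periodic moving-average
smoothing emulates the smoothing of raw measurements into a cyclic
waveform. All generation is driven by a small self-contained seeded
generator, so outputs are bit-reproducible and independent of R's global
RNG state.

The generator makes no claim of physiological fidelity beyond these
qualitative shapes: it contains no side branches, no stenoses, no
subject-specific waveform morphology and no measured centrelines.
Consequently, passing tests demonstrate the *mechanisms* — that bending
raises transverse and oscillatory shear and breaks the homogeneity of the
strain field — and the solver's fidelity against analytic oracles, not
agreement with any particular animal's absolute values, which derive from
in vivo geometries and waveforms that are not part of this package.

## Numerical choices and degenerate inputs

* Geometry in mm/µm at the interfaces, SI internally; mmHg → Pa via
  133.322.
* Membrane and inflation roots are solved by `uniroot` on the
  circumferential stretch in [0.2, 5] at 1e-12 tolerance; ring solves use
  damped Newton with an analytic tridiagonal Jacobian, residual tolerance
  1e-10 kPa, 200-iteration cap, warm-started across time steps.
* Zero-curvature stations centre the bending patch at theta = 0; zero
  loads are exact identities of the equilibrium and pre-stress operators;
  zero-length centrelines, non-monotone arc length, inconsistent waveform
  periods (> 1%), invalid patch fractions and invalid mode weights raise
  errors.
* Default problem sizes (chosen as sufficient for the reduced model's
  accuracy targets): 200 time steps/cycle, 33 radial points, synthetic
  presets at 41 stations x 40 circumferential nodes; the test suite runs
  the same code paths at reduced sizes.

## Known limitations

Beyond the reduced-order character of the solvers themselves: no torsion
loading; no opening-angle residual stress; no side branches or
bifurcations (which likely disturbs flow less than reality, so tSS and OSI
magnitudes are conservative); isotropic constitutive law without fibre
reinforcement; the azimuthal closure coefficients are calibrated only to
limiting behaviour, not to a 3D reference solution; and the coupling
tolerance and time step of the original co-simulation workflow this
emulates are unknown, so ours are package defaults.
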