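---
title: "Halbach-array design and virtual scanning for ultra-low-field MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halbach-array design and virtual scanning for ultra-low-field MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halbachmri)
```

## The problem

An ultra-low-field MRI scanner can be built around a cylindrical *Halbach
array*: permanent-magnet cubes arranged in rings, with the magnetization of
the cube at azimuth $\varphi$ rotated to $2\varphi$ in the transverse plane
(the $k=2$ dipole pattern).  Such an array concentrates a roughly uniform
transverse field $B_0$ inside the bore with little stray field outside, and
needs no cryogenics or power.  The price is field homogeneity: imaging needs
$|B|$ constant to a few hundred parts per million (ppm) across the imaging
volume, while an unoptimized discrete array of a few hundred cubes is
inhomogeneous at the percent level.  This package implements the
computational chain such a scanner needs:

1. **magnetostatics** — closed-form fields of uniformly magnetized cuboids
   and of circular loop coils, with slow numerical oracles for validation;
2. **halbach** — a parameterized multi-ring, multi-layer array and a genetic
   optimizer for its geometry;
3. **fieldmap** — the gridded field-map container produced by a three-axis
   mapping robot, its CSV dialect, homogeneity metrics, and first-order
   spherical-harmonic fits for gradient calibration;
4. **shim** — passive shimming (small cubes on two sleeves, placement found
   by a mixed continuous/binary genetic search) and active shimming (loop
   coil currents by bounded ridge least squares);
5. **scanner** — a spin-echo virtual scanner that turns a phantom and a
   residual field map into k-space and reconstructed DICOM images with the
   geometric distortion that B0 inhomogeneity produces.

Reference numbers throughout correspond to a desk-scale 43 mT system:
990 N40-grade cubes of 12.7 mm edge in 12 rings of 3 layers, bore envelope
26.54 cm (inner) / 39.05 cm (outer) / 35.2 cm (length), an 11 cm target
field of view (FOV), and homogeneity quoted over a 10 cm diameter spherical
volume (DSV).

## Magnetostatic models

The cuboid field uses the charged-surface closed form: a cube uniformly
polarized along $\hat z$ with polarization $J = B_r$ (tesla) is equivalent
to two charged faces, and each Cartesian field component is a sum of 8
corner terms in $\ln$ and $\arctan$.  The formula is valid inside the
magnet as well once $\mu_0 M$ is added there.  Arbitrary magnetization and
cube orientation are handled by rotating into the cube body frame and
superposing the three axis-aligned polarization components.  The hot loop
(990 magnets $\times$ 515 grid points per objective evaluation) is a small
C++ kernel; one evaluation costs tens of milliseconds.

Correctness is established against two independent oracles rather than a
reference library: a midpoint-quadrature surface-charge integrator
(`cuboid_field_numeric`, agreeing to better than $10^{-6}$ relative well
away from faces and converging monotonically in the subdivision count) and
the point-dipole limit with moment $m = (B_r/\mu_0)\,e^3$ (matching to
$<0.1\%$ at 0.5 m).  Points exactly on a face or edge lie on the singular
locus of the closed form and return non-finite values by design; any
physical evaluation point is off-face.

Loop coils (the active-shim elements: 35 mm diameter, 15 turns) use the
exact elliptic-integral solution of a circular filament, multiplied by the
turn count.  The winding cross-section is ignored — at shim-coil distances
(several cm) the filament error is far below a percent, which the
Biot–Savart polygon oracle (`loop_field_numeric`) confirms.

## The homogeneity metric

`ppm over a DSV` here means **peak-to-peak**: $(\max|B| - \min|B|) /
\operatorname{mean}|B| \times 10^6$ over the grid points inside the sphere,
the convention of the Halbach-design literature; an RMS variant is exposed
as an option.  The default evaluation grid is the $11^3$ regular grid
clipped to the sphere (515 points over the 10 cm DSV).  Peak-to-peak on a
finite grid underestimates the continuum value slightly; all quoted numbers
use the same grid, so comparisons are consistent.

## Halbach geometry optimization

The free parameters are the 12 ring positions along the bore, the 3 shared
layer radii, and a per-ring angular offset (bounded to half an azimuthal
magnet spacing, beyond which designs repeat by symmetry).  Three design
choices deserve explanation:

**Equal per-layer counts.**  990 magnets over 12 rings is 82.5 per ring, so
some split is unavoidable.  We assign *equal counts to the three layers of
each ring* — six rings of $3\times28$ and six of $3\times27$, the heavier
rings mirror-symmetric about the center.  Equal counts put all layers of a
ring on one shared azimuth grid: radially adjacent cubes then sit exactly
face-parallel (both are rotated by the same $2\varphi$), so layers can nest
at a radial pitch of a single cube edge instead of the cube diagonal that
arbitrary relative rotations would require.  That packs the magnet mass
~10 mm closer to the bore, which raises the central field by ~5% at no
homogeneity cost — and it mirrors how nested ring formers are actually
machined.  An allocation proportional to layer circumference is the obvious
alternative; it forces diagonal clearances and, in our Pareto measurements,
costs nearly an order of magnitude in achievable homogeneity at the design
field.

**A design-field floor.**  Minimizing ppm alone is ill-posed as a design
objective: homogeneity improves monotonically as the optimizer spreads
rings toward the bore ends and enlarges radii, *discarding* field strength
(we measured ~355 ppm at 30 mT versus ~1000 ppm at 43 mT on the Pareto
front).  A scanner is designed at an operating field — the solenoid coil
tuning (1.825 MHz for protons near 43 mT), gradient strengths and SNR
budget all presuppose it — so `halbach_constraints(design_field = 0.043)`
enters the objective as a floor on mean $|B|$ with a steep penalty, and the
optimizer finds the most homogeneous geometry *at* the design field.

**Mirror-symmetric search with a memetic finish.**  Homogeneous optima are
mirror-symmetric about the mid-plane, so the default search varies 6 ring
positions and offsets and mirrors them (halving the dimension, and letting
the objective evaluate only the upper half of the grid since $|B|$ is even
in $z$).  The genetic algorithm is a standard real-coded GA — simulated
binary crossover, polynomial mutation, binary tournaments, elitist
survivors, population 40, 150 generations, early stop after 40 stalled
generations — followed by a Nelder–Mead polish of the champion.  The polish
matters: the field-floor penalty creates narrow curved ridges on the
peak-to-peak objective along which crossover steps make slow progress, and
a few thousand simplex iterations reliably descend the last factor of a
few.  Ring/radius ordering constraints are enforced by a sort-and-space
repair operator rather than penalties, so every evaluated individual is
geometrically feasible (no overlapping magnets).

With the default budget one optimization run takes a few minutes on one
core and lands at the 43 mT design field with 1000–1800 ppm peak-to-peak
over the 10 cm DSV on the 515-point grid depending on the seed (best
observed ≈1040 ppm, which multistart and asymmetric polishes do not
improve, so we take it as the constrained optimum of this design space); an
unoptimized equal-spacing baseline sits near 5%.

## Field maps and fitting

`simulate_mapping` emulates the mapping robot: it evaluates the superposed
source field at every grid point in raster order (x fastest, as a 3-stage
gantry sweeps) and adds i.i.d. Gaussian probe noise per component
(default 0 — the real probe's noise floor is not a published quantity, so
noise is opt-in).  Maps serialize to a CSV with a `#`-prefixed JSON
metadata header; columns are mm and mT for inspectability, 12 significant
digits, so round trips are lossless to ~$10^{-12}$ relative.

`fit_first_order_sh` fits $B(r) = c_0 + g_x x + g_y y + g_z z$ by least
squares; degree-1 solid harmonics are exactly the Cartesian coordinates, so
the slopes are the gradient strengths, and dividing by the recorded drive
current gives gradient efficiency in mT/m/A — the calibration a gradient
coil needs after winding.  On a symmetric grid the degree-2 harmonics are
orthogonal to degree-1, so pure second-order fields fit zero gradient; the
fit is exact on noiseless linear fields and unbiased under noise (verified
by Monte Carlo against the closed-form standard error).

The synthetic-data generator for shimming studies,
`synthetic_inhomogeneity_map`, models an as-built magnet: nominal 43 mT
along x plus a seeded random mix of degree 1–2 solid harmonics (each
normalized to unit grid RMS) scaled to a requested peak-to-peak ppm over
the DSV — 3000 ppm by default, the scale measured on the physical magnet
after assembly.  It emulates the long-wavelength error field from ring
gaps, magnet tolerance and demagnetization; it does *not* emulate localized
defects, probe drift, or harmonics above degree 2, so a shim result on it
bounds what smooth-error correction can do, not what any real magnet needs.

## Shimming

**Passive.**  22 rings of 25 candidate 3 mm cubes sit on two sleeves
(radius 66.5 mm) flanking the RF coil, the holders fixed 4 cm and 23.5 cm
from the magnet front face (isocenter coordinates $-136$ mm and $+59$ mm
for the 35.2 cm magnet; each holder allows ±3.5 cm of ring travel).  "22
rings" is read as 22 total, 11 per holder — the per-holder reading is a
constructor option.  Shim cubes follow the same $k=2$ magnetization
convention as the main array (the orientation of the physical shim magnets
is not a published detail; with this convention a fully populated ring adds
a nearly uniform transverse field, and partial rings supply the low-order
correction gradients).  Each ring additionally carries a polarity flip bit,
optimized with the placement and on by default.  The flip is not cosmetic:
magnets of fixed polarity can only *add* field, and with both holders on
one side of, or far from, the isocenter, a greedy oracle shows the z-odd
error harmonics ($xz$, $yz$) and the axial second-order term to be
essentially uncorrectable without sign freedom — entire error-field
realizations then cap below 20% improvement.  Reversed rings subtract
field, restoring those harmonics; `allow_flip = FALSE` reproduces the
presence-only behaviour.  The optimizer is the same GA with a mixed
chromosome: continuous ring positions and rotations, plus 550 inclusion
bits and 22 flip bits.  A deterministic baseline individual (evenly spread
rings, empty mask) is injected into the initial population, so with elitism
the reported shimmed ppm can never exceed the unshimmed input — an
invariant the tests assert.  On 3000 ppm-scale degree-1–2 maps the default
budget (population 60, 250 generations) removes 40–65% of the peak-to-peak
spread across generator seeds; on tiny instances ($2^6$ masks) the GA
recovers the exhaustive-search optimum.

**Active.**  30 loop coils on a 76 mm-radius tube, laid out 5 rings
$\times$ 6 staggered azimuths (only the count and coil geometry are fixed
by the hardware; the layout is a constructor option).  Solving currents is
a bounded ridge least-squares problem on the B0-axis component: basis
fields are precomputed per coil at unit current, the mean level is removed
(shimming corrects variation, not the absolute field), and currents are
found by L-BFGS-B on the scaled quadratic within $\pm1$ A per coil.  The
centered coil basis is rank-deficient by symmetry, so $\lambda = 0$ raises
an error that advises regularization; the default $\lambda$ is picked at
the corner (maximum curvature) of the L-curve over a log grid.  If the
solution would worsen the peak-to-peak metric (possible, since the solver
minimizes a component residual, not ppm), the zero-current solution is
returned instead.  With ±1 A and 15-turn 35 mm coils the array can cancel
roughly a third of a 130 µT peak-to-peak perturbation — the current limit,
not the solver, is the binding constraint.

## The virtual scanner

The spin-echo signal model is Fourier encoding plus off-resonance phase:

$$s(k) = \sum_r \rho(r)\, e^{-i 2\pi k\cdot r}\, e^{\,i 2\pi\,\bar\gamma\,
\Delta B_0(r)\, t(k)},\qquad t(k) = \frac{k_{\mathrm{read}}}{N_{\mathrm{read}}
\cdot \mathrm{BW}_{\mathrm{px}}}$$

The refocusing pulse cancels static dephasing at the echo center, so phase
accrues only with the readout-time offset; phase-encode directions are
unaffected.  This reproduces the characteristic distortion of low-field
images — displacement $\Delta f/\mathrm{BW}_{\mathrm{px}}$ pixels along the
readout axis (the sign set by gradient polarity; this implementation
displaces by $-\Delta f/\mathrm{BW}_{\mathrm{px}}$) — without a Bloch
solver.  T2 decay is an optional per-voxel factor $e^{-TE/T_2}$; decay
*during* the readout, relaxation during excitation, and coil sensitivity
are out of model.  The readout bandwidth defaults to 200 Hz/pixel (not a
published protocol value) and is exposed because distortion scales with it.

The simulator evaluates, for each readout index, the centered unitary 3D
DFT of the phase-weighted object and keeps one readout plane — exact for a
voxel-discretized object, $N_\mathrm{read}$ FFTs per acquisition.  With
$\Delta B_0 = 0$ the k-space is exactly the DFT of the phantom, so
reconstruction inverts simulation to numerical precision; the tests assert
NRMSE $< 2\%$ and exact Parseval energy balance.  Acquisition order is
metadata: lines are stored in acquisition order and reassembled by the
reconstructor, which errors on omitted or duplicated lines and produces
bit-identical images under any permutation.  "16 slices" protocols are 3D
slab-encoded (`encoding = "3d"`, one phase–slice line per TR, so
$TA = TR \cdot N_\mathrm{phase} N_\mathrm{slice}$; the reference protocol
TR 500 ms, 384×16 gives 3072 s = 51:12 against a printed 51:14 — the 2 s
gap would be two dummy shots or rounding, and `dummy_shots` is exposed
rather than silently absorbed).  2D multislice acquires all slices each TR.

Phantoms are generated, not shipped: a 10 cm sphere with a message carved
as signal-void glyphs from a built-in 5×7 raster font on a 12 mm-thick
mid-plane plate (thick enough that coarse slice grids intersect it), and a
two-cylinder "syringe" object.  Reconstructions export as one
secondary-capture DICOM file per slice (explicit VR little endian, written
byte-by-byte in-package: correct pixel spacing, slice positions, fresh
study/series/SOP UIDs, 16-bit pixels with a rescale slope), and a matching
minimal parser verifies round trips in the tests.

## Numerical choices and limitations

* Problem sizes: tests run the GA at reduced budgets (population ~16,
  ~12 generations) where only contracts are asserted (trace monotone,
  determinism, better-than-baseline); full-budget runs (population 40/60,
  150–250 generations) are reserved for the end-to-end acceptance checks.
  The virtual scanner tests use 16–48³ matrices; the full 384×384×16
  protocol is minutes of FFTs and is exercised via `acquisition_time`
  rather than simulated in tests.
* The GA is seeded by contract: `ga_params` without a seed is an error
  inside the optimizers, and all pipeline artifacts are byte-reproducible
  given seeds (timestamps aside).
* Repair operators make tie-breaks deterministic: positions are sorted and
  minimally spaced, so any chromosome decodes to a valid geometry and
  equal-by-symmetry duplicates are reduced.
* `design_field` is a floor, not a target: if the constraint set cannot
  reach it, the penalty dominates and the optimizer maximizes field —
  degenerate inputs fail loudly in the pre-optimization feasibility check.
* The homogeneity numbers quoted for optimized designs are grid quantities
  (515 points); continuum peak-to-peak is slightly larger.  The measured
  maps of a physical build include higher-order and asymmetric terms the
  degree-1–2 synthetic generator does not produce, so passing shim tests
  bound smooth-error performance only.
* The magnetostatic model is linear: no demagnetization of neighbors, no
  temperature coefficient of $B_r$.  Both matter at the percent level in
  real arrays and are out of scope.
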