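---
title: "Analysing water structure and dynamics from periodic MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing water structure and dynamics from periodic MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquatraj)
```

aquatraj computes the standard observables used to characterise liquid water
from molecular-dynamics trajectories in cubic periodic boxes: radial
distribution functions and coordination numbers, hydrogen-bond counts under a
smoothed geometric criterion, self-diffusion coefficients with the
hydrodynamic finite-size correction, orientational relaxation times, and the
equilibrium density from energy--volume scans. It also provides a reversible
multiple-time-step integrator and a family of synthetic-trajectory
generators whose statistics are known in closed form, so that every analysis
stage can be validated end to end without any electronic-structure engine.

This vignette explains the models behind each stage, the parameters that
matter, and the numerical decisions taken where the design was genuinely
open.

## Containers, units, and periodic geometry

All coordinates are held in Angstrom and all times in picoseconds;
conversions (Bohr for CPMD-style `TRAJECTORY` files, atomic time units for
the integrator's conventional inner step) are applied exactly once, at the
I/O boundary. Neither the XYZ nor the TRAJECTORY dialect stores the box edge
or the frame spacing, so both are supplied by the caller.

The minimum-image convention maps every displacement component into
`(-L/2, L/2]`; the tie at exactly `L/2` is deterministically resolved to the
positive side. Water topology is assigned geometrically: each hydrogen is
attached to its minimum-image-nearest oxygen, and the assignment must
satisfy the water invariants (exactly two hydrogens per oxygen, every
covalent O--H distance below a configurable bound). The default bound of
1.25 Å accommodates stretched bonds from ab initio dynamics while safely
rejecting hydrogen-bond partners, which sit near 1.7--2 Å. Deuterium is a
mass label only; all geometric analysis is identical.

Trajectories are assumed wrapped on input. An explicit unwrap pass
reconstructs continuous coordinates by accumulating minimum-image
displacements between consecutive frames, which is valid while no atom moves
L/2 or more between saved frames. Because a wrapped jump larger than L/2 is
indistinguishable from a small step after minimum-imaging, the unwrapper
enforces a plausibility bound instead: any per-component displacement above
`max_jump` (default L/4) is an error. Genuine face crossings produce
sub-Angstrom minimum-image steps and pass untouched; corrupted or
undersampled data trip the bound.

## Radial distribution functions and coordination numbers

`compute_rdf()` histograms minimum-image pair distances (default bin width
0.01 Å) and normalises each bin by the ideal-gas expectation for the same
pair counts and box volume: `N(N-1)/2` unordered pairs for a same-species
RDF, `N_A N_B` for O--H. This makes the ideal-gas limit exactly 1, which the
test suite verifies against uniform random configurations. Only complete
bins are kept (a trailing partial bin cannot fill its shell volume and would
bias g low), and the histogram never extends beyond L/2, where the minimum
image stops being valid. Intramolecular O--H and H--H pairs are included by
default — matching experimental O--H curves with their covalent peak — with
an exclusion switch.

First-shell descriptors (position and height of the first maximum and first
minimum) are read off a cubic-spline interpolant of the binned curve:
discrete extrema bracket the root of the spline's analytic derivative, which
is then refined by bisection. Candidate maxima must rise at least 5% of the
curve's range above its minimum; this rejects sub-epsilon floating-point
plateaus and baseline ripple without affecting genuine peaks. The cutoff
`r_c` for coordination integrals is located the same way on the actual
integrand r²g(r). Note a small but systematic geometric fact the tests pin
down: at the minimum of r²g the slope of g is `-2g/r < 0`, so `r_c` always
sits slightly *before* the minimum of g itself.

The coordination number integrates `4 pi rho r^2 g(r)` up to `r_c` under
three cutoff conventions: the first minimum of r²g (the convention used when
comparing with diffraction experiments), the first minimum of g, or a fixed
cutoff. Integration is performed exactly on the binned histogram using the
true shell volume of each bin (a partial last bin enters in r³ proportion);
a spline-based integration is available as an option and differs negligibly
on smooth curves, but the histogram form has the advantage of reproducing
discrete neighbour counts exactly — on the proton-disordered cubic-ice
lattice all three conventions return precisely 4. By default the integral
uses the finite-N partner density `(N-1)/V`, which is what makes neighbour
counts exact; the bulk density `N/V` can be passed explicitly for the
textbook formula (the difference is 1/N).

Because simulations equilibrate at slightly different temperatures,
first-peak descriptors can be rescaled to a common 298 K reference:
`value - fit(T_sim) + fit(298)`, with `fit` a least-squares polynomial
through a user-supplied reference table of descriptor values versus
temperature. The fit degree defaults to 1 (the curvature of these
descriptors over a ±30 K window is below typical simulation noise) and is
exposed as a parameter. The package ships a synthetic example table that
documents the file format; it is generated data, not digitised experimental
values, and users comparing against experiment must supply their own table.

## The smoothed hydrogen-bond criterion

A hydrogen bond between a donor molecule (oxygen O_d, covalent hydrogen H)
and an acceptor oxygen O_a is detected from the product of two smoothed
rectangle functions: one evaluated on the O_d--O_a distance and one on the
path-length excess

d' = |O_dH| + |HO_a| - |O_dO_a|,

the triangle-inequality slack, which is zero exactly when H lies on the
donor--acceptor axis and grows as the donor O--H direction tilts away. A
bond is counted when the product exceeds 0.5.

Each switching function is the rational form

f(d) = (1 - X^n) / (1 - X^m),  X = ((d - d0) / delta)^2,

which equals 1 at the centre `d0`, is symmetric about it (the squared
reduced distance enforces the symmetry for any exponents), passes through
the removable singularity value `n/m` at `|d - d0| = delta`, and decays
monotonically to zero outside. The defaults are `d0 = 2.8` Å,
`delta = 0.45` Å, `n/m = 10/16` for the distance switch — a window covering
the 2.4--3.4 Å first coordination shell of liquid water, centred on the
first O--O peak — and `d0 = 0`, `delta = 0.4` Å, `n/m = 4/8` for the
path-excess switch, which is 1 at 0 Å and decays rapidly to zero once the
excess exceeds about 0.5 Å (f(0.5 Å) ≈ 0.14, f(0.6 Å) ≈ 0.038). The
squared-argument form was adopted over the plain reduced distance
`x = (d - d0)/delta` precisely because the plain form with the 4/8
exponents decays far too slowly to honour that anchor (it still sits at
0.165 at 0.6 Å); with both forms the edge value `n/m` and all window
properties coincide. The results are insensitive to moderate changes of the
exponents, and all four parameters plus the threshold are exposed.

Counting credits each realised (H, acceptor O) pair once; a molecule can
donate at most two bonds and accept without an imposed cap (physically at
most two in practice). The per-molecule count credits each bond to both
partners, so perfect tetrahedral ice gives exactly 4 bonds per molecule —
the package's ice generator satisfies the Bernal--Fowler rules by
construction (two covalent hydrogens per oxygen, one hydrogen per O--O
link), and the smoothed criterion agrees exactly on it with the conventional
distance-plus-angle criterion (O--O < 3.5 Å and bond tilt < 30 degrees),
which is also provided. Acceptor candidates are prescreened by the O--O
distance at `d0 + 2 delta`, beyond which the distance switch cannot reach
the threshold; at the 32--64-molecule scale of ab initio boxes this
distance-matrix prescreen is faster than a cell list would be, and the
brute-force double loop is retained (and tested for exact agreement) as the
oracle.

The angular distribution P(β) histograms the angle at the donor oxygen
between O_d→H and O_d→O_a over all pairs in the first shell
(donor--acceptor distance < 3.4 Å, hydrogen--acceptor distance < 2.5 Å),
normalised to unit integral over degrees on a 0--90° grid. The
complementary hydrogen-centred angle α = 180° − ∠(O_d–H–O_a) is reported
alongside on the same grid.

## Translational dynamics

The mean-squared displacement uses oxygen positions by default (molecular
centres of mass are available) on an unwrapped trajectory, averaged over
molecules and all time origins. With unit origin stride the multi-origin
average is evaluated exactly by an FFT-based correlation algorithm
(O(T log T) per coordinate); larger strides use the direct sum. Both paths
are tested against a naive triple loop.

The diffusion coefficient is the fitted MSD slope divided by 6. The fit
window matters statistically: at lag k, roughly T/k independent origin
blocks remain, so the estimator variance grows linearly with lag. The
package default window is the central 25--75% of the available lags (with
lags extending to half the trajectory); for quantitative recovery work the
tests and the acceptance script instead fit lags of 0.5--2.5 ps out of a
20 ps trajectory, where origin statistics are dense — with 64 molecules and
2000 frames this recovers a known diffusion constant to about 1--2%.
Results are reported in both Å²/ps and 10⁻⁹ m²/s (factor 10).

A coefficient measured in a cubic box of edge L is depressed by the
periodic hydrodynamic self-interaction; the infinite-size limit is

D_inf = D_L + xi k_B T / (6 pi eta L),

with `xi = 2.837297` the dimensionless cubic-lattice constant and `eta` the
shear viscosity (in practice the experimental value; the correction is only
logarithmically sensitive to it). The package recomputes `xi` from scratch
by Ewald summation of a unit point charge in a periodic unit cube with
neutralising background (`ewald_self_constant()`), and the acceptance suite
checks the printed six-figure value. The exact inverse map
(`rescale_exp_to_box()`) converts an experimental infinite-size coefficient
to the hypothetical value for a finite box, which is the cleaner direction
for comparing simulations with experiment when the simulated viscosity is
unknown.

## Orientational dynamics

The orientational autocorrelation functions are
`C_n(t) = <P_n(u(t0+t) . u(t0))>` for Legendre orders 1 and 2, with the
molecular axis u either an O--H bond (both bonds pooled, doubling the
statistics), the H--H direction, or the H--O--H bisector. The bisector is
used as the geometric proxy for the dipole direction — geometry alone
carries no charges, and for a rigid symmetric monomer the two coincide.
Axis vectors are built with minimum-image intramolecular differences, so
wrapped trajectories need no preprocessing. The origin average is again
evaluated exactly with FFTs; for order 2 this uses the six independent
components of the outer product u uᵀ, since (u·u')² is their correlation
sum.

Relaxation times come from a least-squares fit of `A exp(-t/tau)` on
`log C` over a window that starts, for liquid water, after the
sub-picosecond librational decay (default 1 ps, configurable — the
synthetic rotors have no librational regime and are fitted from 0.2 ps) and
ends where C first drops below a floor. The floor defaults to 0.05; for
quantitative recovery the tests raise it to 0.2, because the logarithm
amplifies the statistical noise of the tail and biases the fit. An optional
nonlinear refinement on the linear scale is available. For isotropic
rotational diffusion with constant D_r the closed forms are
`tau_n = 1/(n(n+1) D_r)`; the rotor generator reproduces `tau_2 = 1/(6 D_r)`
to within a few percent and the ratio `tau_1/tau_2 = 3` at the study scale
(64 rotors, 40 ps). A relaxation time is only trustworthy when the
trajectory spans roughly three times its value; shorter fits are flagged
and warned about rather than refused.

## Equilibrium density from volume scans

The equilibrium density is estimated by scanning box volumes around
trajectory snapshots: molecular centres of mass are rescaled with the box
edge while intramolecular geometry is held rigid (molecules are made whole
across periodic faces first), a pluggable energy backend evaluates each
scaled configuration, and the minimum of the interpolated E(V) gives the
snapshot's equilibrium volume. Defaults: 7 scan points spanning ±6% in
volume, 30 snapshots 0.2 ps apart; the density follows from the
snapshot-averaged volume as `n M / (N_A V)`. The scan range and point count
are exposed since different backends have different stiffness.

E(V) interpolation uses a cubic spline through the scan points (the "fmm"
end conditions reproduce polynomials up to cubics exactly, so a quadratic
backend is recovered to machine precision) with the minimum refined on the
spline's analytic derivative; three-point scans fall back to the exact
parabola vertex. A minimum at the scan boundary is reported with a
"minimum not bracketed" warning rather than trusted. The estimate is
invariant under additive shifts and positive scalings of the backend, which
the tests assert. Energy backends are plain R functions
`(frame, volume) -> energy`; the analytic quadratic backend serves as
ground truth in the tests, and users can wire an external engine behind the
same contract. The 64-molecule box at 12.445 Å edge corresponds to
0.993 g/cm³ — the "about 1 g/cm³" correspondence the acceptance suite
checks. The molar mass defaults to H₂O (18.015 g/mol) with D₂O available,
since deuterated simulations are conventionally quoted at the light-water
density.

## Multiple-time-step integration

`respa_propagate()` implements impulse (kick) r-RESPA force splitting: the
slow correction `F_target - F_inner` is applied as symmetric half-kicks at
the outer-step boundaries, with velocity-Verlet integration of the fast
inner forces at `dt_inner` in between. The symmetric variant was chosen over
a one-sided full kick because it is symplectic and time-reversible, which
the tests verify directly (forward propagation, velocity negation, backward
propagation returns the initial state to 1e-8). With a time-step ratio of 1
the scheme reduces exactly — not just to truncation order — to velocity
Verlet on the target forces, including when the inner and target providers
differ, because the two half-kicks then sum to the full target impulse.
Force providers are plain functions returning forces (and optionally a
potential energy, enabling the drift diagnostics); the conventional inner
time step of 15 atomic time units is 15 × `aq_constants$au_time_to_ps`
≈ 0.000363 ps. Energy-conservation diagnostics report the least-squares
drift rate and the maximal deviation; on a harmonic oscillator at one
hundred steps per period the relative secular drift over 10⁵ steps is below
10⁻⁶, and the drift grows monotonically with the time-step ratio when the
inner force is a poor approximation — the quantitative basis for choosing
the ratio "large enough but not larger". Only NVE propagation is provided;
thermostatting belongs to equilibration protocols, not to the propagation
contract.

## What the synthetic generators do and do not emulate

The generators provide *statistical* ground truth, not physical water:

* `brownian_com_trajectory()` — independent Gaussian walks of rigid
  monomers (per-axis step variance 2 D dt), started on a grid so the first
  frame has unambiguous topology. It validates unwrapping and the entire
  MSD/diffusion chain, but has no interactions, no hydrodynamics, and no
  ballistic-to-diffusive crossover.
* `rotor_trajectory()` — isotropic rotational diffusion composed from
  exponential-map rotations (exactly unit-norm orientations, correct
  small-step limit), anchored on a grid. It validates the ACF/relaxation
  chain; real water shows librational decay and anisotropy it does not.
* `make_tetrahedral_ice()` — a proton-disordered cubic-ice (diamond)
  lattice satisfying the Bernal--Fowler rules, built by random assignment
  repaired with single-bond Monte-Carlo flips on the bond-occupancy graph
  (accepting equal-energy moves with probability 1/2 to leave plateaus);
  hydrogens sit exactly on the O--O axes. It pins down H-bond counting,
  coordination numbers, and angular distributions at their ideal values.
* `ideal_gas_trajectory()` — uniform independent placements, the null model
  for RDF normalisation.
* `dimer_frame()` — two waters with controlled O--O distance and donor
  tilt, for hand-checkable switch values and angles.
* `quadratic_EV_backend()` — an analytic E(V) with a known minimum.

Consequently, green tests demonstrate that the estimators are correct and
well-calibrated on processes with known answers; they do not certify
accuracy on real water trajectories, where finite sampling, anisotropy and
cross-correlations enter. The default generator parameters are the study
conditions used throughout the tests: 64 molecules in a 12.445 Å box
(0.993 g/cm³), 2000 frames at 0.01 ps for diffusion (D = 0.23 Å²/ps, a
liquid-water-like value), 2000 frames at 0.02 ps for rotation
(D_r = 0.05 ps⁻¹, so tau_2 ≈ 3.3 ps), and a 2×2×2-cell ice lattice
(64 molecules) at a_OO = 2.75 Å. These sizes keep the full suite around a
quarter of a minute while holding estimator errors in the low percent
range.

## Orchestration

`run_analysis()` executes the requested stages (structure, hydrogen
bonding, diffusion, orientational relaxation, density) in dependency order
from a single declarative config — an R list or YAML file — with per-stage
parameter overrides, one master seed, deterministic reruns, and per-stage
failure isolation (a failed stage is recorded; the others proceed). Curves
are written as two-column text, counts as CSV, and the summary as a
tab-separated table with units. Result objects are tibble-backed with
`tidy()`, `glance()` and `autoplot()` methods, so pipelines compose with
the usual tidyverse verbs; a thin command-line wrapper over the same
functions ships in `inst/exec/aquatraj-cli.R`.

## Known limitations

Only cubic boxes and three-site water are supported; there are no
PDB/DCD/TRR readers, no velocity-based observables (e.g. vibrational
spectra), no H-bond kinetics, no Green--Kubo viscosity, and no
thermostats. The RDF pair loop is O(N²) per frame — appropriate for the
32--216-molecule systems this package targets, not for large droplets. The
298 K rescaling is as good as the user's reference table, and the density
stage is as good as the energy backend wired into it.
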