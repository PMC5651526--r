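---
title: "Methods: reduced-dimension conjugate heat transfer for intravascular waste-heat exchangers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-dimension conjugate heat transfer for intravascular waste-heat exchangers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fully implantable power sources for mechanical circulatory support (total
artificial hearts, ~64 W of waste heat; left ventricular assist devices,
~24 W) must dump their waste heat into the body without cooking the tissue
around them.  The candidate heat sink is the blood flowing through the
descending aorta: a heat exchanger — a titanium conduit embedded in an
aluminum housing that also holds the source — replaces a 10 cm segment of
the vessel, and the bloodstream distributes the heat over the whole body.
The engineering question is local: how hot do the blood-contacting
surfaces and the thermal boundary layer get, and what heat dose do
platelets and red blood cells accumulate while transiting the device?
Three designs are compared: a plain conduit (*base*), the conduit with
intraluminal fins (*fins*), and fins plus a copper *heat guide* that
routes heat around to the far side of the vessel (*finsguide*).

`hemotherm` implements this analysis at desk scale.  The full 3-D aortic
arch with branches and tetrahedral finite elements is out of scope by
design; what is retained is every governing equation (continuity, reduced
momentum, conjugate energy, Lagrangian drag transport), the printed device
dimensions, powers and material data, and the derived statistics (wall
temperature profiles, blood heat flux, outlet statistics, Thermal
Exposure Index).

## Geometric reduction

Two surrogates replace the 3-D geometry:

* **Axisymmetric pipe** (default for the base designs): blood in a
  straight pipe of radius 1.1 cm (the tapered 2.5 to 2.0 cm descending
  aorta is idealised to a constant 2.2 cm diameter, configurable), with
  the titanium wall (0.15 cm) and the 3.1 cm aluminum conductor as
  annular layers over the 10 cm exchanger window of a 23 cm domain.  This
  surrogate smears the source azimuthally; it captures the streamwise
  physics and the global energy balance exactly, so it is used for
  energy-conservation analyses.

* **Planar channel** (default for the fins designs, optional for the base
  designs): a channel of height 2.2 cm with *independent* near-side
  (source side) and far-side solid blocks.  It carries the full
  descending-aorta flow and the full source power by assigning an
  effective out-of-plane depth of half the mean lumen perimeter
  (pi D / 2 = 3.46 cm) per side, which preserves the mixed-temperature
  rise `P0/(rho_b c_p Qbar)` — the quantity controlling systemic heating.
  This surrogate exposes the near/far asymmetry of the real device (the
  side nearer the source takes most of the heat load), so near-side
  interface statistics and cross-design comparisons are run in this mode.

The source is a cylinder (4.6 cm diameter at 64 W, 2.8 cm at 24 W, 1 cm
height) standing on the near side with its axis normal to the vessel.
Its axial footprint along the vessel is therefore its *diameter*, centred
at 50% of the exchanger length, and its emitting surface sits inside the
aluminum housing.  The surrogate injects the power on an internal face
band at a standoff depth of 0.8 cm from the lumen — consistent with the
fins+guide stack (0.15 cm titanium wall, 0.15 cm guide standoff, 0.25 cm
copper, 0.25 cm source standoff).  The mapped face fluxes are normalised
to integrate to exactly the source power, so the reduction never loses or
invents energy.  The lateral-cylinder area `pi d h` (end caps excluded,
configurable) defines the physical surface flux `P0/A` reported by
`source_flux()`.

**Fins.**  The two perpendicular 2 mm full-length titanium fins become a
single 2 mm mid-channel splitter spanning the exchanger, the planar
analog of one fin per symmetry half-plane.  The splitter splits the flow
into two sub-channels sharing one axial pressure gradient, doubles the
wall shear of each passage, and adds regenerator surface.  Titanium
conducts poorly (k = 7.5 W/m/K), so conduction along the fin from the
wall into the core is negligible (~0.3 W/K for the whole fin) and no
out-of-plane fin-root coupling is modelled.

**Heat guide.**  The 0.25 cm copper sheet appears as copper layers in the
near and far blocks (0.15 cm from the lumen on the far side, 0.25 cm
behind the source on the near side, 1 cm uncovered margins at both
exchanger ends) plus an out-of-plane *wrap conductance* per axial cell,
`G = k_Cu t_Cu dx / (pi D)`, linking the near and far copper at the same
axial station.  This is the reduced representation of the sheet wrapping
around the conduit; it is what routes a third of the source power to the
far side and is the mechanism behind the guide's lower peak temperatures.

## Blood rheology and flow

Blood is incompressible and shear-thinning with the standard
Carreau-Yasuda law

    mu(g) = mu_inf + (mu0 - mu_inf) [1 + (lambda g)^a]^((n-1)/a)

with mu0 = 0.16 Pa s, mu_inf = 0.0035 Pa s, lambda = 8.2 s, n = 0.2128,
a = 0.64, rho_b = 1050 kg/m^3.  The exchanger section is a straight
conduit, so the flow is fully developed, `u = u(y, t) x_hat`; the
convective term vanishes identically and momentum reduces to

    rho_b du/dt = g(t) + d/dy( mu(|du/dy|) du/dy )

with the cylindrical metric in pipe mode.  The shear rate fed to the law
is the single nonzero strain component |du/dy|.  The pressure gradient
`g(t)` is not prescribed: each implicit step solves a two-column
tridiagonal system (zero-gradient and unit-gradient solutions) and picks
`g` as the scalar that matches the instantaneous flow rate to the
waveform — the reduced form of the continuity constraint, exact to linear
algebra.  The outlet pressure waveform of the original model is not
represented at all: in a rigid, incompressible vessel it only sets the
absolute pressure level and cannot affect velocity or temperature.

Time integration is fixed-step BDF2 (backward Euler startup) at 2.5 ms,
inside the 1e-8 to 1e-2 s adaptive-step range of the reference
procedure; both schemes are unconditionally stable, so adaptivity buys
nothing at this scale.  One to two Picard sweeps per step update the
lagged viscosity.  Cycles repeat until the saved profiles are periodic
(max change below 1e-5 m/s).  Against the Womersley closed form at
alpha ~ 15 (the physiological regime for R = 1.1 cm at 1 Hz) the solver
is accurate to ~0.1% RMS of peak velocity.

## Synthetic inlet waveform

The reference inflow exists only as a figure, so the generator
`make_inlet_waveform()` states the world instead of digitising it:

* period 1.0 s (the reference reports intra-cycle times of 0.3 s and 1 s,
  consistent with a 1 s cycle; configurable);
* mean inlet flow 5.0 L/min scaled by a descending-aorta fraction of 0.7
  (no numeric flow split is printed; the value is a standard resting
  estimate of the fraction not taken by the arch branches, it is exposed
  in the config and recorded in every manifest);
* systolic peak at 4x the mean (raised-Gaussian lobe), an early-diastolic
  reverse lobe at 5% of the systolic amplitude, and seeded zero-mean
  residual harmonics at the 1% level.

The sample mean and the peak/mean ratio are enforced exactly; the
generator is a pure function of its arguments (an internal Lehmer
generator decouples it from R's global RNG).  What a green test on this
waveform does *not* establish: agreement with any patient's waveform, or
sensitivity of the thermal results to waveform shape beyond mean and
pulsatility.

## Conjugate energy transport

One energy equation covers blood and solids,

    rho_i c_pi dT/dt + rho_b c_pb u dT/dx (blood only) = div(k_i grad T),

discretised finite-volume: first-order upwind for the axial advection,
central differences with harmonic-mean face conductivities for diffusion
(exactly conservative across the fluid-solid interfaces), backward Euler
on the 1e-2 s output cadence.  External boundaries are insulated (the
perfect-insulation assumption: every watt ends up in the blood), the
inlet is fixed at 37 C, the outlet is a zero-diffusive-flux advective
outflow; reverse flow through either end advects 37 C fluid back in.

The transverse fluid mesh is geometrically clustered to ~0.05 mm at every
wall: the Leveque thermal boundary layer at these Peclet numbers is a few
tenths of a millimetre and is where cells meet their peak temperatures.
The discretisation reproduces the developed-region Graetz Nusselt numbers
(48/11 pipe, 5.385 one-side-heated channel) within 2% and the transient
slab-conduction series solution within 1%.

**Two-step solve and periodic acceleration.**  The solid blocks hold
kilojoules per kelvin while the blood removes tens of watts: their
thermal time constant is hundreds of cardiac cycles, which is why the
analysis first solves the steady problem at the mean flow and then
transients to the periodic state.  Plain cycling still relaxes the
residual solid-storage mode with ratio ~0.995 per cycle, which would bias
any cycle-averaged energy balance for hundreds of cycles.
`solve_transient_temp()` therefore applies Anderson acceleration
(depth 4) to the end-of-cycle fixed point — for this linear cycle map it
acts like GMRES and converges in ~15-20 cycles.  Convergence requires
both the cell-wise periodicity residual (default 0.02 C) *and* a
heat-storage drift below 0.5% of the source power, so a reported energy
balance is meaningful.  The acceleration changes the discrete fixed
point's approach path, not the fixed point; the saved field window is
always re-integrated as genuine cycles from the converged state.

## Cell tracking and TEI

Platelets (3 um) and red blood cells (7 um), both at 1050 kg/m^3, obey
drag-only dynamics `dv/dt = (u - v)/tau_p` with
`tau_p = rho_p d_p^2 / (18 mu_b)`; the local Carreau-Yasuda viscosity is
used for `tau_p` by default (the reference formula does not state local
vs constant; constant mu_inf is selectable).  tau_p ~ 1e-7 s is far
below the 1e-2 s step, so each step applies the *exact* exponential
update of the linear drag equation — no stiffness, no sub-stepping.  Wall
crossings reflect specularly at the crossing point, conserving speed to
machine precision.  Platelets seed with areal density proportional to the
cube of the distance from the vessel centre (margination; radial CDF
`(r/R)^5` in the pipe, `(d/(H/2))^4` in the channel — the areal-density
reading of the cubic law; the marginal-pdf reading is selectable), red
cells uniformly.  Cells release at the exchanger inlet at the start of
cycle 2 and are tracked through cycle 10 (nine analysed cycles): in the
exactly periodic surrogate the first cycle carries no initialisation
transient, so "discarding" it means releasing after it — the reading
forced by the sub-second minimum transits behind the population minima.

In the parallel-flow reduction the transverse fluid velocity is zero, so
cells ride streamlines at fixed transverse position; near-wall cells can
stay inside the domain for the whole horizon (`max_time` exit), exactly
the sub-population that accumulates the large heat doses.

The Thermal Exposure Index is the trapezoidal time-integral of the
sampled *absolute* temperature (s*degC).  Absolute, not excess-over-37:
the published population minima (~10 and ~7.4 s*degC) are only consistent
with absolute-temperature integration of sub-second transits.  Delta-t is
the saved 1e-2 s cadence, matching the reference output interval.  An
optional weighting function `w(T)` (identity default) exposes the
"weighted TEI" extension without inventing a specific weighting.
Threshold exposure reports accumulate time above each hyperthermia rule
(protein denaturation above 45 C, 6% hemolysis at 50 C x 1 h, platelet
aggregability loss at 43 C x 5 min, ...) and flag exceeded reference
exposures.

## Numerical choices and degenerate inputs

* Tie-break at zero advection (`u = 0` rows, e.g. the stagnant layer in
  line with the splitter outside the exchanger window): the upwind mass
  flux is zero and only diffusion acts.
* A flat interface profile (zero power) has no argmax; it is reported as
  `NULL`, not as an arbitrary location.
* `peak_ratio = 1` with no reverse lobe collapses the waveform generator
  to exactly constant flow.
* Steady solves on a fully insulated all-solid domain are singular and
  raise a configuration error instead of returning garbage.
* Newtonian degeneration (`mu0 = mu_inf`) is exact, used by every
  closed-form comparison.
* Temperatures are in degC throughout; the equations are shift-invariant
  so no Kelvin conversion is needed.  SI units everywhere else.
* Solid densities (Al 2700, Ti 4506, Cu 8960 kg/m^3) are handbook values
  absent from the printed tables; steady results are independent of them
  and they are overridable.

## What the surrogate does and does not establish

Green tests establish: exact global energy conservation at the periodic
state; the printed constitutive asymptotes; a near-side interface peak
downstream of the source centre at the printed fraction of exchanger
length within the documented scaled-down tolerance; supra-physiological
near-wall temperatures in the 64 W base design; the design ordering
(base hotter than fins hotter than fins+guide) in both peak interface
temperature and maximum TEI; and agreement of every transport kernel
with its closed-form oracle.

Known limitations, stated rather than patched:

* The parallel-flow reduction cannot shed vortices.  The 3-D fins owe
  much of their published cooling (a >8 C drop in maximum cell-sampled
  temperature) to stagnation-point and vortex-shedding mixing; the
  surrogate recovers the effect only through flow splitting and
  regenerator surface, at roughly half the printed magnitude.  The
  corresponding acceptance bound is left failing by design rather than
  recovered with an invented eddy-diffusivity dial.
* The steep temperature gradient at the exchanger distal end is an
  insulation-discontinuity artefact whose magnitude is mesh-dependent;
  it is reproduced qualitatively only.
* Absolute peak temperatures in the planar surrogate run hotter than the
  3-D reference (the near-side flux concentrates on less area than the
  real annular interface); bounds of the form "exceeds X" are
  meaningful, point values of the peak are surrogate-scaled.
* Heat leakage to perivascular tissue, neovascularisation response,
  temperature-dependent rheology, fluid-structure interaction and
  turbulence are out of scope.

## Reproducibility

Every stochastic ingredient (waveform harmonics, seeding) takes an
explicit seed; `run_pipeline()` derives per-stage child seeds from one
master seed and records them, with the config hash, in the run manifest.
Identical configurations produce byte-identical CSV outputs.
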