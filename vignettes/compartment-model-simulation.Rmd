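---
title: "Compartment-model simulation of stirred-tank fermentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-model simulation of stirred-tank fermentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagcm)
```

## The modeling problem

Large stirred fermentors are not well mixed on the timescale of microbial
substrate uptake. A cell circulating through a 50–100 m³ vessel sees its
glucose supply switch between excess near the feed point and starvation
in remote zones every few seconds to minutes; this dynamic environment
shapes metabolism and, ultimately, yield. Spatially resolved simulation
of this interplay traditionally couples CFD with reaction models at a
computational cost of days per simulated hour. `lagcm` implements the
compartment-model (CM) alternative: the vessel becomes a network of tens
to hundreds of ideally mixed zones exchanging mass fluxes derived from a
resolved flow field, and the biomass becomes a population of stochastic
parcels. The loss of hydrodynamic detail buys three to four orders of
magnitude in speed while retaining the two quantities that matter for
scale-up reasoning: the extracellular gradient and the per-cell
("lifeline") view of it.

## Liquid phase: flux matrices and transport

Grid cells are clustered into homogeneous cylindrical bins
(`assign_compartments()`), and the signed convective mass fluxes of all
grid faces on each compartment interface are summed **per direction**:
`phi_c[i, j]` collects only the faces whose flux runs j→i, so opposing
currents across one interface are not cancelled. Turbulent dispersion is
modeled as a bidirectional interface flux per face,

  f_t,face = rho_l · A_face · sqrt(2 k_t,face / 3),

i.e. face area times the RMS velocity fluctuation of isotropic
turbulence. (Area times `2k/3` itself would have units of m⁴/s², not
kg/s; the square-root form is the dimensionally consistent reading and
matches established CM practice.) Both matrices keep minus the total
outflow on the diagonal, so every column sums to zero — conservation is
a structural property, checked to 1e-9 relative in the test suite, not a
calibration outcome.

Transport is mass-based throughout: concentrations are mol per kg broth,
fluxes kg/s, and residence times `tau_i = M_i / |phi_ii|` with
`M_i = rho_l V_i`. The broth is a single-phase Newtonian liquid of
constant density (1000 kg/m³ default), so mass and volume weighting
coincide; the mass basis keeps the equations consistent if a user
supplies a different density.

## Biomass phase: stochastic parcel tracking

Each parcel represents `Cx,p = Cx · rho_l V_T / Np` grams of biomass and
is an ideal flow-follower (micron-sized cells have negligible Stokes
numbers). Within a compartment, ideal mixing makes the escape process
Poisson with rate `1/tau_i`; over a step `dt` the parcel jumps with
probability `P_jump = 1 − exp(−dt/tau_i)`. A single uniform deviate psi
per parcel per step drives both decisions: the parcel jumps iff
`psi < P_jump`, and conditional on jumping the quantifier
`Q = (P_jump − psi)/P_jump` is uniform on (0, 1] and selects the first
neighbor whose cumulative flux probability `phi_ji/|phi_ii|` reaches Q.
Destination tables are ordered by ascending compartment index, and
parcel draws happen in a fixed parcel order, so runs are bit-reproducible
at a fixed seed.

Two properties of this scheme are verified statistically in the tests:
escape times are exponential (Kolmogorov–Smirnov at n = 10⁴, with escape
events attributed uniformly within their step, since at the grid points
the discrete-geometric and exponential CDFs coincide exactly), and
destination frequencies match the flux ratios (chi-square at n = 10⁵).
Because at most one jump per parcel happens per step, residence times
are biased long when `dt` is comparable to `tau_i`; the discrete-chain
mean is `dt/(1 − exp(−dt/tau))`, which the tests confirm together with
its disappearance as `dt → 0`. The mitigation is the step cap `dt_max`,
not multi-jump chaining.

## Coupling and integration

The coupled system (`Nc` liquid states plus `Np × Npool` intracellular
states, plus per-parcel biomass in fed-batch) is integrated with an
embedded Runge–Kutta 3(2) pair (Bogacki–Shampine) written in the
package. The choice is deliberate: parcel jumps must happen exactly once
per **accepted** step, with that step's actual `dt`; rejected trial
steps must consume no random numbers; and the jump pass changes the
right-hand side discontinuously, so the usual first-same-as-last stage
reuse is disabled whenever a post-step hook runs. Reaction sources are
recomputed inside every right-hand-side evaluation from the current
`Cs` and the current parcel assignment — continuous in the state,
piecewise-constant in the assignment. No special event handling is
applied at jump discontinuities; the error controller simply keeps
steps small where the source terms move fast.

Error control uses a mixed norm `abs_tol + rel_tol·|y|` with defaults
`rel_tol = 1e-3` and `abs_tol = 1e-9`; `abs_tol` matters only for
near-zero substrate states (Ks is of order 1e-5 mol/kg). Rate laws
evaluate at `max(Cs, 0)` while the ODE state itself is never clipped, so
the error estimator stays honest near washout. Two conservation
identities are integrated alongside the state (cumulative feed and
cumulative uptake); because they are linear combinations of the balance
equations, `Δ(tank substrate) = feed − uptake` holds to round-off at any
tolerance, and the audit is reported with every run.

One practical stability note: the explicit 3(2) pair has a bounded
stability region, so with very stiff relaxation (a single ideally mixed
chemostat relaxes in under a second) a large `dt_max` parks the
controller at the stability boundary and leaves a tolerance-sized
offset around the fixed point. Runs that must resolve a steady state to
better than the tolerance should cap `dt_max` within the relaxation
time; the chemostat acceptance run uses `dt_max = 0.25 s` for this
reason and reaches the analytic steady state to machine precision.

## The synthetic flow generator

The compartmentizer consumes a gridded flow field; resolved CFD
solutions for industrial vessels are rarely distributable, so the
package generates one. The axial–radial circulation is encoded as a
discrete stream function on grid nodes — a sum of signed Gaussian bumps,
two counter-rotating loops per Rushton impeller, each loop spanning the
zone between its impeller plane and the adjacent flow boundary (vessel
bottom, impeller midplane, liquid surface) — with a
boundary-vanishing envelope. Face fluxes are stream-function
differences, so every cell's balance telescopes to zero exactly; mass
closure is by construction, never by iterative correction. Azimuthal
fluxes (for `Nθ > 1`) are theta-uniform solid-body style and
individually divergence-free. Turbulent kinetic energy is a pair of
Gaussian peaks at the impeller planes over a positive floor.

Defaults are chosen once to be realistic for the default vessel (a
54.4 m³, Hl/T ≈ 2.6 tank with two Rushton impellers at 98 RPM): loop
strength equal to a Rushton pumping-number estimate
(Nq = 0.72 → ≈ 2.6 t/s per loop), kt peak `0.08·v_tip²`, floor
0.01 m²/s². With these values the tracer mixing time computed by the
package is around ninety seconds — the right order for vessels of this
size and aspect ratio — and the layout trends reproduce the expected
behavior of geometric CMs: too few radial divisions overestimate the
mixing time (under-resolved circulation), too few axial divisions
underestimate it (under-resolved axial resistance).

What the generator does **not** emulate: trailing-vortex structure,
baffle wakes, anisotropic turbulence, gas holdup, rheology. Passing the
test suite therefore shows the CM machinery is correct for a
mass-conserving, realistically structured flow — not that any specific
industrial vessel is reproduced. Externally derived fields (e.g.
CFD-exported) can be supplied through the documented CSV schema
(`read_flow_field()`) or as flux matrices (`read_flux_matrices()`).

## Mixing diagnostics

Two mixing-time definitions are implemented. The probe criterion takes
the **last** time the normalized probe signal leaves the ±5 % band (the
"time after which" it stays within); a brute-force scan oracle validates
the crossing search. The volumetric criterion uses the coefficient of
mixing — the volume-weighted coefficient of variation — with threshold
0.0283 (95 % homogeneity). For parcel-based mixing the raw CoM of the
parcel concentration field saturates at the multinomial statistical
floor, about `sqrt((Nc−1)/Np)` once mixed (≈ 1.24 at `Np = 100`,
`Nc = 156` — far above the threshold, which is then flagged
unreachable). `run_parcel_mixing()` therefore also reports a debiased
column: an unbiased estimator of the underlying field CoM² obtained by
subtracting each occupancy term's known multinomial counting variance.
The threshold and `tau95` always use the raw curve.

## Kinetics

**Black-box Monod.** `qs = qs_max·Cs/(Ks + Cs)` with the published
chemostat parameterization for *Penicillium chrysogenum*
(`qs_max = 1.6 mmol/gdw/h`, `Ks = 7.8 µmol/kg`, `Cx = 55 g/kg`) and a
constant feed of 1.23 g glucose/m³/s. For a single ideally mixed
compartment the steady state inverts analytically,
`Cs* = Ks·α/(1−α)` with `α = F/(rho_l·MW·Cx·qs_max)` ≈ 3.02 µmol/kg,
which anchors the chemostat acceptance check.

**Structured model.** The full multi-pool penicillin models in the
literature are not reproducible from their journal articles alone, so
the package ships a documented synthetic stand-in with the stated
structure: eight pools — four metabolic (glycolytic intermediates,
amino acids, storage, product precursor) following `dX/dt = S·r − µX`,
and four enzymatic (transporter `e_glc` = XE,11, amino-acid-,
product-synthesis- and maintenance enzymes) following zero-order
synthesis, first-order turnover, and growth dilution; ATP is handled
algebraically (no ATP state). Uptake is transporter-limited,
`qs = k11·XE,11·Cs/(Ks+Cs)`, with the two published uptake
parameterizations (TU-A: 1.13 mmol/gdw/h, 9.8 µmol/kg; TU-B:
1.6 mmol/gdw/h, 7.8 µmol/kg). Internal rate constants are chosen for
realistic timescale separation — the glycolytic pool turns over in
seconds, amino-acid and enzyme pools in hours, growth at ≈ 0.03 h⁻¹ in
chemostat conditions — and are all overridable (`pool_model(params=)`).
The model's purpose is to exercise the parcel-bound reaction framework
(fixed points, dilution limits, heterogeneity emergence), not to
reproduce any published production rate; users with a complete published
model can plug it in through the same contract. Growth dilutes enzymatic
pools exactly as metabolic ones — a documented choice where published
formulations differ.

**Protocol closures.** Chemostat mode fixes `Cx` and the transporter
pool and applies constant feed with no outflow term; steady state is
feed–uptake balance. Fed-batch mode keeps the total volume fixed (a
deliberate simplification retained from CM/CFD practice), grows
per-parcel biomass `dCx,p/dt = µ_p Cx,p`, lets the transporter pool
evolve, and samples the feed profile every 30 s piecewise-constant; no
particular published profile is claimed, a profile generator
(`feed_profile()`) is provided instead.

## Lifelines and regime analysis

Lifelines sample each tracked parcel's `qs/qs_max` on a uniform grid
(default 0.06 s) by linear interpolation within accepted steps, with the
parcel's pre-jump compartment attributed to the whole step. Samples are
classified Excess (> 0.95), Starvation (< 0.05), Limitation (between;
thresholds strict, so a ratio exactly at 0.95 is Limitation). Two
filters remove short, low-amplitude chatter before statistics: a
centered moving average over 0.36 s (7 samples at the default rate;
shrinking windows at the edges), and a fuzzy threshold band of ±0.01
implemented as hysteresis — Excess is entered only above 0.96 and left
only below 0.94, mirrored around 0.05 for Starvation. Hysteresis is one
of several defensible mechanisms for a fuzzy boundary; it is isolated in
`filter_lifeline()` so alternatives can be swapped. The filters can only
remove regime visits, never create them (property-tested).

Visit statistics are keyed by transition pattern — the flanking regimes
of each maximal run (LEL, LSL, ELE, ELS, SLE, SLS), with end-truncated
runs discarded — and regime fractions are averaged over 1800 s windows
(about twenty mixing times of the default tank) with a 2-standard-
deviation margin across windows, which absorbs the spurious
concentration oscillations induced by finite parcel numbers.

## Finite-parcel-number effects

Two systematic finite-`Np` effects are verified as sign properties. The
volumetric mean substrate concentration exceeds the Eulerian solution,
because uptake happens only in parcel-containing compartments and the
"empty" ones drift up; the offset shrinks monotonically as `Np` grows
(checked at 10², 10³, 10⁴ over a 900 s horizon with 300 s spin-up — a
shorter averaging window leaves the slow low-`Np` fluctuations
unaveraged). And the parcel-registered mean sits below the volumetric
mean, because parcels by definition reside where uptake is active.

## Numerical and degenerate-input conventions

* Single-compartment models are flagged "no transport": residence time
  undefined, jumps no-ops, mixing times identically zero.
* A multi-compartment model with a zero-outflow compartment is rejected
  (infinite residence time).
* Compartment divisions must divide the grid evenly, so no cell
  straddles an interface — this sidesteps the rugged-interface flux
  overestimation that plagues non-aligned compartment boundaries.
* Destination cumulative probabilities are forced to end exactly at 1,
  so the last neighbor absorbs round-off.
* Concentrations may transiently go slightly negative inside the
  integrator; rate evaluations clip at zero, the state is not modified.
* All text-file interfaces carry units in headers; indices are 1-based.

## Problem sizes and runtime

The test suite and the acceptance script run the base case at the
A26R6T1 layout (156 compartments on a 52×12×1 grid) with parcel counts
from 10² to 10⁵ and horizons of 60–2000 s; statistical checks use
10⁴–10⁵ samples. These sizes were chosen so the full verification cycle
completes in a few minutes on one core while leaving every statistical
test comfortably powered; all of them scale up linearly in `Np` and in
simulated time for production use.

## Known limitations

No gas phase, oxygen, CO₂, pH, heat, or rheology; one liquid species
exercised (glucose) though the data model carries `Nliq`; constant
liquid volume even in fed-batch; no parcel birth, death, or division;
geometric compartmentalization only (the tracker itself is
layout-agnostic — it consumes only volumes and flux matrices, so
phenomenological clusterings can be supplied externally); predictions
about population heterogeneity are hypotheses for experimental
follow-up, not validated forecasts.
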