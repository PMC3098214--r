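---
title: "Models, propagation schemes and numerical choices in brownsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, propagation schemes and numerical choices in brownsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brownsim)
```

brownsim simulates coarse-grained particles — proteins, colloids, polymers —
in an implicit solvent. This vignette explains the physical model, the two
propagation schemes, the fast hydrodynamics approximation, the open-boundary
machinery, and every numerical choice a user might want to question. It
states no empirical result that the package's tests or acceptance script do
not themselves compute.

## The particle model

A simulation contains *proteins*: units that are inserted or removed as a
whole. A protein owns one or more *gestalten*, the independently moving
rigid bodies, each tracking a position and a unit quaternion orientation.
A gestalt carries interaction shapes:

* **van-der-Waals spheres** — position in the gestalt frame, radius, and an
  integer *colour*. The colour pair of two spheres selects a short-range
  parameter set, so e.g. a sticky patch and an inert body can coexist on
  one particle.
* **point charges** — charge in units of e and a *burial depth* `b`: the
  stretch of the interaction path that runs through the counter-ion-free
  particle interior and is therefore exempt from Debye screening.
* at most one **hydrodynamic sphere** — radius and self-diffusion
  coefficient, entering the diffusion tensor when hydrodynamic
  interactions (HI) are on.
* the always-present **geometry spec** — translational and rotational
  diffusion coefficients, and an optional mass. The geometry spec is what
  turns accumulated forces into displacements.

Bonds connect gestalten of the same protein with
$U = \tfrac{k_2}{2}(d-L_0)^2 + \tfrac{k_4}{4}(d-L_0)^4$ in the hook-hook
distance $d$; hooks may sit off-center, in which case the bond force also
exerts a torque. External restraints (harmonic confinement, constant
force) attach to gestalt origins. Fixed *walls* — obstacle arrays, static
structures — carry vdW spheres and charges at absolute coordinates;
fixed-fixed interactions are never evaluated, so a step costs
$N_p(N_p-1)/2 + N_p N_o$ pair evaluations.

**Units.** Lengths in nm, times in ps, masses in kDa, charges in e, and all
energies in kT. The thermal energy itself is a config scalar with default
`bd_units()$kT` = 2.4361e-3 kDa nm²/ps², i.e. $k_B \cdot 293\,$K in this
unit system. That default makes the velocity relaxation time of a 20 kDa
bead with $D = 1.2\times10^{-4}$ nm²/ps equal to 0.99 ps, the standard
magnitude for coarse-grained protein beads. In kT-based forces the thermal
energy cancels from the Brownian update entirely; it enters only through
Langevin inertia ($\tau_{rel} = mD/kT$) and the Coulomb prefactor.

## Interactions

**Screened electrostatics.** Charges interact via
$U = \frac{C_e\,q_i q_k}{\varepsilon_r\, r}\, e^{-\kappa (r - B_{ik})}$,
$B_{ik} = b_i + b_k$, with $C_e = e^2/(4\pi\varepsilon_0 kT)$ evaluated
from physical constants at the configured thermal energy (so two unit
charges in water are at 1 kT exactly at the Bjerrum length, ~0.71 nm). The
buried stretch is unscreened because no counter ions penetrate the
particle interior. Cutoff: $r > B_{ik} + 5/\kappa$, where the screened
energy has fallen below ~1% of its contact value; with $\kappa = 0$ no
cutoff is applied.

**Short-range (vdW) interactions.** A Lennard-Jones 12-6 form in the
*surface-surface* distance $s = r - a_i - a_k$, reparameterised so the
minimum of depth $-\varepsilon$ sits at $s = \sigma$:
$U = \varepsilon[(\sigma/s)^{12} - 2(\sigma/s)^6]$. Pairs marked
repulsive-only keep the $s^{-12}$ branch. The default cutoff $3\sigma$
truncates the attractive tail below 0.2% of the well depth.

**Linearisation.** Below a per-pair threshold `r_lin` the force is held
constant and the energy continued linearly — the diverging core cannot be
integrated explicitly. The threshold is a numerical-stability device and
must be set so the capped displacement $D\,F(r_{lin})\,\Delta t$ stays at
a fraction of $\sigma$; the shipped study systems use values satisfying
$F(r_{lin})\, D\, \Delta t \lesssim \sigma/4$. In every shipped parameter
set the modified region lies above ~20 kT, thermally unreachable, so
equilibrium observables are unaffected. (With the former default
$r_{lin} = \sigma/2$ and large $D\Delta t$, rare contacts on the
still-exact part of the ramp received multi-nm displacements in a single
step — bounded-looking trajectories with occasional "catapult" events.
The threshold rule removes them.)

## Propagation

Each step: accumulators are zeroed; all pair, bond and external forces and
torques are evaluated (minimum-image across periodic axes); if HI is on
the TEA machinery corrects the deterministic forces and correlates the
random displacements; every gestalt advances; boundaries and interfaces
apply; a frame is recorded at the output stride.

**Brownian (BD).** Massless gestalten use
$\Delta x = D F \Delta t + R$ with raw $R \sim \mathcal N(0, 2D\Delta t)$
per component. The scheme is conceptually valid for
$\Delta t \gtrsim 10\,\tau_{rel}$; `simulation_config(propagation="bd")`
can force BD for massive gestalten and warns when that bound is violated.

**Langevin (LD).** Gestalten with a defined mass integrate the Langevin
equation analytically under a force held constant across the step:
$v(\Delta t) = v_0 e^{-\Delta t/\tau} + \frac{F}{\gamma}(1-e^{-\Delta t/\tau})$,
$\Delta x = \frac{F}{\gamma}\Delta t + \tau (v_0 - \frac{F}{\gamma})(1-e^{-\Delta t/\tau})$,
with the velocity carried between steps and the random displacement
entering as its equivalent force $\gamma R/\Delta t$. For
$\Delta t \gg \tau$ the exponentials vanish and the update reduces to BD
(the residual is exactly $\tau/\Delta t$). Both schemes may coexist in
one simulation; the scheme is selected per gestalt by the presence of a
mass.

**Rotation.** A world-frame rotation vector
$\omega = D_{rot} T \Delta t + \mathcal N(0, 2 D_{rot} \Delta t)$ per axis
is applied by quaternion composition and renormalised. This small-angle
update requires $D_{rot}\Delta t \ll 1$; configuration validation rejects
$D_{rot}\Delta t > 0.1$.

**Determinism.** All randomness flows through R's RNG, seeded once per
run, with draws in fixed gestalt order; the same seed and configuration
reproduce a trajectory bitwise. (A counter-based stream would offer the
same contract; R's global RNG is the idiomatic choice for an R package
and keeps user-level `set.seed()` semantics.)

**Spring-network stability.** The BD update multiplies a harmonic network
mode of Laplacian eigenvalue $\lambda$ by $1 - Dk\lambda\Delta t$;
stability requires $Dk\lambda\Delta t < 2$ with $\lambda \to 4$ for a
chain and up to twice the coordination number in general. This bound is
why the polymer study uses `polymer_timestep()` =
$0.2/(D(k_N + k_{2N}))$ — the historically used $\Delta t = 5\times10^{-4}$
at $k_N = 1000$, $D = 1$ sits exactly on the marginal point of the
stiffest chain mode, and any steric contribution tips it into bounded
ringing — and why the multi-bead lattice uses $k = 50$ kT/nm² at
$\Delta t = 5$ ps (coordination 12; and a much softer $k$ would let bond
fluctuations $\sqrt{kT/2k}$ reach the vdW core, whose force spikes leak
into the center-of-mass through the HI coupling).

## Fast hydrodynamics (TEA)

Hydrodynamic interactions enter through the Rotne-Prager-Yamakawa (RPY)
mobility tensor over all gestalten carrying a hydrodynamic sphere:
diagonal blocks $D_{ii} I$, far-field blocks for $r \ge a_i + a_k$ in the
unequal-radii form, and the regularised overlap form below contact (for
unequal radii the mean-radius working ansatz, exact for equal radii).
Hydrodynamically the walls and any gestalt without a hydro sphere are
invisible.

Deterministic forces are corrected as
$F_i^{eff} = \sum_k (D_{ik}/D_{ii}) F_k$. Correlating the *random*
displacements requires the tensor's square root; instead of an exact
(Cholesky) factorization the truncated expansion approximation (TEA)
uses normalised pairwise couplings:
$R_i = C_i\,(r_i + \beta \sum_{k\neq i} (D_{ik}/D_{kk})\, r_k)$.

The coefficients are computed per step (or per `tensor_stride`):

* $\epsilon$ — the mean coupling
  $\langle \mathrm{tr}(D_{ik}) / (3\sqrt{D_{ii} D_{kk}}) \rangle$ over
  particle pairs;
* $\beta$ — the root of $a\beta^2 + 2\beta - 1 = 0$,
  $a = \epsilon\,((N-2) - (N-1)\epsilon)$, taken continuous with
  $\beta \to 1/2$ as $\epsilon \to 0$ (the expansion is over the $N$
  hydrodynamic particles; if the quadratic loses its real root the code
  falls back to $\beta = 1$ with a warning);
* $C_i$ — per-coordinate normalisers from the actual tensor row, chosen
  so each particle's self-covariance stays exactly $2 D_{ii}\Delta t$
  ("temperature conservation" — the self-diffusion of the particles is a
  measure of their temperature and must not drift).

The particle-level convention above was selected because it reproduces
the two published accuracy anchors of the method — at most ~5% covariance
error for a dimer of touching spheres, and recovery of at least ~90% of
the exact pairwise correlations in dense many-sphere systems — which
`tea_accuracy()` recomputes against the exact Cholesky oracle
(`cholesky_correlate()`); a coordinate-level average (over all
$3N \times 3N$ off-diagonals) misses the dimer bound by a factor of 2-3
and was rejected. Everything is evaluated streaming over temporary
two-body blocks in $O(N^2)$; the dense tensor is materialised only for
the oracle and the accuracy reports. With LD, the HI corrections are
applied to the average forces that would produce the same displacements
in the BD picture, then fed through the inertial update.

## Boundaries and open interfaces

Axes are independently unbounded, periodic (minimum-image interactions,
coordinates wrapped to $[0, L)$, unwrapped copies recorded for analysis),
reflecting (specular fold, velocity component flipped for LD), or *open*.
An open axis carries constant-density interfaces: particles of the
exchanged species crossing the plane are removed and counted, and new
ones are injected at the one-sided thermal flux of an infinite reservoir,
$\nu = \rho A \sqrt{D \Delta t / \pi}$ per step, with depths drawn from
the one-step crossing profile (length-biased Rayleigh step times a
uniform fraction — validated against a brute-force half-space hop in the
tests) and uniform lateral positions. Species without an interface on a
crossed plane reflect there, which is how immobile-at-the-reservoir
crowders would be handled.

Two implementation details matter. First, removal on *endpoint* crossing
(not a perfect continuous absorber) is what makes the scheme detailed-
balance-consistent: the discrete walk has a Milne-type extrapolation
length of roughly $0.58\sqrt{2D\Delta t}$, comparable to the injection
depths, and both ends of the bookkeeping must see the same boundary. The
test suite verifies that a box between two equal-density interfaces
equilibrates to the reservoir density within 5%. Second, insertions are
redrawn (bounded retries, deferring to the next step when exhausted) when
the new particle would overlap *any* vdW sphere — fixed or mobile —
beyond the pair's linearisation threshold: dropping a sphere inside an
existing repulsive core would discharge the capped contact force as one
violent unphysical kick. Since that depth costs thousands of kT, the
redraw criterion coincides with thermal-equilibrium exclusion.

## Analysis

* `msd_curve()` — overlapping-window time average plus ensemble average
  over equivalent traces, on unwrapped coordinates; `fit_long_time_D()`
  fits a window of the lag grid (default: the last decade of lags, the
  generic long-time regime). For the *center of mass* of an isolated
  particle the internal modes cancel (exactly, without HI) and the CoM is
  diffusive at every lag, so the no-HI scaling studies fit short lags
  where the time average is best conditioned
  (`diffusion_scaling_study(lags = 1:5)`); with HI the CoM retains a
  weak memory of the internal modes, so the HI studies fit lags beyond
  the spring relaxation times (the long-time regime the reported
  coefficients refer to).
* `rotational_relaxation()` — normalised orientation autocorrelation
  $\langle u(0)\!\cdot\!u(t)\rangle$ fitted single-exponentially from lag
  0 to the first crossing of $e^{-2}$ (the reported quantities are single
  correlation times); a correlation that never falls below $e^{-1}$ flags
  the fit unreliable, a frozen orientation returns $\tau = \infty$. For a
  rigid sphere $\tau_{rot} = 1/(2 D_{rot})$.
* `scaling_exponent()` — log-log least squares, exact on noiseless power
  laws.
* `transport_fit()` — straight line through the cumulative exit count
  after a burn-in (default: everything before the first absorption, the
  paper-style fill-up transient); slope $R_D$, x-intercept $T_D$.
* `build_network()` / `network_timeseries()` — one node per patch
  sphere, an undirected link for every (minimum-image) center distance
  strictly below the cutoff; per-frame cluster-size multisets, mean and
  maximal degree, number and mean size of non-trivial clusters. The
  strict inequality follows the stated criterion; whether the original
  analysis applied it at every output step is not documented, so the
  per-frame application here is an assumption.

## The four study generators

The generators are first-class, tested code; their defaults are the study
conditions, not tuning knobs.

1. **Constrained polymers** (`example_polymer_system()`): beads of radius
   and diffusion coefficient 1 (reduced units), $k_N = 1000$ springs of
   length 2.5 between neighbours, angle-confining next-neighbour springs
   of length 5 with $k_{2N}$ from 0.1 to 1000, repulsive exclusion
   ($\varepsilon = 1$ kT, $\sigma = 0.4$ — negligible at the rest gap,
   effectively hard below quarter-overlap), no bead rotation. Timestep
   from the stability rule above.
2. **HCP multi-bead proteins** (`example_hcp_system()`): 2 nm beads,
   $D_{bead} = 1.2\times10^{-4}$ nm²/ps, 5 nm springs to up to twelve
   direct neighbours; N = 4 (tetrahedral cell — the site selection that
   makes all six pairs nearest neighbours), 13, 39, 57 (complete shells
   around a central site; the analysed odd size mentioned once in the
   source material is treated as a typo for 13). Spring constant and
   timestep as derived above.
3. **Obstacle transport** (`example_transport_system()`): 30 nm channel
   with 20x20 nm² 2D-periodic cross-section, reservoir at
   $\rho_0 = 4\times10^{-4}$ nm⁻³ on one side, absorbing $\rho = 0$ on
   the other, 2 nm mobile spheres with $D = 10^{-4}$ nm²/ps, dt = 10 ps,
   started empty; optionally one or two 3x3 layers of fixed obstacle
   spheres, purely repulsive or with a 1 kT short-range attraction (the
   attraction strength is not documented in the source; 1 kT gives a
   clearly-binding but reversible well and a modest bound population,
   matching the reported resident-count increase under attraction). Two
   geometry remarks. First, the analytic steady state of the printed
   30x20x20 nm control geometry, $D A \rho_0 / L_x \approx
   5.3\times10^{-7}$ ps⁻¹ with ~2.4 particles resident, is a factor ~2
   below the reported control rate, whose printed cross-check is
   internally inconsistent; the control study reports what the stated
   geometry actually produces. Second, on a 20 nm cross-section radius-5
   obstacles on the 3x3 grid (6.67 nm spacing) would overlap each other
   and seal the layer, contradicting every reported obstacle rate —
   whereas the reported impermeability threshold $A_o = 7.4$ nm equals
   the cell-center clearance $a/\sqrt2 - A_o = 2$ nm (the bead radius)
   exactly for $a = 40/3$ nm. The obstacle-array comparisons therefore
   use a 40x40 nm cross-section, which also reconciles the reported
   resident count (~20 $\approx \rho_0 \cdot 30{\cdot}40{\cdot}40$).
4. **Patchy-particle agglomeration** (`example_agglomeration_system()`):
   27 two-sphere particles (1.7 nm spheres at ±0.5 nm, patch colour vs
   body colour), patch-patch attraction 0.9 kT ("slightly below thermal
   energy", so complexes form transiently), everything else repulsive,
   transport coefficients of an equivalent 2 nm sphere, mass 18 kDa
   (LD), 30 nm periodic box, dt = 10 ps.

## What the generators do and do not emulate

The synthetic systems exercise every code path the analyses need —
flexible multi-gestalt mechanics, mixed BD/LD, HI on and off, open
boundaries, patchy association — under exactly known conditions, which is
what makes the quantitative checks (scaling exponents, reservoir
equilibration, covariance errors) possible at all. They do **not**
emulate real proteins: no rough surfaces or charge heterogeneity, perfect
spheres only, no rotational hydrodynamic coupling (out of scope), no
hydrodynamic coupling to walls, and the RPY far field underestimates
near-contact coupling. Passing tests therefore demonstrate correctness of
the algorithms under the model's assumptions, not predictive accuracy for
any particular biological system.

## Problem sizes

The shipped tests and the acceptance script run reduced-scale versions of
the studies: polymers N ≤ 15 at ~10⁵ steps and 2-3 seeds; HCP sizes up to
57 beads at ~3x10⁴ steps and 3 seeds; transport at 2x10⁶ steps of 10 ps
and 3 seeds; TEA accuracy on up to 50 spheres. These lengths were chosen
so each fitted quantity's sampling error is a few percent — small against
the tolerances being checked — while a full run of everything stays in
the tens of minutes on one core.

## Known limitations

* No divergence-term correction for the configuration dependence of the
  diffusion tensor (the plain RPY tensor is divergence-free; the TEA
  approximation to its square root is not exactly so).
* The constant-force LD step mildly under-thermalises velocities at
  $\Delta t \sim \tau_{rel}$ (equilibrium velocity variance low by
  $1 - \tfrac{2}{\theta}\tanh\tfrac{\theta}{2}$, under 2% at
  $\theta = 0.5$).
* Rotational RPY blocks, lubrication corrections, reactive interfaces
  and shear fields are out of scope.
* Injected particles start with zero velocity and identity orientation;
  for the isotropic injected species used here this is immaterial.
* `tensor_stride > 1` (freezing TEA coefficients across steps) is an
  undocumented-approximation escape hatch; the default recomputes every
  step.
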