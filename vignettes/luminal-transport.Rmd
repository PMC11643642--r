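---
title: "Modelling luminal flow and particle transport in contracting tubular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling luminal flow and particle transport in contracting tubular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubuleflow)
```

## The physical problem

The peripheral endoplasmic reticulum (ER) is a planar network of membrane
tubules of radius about 30 nm joined at three-way junctions, with tubule
lengths of order 1 um. Luminal proteins move through this network faster than
diffusion alone seems to allow, and transient constrictions ("pinches") of
the tubules have been proposed as the pump. `tubuleflow` implements an
in-silico model of this system: prescribed stochastic contraction kinematics
drive low-Reynolds-number luminal flows, solved instant by instant on the
network graph, and Brownian point particles are advected through the
resulting flow field. The same machinery also represents three alternative
flow generators — contracting tubular junctions, a perinuclear sheet
reservoir, and contracting peripheral sheets — so that their transport
signatures can be compared under identical observables.

The Reynolds number of these flows is of order `r signif(reynolds(1e-5, 1e-8, 1e-6), 1)`
(`reynolds(1e-5, 1e-8, 1e-6)`), so inertia is negligible and the flow is
quasi-steady: at every instant the fluxes are fully determined by the
instantaneous geometry and sources. This is what makes a network (Kirchhoff)
formulation exact within lubrication theory.

## Network geometry

A `tubular_network` is a connected planar graph with node coordinates (um),
a role per node, and a length and radius per edge. All lengths are in um,
times in s, volumes in um^3. Two built-in generators stand in for
microscopy-reconstructed networks, whose node coordinates are not publicly
available; reconstructed COS-7 networks are reported to have mean edge
lengths around 1 um and mean degrees close to 3, and transport results are
insensitive to the precise geometry at fixed edge-length and degree
statistics:

* `build_honeycomb(rows, cols)` — the idealised lattice: every interior node
  has degree 3 and every edge is exactly 1 um (by construction on an integer
  lattice). Boundary nodes are exit nodes.
* `generate_er_like_network(n_nodes, target, seed)` — a disc-clipped,
  jittered and edge-diluted honeycomb, rescaled so the mean edge length
  matches the target exactly. The dilution level is capped so the mean
  degree stays in [2.5, 3.5]. This generator reproduces the summary
  statistics of real networks (degree ~3, mean length ~1 um, planarity,
  connectivity) but not their long-range spatial irregularity or the
  broader edge-length tails of a real cell; conclusions that depend only on
  those summary statistics transfer, per-edge geometric detail does not.

Exit nodes model connections to a large reservoir at the network periphery:
they share a common pressure (taken as 0 — only differences matter) and
absorb whatever net volume the contractions inject. Their exact placement
does not influence transport provided there are enough of them; the package
defaults to all boundary (degree < 3) nodes.

## Pinch kinematics

Each tubule carries one pinch site at its midpoint. Pinching is a renewal
process per site: an event of duration 2T, then a wait, then the next event,
all independent across sites. The measured laws are the package defaults:

| quantity      | law                        | default                                  |
|---------------|----------------------------|------------------------------------------|
| duration 2T   | exponential                | rate ln(10)/0.167 /s (mean 0.0725 s)      |
| wait Twait    | exponential                | rate ln(10)/0.851 /s (mean 0.370 s)       |
| length 2L     | uniform                    | mean 0.14 um, sd 0.040 um                 |
| min radius b0 | fixed fraction of R        | 0.01 R                                    |
| radius R      | fixed                      | 0.03 um                                   |

The uniform support is mean +/- sqrt(3) sd = [0.0707, 0.2093] um. Each site
starts in a wait drawn from the full exponential — by memorylessness this is
the stationary initialisation. Event lengths are resampled per event and
clamped to the tubule length; the `"full"` length policy forces 2L = l
(the "maximally long pinches" configuration). Rate multipliers
`alpha` (divides durations and waits: a pure fast-forward) and `beta`
(further divides waits) explore stronger forcing.

Within an event the minimum radius follows the smooth law
b(t) = (R + b0)/2 + (R - b0) cos(pi t / T)/2, so bdot = 0 at both event
boundaries and the volume source is continuous. The pinch profile is linear
in |z - z0| across the half-length L. The instantaneous source
q = -(2 pi / 3) bdot L (R + 2 b) is exactly the rate of change of the
pinch-region volume, so a completed cycle injects zero net volume.

## Hydraulics

Lubrication theory in a slowly varying axisymmetric tube gives a parabolic
axial profile with cross-sectional flux Q(z, t) obeying
dQ/dz = -2 pi a da/dt, and a pressure gradient -8 mu Q / (pi a^4) (no
slip). Integrating through the piecewise-linear pinch yields a two-segment
resistor model per edge: the tubule is split at the pinch into resistances

r = (8 mu / pi) [ L_straight / R^4 + L (R^2 + R b + b^2) / (3 b^3 R^3) ]

with the pinch source attached at the splitting ("dummy") node. The second
term is the algebraically simplified form of
L (1/b^3 - 1/R^3) / (3 (R - b)): the apparent 0/0 at b = R cancels exactly,
so no numerical expansion is needed and the classical Hagen-Poiseuille law
is recovered continuously as b approaches R.

With a wall slip length lambda, the axial profile flattens
(u proportional to 1 - (r/a)^2 + 2 lambda / a, normalised to the same Q)
and the resistance acquires a logarithmic closed form. That form computes an
O(lambda^3) bracket from O(lambda) terms, so for 4 lambda / b < 0.1 the
package switches to its series in lambda, whose leading term is exactly the
no-slip resistance; both branches agree to machine precision at the
crossover. Slip changes the profile shape but not the cross-sectionally
averaged speed at fixed Q, which is why it leaves network transport
essentially unchanged.

The instantaneous network solve treats the 2E segment fluxes plus the exit
(and sheet) sources as unknowns, with equations: mass conservation at every
node including dummy nodes (K1), zero pressure drop around each of the
E - N + 1 fundamental cycles (K2), equal pressure along spanning-tree paths
between exit nodes (and separately between sheet nodes), and the prescribed
total sheet source. The cycle basis comes from a breadth-first-search
spanning tree started at the lowest node id with neighbours explored in
ascending id order, making the basis — and hence the assembled system —
reproducible. The viscosity multiplies every pressure equation uniformly and
cancels: fluxes never depend on mu. The sparse system (Matrix) keeps a fixed
pattern across time steps; only the resistance values are refreshed. Every
solve is checked against its residual, and the test suite cross-checks the
whole solver against an independent dense nodal-analysis implementation with
quadrature-derived resistances.

Resistances and sources are refreshed every `dt_flow` = 1 ms (configurable),
two orders of magnitude below the mean event duration of 72.5 ms, and the
flow is held frozen between refreshes; kinematic quantities are evaluated at
the interval midpoint.

## Particle transport

Particles are independent rigid spheres of diameter 5 nm with diffusivity
D = 0.6 um^2/s, advanced by explicit first-order Euler advection plus an
isotropic Gaussian increment of variance 2 D dt per axis. Model choices the
source physics does not pin down, recorded here as the package's defaults:

* **Brownian step** `dt_bd` = 1e-5 s, giving a step length of ~3.5 nm
  (about R/9), small enough to resolve the confinement; only the 18 ms
  recording cadence is physically prescribed.
* **Wall collisions** are specular reflections about the local wall
  position, repeated up to 10 times, then clamped to the axis. If the wall
  moves inward past a particle between flow updates, the particle is
  projected back to r = a - r_p (or the axis when the lumen is narrower
  than the particle, as happens at the centre of a deep pinch).
* **Node residence is instantaneous**: a particle reaching a tubule end is
  assigned to the node and redirected within the same step, re-entering the
  chosen tubule at the node-side end on the axis. The outgoing tubule is
  drawn with weight max(Pe_i + 1, 0), Pe_i = U_i R / D, where U_i is the
  cross-sectionally averaged speed at the node-side end, positive outward;
  with no flow the choice is uniform. At the measured flow speeds
  Pe ~ 0.07, so these weights sit within ~7% of uniform.
* Transverse Brownian increments act in the two local normal directions:
  diffusion is fully three-dimensional inside each axisymmetric tubule even
  though the network itself is planar.

Edge traversals are extracted online: since node residence is instantaneous,
every node visit is also a departure, so consecutive distinct node visits
delimit exactly one traversal and a revisit of the origin refreshes the
departure time ("most recent departure"). The traversal speed is the edge
length over the traversal time; the headline observable is the mean over
edges of the per-edge average traversal speeds. Instantaneous speeds are
finite-difference displacement magnitudes at the 18 ms cadence. Flow
statistics use the flux entering each edge (Q1): the mean of |Q1|/(pi R^2)
over edges and time, and the per-edge rate of sign changes of Q1 sampled at
`dt_flow` for the direction-alternation frequency. (An alternative
convention — counting alternations of the flow at fixed interior points —
would give similar magnitudes; the per-edge entry flux is used because it is
the quantity the solver naturally produces at every step.)

The two-colour mixing experiment seeds equal particle numbers uniformly in
the two halves of the network and tracks Var(n_blue - n_red) over 20
equal-width vertical strips; zero variance is perfect homogeneity.

## Alternative mechanisms

**Junctions.** Each non-exit node contracts as an independent renewal
process structurally identical to tubule pinching: event durations are
exponential with mean alpha^-1 times the pinch-duration mean, waits
beta^-1 times the pinch-wait mean. An event of duration 2T produces the
source S(t) = f dV (pi / 2T) sin(pi t / T) over the whole event, so the
contraction [0, T] expels f dV and the relaxation [T, 2T] — mirrored, with
equal duration — takes it back; net volume per cycle is zero. Junction
volumes dV are truncated-normal: N(0.0045, 0.0021) um^3 rejected outside
[0.0020, 0.0081] um^3. (One part of the source text quotes a mean of
0.045 um^3; the value 0.0045 um^3 is used as it is the one consistent with
the quoted range and with the rest of the analysis.)

**Perinuclear sheet.** A subset of boundary nodes becomes sheet nodes: they
share one (unknown) pressure and their sources are additional unknowns
constrained to sum to S_sheet(t) = V_sheet pi sin(pi t / T) / (2T), with
V_sheet = 10 um^3 and 2T = 5 s by default. The solver gains M2 unknowns,
M2 - 1 equal-pressure equations and one total-source equation.

**Peripheral sheets** are represented through node contractions with
measured sheet volumes V_k ~ N(0.12, 0.04) um^3: scenario 1 has every node
expelling V_k/6 at rates 2.5x slower than tubule pinches; scenario 2 has a
random third of the nodes (a fixed per-run subset chosen by the seed)
expelling V_k/2 at 5x slower rates. Both inject the same expected volume
per unit time.

## Closed-form estimates

* Single-pinch advection: a centreline particle ahead of a pinch whose flow
  all escapes one way is displaced by
  dz = (8L/3)(1 - b0/2R - b0^2/2R^2) per contraction, independent of the
  contraction's time course; the bound 8L/3 (~0.19 um at 2L = 0.14 um) is
  attained at complete closure. Two coordinated pinches (close 1, close 2,
  open 1, open 2) achieve this bound as a *net* displacement, escaping
  single-pinch reciprocity.
* Pinch mechanics: the bending-energy difference of a pinched tubule scales
  as dE ~ k_c L / sqrt(b0 R); with k_c = 50 kBT at 300 K, L = 70 nm,
  b0 = 10 nm, R = 30 nm this gives ~8e-19 J and a force dE/R ~ 30 pN. The
  scaling form is reconstructed to reproduce exactly these quoted values
  from the quoted inputs (the printed intermediate expressions in the
  source text are corrupted); its 1/sqrt(b0) dependence is asserted in the
  tests.
* Peripheral-sheet energetics: W_inside = 9 pi mu Rs^4 / (Dh T) (lubrication
  dissipation between the contracting membranes; same reconstruction note)
  and W_outside = mu Vs^2 l / (pi R^4 T) from the geometric series of
  dissipation in a three-fold branching cascade of tubules,
  sum_i 3^i 8 mu l (Q/3^i)^2 / (pi R^4) = 4 mu Q^2 l / (pi R^4) with
  Q ~ Vs/2T. With a luminal viscosity of 10x water these give ~8e-18 J and
  ~1e-16 J, about 1000 ATP per contraction.
* Room temperature is taken as 300 K; order-of-magnitude comparisons use
  one-significant-figure rounding, matching how such estimates are quoted.

Two time-scale conventions coexist in the source material: the
renewal-process mean 2T = 0.0725 s (used by all simulations here) and a
coarser average 2T = 0.213 s quoted alongside the theoretical speed bounds.
The bound formulas (8L/3T and 8L/9T) are implemented; the speed values
printed from the coarser convention are not asserted anywhere.

## Problem sizes and numerical tolerances

The test-suite simulations use a 240-node honeycomb with 300 particles for
10 s for the headline transport quantities, a 96-node honeycomb for the
active-versus-diffusion, slip, mixing and parameter-progression comparisons
(120-300 particles, 2.5-6 s), and 3x3 honeycombs for junction sweeps —
sizes at which the Monte-Carlo error of the compared means is a few percent,
well inside the assertion bands. Determinism is exact per seed: schedules,
volume draws and the compiled Brownian kernel all consume R's RNG stream.
Solver agreement with the dense oracle is asserted at 1e-9 relative,
resistance closed forms against quadrature at 1e-8, flux conservation at
1e-10 relative, the dissipation series at 1e-12, and the velocity-field
divergence at 1e-6 under central differences.

## Limitations

* Contraction kinematics are prescribed, not force-balanced: there is no
  membrane elasticity or fluid-structure feedback, no osmotic flow, and no
  compliance of the tubule walls.
* Particles are passive, dilute and point-like in their hydrodynamics
  (finite size enters only at wall collisions); there are no interparticle
  interactions and no size-dependent mobility corrections.
* One pinch site per tubule; multi-site coordination is treated only in the
  two-pinch closed form.
* The synthetic networks reproduce summary statistics of real ER networks,
  not their actual geometries, so simulated numbers carry a
  geometry-insensitivity assumption that has been verified only at the
  level of those statistics.
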