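---
title: "Model and methods: a flexible polymer two-way coupled to a nematic MPCD solvent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a flexible polymer two-way coupled to a nematic MPCD solvent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemapoly)
```

# The physical problem

A flexible polymer suspended in a nematic liquid crystal experiences a
competition between its conformational entropy, which favours a random
coil, and the elastic cost of mis-aligning its backbone with the nematic
director, which favours a rod stretched along the director.  At
intermediate coupling the chain resolves this competition with
*hairpins*: localized, topologically protected back-folds whose two arms
are both aligned with the director (the nematic is head-tail symmetric, so
an anti-parallel arm costs nothing).  Hairpins diffuse along the backbone,
letting the chain explore conformations at nearly constant energy, and
their number controls both the chain's shape and — through the shape —
its anisotropic centre-of-mass diffusion, even when the solvent viscosity
itself is isotropic.

`nemapoly` simulates this system with a hybrid scheme: the solvent is a
nematic multi-particle collision dynamics (N-MPCD) fluid, the chain is a
molecular-dynamics (MD) bead-spring polymer, and the two are coupled both
ways.  Everything is expressed in simulation units: cell size $a$, fluid
particle mass $m$, and thermal energy $k_\mathrm{B}T$ all equal 1, giving
the time unit $t_0 = \sqrt{m a^2 / k_\mathrm{B}T} = 1$.

# The solvent: N-MPCD

The fluid is a set of point particles with position $\mathbf r_i$,
velocity $\mathbf v_i$ and a unit orientation (mesogen axis)
$\mathbf u_i$, at number density $n = 20/a^3$.  Each timestep
$\Delta t = 0.1\,t_0$ consists of ballistic streaming
$\mathbf r_i \to \mathbf r_i + \mathbf v_i \Delta t$ followed by cell-wise
stochastic collisions on a cubic grid of edge $a$, with a random grid
shift (uniform per axis in $[-a/2, a/2)$) redrawn every step so that the
collision grid does not break Galilean invariance.  The shift affects
binning only, never stored positions.

**Velocity collision.**  Within each cell the Andersen-thermostatted
operator replaces every member's velocity by
$\mathbf v_i' = \mathbf v_\mathrm{cm} + \boldsymbol\xi_i -
\langle\boldsymbol\xi\rangle$, with $\boldsymbol\xi_i$ fresh
Maxwell–Boltzmann deviates at $k_\mathrm{B}T$ for the member's own mass
and $\langle\cdot\rangle$ the mass-weighted cell mean, so cell linear
momentum is conserved to machine precision.  A rigid-body rotation about
the cell centre of mass is then added to restore the cell's *angular*
momentum.  We chose the angular-momentum-conserving variant because the
backflow construction (below) lives in the same bookkeeping, and because
the kinetic-theory viscosity of this variant at $n = 20$,
$\Delta t = 0.1$ ($\eta \approx 8.9\,k_\mathrm{B}T t_0/a^3$, dominated by
the collisional part $\sim (n - 7/5)m/(24 a \Delta t)$) matches the
calibration value $\eta = 8.6 \pm 1.0$ that this solvent is required to
reproduce, whereas the non-conserving variant would give
$\eta \approx 12$–$17$.  The measured viscosity of the implementation
(forced-flow fixture, below) is $\approx 9.0$.

**Orientation collision.**  Each cell's orientation tensor
$Q = \tfrac{d}{d-1}(\langle \mathbf u \mathbf u\rangle - I/d)$ yields the
local scalar order parameter $S_c$ (largest eigenvalue) and director
$\mathbf n_c$ (its eigenvector; the sign is fixed deterministically for
reproducible logs — physics is sign-independent).  Mesogen orientations
are then redrawn from the canonical Maier–Saupe single-particle
distribution about the director,
$p(\mathbf u) \propto \exp\!\big[U S_c P_2(\mathbf u \cdot \mathbf
n_c)/k_\mathrm{B}T\big] \propto \exp\!\big[\tfrac{d}{d-1} U S_c (\mathbf u
\cdot \mathbf n_c)^2 / k_\mathrm{B}T\big].$
The $P_2$ form matters: with the bare $(\mathbf u\cdot\mathbf n)^2$
exponent (no $d/(d-1)$ factor) the self-consistency map
$S = f(US)$ only orders for $U > 7.5$, so the working point $U = 6$ would
sit in the isotropic phase; with the $P_2$ convention the 3D transition is
near $U \approx 5$ and $U = 6$ gives a nematic with a self-consistent
fixed point $S^* \approx 0.73$ (the simulated bulk value is
$\approx 0.69$, the difference being the finite, $\sim$20-member cells
over which $Q$ is estimated).  Sampling uses rejection with an
$e^{a|x|}$ envelope for the aligned regime (acceptance $\gtrsim 0.5$ at
the working point), verified against quadrature.

**Flow coupling and backflow.**  A per-cell velocity gradient is
estimated by least squares of member velocities against positions (cells
hold $\sim n = 20$ members, enough for a stable fit; cells with fewer
than $d+1$ members skip the update and are counted).  Orientations then
follow Jeffery's equation for elongated tracers,
$\Delta\mathbf u = \alpha\,\Delta t\,[\Omega\mathbf u + \lambda(E\mathbf u -
(\mathbf u \cdot E \mathbf u)\,\mathbf u)]$, with bare tumbling parameter
$\lambda = 2$ (flow-aligning) and shear susceptibility $\alpha = 0.5$.
Finally the net angular momentum $\gamma_R \sum_i \delta\theta_i$ imparted
to the director field by the orientation update is returned to the flow
with opposite sign as a rigid-body velocity correction (again about the
cell centre of mass, so linear momentum is untouched).  The rotational
friction is small, $\gamma_R = 0.01\,k_\mathrm{B}T t_0$, deliberately
minimizing backflow effects.

# The polymer: FENE + WCA + nematic coupling

The chain has $N = 20$ beads of mass $M = 10\,m$, connected by FENE
bonds and interacting through the purely repulsive, cut-and-shifted
Lennard-Jones (WCA) potential with $\varepsilon = 1$, $\sigma = 1$ and
cutoff $2^{1/6}\sigma$ on all pairs.  It is integrated by velocity Verlet
with $\Delta t_\mathrm{MD} = 0.002\,t_0$, i.e. 50 MD substeps per MPCD
step, with the director field frozen between collision steps.  The chain
feels the solvent only through the collision step: monomers are binned
with the same grid shift and participate in the velocity collision with
their mass $M$ — that momentum exchange *is* the thermal and hydrodynamic
force of the solvent.  Monomers carry no orientation and are excluded
from the orientation collision.

**FENE divergence radius.**  The FENE form is
$V = -\tfrac12 k_\mathrm{FENE} r_\mathrm{max}^2 \ln[1 -
(r/r_\mathrm{max})^2]$ with $k_\mathrm{FENE} = 120\,k_\mathrm{B}T/a^2$.
The divergence radius was a genuinely open design choice: with
$r_\mathrm{max} = 1\,a$, exact canonical single-bond statistics (an
independent quadrature over $r^2 e^{-\beta V(r)}$, reproduced by the
simulation to three digits) give a mean bond length
$\langle b\rangle = 0.847\,a$, outside the reference value
$b = 0.89 \pm 0.02\,a$ that this chain must reproduce; with the
Kremer–Grest-style $r_\mathrm{max} = 1.5\,a$ the canonical value is
$0.893\,a$, inside it, and $r_0 = 1\,a$ retains its stated role as the
nominal equilibrium bond length.  We therefore default to
$r_\mathrm{max} = 1.5\,a$ (configurable), and treat the measured bond
length as the empirical disambiguator.

**Two-way nematic coupling.**  Each bond tangent
$\mathbf t_{jl}$ couples to the director of the cell containing the
higher-index monomer through the harmonic angular potential
$V_\mathrm{NPC} = \tfrac12 k \theta^2$ with
$\theta = \arccos|\mathbf t \cdot \mathbf n_c| \in [0, \pi/2]$ — the
*acute* angle, making the potential head-tail symmetric, which is what
allows hairpin arms to be unpenalized.  The restoring torque on the bond
is $\tau = k\theta$ about $\mathbf t \times \mathbf n$; the
equal-but-opposite reaction is applied to the solvent.  The exact
discretization of that reaction was open; we accumulate the reaction
angular impulse $\mathbf J_c = -\sum \tau\,\hat{\mathbf e}\,
\Delta t_\mathrm{MD}$ over the 50 MD substeps of one MPCD step and rotate
each of the $N_c$ mesogens of the cell by
$\delta\theta = |\mathbf J_c| / (\gamma_R N_c)$ about
$\mathbf J_c/|\mathbf J_c|$, once per MPCD step, before the orientation
collision.  Uniform apportionment makes the action–reaction bookkeeping
close exactly by construction; the apportionment is exposed as an option
for sensitivity checks.  Setting $k = 0$ decouples chain and director
exactly.

# Geometry

Production geometry is a cylinder of length $L = 30\,a$ and radius
$R = 10\,a$, axis along $z$, capped by periodic boundaries.  The wall is
impermeable with perfect slip: a crossing particle is specularly
reflected at the crossing point (normal velocity negated, tangential and
axial components untouched), conserving kinetic energy exactly.  Strong
planar anchoring is realized as the infinite-strength limit: mesogens in
wall-intersecting cells (detected per step in the shifted frame) are
reset to $\pm\hat z$ each collision step.  No phantom particles are added,
so wall cells simply collide with however many members they have.  The
polymer is initialized fully extended on the centre line, aligned with
the global director, and the fluid starts with Maxwell–Boltzmann
velocities and $\mathbf u = \hat z$.  Periodic 2D and 3D boxes are
provided for calibration fixtures and for the strongly coupled 2D
demonstration ($L = 30\,a$, $N = 20$, $k = 20$).

# Analysis stack

**Conformation.**  The gyration tensor
$G = \langle (\mathbf r - \mathbf r_\mathrm{cm})(\mathbf r - \mathbf
r_\mathrm{cm}) \rangle$ over beads is decomposed along the global
director (taken as the cylinder axis, which the strong anchoring
enforces): $R_{g\parallel}^2 = \hat n \cdot G \cdot \hat n$,
$R_{g\perp}^2 = (G : (I - \hat n \hat n))/2$ per transverse component.
Ensemble aspect ratios are formed from ensemble-averaged squares,
$\beta = \sqrt{\langle R_{g\perp}^2\rangle / \langle
R_{g\parallel}^2\rangle}$, so an uncoupled coil gives $\beta \approx 1$
(the average of per-frame ratios would not: instantaneous coils are
aspherical).  The parallel component is normalized by the closed-form rod
radius $R_\mathrm{rod} = b\sqrt{(N^2-1)/12}$; the perpendicular one by
the *measured* zero-coupling value of the same chain length (empirical
self-normalization, which guarantees $r_{g\perp} \to 1$ in the coil limit
independent of any self-avoiding-walk prefactor convention).  End-to-end
components are normalized by $N^\nu b$ with $\nu = 3/5$ (coil) or
$\nu = 1$ (rod).

**Steady-state onset** is detected by the iterative procedure: compute
the mean of the ensemble-averaged observable from the current onset to
the end; find the first time the series falls below that mean; update the
onset; repeat until the index stabilizes (we accept a change of at most
one index as converged, which keeps the procedure well-behaved on slowly
relaxing series whose residual decay is below the noise).  The default
observable is $R_{g\parallel}(t)$, the slowest mode of an initially
extended chain; a series with no crossing is flagged unsteady.

**Hairpins.**  Scoring, detection and tracking were open reconstruction
choices, fixed as follows and exposed in full as parameters.  For monomer
$j$, $P^-$ and $P^+$ are the mean director projections of the $w = 3$
bonds before and after $j$; the score is $(|P^-| + |P^+|)/2$ when the two
arms point oppositely along the director and 0 otherwise.  A straight rod
scores 0 everywhere; an ideal U-turn scores $\approx 1$ at its apex.
Detections are score maxima above a threshold of $0.5$ with non-maximum
suppression within $w$ bonds; polarity is $+1/2$ when the fold opens
toward $+\hat n$ ($P^- < 0 < P^+$).  Tracks are linked greedily between
consecutive frames by contour distance with a maximum jump of 4 bonds and
matching polarity; ties resolve to the lower monomer index.  Births
within $w$ of a chain end are end entries, otherwise pair creations when
a simultaneous opposite-polarity birth exists; deaths symmetrically.
Hairpin diffusivity is fit from the track-averaged arc-length MSD,
$\langle \delta s^2 \rangle = 2 D_H\,\delta t$, with short-lived tracks
excluded.  At weak coupling ($k/U < 1$) the detector fires on ordinary
coil back-turns, so counts there are reported but not interpreted, and
lifetimes are too short for diffusivity fits — the hairpin-dynamics
analysis is restricted to $k/U \ge 1$.

**Diffusion.**  The unwrapped centre-of-mass trajectory gives
time-origin-averaged MSDs decomposed along the director
($\langle \delta r_\parallel^2 \rangle = 2 D_\parallel \delta t$,
$\langle \delta r_\perp^2 \rangle = 4 D_\perp \delta t$,
total $= 6 D \delta t$), fitted in a lag window guarded by a log-log
slope criterion ($|$slope$-1| \le 0.1$; ballistic or caged windows are
flagged invalid).  Fit errors come from refitting 5 consecutive segments.

# Analytic models

**Segment partition function.**  With the $\sin^2$ approximation of the
angular potential, one bond's partition function is
$Z_1(\kappa) = 2\pi \int_{-1}^{1} e^{\kappa (1 - x^2)}\,dx$ with the
dimensionless coupling $\kappa = -k b / 2 k_\mathrm{B}T \le 0$, evaluated
by adaptive quadrature (relative tolerance $10^{-10}$; the printed
approximation equates $k\sin^2\theta/2$ with $k(1-(\mathbf t\cdot\mathbf
n)^2)$, which differ by a factor 2 — we resolve in favour of
$\tfrac{k}{2}\sin^2\theta$, the form consistent with the harmonic
potential actually simulated).  Differentiating the free energy gives
$\langle 2 t_\perp^2 \rangle = \partial \ln Z_1 / \partial \kappa$, hence
$\langle t_\perp^2\rangle \to 1/3$ as $\kappa \to 0$ and
$\langle t_\parallel^2 \rangle + 2\langle t_\perp^2\rangle = 1$
identically; the quadrature route and a central-difference route
(step $10^{-4}$) are both implemented and must agree.

**Ellipsoid drag with wall correction.**  The chain's average shape is
approximated by a prolate spheroid with semi-axes $R_{g\parallel}$,
$R_{g\perp}$; Perrin's friction factors give
$D^e_\alpha = k_\mathrm{B}T / (\eta\,\ell\,K_\alpha)$ with a
parallel-to-perpendicular ratio depending only on $\beta$, equal to 1 for
a sphere and rising (logarithmically slowly) to 2 for an infinitely thin
rod.  The slender limit is evaluated stably via
$1 - e = \beta^2/(1+e)$ and recovered exactly by extrapolation in
$1/\ln(1/\beta)$.  Confinement is modelled by the leading-order hindered
diffusion correction $D_\alpha = D^e_\alpha (1 - C_\alpha R_g^0 / R)$
with the fitted constants $C_\parallel = 1.20$, $C_\perp = 1.35$; the
multiplicative form is a documented choice (the reference expression is
not printed) and is swappable.

**Kramers hopping.**  A hairpin hop requires one bond to rotate through
the director field, an activated event with rate
$\Gamma = \sqrt{V''_a V''_b}/(2\pi\zeta)\,e^{-E_b/k_\mathrm{B}T}$ and
$D_H = b^2 \Gamma / 2$.  The convenience wrapper estimates
$E_b = c_1 k$, $V'' = c_2 k$ and $\zeta = k_\mathrm{B}T / D_0$ (Einstein
relation on the uncoupled chain); the prefactors are order-of-magnitude
calibrations exposed as arguments, because only the exponential
dependence on $k$ is quantitatively testable.

# Fixtures, problem sizes and what the tests show

All test inputs are generated in code.  The calibration fixtures use
periodic boxes of $6^3$–$8^3$ cells (4\,320–10\,240 solvent particles):
viscosity from the steady amplitude of a Kolmogorov (sinusoidally forced)
flow, $\eta = n m g / (k^2 u_\mathrm{steady})$; self-diffusion from
tracked unwrapped fluid trajectories; bond statistics from a solvated
$N = 20$ chain at $k = 0$.  The coupling sweeps use a reduced cylinder
($R = 3.5\,a$, $L = 20\,a$, $N = 15$, a few thousand $t_0$ per coupling
value) — about an order of magnitude below the production geometry in
particle number and one to two in duration.  These sizes resolve the
qualitative physics (coil-rod transition, hairpin statistics, diffusion
anisotropy trends) with modest statistics; they do *not* reproduce
full-scale quantitative values whose error bars require the production
cylinder ($\approx 1.9\times10^5$ particles, $1.2$–$1.5\times10^5\,t_0$,
twenty repeats).  Within the sweeps, the slowest relaxation is the
*uncoupled* chain's entropic coiling away from the extended initial
conformation ($\sim 500\,t_0$; coupled chains are driven quickly to
their elongated steady states), so the $k = 0$ leg gets a
correspondingly longer relaxation period and every leg is gated by the
iterative onset detector before averaging.  Observables such as
$\langle N_H \rangle$ and $\beta$ decorrelate over $\sim 100\,t_0$, so
single desk-scale runs resolve trends only between couplings separated
by $\gtrsim 1.5\,U$; the tests compare exactly those.  The narrower
cylinder also hinders perpendicular
diffusion more strongly than the production one (the wall correction
factor $C_\perp R_g^0/R$ roughly triples), so diffusivity *ratios* in the
reduced cylinder sit well above their full-scale counterparts at every
coupling and would mask the shape-anisotropy signal; the diffusion-trend
fixture therefore uses a periodic box, where the uncoupled ratio is
$\approx 1$ by symmetry and elongation raises it toward the thin-rod
regime.  In that box the strongly coupled chain is longer than the
periodic cell along the director, i.e. it effectively threads its own
images — acceptable for demonstrating shape-induced anisotropy,
not for quantitative drag coefficients.  What a passing reduced-scale
suite shows is that
every mechanism moves in the right direction with the right couplings —
not that full-scale numbers are reproduced on a desktop.

Two further caveats on scope.  The solvent reproduces the isotropic
viscosity calibration, but this fluid's Schmidt number at the stated
density and timestep evaluates to order 10 ($\nu \approx 0.45\,a^2/t_0$,
$D_f \approx 0.06\,a^2/t_0$), i.e. a moderately liquid-like regime; we
report the measured value as-is.  And the synthetic solvent is a
structureless point-particle nematic: it has no elastic-constant
anisotropy, no anisotropic viscosity and no defect-loop physics of real
lyotropic suspensions, so agreement at fixture scale validates the
algorithmic machinery, not the microscopic realism of any particular
experimental system.

# Numerical and degenerate-input choices

Cell directors for cells with a single mesogen are that mesogen's axis
with $S = 1$; empty cells have no director, and coupling forces for a
monomer in such a cell are skipped for that substep.  Kicks whose angle
would exceed $\pi/2$ are clamped and counted (never observed at the
reference $\gamma_R$ with $k \le 20$).  Velocity-gradient fits use the
cell's members only; under-populated cells skip the Jeffery update and
increment a counter (boundary cells, which are anchored anyway, dominate
that count).  Reflections are resolved by linear backtracking to the
crossing point, iterated up to five times, with a final clamp to the wall
radius against rounding.  The FENE integrator aborts with a diagnostic if
a bond reaches the divergence radius (the symptom of a too-large MD
step).  All randomness flows from labelled xoshiro256++ streams
(initialization, grid shift, velocity collision, orientation collision)
seeded from the run seed, so a run is bit-reproducible given
(configuration, seed) and analysis code can never perturb the physics;
checkpoints carry the stream states and resume exactly.

# Known limitations

The chain is freely jointed (no bending stiffness) and single; the
solvent has isotropic viscosity by construction; anchoring is only the
infinite-strength planar limit acting on wall-intersecting cells; the
hairpin score, threshold, window and linking rules are reconstructions
validated on constructed conformations and qualitative statistics, not
against any reference implementation; and the Kramers prefactor estimates
are order-of-magnitude only.  The 2D mode exists for visualization-style
demonstrations and is not used for quantitative claims.
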