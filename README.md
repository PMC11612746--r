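# nemapoly

Hybrid N-MPCD / MD simulation of a single flexible polymer two-way
coupled to a nematic liquid-crystal solvent, with the full analysis stack
for its conformation, hairpin defects and anisotropic diffusion.

## The problem

A flexible chain in a nematic background trades conformational entropy
against the elastic cost of mis-aligning with the director **n**.  Weak
coupling leaves a self-avoiding coil; strong coupling makes a rod;
intermediate coupling produces *hairpins* — localized back-folds whose
anti-parallel arms are both unpenalized by the head–tail-symmetric
nematic.  Hairpins hop diffusively along the backbone, and their number
controls the chain's shape and, through the shape, the anisotropy of its
centre-of-mass diffusion even in a solvent whose viscosity is isotropic.
This package is for soft-matter / biophysics researchers who want a
desk-scale, fully scriptable model of that physics (think DNA in a
nematic virus suspension, coarse-grained far past chemistry).

## The model

* **Solvent** — nematic multi-particle collision dynamics: point
  particles with velocity and orientation at density 20/a³; streaming +
  grid-shifted, Andersen-thermostatted collisions that conserve cell
  linear and angular momentum exactly; Maier–Saupe orientation collision
  about the local cell director (`p(u) ∝ exp[U S_c P₂(u·n_c)/k_BT]`,
  nematic at the working point U = 6); Jeffery shear coupling (λ = 2,
  α = 0.5) and backflow compensation with rotational friction
  γ_R = 0.01.
* **Polymer** — N = 20 beads (mass 10 m), FENE bonds
  (k_FENE = 120 k_BT/a², divergence radius 1.5 a) plus WCA excluded
  volume (ε = σ = 1), velocity-Verlet at Δt_MD = 0.002 t₀ (50 substeps
  per collision); monomers exchange momentum with the solvent by joining
  the cell collision.
* **Two-way coupling** — each bond tangent feels
  `V = (k/2)·θ²` against its cell director (θ the acute angle); the
  equal-and-opposite torque rotates the cell's mesogens by
  `δθ = τΔt/(γ_R N_c)`.
* **Geometry** — cylinder (L = 30 a, R = 10 a) with perfect-slip,
  impermeable walls, strong planar anchoring along the axis and periodic
  caps; periodic 2D/3D boxes for calibration fixtures.
* **Analysis / theory** — gyration tensor decomposition and end-to-end
  scaling; iterative steady-state onset; hairpin scoring, detection,
  tracking and Poisson count statistics; MSD decomposition along the
  director; single-segment partition function
  `Z₁(κ) = 2π∫ exp(κ(1−x²)) dx` (κ = −k b/2k_BT); Perrin prolate-ellipsoid
  drag with the wall correction `D = Dᵉ(1 − C·R_g⁰/R)`
  (C_∥ = 1.20, C_⊥ = 1.35); Kramers hopping rate
  `Γ = √(V''_a V''_b)/(2πζ)·e^(−E_b/k_BT)`, `D_H = b²Γ/2`.

All quantities are in simulation units a = m = k_BT = 1 (t₀ = 1).  The
simulator core is compiled (Rcpp); everything is driven from R.  See the
methods vignette (`vignettes/nematic-polymer-model.Rmd`) for the model in
full, including the reconstruction choices and their rationale.

## Worked example

Solvate a chain at moderate coupling in a small periodic box, then look
at its shape and hairpins:

```r
library(nemapoly)

cfg <- sim_config(geometry = "box", Lx = 8, Ly = 8, Lz = 8,
                  N = 20, k = 12, steps = 3000, out_every = 10, seed = 1)
run <- run_simulation(cfg, warmup = 1000)
run
#> <nemapoly_run>
#>   10240 fluid particles, N = 20 beads, 300 frames, t = 101 .. 400 t0
#>   <T> = 1.0000  <S> = 0.653  <b> = 0.8933

conf <- analyze_conformation(run)
conformation_summary(conf, N = 20)
#>        beta one_minus_beta   Rg_par  Rg_perp    rg_par rg_perp  rho_par2
#> 1 0.6634919      0.3365081 1.725026 1.144299 0.3361319      NA 0.0383922
#>   rho_perp2   t_par2
#> 1 0.9629519 0.593747

hp <- analyze_hairpins(run)
mean(hp$counts)        # average number of hairpins per frame
#> [1] 1.99
hp$statistics$lambda   # Poisson rate fitted to the count distribution
#> [1] 1.99
```

The fluid sits at temperature 1 with bulk nematic order S ≈ 0.65, and
the chain's mean bond length is 0.893 a.  Starting from a coil, 400 t₀
at k/U = 2 leaves the chain in the hairpin-dominated regime: about two
hairpins per frame (Poisson-distributed), a parallel gyration radius of
only a third of a rigid rod's, and end-to-end components (ρ∥² ≈ 0.04,
ρ⊥² ≈ 0.96) far from the rod limit even though the bond tangents are
already substantially aligned with the director (⟨(t·n)²⟩ ≈ 0.59).  The
theory side of the same physics:

```r
kappa <- dimensionless_coupling(12, b = 0.893)
tangent_expectations(kappa)
#>    kappa    t_par2   t_perp2
#> 1 -5.358 0.7814698 0.1092651
```

The independent-segment thermodynamic expectation ⟨t∥²⟩ = 0.78 sits
above the measured 0.59: exactly the intermediate-coupling signature —
back-folds (and the slow conformational relaxation they cause) depress
the global alignment below what equilibrium single-segment theory
predicts, which is why hairpins, not segment fluctuations, control the
conformation in this regime.

A thin command-line driver is installed as `exec/nemapoly`
(`run`, `analyze`, `theory`, `fixture` subcommands) for use outside R.

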