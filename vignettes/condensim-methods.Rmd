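---
title: "Modeling condensin-driven chromosome shaping and segregation with condensim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling condensin-driven chromosome shaping and segregation with condensim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

condensim simulates mitotic chromosomes as coarse-grained bead-spring
polymers decorated with condensin point particles. Each chromosome is a
chain of `N` spherical monomers of diameter `sigma = 1` (one monomer is
roughly ten nucleosomes, a few kilobases of DNA), connected by harmonic
springs of natural length `d_B = 1` and stiffness `eps_spr = 1000` kT.
Monomer excluded volume is a Weeks-Chandler-Andersen (WCA) potential with
contact energy `eps = 1` kT, capped at `eps_cut = 1000` kT so that the
non-self-avoiding starting configurations remain integrable. Springs are
*phantom*: they carry no excluded volume of their own, so chain strands can
pass through one another — a deliberately permissive stand-in for
topoisomerase II strand-passage activity. Passage is nevertheless rare,
because the monomers joined by each spring do repel.

Condensins are point particles (no excluded volume) with two activities:

* **Loop holding.** Condensin `i` is bound by zero-rest-length harmonic
  tethers of strength `F_loop` to two base-point monomers, `(i-1)L + 1`
  and `iL` (1-based), closing a chromatin loop of `L = N/M` monomers.
  Consecutive loops partition the chain, so the condensins trace a curve
  along the chromosome — the condensin axis.
* **Finite-range attraction.** Every condensin pair closer than `Delta`
  attracts through `U(r) = -F_cond (r - Delta)^2`, in cis and in trans
  alike; the well depth for a pair at contact is `F_cond * Delta^2` kT.
  Below `Delta ~ 1` the monomer corona around the loop bases keeps pairs
  from ever engaging; wells of tens of kT (large `F_cond * Delta^2`) bind
  essentially irreversibly and oppose the segregation of two chromosomes.

`F_cond`, `F_loop` and `Delta` are the three biological control parameters.
All four potentials are exposed individually
(`wca_energy_force()`, `spring_energy_force()`, `loop_energy_force()`,
`attraction_energy_force()`) and assembled by `total_forces()`.

A note on force units: the source literature for this class of model
describes the condensin force parameters as "normalized by the cut-off
energy". We implement the equations exactly as printed — `F_cond` and
`F_loop` are the harmonic coefficients in kT per sigma squared. We also
tested the alternative reading in which the printed values multiply
`eps_cut`: the resulting tethers (about 1000 kT per sigma squared) crush
each pair of base-point monomers onto the steep part of the WCA wall,
where the local pair stiffness corresponds to `omega * dt` well above 1 at
the model timestep; any velocity-Verlet integrator then detonates into a
self-heating state (kinetic temperature thousands of kT) even for a
minimal two-monomer/one-condensin unit. Since the model is specified with
`dt = 0.01`, the literal coefficients are the only self-consistent choice,
and they are what the package uses.

# Dynamics

`langevin_step()`/`run_dynamics()` integrate Langevin dynamics with the
Gronbech-Jensen/Farago (GJF) discretization of velocity Verlet: friction
`gamma = 1`, thermal energy `kT = 1`, timestep `dt = 0.01`, mass `m = 1`
for monomers and condensins alike. GJF was chosen over naive
velocity-Verlet-with-friction because its half-step velocity has the exact
Maxwell variance for harmonic forces at any stable timestep — with chain
springs of stiffness 1000 the spring-mode `omega * dt` is about 0.45, where
naive discretizations carry a several-percent kinetic-temperature bias that
would fail an equipartition check. The half-step kinetic energy is reported
alongside each run (`ke_half_mean`). At `gamma = 0` the scheme reduces
exactly to microcanonical velocity Verlet (no noise is drawn), which the
test suite exploits for energy-conservation checks.

All noise comes from R's RNG: `set.seed()` before a run makes the entire
trajectory bit-reproducible, and every experiment records its seeds.

# Initial configurations

`build_initial()` reproduces the study's initialization pipeline:

1. **Confined coil.** Each chain starts as a fixed-step random walk
   generated inside the target shell (steps that would exit are redrawn).
   For `N` much larger than the squared shell radius the walk fills the
   shell quasi-uniformly, which is where the subsequent equilibration
   would end up anyway; starting there makes equilibration local instead
   of requiring the chain to swell across the shell diffusively.
2. **Compaction and equilibration** (`compact_into_shell()`). A harmonic
   wall of stiffness `eps_cut` confines the monomers to a sphere of
   diameter `22.85 * n_chains^(1/3)` (22.85 for one chain, 28.79 for two
   — constant volume per chain, matching interphase nuclear chromatin
   density for the reference 5000-monomer chain; `make_fixture()` rescales
   the shell as `N^(1/3)` so smaller test systems keep the same density).
   Because the starting coil is not self-avoiding, deeply overlapped
   monomer pairs exist at first; a warmup stage at `dt/10` lets them
   resolve gently — at the full timestep the capped potential releases
   their energy impulsively and the system can lock into a self-sustaining
   hot state (the dynamics are bistable in this respect). The wall force is
   clamped during gathering so far-flung monomers drift inward at bounded
   speed, then unclamped to hold the target density.
3. **Deterministic loop extrusion** (`extrude_loops()`), after the
   confinement is released. Each condensin starts with both bonds on the
   monomer at the middle of its future loop; the bonds then step outward
   symmetrically, one monomer per round on each side, with MD relaxation
   between rounds. Each time the extruded loop length reaches a further
   multiple of `L/Cr`, the two springs flanking the bond pair are rewired
   (`crossing_rewire()`): springs `(a-1, a)` and `(b, b+1)` become
   `(a-1, b)` and `(a, b+1)`, reversing the enclosed path segment and
   installing one crossing — a static mimic of a supercoil crossover. Two
   bookkeeping rules keep the result exactly the intended topology: the
   rewire never touches the spring that joins two adjacent loops (on a
   clamped side the pair is pulled in by one monomer instead), so
   consecutive loop bases stay adjacent; and each chain's spring graph
   remains a single Hamiltonian path throughout, which `is_single_path()`
   verifies by traversal. Extrusion relaxation runs at `dt/10` with the
   kinetic temperature rescaled after every round: each rewire reconnects
   a stiffness-1000 spring across a finite gap, and the injected elastic
   energy (of order a thousand kT per crossing) must be drained for the
   emerging configuration to stay thermal.
4. **Anneal.** A short run at `dt/10`, with the confining wall
   re-applied, removes any remaining deep overlaps and drains the elastic
   energy stored by the rewires; production at the full timestep then
   holds the target temperature indefinitely. Re-applying the wall during
   this purely numerical stage keeps the physical post-release expansion
   out of the initialization: the dense released system expands rapidly
   (the osmotic pressure of a 0.4 volume-fraction melt), and letting that
   happen before the report would conflate initialization with the start
   of production.

The returned report records per-chain radius of gyration and asphericity
and, for two chains, the loop-sphere overlap, all describing the system
at the moment the confinement is finally released (the report's `time`
field records when, so alternative conventions — e.g. measuring after
extra free equilibration — remain reproducible).

# Order parameters

* `gyration_tensor()` / `asphericity()`: the covariance tensor of monomer
  positions; with eigenvalues `l1 >= l2 >= l3` (squared principal axes),
  `Rg = sqrt(l1 + l2 + l3)` and asphericity
  `(l1 - (l2 + l3)/2) / (l1 + l2 + l3)`, 0 for a sphere, 1 for a rod.
* `loop_spheres()` / `overlap()`: loop `i`'s region is the sphere at the
  centroid of its `L` monomers with radius the maximum centroid-monomer
  distance; a chromosome's region is the union of its loop spheres, and
  the overlap is the fraction of one chromosome's monomers inside the
  other's region. The headline scalar symmetrizes the two directions
  (their mean); both directional values are returned, since the
  one-directional convention is also in use.
* `attraction_fractions()`: the fraction of condensins with at least one
  partner of another chain (trans) or of their own chain (cis) within
  `Delta`; a condensin may count toward both.
* `segregation_metrics()`: the segregation time is the first time the
  overlap crosses below 0.2, linearly interpolated between samples so the
  value is stable under resampling; the segregation speed is its inverse.
  The trans-decay time is the first sample where the trans fraction is
  exactly zero and stays zero for at least one further sample (a guard
  against single-sample flicker). Series that never cross are *censored*:
  time `NA`, speed 0 — never a fake finite speed.
* `axis_density()`: the condensin axis is approximated by straight
  segments joining every `interval`-th condensin (default 5, i.e. 10
  segments for 50 condensins); each condensin's distance to its own
  segment is histogrammed (default bin width 0.25 sigma) and the profile
  is reported raw and normalized to the origin bin. The axis is only a
  meaningful construct where one forms (intermediate `Delta`), but the
  operation computes for any input.

# Experiments

`run_experiment()` drives the four modes (`init_only`,
`equilibrium_shape`, `segregation`, `axis_density`) over `n_replicates`
independent replicates; replicate `r` derives its seed as
`seed + 7919 (r - 1)`, so every number in an `experiment_result` is
regenerable from the config and master seed alone. Aggregates are
replicate means; censored replicates contribute a speed of zero and their
count is reported. `sweep_experiment()` evaluates a cartesian grid over
`(F_cond, Delta, F_loop)` and labels each point with the attraction-range
branch (`Delta` below or above 2.5), the split at which the
shape-segregation correlation bifurcates in this model family.
Equilibrium values are means over the tail half of the observable series.

# Problem sizes and study conditions

The full-scale reference system (fixture `"reference"`) is two chains of 5000
monomers with 100 loops of 50 and five crossings per loop. Desk-scale
work uses the `"small"` fixture (two chains of 500 monomers, 10 loops of
50, five crossings, shell rescaled to equal density): initial-configuration
builds take well under a minute there, and the package's own test suite
and acceptance script run their dynamics at that scale — production
horizons of 1500 time units for single-chain shape runs and 3000-5000 for
two-chain segregation runs, with 2-3 replicate seeds. These horizons are
the package's desk-scale study conditions, not converged equilibrium
claims: at 500 monomers, segregation of two entangled chains is dominated
by centre-of-mass diffusion (relative diffusion constant `2kT/(N gamma)`),
so overlap decay is slow and runs may end censored; the test suite treats
censoring as data, not failure of the machinery.

# What the generator emulates, and what it does not

The synthetic initial states emulate the geometry the model calls for —
density-matched confinement, consecutive crossed loops, heavy interchain
entanglement — but not sequence heterogeneity, condensin I/II differences,
explicit topoisomerase kinetics, or hydrodynamics, all of which are
outside the model. Passing tests therefore certify the mechanics of the
model and its observables, not biological realism of any particular
chromosome.

# Known limitations

* The flat energy cap makes the force vanish for deeply overlapped pairs;
  configurations that wander inside the cap radius at the full timestep
  can ignite a numerically hot state. The initializer's warmup/anneal
  stages exist precisely to avoid handing such states to production; the
  `wca_cap = "force"` variant (constant-force continuation) is provided
  for comparison because the cap realization affects how fast overlaps
  resolve.
* At literal (kT-scale) condensin force coefficients the attraction is
  inert below `Delta ~ 1` and the condensin-axis cohesion is weak;
  shape differences across `Delta` at desk scale are small compared to
  seed-to-seed scatter. The test suite asserts the directions the model
  does produce and records censored outcomes honestly.
* Initial-configuration statistics depend on exactly when they are
  measured relative to the release of confinement (the post-release state
  expands); the report's timestamp pins the package's convention.
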