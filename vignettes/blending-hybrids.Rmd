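---
title: "Blending-region hybrid simulation of stochastic reaction-diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blending-region hybrid simulation of stochastic reaction-diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blendsim)
```

# The modelling problem

Reaction–diffusion systems in cell and developmental biology are often
multiscale: in part of the domain copy numbers are high and a cheap
deterministic description is adequate, while elsewhere low copy numbers make
stochasticity and particle identity essential. `blendsim` implements three
single-scale engines and couples them pairwise so that each part of the domain
can be simulated at the cheapest adequate resolution:

* **macroscopic** — a concentration field `c(x, t)` obeying
  `dc/dt = d/dx( D(x) dc/dx ) + R(c)` with constant-flux boundary conditions,
  solved by a cell-centred finite-volume scheme;
* **mesoscopic** — well-mixed compartments of width `h` with particles jumping
  between neighbours and reacting within a compartment (the
  reaction–diffusion master equation picture), simulated exactly by the
  Gillespie direct method;
* **microscopic** — off-lattice Brownian particles advanced with a fixed time
  step, with bimolecular reactions by the lambda–rho rule (a pair within
  distance `rho` reacts with a per-step probability `P_lambda`).

The coupling device is a **blending region** `[I1, I2]` in which *both*
neighbouring representations coexist as equivalent descriptions of the same
mass. The macroscopic diffusivity `D` is split as `D = D1(x) + D2(x)` using
complementary blending functions: `D1` equals `D` on the coarse side, decays
monotonically across the blending region (linearly, in the shipped blend:
`beta1(x) = (I2 - x)/(I2 - I1)`), and vanishes on the fine side; `D2` is its
complement. Each engine carries its split diffusivity, and one coupling window
of length `dt` applies the two flow maps in sequence (Lie operator splitting).
Because `D1(I2) = 0` and `D2(I1) = 0`, neither engine transports mass beyond
its own region, and the splitting error is first order in the window length —
a property the test suite verifies directly by composing two PDE operators and
comparing against a single full-`D` solve.

# Keeping the two representations synchronized

**PDE–compartment coupler** (PDE with `D1` on `[a, I2]`, compartments with
`D2` on `[I1, b]`). After the PDE window, every blending compartment count is
overwritten by the integral of the PDE concentration over its `gamma = h/dx`
voxels; these counts are generally non-integer, and the stochastic simulation
algorithm simply uses the real-valued propensities for its waiting times while
events still change counts by integers. After the SSA window, the accumulated
integer count change of each blending compartment is added back to its voxels
uniformly (`delta/(gamma dx)` per voxel). Per-event and per-window mirroring
are algebraically identical because the update is linear in `delta`; the
engine mirrors per window, and `debug = TRUE` asserts the mass agreement after
every window.

**Compartment–Brownian coupler** (compartments with `D1` on `[a, I2]`,
particles with `D2` on `[I1, b]`). Synchronization is at particle level and
*immediate*: when the SSA moves a particle between blending compartments, one
uniformly chosen Brownian particle of the source compartment is displaced by
exactly `±h`, so a later event in the same window sees the post-move
configuration; a jump across the `I1` interface deletes a uniformly chosen
particle or creates one uniformly in `[I1, I1 + h)`. After the Brownian
update, the blending counts are reset from the particle histogram (half-open
bins; a position exactly on a boundary belongs to the right cell). Every one
of these operations conserves the total particle number by construction, which
is why a pure-diffusion run reports *exactly* its initial count at every
output time — an integer invariant, not a statistical one.

**Reactions in the blending region always follow the compartment paradigm**
(the coarser of the two stochastic descriptions there): the PDE's mean-field
reaction term is masked to the pure-PDE voxels, and Brownian-side scalar and
pair reactions act only in the pure-Brownian region. In the
compartment–Brownian coupler a blending reaction creates its Brownian twin
uniformly within the firing compartment or deletes uniformly chosen twins.
A lambda–rho pair straddling `I2` reacts only if *both* partners are in the
pure-Brownian region; otherwise the pair is governed by the blending
compartment's mesoscopic channel. This both-in-region rule is a design choice
to avoid double-counting reactive flux at the interface; it is not forced by
the framework.

# Numerical choices

* **PDE scheme.** Cell-centred finite volume; the face diffusivity is
  evaluated analytically at the face coordinate (the blend is known in closed
  form); theta = 1/2 (Crank–Nicolson) time stepping via a Thomas tridiagonal
  solve. The scheme is unconditionally stable, second order, and conserves
  mass discretely (zero-flux, reaction-free mass drift < 1e-10 relative).
  Boundary fluxes are prescribed at the outer faces (`Ja = D dc/dx` at `a`;
  `Ja = -J` injects mass at rate `J`). Reactions are integrated explicitly
  inside each step; this Lie split leaves an O(`mu dt/2`) relative bias in
  reactive steady states (5e-4 at the default `dt = 1e-4`, `mu = 10`) —
  negligible against the Monte-Carlo scales of the stochastic comparisons.
  Being non-L-stable, Crank–Nicolson rings on discontinuous data if `dt` is
  large relative to `dx^2/D`; the redistribution test refines `dt`
  proportionally to `dx^2`.
* **Jump rates.** The per-particle rate from compartment `i` across a face is
  the engine's diffusivity evaluated at the *shared face*, divided by `h^2`.
  The diffusive limit of this chain is exactly the divergence-form equation,
  so the uniform profile is the equilibrium even under a spatially varying
  blend (the test suite distinguishes this from the incorrect
  centre-evaluated "Fickian hopping" convention, whose equilibrium is not
  uniform), and the rates vanish automatically at the interfaces where the
  split diffusivity is zero.
* **Brownian update.** Drift-corrected Euler–Maruyama:
  `y <- y + dt * dD2/dx + sqrt(2 D2(y) dt) * xi` with the diffusivity
  evaluated at the pre-move position and coordinate-wise independent noise in
  3D. The drift term is what makes divergence-form diffusion — and hence the
  uniform equilibrium — the Fokker–Planck limit of the update; its omission or
  sign error is the single most common coupling mistake, and the suite checks
  the uniform equilibrium under the linear blend directly. At the blend's
  kinks (`I1`, `I2`) the one-sided derivative from inside the blending region
  is used; the choice matters only on a measure-zero set but is fixed for
  reproducibility. Rare finite-time-step crossings of `I1` are reflected back
  (`y -> 2 I1 - y`) and tallied in the state's `reflections` field.
* **Propensity floors.** Blending counts can transiently be negative (an SSA
  removal from a compartment holding fractional synchronized mass). All
  propensities are computed from `max(C, 0)` — including the pair channel,
  where flooring the *count* rather than the product `C (C-1)` matters,
  because `C (C-1) > 0` for negative `C`. The next synchronization restores
  consistency.
* **Exact exponential decay.** First-order Brownian removal uses
  `1 - exp(-mu dt)` rather than `mu dt`, removing an O(`dt`) bias at no cost.
* **Pair search.** All-pairs distance check, randomised processing order, a
  consumed particle is ineligible for further pairs in the same step. At the
  population sizes of the built-in problems (tens of particles in the pure
  Brownian region) the O(N^2) scan is far from the bottleneck.
* **Random numbers.** Every stochastic draw — SSA waiting times and event
  selection, particle selection for mirroring, Gaussian increments, Poisson
  production, pair ordering — comes from R's global RNG, so `set.seed()`
  determines a run completely; ensemble repeat `m` uses `seed + m`.

# The built-in test problems

The four problem generators are first-class, tested code: they *are* the study
conditions, not tunable fixtures.

| problem | domain | dynamics | defaults |
|---|---|---|---|
| `uniform` | `[0,1]`, interfaces 1/3, 2/3 | pure diffusion from the uniform steady state | `N = 1000`, `D = 1`, `h = 1/30`, `dx = 1/300`, `dt = 1e-4`, `M = 500` |
| `redistribution` | same | pure diffusion, all mass initially uniform on `[0, 1/3]` | as above |
| `morphogen` | same | decay `mu = 10` everywhere, boundary influx `D J = 1e4` at `x = 0`, started uniform at `D J / mu` | `M = 1000` |
| `bimolecular3d` | `[0,10] x [0,1] x [0,1]`, interfaces 10/3, 20/3 | production `k2 = 89.7`, pair annihilation `k1 = 0.1` (`rho = 0.06`, `P_lambda = 2.5e-5`), linear initial profile `c(x) = (183 - 18x)/2` (465 particles) | `h_x = 1/3`, `M = 500` |

The morphogen parameters balance influx against degradation so the expected
population is 1000 throughout; with the steady-mass uniform start the analytic
total is *exactly* `D J / mu` at every time. The boundary influx is realised
mesoscopically as a zeroth-order channel of rate `D J` in the leftmost
compartment.

**Initialization.** Deterministic components are set exactly to the initial
profile. Stochastic components receive integer particle numbers apportioned to
the expected region masses by largest remainder, with positions drawn from the
normalised profile (inverse-CDF sampling for the linear profile). In blending
regions the finer representation is sampled first and the coarser matched:
particle positions are binned to seed the blending counts in the
compartment–Brownian coupler, while the PDE–compartment coupler synchronises
its (non-integer) blending counts from the exactly-initialized PDE. Each
repeat thus starts with exactly its apportioned total; the package does not
Poisson-distribute initial counts, which affects ensemble variances slightly
but no means.

**References and diagnostics.** For the first three problems the reference is
the analytic solution: a cosine eigenfunction series for the diffusion
problems (truncated when the next amplitude falls below 1e-12, and
cross-checked in the tests against an independent explicit finite-difference
solver) and, for the morphogen problem, the `cosh` steady profile plus a
cosine transient decaying at rates `mu + D n^2 pi^2`. The region diagnostic is
the relative mass error `(hybrid - reference)/reference` per region
(pure-coarse, blending, pure-fine) and output time. The bimolecular problem
has no exact mean-field reference — the `-k1 c^2` term follows from a Poisson
moment closure that the stochastic model does not satisfy — so its ground
truth is an ensemble of the finest-scale engine, and `moment_closure_gap()`
quantifies the systematic PDE-vs-mesoscale discrepancy itself (about 3–4% at
the default conditions, with the stochastic mean sitting above the mean-field
density).

# Problem sizes used by the tests

The shipped suite runs ensembles of `M = 100` repeats for the relative-mass
-error checks (the full study conditions use `M = 500` or `M = 1000`; at
`M = 100` the Monte-Carlo 3-sigma band on a region RME is about 2–3%, so the
0.05 assertion threshold is meaningful and not noise-limited), `M = 500` for
the moment-closure comparison, and reduced particle counts or durations for
the pure property checks (e.g. 1e4 lattice particles for the mean-squared
-displacement law, 8e3–1e4 Brownian particles for the uniform-equilibrium
drift check). The acceptance script re-runs the morphogen hybrid at `M = 100`
and the moment-closure comparison at `M = 500` from scratch.

# What the generators do and do not emulate

The built-in problems exercise high interface flux (redistribution), reactions
across all three placements (morphogen), dimension > 1 and second-order
kinetics (bimolecular) — the coupling machinery itself. They do not emulate
curved or moving interfaces, multiple species, crowding/volume exclusion, or
concentration-dependent diffusivity; passing tests say nothing about those
regimes. Two further limitations are worth stating plainly:

* The mesoscopic pair rate `k1` and the microscopic pair `(rho, P_lambda)`
  are configured independently and the package applies no compartment-size or
  time-step correction to either. At the bimolecular defaults the lambda–rho
  parameters realise a much weaker well-mixed rate than the mesoscopic
  channel (under the standard reaction-limited matching
  `k ~ (P_lambda/dt) (4/3) pi rho^3`, about three orders of magnitude
  weaker), so in a compartment–Brownian run of that problem the pure-Brownian
  region equilibrates to a visibly higher density than the compartment
  region. Users coupling second-order kinetics across the mesoscopic/
  microscopic interface should choose the two parameterizations to match the
  same macroscopic rate.
* The 3D path meshes the PDE along `x` only (one cell across the unit
  cross-section) and blends along `x` only. This is exact for the
  y,z-invariant built-in geometry; general 3D tensor grids and non-planar
  interfaces are out of scope.

# Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `D` | length^2/time | 1 | macroscopic diffusivity, split by the blend |
| `I1`, `I2` | length | 1/3, 2/3 | blending-region boundaries |
| `h` | length | 1/30 | compartment width; jump rates scale as `D/h^2` |
| `dx` | length | 1/300 | PDE voxel width; `h/dx` must be integer |
| `dt_p`, `dt_b` | time | 1e-4 | coupling window = PDE/Brownian step |
| `mu` | 1/time | problem | first-order decay |
| `k2` | particles/(volume time) | problem | zeroth-order production |
| `k1` | volume/(particles time) | problem | mesoscopic pair annihilation |
| `rho`, `P_lambda` | length, — | problem | microscopic pair rule |
| `repeats`, `seed` | — | problem | ensemble size; repeat `m` uses `seed + m` |

Shrinking `h` below the scale where blending compartments hold O(1) particles
degrades the real-valued-count approximation in the PDE–compartment coupler —
but a blending region with so little mass is itself a sign that the PDE side
of the coupling is the wrong model there.
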