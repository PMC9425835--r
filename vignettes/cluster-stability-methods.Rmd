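---
title: "Methods: phase reduction and cluster stability on torus lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase reduction and cluster stability on torus lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `torusphase` computes, the assumptions behind
each step, the numerical choices that matter, and what the package's tests
do and do not establish about real inhibitory networks.

## The model chain

The package analyzes an `m × n` lattice of identical, intrinsically
oscillating inhibitory neurons with periodic boundary conditions. Each cell
is a conductance-based Wang–Buzsáki interneuron: fast sodium (activation
instantaneous at `m_inf(V)`, inactivation `h`), delayed-rectifier potassium
(`n`), leak, and a first-order synaptic gate `s` that activates steeply when
the presynaptic voltage rises (`alpha_0 / (1 + exp(-V/5))`) and decays with
`tau_inh = 2` ms. Cells couple through inhibitory synaptic currents
`g_syn (V_i - V_syn) * sum_j W_ij s_j` with reversal `V_syn = -75` mV, below
rest. All parameters and defaults are in `wb_params()`; at the default
applied current `I_app = 0.4` µA/cm² the isolated cell fires tonically with
period `T ≈ 50.06` ms. The temperature factor on the gating kinetics is 1
here, which is why the period is several times longer than in fast-spiking
applications of the same model; all results are expressed in phase and are
insensitive to this overall time scale.

Because the synaptic conductance is small relative to the intrinsic
currents, the network is treated as weakly coupled and reduced to one phase
per cell:

```
dtheta_ij/dt = Omega + epsilon * sum_{(p,q) in S} w_pq H(theta_{i+p,j+q} - theta_ij)
```

with `Omega = 2*pi/T` and the interaction function

```
H(psi) = (1/T) * integral_0^T  Z(t) . G[X(t), X(t + psi/Omega)] dt,
```

where `X(t)` is the periodic orbit, `Z(t)` the adjoint (infinitesimal phase
response, normalized so the period mean of `Z.F` is 1), and `G` the coupling
field. The stencil `S` holds the 12 offsets of `coupling_stencil()`: four
nearest neighbors (`h1`, `v1`), four diagonal (`d`), four second-nearest
(`h2`, `v2`), all with torus wraparound.

**Scale convention.** We take `epsilon = g_syn`, put the connection weight
(dimensionless) and the `1/C` factor inside `G`, and use unit weight when
tabulating `H`. This makes `H` independent of `g_syn`; all sign, ratio and
threshold results downstream are invariant to this choice, and only the
absolute magnitudes of `H` depend on it.

## Computing the orbit, the adjoint, and H

`find_limit_cycle()` integrates the single cell (deSolve `lsoda`, relative
tolerance 1e-8, absolute 1e-10 — the downstream quantities are derivatives
of an integral of the adjoint, which is second-derivative-sensitive, so the
integrator is run well below the target accuracy) through a 1500 ms
transient, then iterates the Poincaré return map of the section "upward
crossing of V = 0 mV", which also fixes the phase origin. Each crossing time
is polished by Newton iteration on `V(t)` (the section residual converges to
~1e-12 mV), and the return map is iterated until successive periods agree to
1e-8 relative. The orbit is then resampled at `n_grid = 1024` uniform
phases. The phase origin is arbitrary: `H` depends only on phase
differences, so any fixed section gives the same analysis.

`compute_adjoint()` solves `dZ/dt = -DF(X(t))^T Z` backward in time; the
directions stable forward in time decay backward, leaving the unique
periodic adjoint. The orbit between samples is evaluated by periodic cubic
splines. Convergence is declared when the normalized adjoint changes by
less than 1e-7 (sup norm, relative) between consecutive periods; the floor
of this residual is set by the orbit interpolation error, which is why the
tolerance is not pushed lower at moderate grids. `DF` is the analytic 4×4
Jacobian (the synaptic gate is part of the single-cell system); it is tested
against finite differences. The removable singularities of the sodium and
potassium activation rates at V = -35 and -34 mV are evaluated by series
expansion when the denominator is below 1e-7.

`interaction_function()` evaluates the `H` integral with the trapezoid rule,
which on a uniform periodic grid is simply the grid mean — for periodic
integrands this converges faster than any polynomial order, so the 1024-point
grid is far more accurate than the finite differences applied afterwards.
The argument convention is presynaptic phase minus postsynaptic phase.
Derivatives use central finite differences with periodic wrap
(`if_derivative()`), the odd part is formed grid-exactly by index reversal
(`odd_part()`), and downstream consumers evaluate the tables by periodic
linear interpolation (`if_eval()`). With the default parameters the
derivative of the odd part is negative at phase 0 (synchrony-destabilizing,
as expected for synapses that arrive with a small effective delay) and
positive in a band around pi; its sign structure is what drives every
stability result.

## Cluster solutions and their stability

`enumerate_solutions()` lists all phase-locked states with constant phase
steps: `psi_h = 2*pi*l_h/p_h` between horizontal neighbors (`p_h` dividing
`n`, `l_h` coprime) and similarly vertically; the network splits into
`p = lcm(p_h, p_v)` equal clusters. Per direction the admissible steps are
exactly the `n` multiples of `2*pi/n`, so an `m × n` torus has `m*n`
solutions, counting mirrored diagonal variants as distinct.

Linearizing the phase model about such a solution gives a block-circulant
Jacobian whose eigenvalues come in closed form, indexed by lattice
wavenumbers `(j, k)`:

```
Re lambda_jk = - sum_{(p,q) in S} w_pq H'(p psi_h + q psi_v)
               * (1 - cos(2*pi*(j*p/n + k*q/m)))
```

`eigen_real_parts()` implements this general (possibly asymmetric-weight)
form; for symmetric weights the paired offsets combine through
`H'(x) + H'(-x) = 2 H'_odd(x)`, recovering the symmetric-case expression —
a reduction verified numerically in the tests rather than assumed. The
`(0,0)` mode is always zero (uniform phase shift); `classify()` calls a
solution stable when every other mode is below `-tol`, with
`tol = 1e-9 * max(1, c)` absorbing roundoff, and "marginal" when a nonzero
mode sits inside the band. The coupling strength `epsilon > 0` scales all
eigenvalues and never changes a verdict, so the module works with
`epsilon = 1`.

Two structural details: (i) on small lattices stencil offsets can coincide
(on a 4-torus, +2 and -2 reach the same site); their weights are summed, as
the modular arithmetic implies, and `build_connectivity()` warns. (ii) An
offset that wraps onto the cell itself (possible when `n` or `m` is at most
2) is self-coupling and cancels out of the linearization; it is excluded
from the effective rate `c`.

The closed form is not trusted on faith: `jacobian_oracle()` assembles the
dense `N × N` linearization entry by entry and the test suite checks, over
200 randomized lattices, solutions, weights and smooth interaction
functions, that its full spectrum matches the closed form as a multiset to
1e-8, along with the trace identity, the neutral mode, and the
direction-swap symmetry.

Two derived quantities get dedicated functions because they summarize the
interesting physics: `diagonal_destabilization_ratio()` returns
`-H'_odd(pi) / (2 H'_odd(0))`, the critical ratio of diagonal to nearest
weight at which the anti-phase diagonal stripe loses stability (about 7.5
for the default cell), and `horizontal_stripe_condition()` evaluates the
necessary condition `2 d H'_odd(psi_v) + h1 H'_odd(0) > 0` for
horizontal-stripe stability — necessary only, so the full grid is still the
verdict.

## Biophysical verification

`simulate_biophysical()` integrates the full `4N`-dimensional network
(vectorized `lsoda`, relative tolerance 1e-6), with spikes detected as
upward crossings of 0 mV and interpolated in time, and
`init_from_pattern()` starts each cell on the single-cell orbit at its
pattern phase. `empirical_phases()` reads per-cell phases back from the
spike trains over the last five firing periods, relative to the first cell;
the sign convention (a cell firing earlier than the reference has a larger
oscillator phase) matches the initialization, so an undisturbed pattern
reads back as itself. `matches_pattern()` compares fields up to a single
global phase shift with a per-site circular tolerance corresponding to 2 ms
of the firing period.

`is_empirically_stable()` is the perturb-and-relax protocol: settle for
200 ms, add a transient extra current to a fixed pseudo-random half of the
cells for 100 ms, relax for 2700 ms, compare. The amplitude of this probe
deserves emphasis. A large pulse (a few percent of `I_app`) reliably throws
the network into *another* coexisting attractor — that is exactly how the
switching demonstrations work (`inst/scripts/switching_demo.R`) — because
with strong diagonal coupling the basins of the many coexisting cluster
states become narrow. Local stability therefore has to be probed gently:
the default `delta_I = 0.002` µA/cm² (1/200 of the driving current, two
firing periods long) displaces phases by a few hundredths of a radian,
small enough to stay inside the basin of every solution the eigenvalues
declare stable, yet large enough that a linearly unstable mode grows to
detection level within the relaxation window (an instability with rate
`epsilon * |Re lambda| ~ 0.004`/ms e-folds every ~250 ms, amplifying the
probe a thousandfold before readout). A cell that falls silent during
relaxation — strong reorganized inhibition can suppress cells — counts as
"pattern not maintained".

One subtlety matters for threshold measurements such as the critical
diagonal weight. As the diagonal coupling grows, many attractors coexist and
the stripe's basin becomes anisotropic: whether one small pulse is
reabsorbed depends on *which* cells it hit. Empirically, at diagonal weights
well above the phase-model threshold some probe directions still return to
the stripe while others escape, so a single probe samples the basin's
angular measure once and a bisection built on it inherits that randomness.
`is_empirically_stable(n_probes = 5)` therefore repeats the protocol with
five independent pseudo-random subsets and takes the majority verdict; the
bisection over the diagonal weight then asks for the point where most small
perturbation directions stop being reabsorbed, which is reproducible across
seeds to a few percent.

The alternating-phase 4-cluster state (`alternating_phase_field()`), whose
phase steps alternate between +pi/2 and -pi/2, is not a constant-step
solution and has no closed-form verdict; it is handled purely empirically,
as a simulation template.

## Problem sizes and runtimes

The shipped analyses use the 1024-point phase grid, 4×4 and 6×6 lattices,
3-second network simulations, and bisection to 0.1 in the diagonal weight:
sizes at which the full acceptance analysis (phase reduction, both stability
tables, the biophysical bisection and the 4×4 pattern survey) completes in a
few minutes on one core. Larger lattices only grow the simulation cost
linearly in `N` per step; the closed-form analysis is effectively free at
any size a discrete-lattice question would use.

## What the tests do and do not show

The synthetic ingredients are analytic interaction functions (`sin`, `-sin`,
and a two-harmonic function with the biophysical sign structure) and
randomized smooth trigonometric `H'` tables; they exercise the algebra
(enumeration, eigenvalues, classification) independently of the ODE
pipeline. The biophysical runs use identical cells, noiseless dynamics,
homogeneous weights and exact pattern initialization. Consequently the
green suite shows that the closed-form analysis is internally correct and
that its predictions survive in the full conductance-based model under
small perturbations — it does not show robustness to heterogeneous cell
parameters, synaptic noise, conduction delays, or sparse random
connectivity, none of which are modeled. Within the weak-coupling
assumption, agreement between the phase model and the biophysical network
degrades as `g_syn * d` grows; empirically the biophysical destabilization
threshold of the diagonal stripe sits within ten percent of the phase-model
prediction even at diagonal weights where the total coupling is no longer
small.

## Known limitations

- Stability of the alternating-phase 4-cluster and of non-uniform 2-cluster
  states is empirical only; no closed form is provided.
- The general asymmetric-weight eigenvalue formula is exposed and oracle-
  tested, but no asymmetric-weight phenomenology is studied.
- `cluster_partition()` uses a greedy circular-distance grouping adequate
  for analytic and near-converged fields, not a general clustering method.
- The perturb-and-relax verdict depends on the probe staying inside the
  (possibly narrow) basin; near a threshold the returned bisection point
  inherits a few-percent uncertainty from the choice of perturbed subset.
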