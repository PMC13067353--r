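---
title: "Hydration-coupled proton transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-coupled proton transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonpath)
```

`protonpath` analyses proton transfer through hydrated protein channels in
collective-variable (CV) space. This vignette is the package's account of
the science behind each stage: the CVs and their conventions, the model
free-energy surface and sampler that generate all test data, the estimators
(WHAM, block averaging, metadynamics bias inversion), the minimum
free-energy path (MFEP) extraction, and the numerical choices made where the
design was genuinely open. No empirical claim is made here beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## Pathway construction

The transfer pathway is an ordered set of `n_nodes` (default 25) equidistant
3D nodes through the channel. `fit_principal_curve()` implements an
iterative projection/local-averaging principal curve: initialise along the
first principal component, project all water-oxygen positions onto the
current polyline (ties between segments resolved toward the lower segment
index, for determinism), smooth each coordinate against projected arc length
with a *local-linear* Gaussian kernel (bandwidth = `smoothing` x total arc
length, default 0.10 — local-linear rather than local-constant because the
latter shrinks the curve ends toward the cloud centroid), resample to
equidistant nodes, and iterate until the mean node displacement falls below
`tol`. The variant and bandwidth are deliberately exposed: principal-curve
fits are not unique, and 10 % of the arc length is a conventional
middle-of-the-road bandwidth — small enough to follow a curved channel,
large enough to not chase individual hydration shells.

`resample_equidistant()` places nodes at equal arc steps and then iterates a
chord-length reparameterisation to a fixed point, because on a curved
polyline equal *arc* steps give slightly unequal straight-line (chord)
spacings while the node container guarantees chord equidistance to 1e-6
relative. On straight or uniformly curved polylines the two coincide and the
iteration is a no-op.

Node indices are 1-based throughout (idiomatic R). The path frame — which
node is the origin `xi* = 0` and which direction counts positive — is user
metadata (`set_path_frame()`), never inferred: the anchoring residue is a
modelling decision, not a property of the geometry.

## Collective variables

**Occupancy.** Each node's water occupancy sums the rational switching
function `sigma(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` over water oxygens
(defaults `r0 = 2.5` Angstrom, `n = 6`, `m = 12`; the removable singularity
at `r = r0` is evaluated by its limit `n/m`). Two numerical choices matter:

* The sum is *softly* capped at 1 with the softmin
  `x - log(1 + exp(k (x - 1)))/k`, `k = 20`, keeping the CV differentiable
  everywhere. The cap costs `log(2)/k ~ 0.035` exactly at saturation, so a
  node with precisely one water at its centre reads 0.965, not 1.000.
* The switching function is truncated at `switch_dmax` (default `2.5 r0`)
  with the usual shift-and-rescale, so it is exactly 0 beyond the cutoff.
  Without a finite cutoff no node pair could ever reach occupancy 0 and the
  connectivity could never report a genuinely broken wire.

**Connectivity.** `water_wire_connectivity()` is the geometric mean of the
pair averages `f_{i,i+1} = (o_i + o_{i+1})/2`, computed in log space; any
zero pair gives exactly 0. The geometric mean is the right aggregator for a
serial process: it is dominated by the weakest link, bounded by the
arithmetic mean, and monotone in every occupancy (both properties are
tested on 1000 random profiles). The localised `phi*` weights each pair by
`exp(-d^2 / (2 sigma_loc^2))` with `d` the probe-to-pair-midpoint distance;
`sigma_loc` defaults to 3 Angstrom — about three node spacings, wide enough
to span the hydrogen-bond partners of the hydronium, narrow enough that
hydration changes a channel-length away do not move the CV. As
`sigma_loc -> Inf` the weights flatten and `phi* -> phi` (tested).

**Path progress.** The geometric path CV is

    xi' = i1 + sign(i2 - i1) *
          ( sqrt((v1.v3)^2 - |v3|^2 (|v1|^2 - |v2|^2)) - v1.v3 - |v3|^2 )
          / (2 |v3|^2)

with `i1` the node closest to the excess-charge probe, `i2` the *adjacent*
node nearer the probe, `v1` the vector from the probe to node `i1`, `v3`
from node `i1` to node `i2`, and `v2` from the node on the opposite side of
`i2` (linearly extrapolated as a virtual node at the path termini) to the
probe. Restricting `i2` to a neighbour of `i1` — rather than the globally
second-closest node, which on a strongly curved path may not be adjacent —
is what guarantees continuity of `xi'` as the probe crosses the mid-plane
between nodes; the discriminant is clamped at 0 against round-off at exact
node hits, and equidistant `i1` candidates tie-break to the lower index.
The tests verify the symbolic values (probe at node j gives `xi' = j`,
mid-point gives `j + 1/2`), invariance under perpendicular displacement and
rigid motions, continuity along scans, and agreement with the signed
arc-length projection on straight paths to 1e-6. `xi* = (xi' - origin) x
spacing x orientation` rescales to Angstrom-comparable units.

## The synthetic model surface

All pipeline tests run on a closed-form 2D surface `F(xi, phi)`
(`make_surface()`), in kcal/mol:

    F = dG * s(u) + A * b(u) * (1 + c (phi - phi_min(xi))^2)
        + kappa_phi (phi - phi_min(xi))^2 + wall terms,   u = (xi - xi_R)/(xi_P - xi_R)

* `s(u)` is a clamped quintic smoothstep carrying the reaction free energy
  `dG` with zero slope and curvature at both basins.
* `b(u) = u^2 (1-u)^2 exp(beta2 u) / norm` is the barrier bump, peaked
  exactly at the requested saddle position `xi_S` (via `beta2`), *not*
  clamped outside `[0, 1]`: its quartic growth confines the dynamics and
  gives both minima genuine quadratic curvature. The amplitude `A` is solved
  numerically (1D root find) so the maximum of the channel-floor profile
  equals `dF` exactly; with the harmonic phi term vanishing on the floor,
  the declared stationary free energies (0, `dF`, `dG`) are exact, which the
  constructor verifies numerically.
* `phi_min(xi)` interpolates the floor hydration `phi_R -> phi_S -> phi_P`
  with a smoothstep plus a C2 cubic-edged bump, so leaving the hydrated
  valley costs `kappa_phi` (default 50 kcal/mol per phi^2) and the barrier
  itself grows when phi deviates from the floor (coupling `c`, default 2).
  This reproduces the coupling signature of interest: along the MFEP, phi
  rises together with xi from the reactant basin to the saddle.

Presets: `"headline"` (dF 17.1, dG 7, basins at phi 0.75/0.90, saddle near
xi = 6 at phi > 0.9), `"recovery"` (dF 6, dG 3 on the same geometry — small
enough that desk-scale sampling crosses the barrier in every window set),
and `"metad1d"` (double well, barrier 4 and tilt 1 kcal/mol, minima at 0.2
and 0.8 of a [0, 1] hydration-like coordinate).

What the generator emulates — and does not. It reproduces the *statistical*
structure the estimators consume: Boltzmann sampling under harmonic
restraints, a coupled two-basin landscape, hill logs from shared-bias
walkers, and hydration frames with a tunable weakly hydrated gap. It has no
explicit solvent, no Grotthuss chemistry, no multi-proton effects, no
protein degrees of freedom, and its hydration channel is harmonic rather
than bistable in phi at fixed xi. Passing tests therefore demonstrate that
the *analysis chain* is correct and self-consistent at stated tolerances;
they say nothing about force fields or sampling adequacy in real systems.

## The sampler

`langevin_sample()` integrates overdamped Langevin dynamics in reduced time
units (friction default 1, timestep default 2e-4) with the temperature kept
physical through `kB T` in kcal/mol (310 K by default, kT = 0.616 kcal/mol).
The integrator is a Strang splitting: half-step Euler drift of the surface
force, an *exact* Ornstein-Uhlenbeck update of the combined harmonic
restraint (including its noise), then the second half-step drift. Treating
the restraint analytically matters: the stiff hydration restraint
(k = 2500 kcal/mol) would need `k dt / gamma << 1` under plain
Euler-Maruyama — at dt = 2e-4 the sampled restraint variance would be inflated
by a third, which propagates directly into the WHAM stitching. With the OU
splitting the harmonic part is sampled without time-step bias at unchanged
cost (verified against `kB T / k` in the tests). phi is kept in [0, 1] by
reflection; a divergence guard errors, naming the step, if xi leaves the
surface domain extended by 50 % of its span.

`run_umbrella_set()` starts each window at the previous window's final point
(the probe is dragged along the path) and jumps the restrained coordinates
to the new centres before sampling; the 2D preset uses 130 windows (13 xi*
centres spanning the basins x 10 phi* centres over [0.65, 0.965]) with
force constants 10 (xi*) and 2500 (phi*) kcal/mol, the 1D preset 24 windows
at k = 20. `run_metadynamics()` runs multiple walkers (defaults: hills of
height 0.6 kcal/mol and width 0.02 every 1000 steps, bias factor 35, 8
walkers) that refresh their private view of the shared bias every 100 steps
— hills deposited by other walkers within the current sharing interval are
invisible until the next refresh, mirroring file-mediated sharing. The bias
and its gradient are accumulated on a dense grid (O(1) force evaluation);
well-tempered heights use the walker's own current bias at the deposition
point. With an infinite bias factor the scaling reduces to standard
metadynamics (constant heights).

`sample_boltzmann_1d()` draws *exact* (inverse-CDF, grid-resolved) samples
from a biased Boltzmann density; it exists so estimator tests do not inherit
the integrator's statistics.

## Free-energy estimators

`wham()` solves the binned self-consistent WHAM equations (bin centres,
half-open bins; the bias of each window evaluated at bin centres) by direct
iteration, vectorised as one matrix-vector product per sweep, to
`max |delta f_k| < 1e-7` kcal/mol (default; `max_iter = 1e5`, with an error
reporting the residual on non-convergence). Unsampled bins are masked,
never interpolated or zero-filled. Window connectivity is checked through
shared sampled bins (an error names the disconnected windows) and thin
overlaps (< 10 pooled counts with the best neighbour) warn. Statistical
inefficiency weighting is deliberately absent: the convergence protocol is
block averaging, not autocorrelation modelling.

`block_averaged_wham()` splits every window into `n_blocks` equal time
blocks, runs WHAM per block, and averages the last `keep_last` min-shifted
block PMFs bin-wise (8/4 for the 2D protocol, 6/3 for 1D), reporting the
per-bin standard error across retained blocks. Discarding the early blocks
removes the window-equilibration transient; the drift test constructs a
deliberately mis-sampled first half and checks the retained average tracks
the equilibrated reference while the early blocks do not.

`metad_free_energy()` inverts the accumulated bias,
`F = -(gamma/(gamma-1)) V`, on a grid. Because the instantaneous bias
oscillates around the free energy with amplitude of order the hill height
(at bias factor 35 and a ~4 kcal/mol landscape the tempering is weak —
heights only decay by ~20 %), the inversion estimate is averaged over the
deposition history from `average_from = 0.5` onward, implemented exactly as
a per-hill weight. This stays within bias inversion — no sample reweighting
is involved — and halves the seed-to-seed scatter of well free-energy
differences in the tests.

## MFEP and rates

`find_mfep()` uses the min-max (lowest-saddle) criterion: among all paths on
the 8-connected graph of *sampled* bins, minimise the maximum free energy
encountered, tie-broken by the minimal path integral of F. It is computed
exactly in two Dijkstra sweeps (bottleneck metric, then sum metric
restricted to bins at or below the bottleneck level) — unlike string-method
local optimisation this is deterministic, has no initialisation or step-size
parameters, and is checkable against enumeration oracles on small grids
(tested, including a local-optimality audit: no single-bin perturbation
lowers the path maximum). The bin path is smoothed by a width-3 moving
average for reporting; `project_profile()` collapses the path onto the xi*
axis taking the per-bin *minimum* F — so hairpin stretches where the path
doubles back in xi* keep the branch a barrier reading would follow.
`barrier_and_dg()` reads `dF` (interior maximum minus reactant minimum),
`dG` and the reverse barrier `dF - dG` off the profile, erroring on
barrierless profiles. Basin regions are specified in both coordinates: the
anchor is the minimum-F bin inside the region, and keeping the region tight
around the known basin hydration limits the extreme-value bias of taking a
minimum over many noisy bins.

`tst_rate()` evaluates `k = (kB T / h) exp(-dF / (R T))` with CODATA-2018
constants pinned in `pt_constants` (`R = 1.987204e-3` kcal/(mol K)), so
rates are bit-reproducible; `convert_energy()` converts exactly between
meV, eV, kcal/mol, kJ/mol and kB T at a stated temperature
(1 eV = 23.060548 kcal/mol). Forward and reverse rates satisfy
`k_f / k_r = exp(-dG / RT)` by construction.

## Problem sizes and tolerances

The shipped tests and the acceptance script run at desk scale, sizes chosen
so each stage's statistical error is several times smaller than the
tolerance it is tested at: 2e5 steps per umbrella window (130 windows,
stride 20, 8/4 block averaging; recovers dF = 6 and dG = 3 within +/- 0.5
kcal/mol across seeds), 8e5 steps per metadynamics walker (8 walkers, ~6400
hills; well positions within one 0.03-wide bin, well dF within 0.4
kcal/mol), 3e4 exact samples per WHAM oracle window (RMS < 0.2 kcal/mol
against the analytic double well), and 1e6-step unbiased runs for the
Boltzmann-consistency check (KL < 0.01). WHAM grids use 70 x 50 bins over
xi* in [-0.75, 9.75] and phi* in [0.5, 1.0] — xi bins of 0.15 Angstrom keep
the discretisation error of the projected barrier below ~0.05 kcal/mol.

## Known limitations

* The MFEP criterion is the lowest saddle on a grid graph; on very noisy
  PMFs the min over crossing corridors biases barriers slightly downward
  and basin minima downward (mitigated, not removed, by tight basin regions
  and block averaging).
* Metadynamics reconstruction is bias inversion only; reweighting-based
  estimators (and their better error properties near basin edges) are out
  of scope.
* WHAM is binned; no MBAR-style binless generalisation, no grids beyond 2D.
* The occupancy cap makes `phi = 1` unreachable by ~0.035 at full
  saturation; comparisons of near-saturated wires should use the raw
  (uncapped) occupancies if absolute saturation matters.
* Minimum-image distances are applied only when a box is supplied, and only
  for orthorhombic boxes.
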