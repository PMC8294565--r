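---
title: "Modelling chestnut gall wasp biocontrol: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chestnut gall wasp biocontrol: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torysim)
```

## The biological system and its model

*Dryocosmus kuriphilus* (Asian chestnut gall wasp) is a thelytokous pest:
all-female, parthenogenetic, laying up to `N_d` eggs per female inside
chestnut buds over a summer season of length `T_d` days, with adults
living only `a` days.  Its larvae overwinter inside the buds; a fraction
`eta` survives to emerge as adults the following summer.  The univoltine
parasitoid *Torymus sinensis* flies in early spring, before the pest, and
lays its eggs (up to `N_t` per female over its adult life `T_t`) in the
pest larvae of the previous season; parasitized larvae never emerge.
Because the parasitoid reproduces sexually, at most half of its eggs
become females, so its overwintering survival satisfies `gamma < 0.5`.

Each year is therefore two consecutive initial-value problems:

* **Parasitoid phase** (`t` in `[0, eta*tau]`, nondimensional): females
  `p` deplete the stock of host larvae `v_prev - q`, accumulating eggs
  `q`.  The pair `(p, q)` obeys `p' = -(1/tau)(v_prev - q) p`,
  `q' = (E_t/tau)(v_prev - q) p`, so `q + E_t p` is conserved — a useful
  exactness check.
* **Gall wasp phase** (`t` in `[0, 1]`): survivors emerge at the constant
  flux `c = v_prev - q_end`, deplete the habitat's free buds, and the egg
  field `v` saturates towards the carrying scale 1.

Densities are nondimensionalized by the habitat egg capacity
`V_max = M * beta_max` (about `1e7` eggs/ha for mature orchards), which
makes `v = 1e-7` the density of a single insect per hectare — the
conventional local-extinction threshold, scaled by area via
`egg_capacity_and_threshold()`.

The spatial variant adds Fickian dispersal of the *adult* stages only
(`delta * Lap(p)` and `Lap(u)`; eggs are immobile), with the diffusivity
ratio `delta = D_t/D_d < 1` encoding the pest's superior dispersal.  The
unit of length is `sqrt(D_d * T_d)`.  With the default Portugal constants
this is 5.96 km, so the reference 4 x 4 domain is roughly 24 km across;
summaries of this system sometimes quote ~5.5 km per unit, a discrepancy
we document but do not adopt, since it does not follow from the stated
constants.

## Parameters that matter

| parameter | meaning | default | unit |
|---|---|---|---|
| `eta`   | pest overwintering survival | user choice (0.65–0.85) | fraction |
| `gamma` | parasitoid overwintering survival | 0.47 | fraction |
| `N_d`, `N_t` | fecundities | 150, 71 | eggs/female |
| `T_d`, `a` | pest season and adult lifespan | 40, 4 | days |
| `M`, `beta_max` | eggs/bud, bud density | 5, 2e6 | –, buds/ha |
| `D_d`, `D_t` | diffusivities | 0.889, 0.016 | km²/day |

Derived: `mu = T_d/a = 10`, `E_d = eta*N_d`, `E_t = gamma*N_t = 33.37`,
`delta = 0.018`.  By default the two species' seasons are taken equal
(`T_t = T_d`), which reduces `tau = T_t/(eta*T_d)` to `1/eta` and makes
the parasitoid phase exactly one time unit long; the general form is used
whenever `T_t` is supplied.

`gamma` is tightly constrained (0.45–0.5 by observed parasitism and the
sexual-reproduction bound), while `eta` is the genuinely uncertain knob:
lower values mean more natural parasitism of the pest.  The package
treats `eta` as a required argument for exactly this reason.

## Numerical scheme: why the parasitoid phase carries three states

The interesting regimes of this system hinge on *residuals of
near-complete parasitism*.  In a suppression season nearly every host
larva is parasitized, and next year's pest cohort is the tiny remainder
`r = v_prev - q`.  Two naive implementations fail:

* integrating `(p, q)` and forming `r` by subtraction loses `r` to
  catastrophic cancellation as soon as `r < 1e-16 * v_prev`, and any
  solver whose error norm is dominated by the O(1) component `p` floors
  `r` near `rtol * v_prev` long before that;
* integrating `(p, r)` alone recovers `r` perfectly but loses `q` in the
  opposite regime (scarce parasitoids, `q` tens of decades below
  `v_prev`).

The homogeneous engine therefore integrates `(p, q, r)` simultaneously
(`q' = E_t w`, `r' = -E_t w`, `w = r p / tau`), so each tail is a state
of its own and is tracked in *relative* error.  Phases use `lsoda` with
`rtol = 1e-8` and `atol = 1e-60`: the in-season dynamics are linear in
amplitude, so the tiny absolute tolerance is safe, and it keeps
post-crash densities meaningful down to the `1e-50` scale and below.
End-of-season values agree with a fixed-step 4th-order Runge–Kutta oracle
at `dt = 1e-5` to `1e-8` relative, and with closed forms in the `E_d -> 0`
limit (`u(t) = (c/2mu)(1 - exp(-2 mu t))`).

A consequence worth stating plainly: **density minima reported by this
package are deeper than those of implementations whose solvers floor the
parasitism residual.**  With `eta = 0.65` the pest falls below the
extinction threshold two seasons after the parasitoid passes density 0.1
— a residual floor of order `1e-3 * v_prev` would report three — and the
30-year pest minimum at `eta = 0.85` is `~5e-17` rather than `~1e-9`.
Likewise the 300-year parasitoid minima reach `1e-60`–`1e-80` depending
on `eta`, not `1e-30`–`1e-50`.  Below roughly `1e-7` none of these values
are biologically meaningful (a real population is long extinct); what
matters is that they are properties of the equations, not of the solver.
The acceptance tests encode the literature's printed values for these
quantities and are allowed to fail where exact integration disagrees;
the test comments say so explicitly.

## Spatial discretization

The reaction–diffusion system is semi-discretized on a regular
cell-centered grid (default `h = 0.05`, comfortably below the 0.1 at
which the parasitoid wave is still resolved) with the 5-point Laplacian;
zero-flux boundaries enter by ghost-cell reflection, which keeps the
operator exactly conservative (its sum vanishes for any field — asserted
in the tests, together with the O(h²) convergence of the Neumann cosine
eigenpair).  Time stepping per phase uses `lsodes`, the sparse
stiff solver, driving a compiled C right-hand side; tolerances are
`rtol = 1e-6`, `atol = 1e-12`, since spatially the minima of interest are
around `1e-6`–`1e-4` and the `1e-50` machinery of the homogeneous engine
is unnecessary.  Two structural checks gate the PDE code: spatially
uniform runs reproduce the homogeneous engine to `1e-6` at every node,
and halving `h` from 0.1 to 0.05 moves probe values of `log10(v)` by
less than 0.2 in the corner-release experiment.

Releases place adult density `amplitude` (default 1) on the single grid
cell nearest each station, additive and clipped at 1.  The released
*mass* then scales with `h²`, which is the natural reading of "seed one
location" but makes the experiment resolution-dependent; for
grid-convergence work a fixed-radius disc footprint
(`footprint = 0.1`) is provided, and the convergence test uses it.
Footprint choice shifts probe minima by factors of a few (single cell at
`h = 0.05` releases mass 0.0025; the 0.1-radius disc about 0.0075), so
spatial minima should be read at order-of-magnitude precision.

In the lattice-release experiments (`grid_release_layout()`: stations at
the `(k+1)²` vertices of a regular lattice, spacings 4, 2, 4/3, 1 on the
4 x 4 domain) many synchronized fronts meet, spatial asynchrony is lost,
and local minima of `v` approach the homogeneous model's deep crashes —
far below `1e-6`, and at strongly symmetric probe points below the
spatial solver's own resolution.  A reported floor of `1e-6` in such
experiments is again characteristic of an absolute-tolerance-limited
solver rather than of the model.  The corner-release minimum at the probe
(`~2e-4`) is robust, because a single asynchronous wave genuinely lets
the pest recolonize.

## Scenario and diagnostic conventions

* Year numbering: the first release happens at the start of season 1;
  outputs are labelled by seasons since that release.  Timed re-release
  (`n_r`) and periodic (`k_r`) schedules count in the same frame, so
  gap- and minimum-based summaries are invariant to the label origin.
* `time_to_suppression()` uses strict first crossings of end-of-season
  values: establishment at `q > 0.1`, local extinction at `v < 1e-7`
  (both overridable).
* "Implantation" is a run of seasons with `v > 0.9` (near carrying
  scale) occurring after the first suppression; the 0.9 level is a
  package convention, exposed as a parameter, since the term is usually
  left verbal.  Re-release experiments are best compared with
  `implantation_runs()` at the probe.
* The 1% infestation level that makes re-releases effective is read as
  pest egg density `v > 1e-2` at the monitoring point.
* `front_radius_series()` quantifies the radially expanding suppression
  wave as the median distance, over radial transects, at which `v` first
  rises through 0.5 moving outward from the release point; it is
  undefined before local suppression and after a front leaves the domain.
* `cycle_periods()` detects peaks of `log10 v` above `1e-2` and reports
  peak-to-peak intervals; plateaus at saturation collapse to one peak.

## Problem sizes and run times

The reference experiments are 300-year homogeneous runs (well under a
second each) and 35-season spatial runs on the 4 x 4 domain at
`h = 0.05` (6400 cells, 12800 equations per phase; about a minute each
on one core).  These sizes were chosen because the homogeneous cycles
need a few centuries to show their slow modulation, while 35 seasons
cover the full first sweep-and-recolonization cycle of the spatial
system.

## What the scenarios do and do not emulate

The generators reproduce idealized study conditions: uniform full
infestation (`v = 1` everywhere), trace or unit-amplitude point releases,
homogeneous habitat, constant parameters.  Real orchards have patchy bud
density, temperature-driven phenology, refugia that shelter a handful of
galls during crashes, and demographic stochasticity at low density —
none of which are modelled.  Passing tests therefore demonstrate
fidelity to the deterministic model, not predictive accuracy at
densities anywhere near the extinction threshold; any practitioner
should read sub-threshold dynamics simply as "local extinction happened
here".

## Known limitations

* Deterministic only: no demographic noise, no refugia; the deep-crash
  densities are mathematical bookkeeping, not populations.
* Homogeneous habitat: no GIS landscapes, advection, or unstructured
  meshes; domains are rectangles with zero-flux edges.
* Parameters are constant within and across seasons; `eta` and `gamma`
  are inputs, not estimated from field data.
* The released amount at a station is a density amplitude, not an
  individual count; comparisons with field release protocols need the
  `V_max` scaling.
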