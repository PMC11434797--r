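---
title: "Coupling tableting reduced-order models to dry-granulation attributes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling tableting reduced-order models to dry-granulation attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabletrom)
```

## The problem

Dry granulation (roller compaction followed by milling) is used to improve
the flowability of pharmaceutical blends before tableting. The price is a
loss of tabletability: the plastic work imparted while forming the ribbon
reduces the granules' capacity to bond during the main compression. In a
continuous line the roller-compactor settings therefore propagate into every
tablet critical quality attribute (CQA): weight, relative density, and
tensile strength, and into critical process parameters (CPPs) such as the
main-compression punch force.

`tabletrom` implements a family of semi-mechanistic tableting reduced-order
models (ROMs) whose parameters are *coupled* to two upstream material
attributes — the ribbon relative density $\rho_{ribbon}$ and the granule
size distribution (GSD) — through normalized bivariate rational functions.
The package covers the full workflow: the base ROMs, the rational-surface
library, automated model selection by AIC, constrained global estimation,
Monte Carlo uncertainty propagation, and a synthetic campaign generator for
parameter-recovery studies.

## Base models

Tablets are made with a doubly convex tool (diameter $D$, cup depth $h$).
The enclosed volume at punch separation $t$ is
$\pi D^2 t/4 + (\pi h/6)(3D^2/4 + h^2)$; during die filling, with the die
open at the top, half the two-cap term applies. Relative densities are
$\rho = W/(\rho_t V)$ with $W$ the weight and $\rho_t$ the true
(pycnometric) density. Tensile strength of a convex tablet is obtained from
its diametral breaking force $F$ through the Pitt relation
(`tensile_strength_pitt()`).

The four stages of compaction are modelled as:

* **Die filling / weight.** $W = \phi(X_w, Y_w)\,\rho_t\,\rho_{ribbon}\,V_{fill}$,
  where $\phi$ is the packing fraction of the granule bed. For a bimodal
  GSD the covariates are $X_w = (1-\alpha)(1-\mu_1^3/\mu_2^3)$ and
  $Y_w = \alpha$ ($\alpha$ the small-mode fraction, $\mu_i$ the mode
  means), and
  $\phi = p_4 (q_2 X_w + 1) / (q_1 X_w Y_w + q_2 X_w + 1)$ with $p_4$ the
  unimodal packing fraction and $q_1 < 0$, so that $\phi \ge p_4$. The form
  extends the Brouwers analytical packing fraction for bimodal hard spheres
  (`brouwers_packing()`), which the package keeps as a qualitative
  reference oracle.
* **Compaction.** A Kawakita-type force model with explicit jamming
  density:
  $F_{punch} = \pi D^2(\rho_{in\text{-}die}-\rho_c) /
  [4b(\rho_{in\text{-}die}(a-1)+\rho_c)]$. Parameter $a$ is the total
  compressibility, $b$ a pressure scale, $\rho_c$ the critical (jamming)
  in-die relative density.
* **Unloading.** Elastic recovery
  $\epsilon_\rho = \epsilon_0[(\rho_{in\text{-}die}-\rho_{c,\epsilon})/(1-\rho_{c,\epsilon})]^n$
  and out-of-die density $\rho_{tablet} = \rho_{in\text{-}die}(1-\epsilon_\rho)$.
* **Strength.** Leuenberger-type
  $\sigma_t = \sigma_0[1 - \frac{1-\rho_{tablet}}{1-\rho_{c,\sigma}}e^{\rho_{tablet}-\rho_{c,\sigma}}]$.
  The printed form of this model is typographically ambiguous about whether
  the exponential multiplies the porosity ratio; only the grouping used
  here satisfies both boundary facts ($\sigma_t = 0$ at $\rho_{c,\sigma}$
  and $\sigma_t = \sigma_0$ at $\rho_{tablet} = 1$), so that grouping is
  adopted.

## The coupling

Each coupled parameter $\xi \in \{a, \rho_c, \epsilon_0, \rho_{c,\epsilon},
\sigma_0, \rho_{c,\sigma}\}$ is modelled as a normalized bivariate rational
function
$$f(X, Y) = \frac{p_1 XY + p_2 X + p_3 Y + p_4}{q_1 XY + q_2 X + q_3 Y + 1},$$
of covariates mapped from physical bounds onto $[0, \infty)$ by
$X = [(x - lb)/(ub - x)]^{r}$. The bounds are physical: the ribbon density
lives in $(\rho_{c,rib}, 1)$, where $\rho_{c,rib} = 0.566$ is the smallest
density at which a ribbon forms; the mean granule size lives in $(0, D/6)$,
one sixth of the die diameter being the conventional upper limit for proper
die filling; for the strength model the second covariate is the packing
fraction normalized between $\phi_{min}$ and $\phi_{max}$. The corner
values of $f$ are interpretable ($f(0,0) = p_4$, $f(\infty,\infty) =
p_1/q_1$, …) and the package evaluates infinite covariates by explicit
limit algebra (`eval_surface()`, `surface_limit()`) rather than
floating-point overflow; a limit that depends on the approach path (possible
only outside the constrained library) signals an error instead of returning
an arbitrary value.

Nine constrained variants of $f$ (progressively zeroing coefficient pairs
and/or pinning $r_X = r_Y = 1$) generate a 25-pair model library
(`model_library()`): matched pairs $(v,v)$, constant-second pairs $(v,9)$,
and constant-first pairs $(9,w)$. A pair's two surfaces share their
exponents; the exponents count as free parameters unless both members pin
them. `n_parameters()` reproduces the resulting bookkeeping (e.g. 9 for
the force pair $(7,7)$ plus $b$; 7 for the recovery pair $(4,9)$ plus $n$;
16 for the strength pair $(1,1)$).

## Parameters and defaults

| Quantity | Symbol | Default | Units |
|---|---|---|---|
| Die diameter | $D$ | 7.94 | mm |
| Cup depth | $h$ | 0.3302 | mm |
| True density | $\rho_t$ | 1.558 | g/cc |
| Critical ribbon density | $\rho_{c,rib}$ | 0.566 | — |
| Packing normalization bounds | $\phi_{min}, \phi_{max}$ | 0.367, 0.631 | — |
| Weight noise (per tablet) | RSD | 1.6 | % |
| Observation noise (force, density, strength) | RSD | 2 | % |
| Monte Carlo sample count | — | 10{,}000 | draws |
| Critical-density floor | $\bar\rho_c$ | 0.3 | — |

The full fitted reference parameter set ships as a versioned YAML
configuration (`reference_parameters()`); the packing interaction
coefficient is stored with its negative sign, where published summaries
report its magnitude. Exponents are constrained to $(0, 10]$, surface
coefficients to be positive where the per-attribute constraint sets demand
it, and the recovery surfaces obey the order constraints $0 < p_i < q_i$
(with $q_4 = 1$) that keep $\epsilon_0 \in (0,1)$.

## Estimation

`fit_rom()` minimises the sum of squared errors between model predictions
and condition-level campaign observations, with the Akaike information
criterion $AIC = n\ln(SSE/n) + 2N_p$ used by `select_rom()` to rank library
pairs (ascending AIC; ties broken by smaller $N_p$, then pair id). Because
a uniform rescaling of observations and predictions shifts every model's
AIC by the same $n \ln c^2$, the ranking is unit-invariant — a property the
test suite asserts directly.

The search runs in three stages, honouring the
global-then-local-then-multistart contract: (1) a real-coded genetic
algorithm over the box constraints, Latin-hypercube initialised; (2) local
refinement of the surviving elites (Nelder-Mead simplex followed by bounded
Levenberg-Marquardt); (3) multi-start Levenberg-Marquardt polishing from
fresh Latin-hypercube points plus jittered restarts, finished by a
valley-descent loop that alternates simplex and Levenberg-Marquardt passes
until the objective stops improving. Over-parameterized pairs (the
16-parameter strength pair especially) produce long curved valleys in the
SSE landscape that defeat any single local pass; the alternation walks
them. For attribute/pair combinations without a shared scalar constant the
optimizer additionally seeds itself by *profiling*: the two base-model
parameters are fitted batch by batch (well-conditioned two-parameter
problems), and surface coefficients reproducing those per-batch targets are
then obtained exactly by a singular-value decomposition of the defining
linear relation, with a one-dimensional null-space line search favouring
sign-feasible solutions.

Nonlinear data-dependent feasibility predicates (e.g.
$\rho_{in\text{-}die} > \rho_c$ and
$\rho_{in\text{-}die}(a-1)+\rho_c > 0$ at every observation) are enforced
by rejection: the reported SSE of an infeasible parameter vector is
infinite. Internally the stages minimise a graded-penalty version of the
same objective so that the population stage retains gradient information
near the feasible boundary. All optimizer randomness is governed by a
single seed; identical seeds give bitwise-identical fits.

Fitting proceeds per attribute in the order weight, force, recovery,
strength. Two pieces of information flow along that order: the fitted
packing bounds feed the strength covariate $Z$, and the force model's
minimum fitted jamming density over the batches provides $\bar\rho_c$, the
floor of the recovery onset density ($\rho_{c,\epsilon} > \bar\rho_c$ —
elastic recovery cannot begin below jamming). The second chaining matters
in practice: without it the onset density is nearly non-identifiable from
campaign data, because its SSE profile is almost flat against compensating
changes in $\epsilon_0$ and $n$ over the experimentally accessible density
range.

`fit_rom()` fits condition-level means with $n$ equal to the number of
conditions. Per-tablet records carry no extra information about the mean
model under the independent noise assumption, and condition counts keep
$AIC$ penalties comparable across attributes.

## The synthetic campaign generator

`simulate_campaign()` emulates a steady-state tableting campaign: for each
condition it draws per-tablet weights from a normal distribution with the
model-chain mean and a 1.6% relative standard deviation, pushes each draw
through the coupled chain at fixed in-die thickness, applies independent
2% multiplicative observation noise to force, out-of-die density and
strength, and back-computes thickness and hardness records through the
inverse volume and Pitt relations so the table looks like raw tablet-tester
output. The default campaign is 6 granule batches × 4 conditions × 100
tablets.

Condition setpoints are model-guided: the main-compression thickness is
evenly spaced across each batch's printed operating window, while the
dosing position is solved from the weight model to hit evenly spaced
target in-die densities (0.74–0.92) and clipped to the press's 6–14 mm
dosing range. A naive pairing of window extremes is corner-infeasible — for
the wider dosing windows it implies in-die relative densities above 1 —
so the generator reproduces the *procedure* used to design such campaigns
(model-guided selection of safe setpoints) rather than a grid no press
could run.

What the generator does *not* emulate: feed-frame segregation, press
dynamics and startup transients, strain-rate (turret-speed) effects,
tooling wear, ejection forces, and measurement drift. Passing
parameter-recovery tests on these synthetic campaigns therefore
demonstrates that the estimation machinery is unbiased and well-seeded
under the stated noise model — not that the reference models describe any
particular press beyond the data they were derived from.

## Numerical choices and degenerate inputs

* Normalization rejects inputs below the lower bound (domain error) and at
  or above the upper bound (a distinct overflow condition), since the two
  violations mean different things in process terms.
* Below-onset states return zero elastic recovery (with a message) rather
  than a complex power.
* A zero SSE yields $AIC = -\infty$ with a warning — a perfect fit ranks
  first but is flagged.
* Monte Carlo draws violating a model precondition (non-positive weight,
  density at or beyond a critical bound, incoherent tablet) are rejected
  and counted; the rejection fraction is reported and is far below 1e-6 at
  the default noise level.
* Ranking ties are broken by parameter count, then lexicographic pair id,
  so reports are reproducible.

## Known limitations

* The recovery onset density is identifiable only through the
  jamming-consistency constraint described above; reported onset values
  inherit the force model's accuracy.
* The base ROMs were developed for elasto-plastic excipient-dominated
  formulations (microcrystalline cellulose with a small API fraction);
  brittle excipients would need different base models even though the
  coupling machinery would carry over.
* The library is bivariate by construction. A third upstream attribute
  would require replacing the surface family, not just extending bounds.
* Printed mode means for the two lowest-pressure reference batches are
  inconsistent with the gamma-function mean of their own Weibull
  parameters; the package always recomputes means from the parameters and
  keeps the printed values as metadata only.

## A worked pass through the chain

```{r chain, eval = FALSE}
library(tabletrom)

conditions <- campaign_conditions()          # 6 batches x 4 conditions
chain <- predict_tablet_cqas(conditions)     # deterministic model chain

campaign <- simulate_campaign(conditions, tablets_per_condition = 100,
                              seed = 11)     # 2400 synthetic tablets
obs <- summarize_campaign(campaign)          # condition-level observables

fit_w <- fit_rom(obs, "weight", seed = 2)
fit_f <- fit_rom(obs, "force", pair = c(7, 7), seed = 2)
rho_bar <- min(fitted_surface_values(fit_f)$rho_c)
fit_r <- fit_rom(obs, "recovery", pair = c(4, 9),
                 constraints = rom_constraints(rho_bar_c = rho_bar),
                 seed = 2)
fit_s <- fit_rom(obs, "strength", pair = c(1, 1), seed = 2)

propagate_uncertainty(conditions[1, ], n_samples = 10000, seed = 42)
```

The test suite runs exactly this workflow (at these problem sizes) and
checks that the refitted surfaces reproduce the generating parameter
surfaces at all six batches — within 1% from noise-free campaigns and
within 5% at the default noise model.
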