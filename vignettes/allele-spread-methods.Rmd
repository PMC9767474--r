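---
title: "Modeling the spatiotemporal spread of a beneficial allele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the spatiotemporal spread of a beneficial allele}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`allelewave` infers how a recently selected allele spread across a landscape
from geolocated, time-stamped genotypes — typically a mixture of
low-coverage ancient genomes and high-coverage present-day panels. The
population-genetic process is summarized by a deterministic
diffusion–advection–reaction PDE for the allele frequency surface
$p(x, y, t)$:

$$\frac{\partial p}{\partial t}
  = \tfrac{1}{2}\sigma_x^2 \frac{\partial^2 p}{\partial x^2}
  + \tfrac{1}{2}\sigma_y^2 \frac{\partial^2 p}{\partial y^2}
  + v_x \frac{\partial p}{\partial x}
  + v_y \frac{\partial p}{\partial y}
  + \gamma(p, s, d),$$

with the local growth term

$$\gamma(p, s, d) = p(1 - p)\bigl(pd + s(1 - 2p)\bigr),$$

the selection coefficient $s$, and the dominance coefficient $d$. All
analyses default to additivity, $d = 2s$, under which $\gamma$ reduces to
logistic growth $s\,p(1-p)$ and the equation is the classical
Fisher–KPP wave-of-advance model with anisotropic dispersal and directional
transport. Three nested variants are exposed: model A (isotropic diffusion,
$\sigma_x = \sigma_y$, no advection), model B (distinct longitudinal and
latitudinal diffusion), and model C (model B plus advection $v_x, v_y$).
Advection absorbs net directional population movement — e.g. large
migrations — that symmetric diffusion cannot represent.

The landscape is a plate-carrée grid (default 1°) over a bounding box
(default 30–75°N, 10°W–80°E), with cell metric geometry (east–west width,
north–south height, area) from haversine distances on a 6371-km sphere.
Cells with negative elevation in the input topography raster are water:
internal zero-flux boundaries across which the frequency cannot diffuse.
User-configurable land bridges (defaults connect Great Britain and
Sardinia/Corsica to the mainland) re-open dispersal paths that a coarse
raster would close. The outer map frame is absorbing ($p = 0$ ghost
cells), so frequency mass can exit the study box.

Time is measured in generations (29 years by default) since the allele's
origin. The allele age is an *input*, not an estimated parameter: age and
selection intensity trade off along a ridge, so the method conditions on an
externally estimated age and, if desired, profiles the likelihood over a
set of candidate ages (`profile_allele_age()`). The initial condition is a
single point mass $p_0 = 1/(2DA)$ in the origin cell — one chromosome
among the $2DA$ present in a cell of area $A$ at population density $D$
(default 2.5 individuals/km²). All spread parameters may change once, at an
epoch boundary (default 5000 years BP), reflecting the shift in mobility
around the Bronze Age; the two epochs are fitted jointly against a single
PDE solution, not as two separate fits.

## Observation model

Each individual $i$ contributes one of three evidence types at the focal
locus, evaluated against $p_i = p(x_i, y_i, t_i)$:

* **Genotype likelihoods** (beagle-style triplets over 0/1/2 copies of the
  derived allele, computed upstream by e.g. ANGSD):
  $L_i = \sum_{h=0}^{2} \mathrm{GL}_i[h]\,\Pr[g = h \mid p_i]$, with the
  Hardy–Weinberg binomial prior $\Pr[g = h \mid p] = \binom{2}{h}p^h(1-p)^{2-h}$.
  Unnormalized triplets only shift the log-likelihood by a constant and are
  accepted.
* **Hard diploid genotypes** (present-day panels): the degenerate triplet.
* **Pseudohaploid calls** (a single randomly sampled allele, the standard
  representation of low-coverage ancient DNA): a Bernoulli($p$) likelihood
  for the derived call — the marginal of binomial genotype sampling
  followed by fair single-read sampling.

Individuals are independent given the surface, so the data log-likelihood
is the sum over observations. An observation with exactly zero likelihood
(e.g. a derived pseudohaploid call where the model says $p = 0$)
contributes a floor of $\log 10^{-300}$ with a warning instead of $-\infty$,
so the optimizer can move away from impossible parameter regions; computing
genotype likelihoods from raw reads is out of scope.

## Numerics

**Discretization.** Method of lines on land cells only. Diffusion uses
second-order central differences in flux (finite-volume) form: the
north/south face fluxes carry the ratio of the shared face width to the
cell's own width, so area-weighted mass is conserved *exactly* on the
latitude-dependent metric (the naive Laplacian leaks mass at the per-mille
level over hundreds of generations, which the test suite would catch).
Advection uses first-order upwind differences for stability. A water face
contributes zero flux (mirror ghost); a face on the outer frame drains
against a $p=0$ ghost.

**Integration.** Two interchangeable integrators, validated against each
other:

* `method = "dopri"` (default): adaptive Dormand–Prince 5(4) with
  error-per-step control, relative tolerance $10^{-6}$ and absolute
  $10^{-8}$ by default. At 1° resolution the semi-discrete system is only
  mildly stiff (the diffusion stability step is a few generations at
  $\sigma^2 = 100$ km²/gen), so an error-controlled explicit method is both
  accurate and fast. The zero-dispersal limit reproduces the logistic
  closed form to $<10^{-4}$ relative error over 500 generations.
* `method = "adi"`: Peaceman–Rachford alternating-direction implicit
  stepping with Strang-split reaction (the additive-case reaction substep
  is the exact logistic map). Unconditionally stable with cost independent
  of $\sigma^2$ — the right tool when the dispersal bound is interpreted on
  $\sigma$ rather than $\sigma^2$ (below), where stability would force the
  explicit method to thousands of steps. Splitting error is $O(\Delta t^2)$;
  at $\Delta t = 0.5$–1 generation it agrees with the adaptive solver to
  $\sim 10^{-4}$ absolute in $p$, far below the sampling noise of any
  dataset fitted here. The first 20 generations are substepped 8× to
  resolve the point-mass initial condition.

Solutions are clipped to $[0,1]$ after integration; the pre-clip excursion
is retained as a diagnostic and stays below $10^{-3}$ in all tested
scenarios. Internally, time and rates can be non-dimensionalized by a
common factor (historically ×10 for speed in this class of models); results
are invariant to this rescaling and the suite tests that invariance.
Sample times interpolate the stored surface linearly in time; the storage
grid (default every 5 generations) contributes interpolation error that
shrinks quadratically and is tested to be $\lesssim 10^{-3}$ in $p$.

**Why not an off-the-shelf ODE solver.** The original approach in this
literature used LSODA. No stiff ODE library is available in this
environment, so the integrators are implemented in compiled code inside the
package and validated against closed forms (logistic growth, stencil
oracles, conservation, symmetry, A/B/C nesting) rather than against another
solver.

## Parameter search

The likelihood of $\theta$ (per-epoch $s$, $\sigma_x^2$, $\sigma_y^2$,
$v_x$, $v_y$, depending on the variant) and a discrete origin cell is
maximized in two layers, as is standard for this rugged, mixed
discrete–continuous surface:

1. **Simulated annealing** from Latin-hypercube starting points (default
   50), each paired with a random origin from a candidate set. Proposals
   are Gaussian (SD = 5% of each bound range, reflected into the box) plus
   occasional origin jumps within the candidate set (probability 0.2).
   Cooling is geometric and reaches $10^{-3}$ of the initial temperature —
   set from the spread of starting log-likelihoods — by the last iteration
   (default 200 per start), so shortened chains still anneal fully. The
   incumbent is the best pair ever evaluated and cannot be worse than the
   best start.
2. **L-BFGS-B** refinement of the continuous parameters with the origin
   held fixed (the origin lives on a discrete grid and cannot be refined by
   a quasi-Newton step). A failed line search returns the incumbent with a
   flag; estimates pinned at a bound are flagged `at_boundary`.

Default box constraints: $s \in [0.001, 0.1]$,
$\sigma^2 \in [1, 100]$ km²/gen per axis, and $v \in [-2.5, 2.5]$ km/gen —
the narrow advection range acts as regularization. 95% confidence intervals
are Wald intervals from the observed Fisher information,
$\hat\theta_j \pm 1.96\sqrt{(F(\hat\theta)^{-1})_{jj}}$, with $F$ the
negative numerical Hessian (symmetrized central differences, relative step
$10^{-3}$). A non-positive-definite $F$ — common when estimates sit on a
bound — yields `NaN` intervals with a warning rather than fabricated ones.
The Hessian treats both epochs jointly, matching the joint likelihood.

Two points were genuinely open and are decided here:

* **$\sigma$ vs $\sigma^2$ bounds.** The dispersal search range
  "1–100 square kilometers per generation" is ambiguous about whether it
  bounds $\sigma$ or $\sigma^2$, given that $\sigma^2$ is what enters the
  PDE. The package default bounds $\sigma^2$ (the literal reading of the
  units). The alternative — bounding $\sigma$ at 1–100 km/gen^½, i.e.
  $\sigma^2$ up to $10^4$ — is exposed via `parameter_bounds(sigma2 =
  c(1, 1e4))`. The individual-based validation experiment (below) *requires*
  the wide interpretation: its realized allele dispersal, dominated by
  mate choice over a 250-km radius, is several thousand km²/gen, and under
  the narrow cap the optimizer distorts selection and origin to compensate.
* **Origin candidates.** The original candidate set of 28 hand-placed
  points is not reconstructible; the default here is a coarse lattice of
  land cells (every 5th row/column), augmented — because inferred origins
  empirically track the earliest appearance of the derived allele — with
  the cells of the five oldest derived-allele observations
  (`augment_origins`). Before annealing, the candidates are screened by a
  single likelihood sweep at a mid-bounds parameter vector and only the
  best few are explored (`screen_origins`/`screen_keep`); after
  refinement, a discrete polish pass walks the origin over neighboring
  land cells, re-refining after each accepted move
  (`origin_polish`/`polish_rounds`). Both additions address the one
  failure mode seen in replicate validation — an origin stranded a few
  cells off, which the continuous layers cannot repair because the origin
  is frozen during quasi-Newton refinement. All are user-overridable.

## Synthetic data

Two generators, both first-class and tested:

* **Deterministic-surface sampling** (`sample_from_surface()`): genotypes
  drawn Binomial(2, $p$) from a solved surface at designed locations and
  ages — uniform over land ("homogeneous") or over centrally restricted
  sub-boxes covering 50% / 20% of each bbox axis ("intermediate" /
  "extreme"; the original study's exact polygons are unpublished, so the
  central-fraction convention is fixed here once), with an ancient/recent
  quota across the epoch boundary (e.g. 75%/25%) and log-uniform or uniform
  ages within each side. This emulates aggregation of ancient-DNA
  compilations with uneven spatial and temporal sampling. What it does
  *not* emulate: genetic drift, spatial autocorrelation of genotypes
  beyond what the smooth surface induces, and dating error. A green
  parameter-recovery test therefore establishes self-consistency of
  inference under the model, not robustness to model misspecification.
* **An individual-based forward simulator** (`forward_simulate()`),
  emulating the published SLiM/slendr experiment: non-overlapping
  generations at fixed population size, additive fitness $1, 1+s, 1+2s$
  acting through both parents (mothers sampled with fitness-weighted
  probability; mates drawn within a 250-km radius, also
  fitness-weighted — weighting only one parental pathway would halve the
  realized selection relative to the $\gamma = s\,p(1-p)$ reaction term,
  a defect the panmictic-limit check in the test suite guards against),
  offspring displaced from the mother by an isotropic Gaussian (SD 25 km)
  and re-drawn if they land on water, and a single beneficial copy
  introduced in one individual (default: Central Europe, taken as
  50°N 10°E, 15,000 years BP, $s = 0.03$).
  Population regulation — which SLiM delegates to spatial competition — is
  emulated by sampling each offspring's mother with weight proportional to
  fitness divided by the local population density within the interaction
  radius; the global size is exactly constant. Allele loss is reported and
  retried with derived seeds, i.e. runs condition on establishment. This
  is documented as an emulation, not a SLiM re-implementation:
  conditional on spatial clustering the crowding weights are not exactly
  genotype-blind, and the mating kernel is uniform-in-disk rather than any
  particular SLiM interaction function.

A consequence of radius-based mate choice worth stating: an offspring's
*paternal* allele jumps, on average, tens of kilometers per generation
(uniform within 250 km), so the realized allele dispersal in this
experiment is far larger than the 25-km offspring dispersal alone — which
is why the wide dispersal bound is needed when fitting it.

When fitting the forward simulation, the founder density $D$ entering
$p_0 = 1/(2DA)$ is set to the simulation's actual density
($N$ / land area) rather than the 2.5/km² used for empirical human data:
for a simulated world the true density is known, and using it removes an
artificial four-order-of-magnitude establishment lag from the initial
condition. The recovered selection
coefficient then centers on the true value (slightly below it in
replicate runs), whereas fitting with a density far below the simulated
population's true density inflates the estimate by tens of percent —
the deterministic PDE absorbs the artificial establishment lag into
selection intensity. Published analogues of this experiment report a
moderately inflated recovery, consistent with that mechanism.

## Scaled-down validation settings

The acceptance checks (`scripts/acceptance.R`, `tests/testthat/test-acceptance.R`)
run the full pipelines at reduced *optimizer* effort so the whole suite
fits desk-scale budgets: fewer multistarts and shorter annealing chains
than the 50 × 200 defaults, and the ADI solver for the wide-dispersal fit.
Grid size (45×90 at 1°), sample size (1040), population size (20,000),
and all biological parameters stay at their stated values; only the
config-exposed search-effort knobs are reduced. The model-B recovery
experiment fixes its true parameters once at mid-range values
($s = 0.03/0.015$, $\sigma_x^2 = 20/40$, $\sigma_y^2 = 10/30$ km²/gen,
origin on the candidate lattice, allele age 15,000 years BP) because the
original per-simulation parameter tables are not published in the main
text.

## Known limitations

* The PDE is deterministic: drift, allele surfing, and frequency
  autocorrelation are unmodeled, so parameter uncertainty is understated
  for weakly selected or sparsely sampled alleles.
* Diffusion and advection trade off: very different $(\sigma^2, v)$
  combinations produce near-identical surfaces (tested as a property), so
  individual dispersal parameters should be interpreted through the
  inferred maps, not as point estimates.
* One epoch boundary, axis-aligned anisotropy only, static coastlines,
  single locus; Bayesian fitting and stochastic PDEs are out of scope.
* Wald intervals are asymptotic and undefined at the search bounds.
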