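---
title: "Spatial evolutionary games of plant volatile emission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial evolutionary games of plant volatile emission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(bvocgame)
library(ggplot2)
set.seed(1)
```

## The model

Plants that emit biogenic volatile organic compounds (BVOCs) after herbivore
attack create a public good: the airborne signal primes defenses both in the
emitter's own undamaged tissue and in any neighbor close enough to eavesdrop.
A non-emitting plant — a *cheater* — enjoys the neighborhood benefit without
paying the carbon cost of emission. `bvocgame` implements this public-goods
game in two complementary forms: a stochastic, spatially explicit lattice
model, and a deterministic mean-field ("random distribution") model that
ignores spatial correlation.

Both rest on the same fitness arithmetic. Herbivory removes a fraction $p$ of
seed output; a plant's own signaling scales that damage by the
*intra-communication effect* $\alpha_1 \in (0,1]$, and every emitting
neighbor scales it by a further factor $\alpha_2 \in (0,1)$ (the
*inter-communication effect*). Both are damage multipliers, so *smaller*
values mean *stronger* protection. With $M$ emitting neighbors in signaling
range, the gross inter-communication effect is $\hat\alpha_2 = \alpha_2^M$,
and

$$
f_E = (1 - p\,\alpha_1 \hat\alpha_2)(1 - c)\,\hat f, \qquad
f_N = (1 - p\,\hat\alpha_2)\,\hat f,
$$

where $c$ is the emission cost and $\hat f$ the seed output absent herbivory
and cost. $\hat f$ is a common scale factor of every fitness: it cancels from
the colonization probabilities of the lattice model and from the sign of the
replicator dynamics, so its default of 1 never changes a reported outcome; it
is kept as a parameter for fidelity to the fitness definitions. Herbivory
enters only as this expected multiplicative damage — there is no per-plant
stochastic attack, and no herbivore movement or aggregation.

## The mean-field model

When individuals are placed at random, the number of emitters among the $n$
plants in signaling range is binomial with success probability the global
emitter frequency $x_E$, and the expected damage multiplier has the closed
form

$$
\bar\alpha_2(x_E) = \mathbb{E}\,[\alpha_2^k] = (1 + (\alpha_2 - 1)x_E)^n .
$$

`gross_inter_effect_meanfield()` implements the closed form and
`binomial_gross_inter_oracle()` the explicit sum; a test holds them to
within $10^{-12}$ of each other over random draws. Strategy frequencies then
follow replicator dynamics $dx_E/dt = g(x_E) = x_E\,(f_E - \phi)$ with mean
fitness $\phi = x_E f_E + (1 - x_E) f_N$. Equilibria are $x_E^* \in \{0, 1\}$
plus, when the fitness curves cross inside $(0,1)$, the coexistence
frequency obtained by solving $f_E = f_N$ for $\bar\alpha_2$ and inverting
the closed form. Coexistence requires

$$
\frac{\alpha_2^n p - c}{\alpha_2^n p (1 - c)}
  \;<\; \alpha_1 \;<\; \frac{p - c}{p(1 - c)},
$$

and the upper bound is also the *viability threshold*: above it an isolated
emitter is beaten by an isolated cheater and emission cannot evolve at all.
At the package's focal parameters ($p = 0.4$, $c = 0.1$) the threshold is
$5/6 \approx 0.833$.

```{r ess}
focal <- bvoc_params(alpha1 = 0.5, alpha2 = 0.9, p = 0.4, c = 0.1, n = 8)
ess <- classify_ess(focal)
glance(ess)
autoplot(ess)
```

Stability is labeled from the sign of $dg/dx_E$ at each equilibrium,
estimated by a central finite difference with step $h = 10^{-6}$ (the
analytic band conditions on $\alpha_1$ are used for the regime label, and
the finite-difference check is asserted against them in the tests). The
flow is evaluated through its analytic extension just outside $[0,1]$ so
the central difference is well defined at the boundary equilibria. A
parameter point lying numerically on a band boundary (within $10^{-9}$) is
labeled `marginal` and no stability claim is made; this degenerate set has
measure zero and the neighboring classifications take over on either side.

`integrate_dynamics()` confirms classifications by forward integration
(`deSolve::lsodar`). The state is clipped to $[0,1]$ after each output step
— analytically the flow cannot leave the interval, clipping only guards
round-off — and integration terminates early through a root function once
$|g| < 10^{-13}\max(1,\hat f)$: continuing to integrate a numerically
stationary state for very long horizons destabilizes the solver's step-size
control, and past that point the trajectory is constant by construction.

## The lattice model

The spatial model places plants on an $L \times L$ torus (full scale
$L = 100$). Each site is an emitter, a non-emitter, or vacant. Signaling
acts over the Moore neighborhood (Chebyshev distance) of radius
$r_\mathrm{BVOC}$, seed dispersal over radius $r_D$. One synchronous
generation applies, in order: fitness evaluation at every site; independent
death with probability $d$; and colonization of every vacant site —
including those vacated this step — by a single categorical draw weighted by
the post-death fitness totals of each strategy within dispersal range. A
vacant site with no occupied neighbor in range stays vacant; otherwise the
two colonization probabilities sum to one. Dead plants disperse no seeds in
the step they die (their fitness is zeroed before the dispersal sums), which
resolves the ordering between dispersal and death in favor of the enumerated
update protocol.

Two conventions deserve note. First, the focal plant is *excluded* from its
own emitter count $M$: the benefit of its own signal is exactly what
$\alpha_1$ models, and counting the plant in $M$ would credit that benefit
twice. `count_emitters_in_range()` exposes `include_focal = TRUE` so the
alternative convention can be explored. Second, sites are indexed 1-based in
row-major order, the natural convention for R matrices; the torus metric is
unaffected.

A subtlety worth spelling out is what "neutral" means here. Setting
$\alpha_1 = 1$ and $c = 0$ equalizes the two strategies' fitness *at any one
site*, but it does not make the spatial process label-symmetric: with
$\alpha_2 < 1$, emitters raise the fitness of everyone near them, emitters
are disproportionately near other emitters (limited dispersal grows
monotype clumps from single colonists), and so emitters still spread — a
genuine assortment advantage through the public good, with no cost and no
own-signal benefit. The package's drift-symmetry check therefore also sets
$\alpha_2 = 1$, switching inter-communication off, which makes the two
labels exactly exchangeable; the residual emitter advantage at
$\alpha_2 < 1$ is itself asserted as a property (it is the clustering
mechanism behind the dispersal-range results).

Census timing: frequencies are measured after colonization and before the
next mortality event, so once the population has established the lattice is
(near-)fully occupied at census — colonization is certain wherever an
occupied site is in range, so vacancies are transient. Stochastic extinction
of either strategy is a legitimate outcome of the finite lattice and runs
are never restarted; a run whose population disappears entirely terminates
early with an extinction flag.

```{r lattice, fig.height = 3.5}
cfg <- sim_config(bvoc_params(alpha1 = 0.3, alpha2 = 0.7),
                  L = 50, steps = 1500, seed = 42)
sim <- run_simulation(cfg)
glance(sim)
autoplot(sim)
plot_lattice(sim$final_state)
```

Reproducibility: every run is a pure function of its seed, and the
experiment drivers derive per-replicate seeds from one master seed with
`replicate_seeds()` (a single `sample.int()` draw under the master seed;
replicate $k$ always receives the $k$-th element), so a whole phase diagram
replays bit-identically.

## What the experiments emulate

The synthetic study conditions mirror the model's reference design: herbivory
$p = 0.4$, cost $c = 0.1$, mortality $d = 0.05$, seeding densities
$(0.001, 0.001)$ on a vacant lattice (the asymmetric pairs
$(0.001, 0.0002)$ and $(0.0002, 0.001)$ are available through
`sim_config()`), and $n = 8$ mean-field neighbors, matching the Moore-1
neighborhood size. The full-scale profile ($100 \times 100$, 30,000 steps,
10 replicates per cell) reproduces the published phase diagrams but costs
hours of CPU per diagram; the package's tests and examples therefore use a
scaled desk profile — $L = 50$, 3,000–5,000 steps, 10 replicates, and a
handful of grid cells — which this vignette and the test suite state
explicitly wherever used. At desk scale the *regime structure* (which
strategy wins where, and the direction of every spatial-range effect) is
stable across seeds; individual cell frequencies still carry replicate noise
of a few percent, so reproduction is asserted at the regime/ordering level,
never cell-by-cell.

```{r phase, fig.height = 3.2}
pd <- phase_diagram_meanfield(seq(0.02, 0.98, by = 0.02),
                              seq(0.02, 0.98, by = 0.02),
                              bvoc_params())
plot_phase_diagram(pd, overlay_boundaries = bvoc_params())
```

The lattice counterpart (`phase_diagram_lattice()`) shows the same three
regions — emitters dominant at small $\alpha_1$/large $\alpha_2$, cheaters
dominant above the viability threshold, coexistence between — but the
all-cheater region is reached by *stochastic extinction* of emitters rather
than by a deterministic attractor, and spatial clustering shifts the
boundaries in the emitters' favor relative to the mean-field prediction.

Two range experiments probe the role of space. `range_comparison()`
contrasts signaling radii $r_\mathrm{BVOC} = 1$ vs 2 at fixed dispersal:
widening the signal's reach hands the public good to more cheaters and
depresses emitter frequency. `dispersal_comparison()` runs all four
$(r_\mathrm{BVOC}, r_D)$ combinations: short dispersal clumps emitters into
patches that preferentially help each other. Because the published evidence
for clumping is pictorial, the package adds a *join-count statistic* — the
fraction of same-strategy pairs among occupied rook-adjacent torus pairs —
to make it quantitative; under random labeling of the occupied sites its
expectation is hypergeometric (`join_count_expected()`), and values above
it indicate clumping.

## What passing tests do and do not show

The generator produces idealized data: one species, two discrete strategies,
constant herbivory pressure with no herbivore behavior, no environmental
heterogeneity, no seed-bank or age structure, and exchangeable sites on a
torus. Passing tests show the implementation is faithful to this model and
that the model's qualitative claims (regime structure, range orderings,
drift symmetry) are robust at desk scale — not that real plant populations
behave this way. In real communities BVOC "emission" is a continuum, blends
differ qualitatively, and herbivores move; none of that is modeled.

## Numerical choices

* Neighborhood sums are separable torus convolutions (rows then columns), so
  a generation costs $O(L^2 r)$; a $50\times50\times5000$-step run takes a
  few seconds.
* The neighborhood radius must satisfy $2r + 1 \le L$; larger radii would
  wrap and double-count sites and are rejected.
* Colonization uses one uniform draw per site and per generation; ties
  (`u` exactly at the emitter share) go to the non-emitter, an event of
  probability zero.
* The mean-field phase diagram classifies cells by the closed-form band
  bounds (fast path); `classify_ess()`'s finite-difference stability is
  asserted to agree with the bands in the test suite.
* Boundary parameter values: `alpha1 = 1`, `alpha2 = 1`, `c = 0` and `d = 0`
  are admitted (the strict interior is the model's usual domain) because the
  neutral limit and the frozen-lattice invariant are defined exactly there.
* `interior_equilibrium()` returns `NA` (never raises) when the fitness
  curves do not cross inside $(0,1)$, including the degenerate
  non-positive-radicand case.

## Limitations

The lattice engine is synchronous-update only, as the model prescribes; no
asynchronous variant is provided. The mean-field model is infinite-population
and deterministic — there is no finite-population Moran/Wright–Fisher
counterpart. Sensitivity analyses beyond the $(\alpha_1, \alpha_2)$ plane
(e.g. systematic sweeps of $c$ and $p$) are supported by the API (`p` and
`c` are ordinary parameters) but are not packaged as dedicated experiment
drivers; the monotonicity of the viability threshold in $c$ and $p$ already
implies that low cost and high herbivory favor emission.
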