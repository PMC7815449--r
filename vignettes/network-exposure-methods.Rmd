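---
title: "Methods: network exposure analysis of annotated recommendation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network exposure analysis of annotated recommendation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netexposure)
```

## The problem

Video platforms recommend a handful of "related" videos next to whatever is
playing. Crawling those links breadth-first from a set of start videos — the
top results of a keyword search, or a curated playlist of antivaccine seed
videos — yields a recommendation network whose nodes are videos and whose
edges are recommendation links. Once every video is annotated (vaccine-related
or not; pro- or antivaccine; autism-related; health-related; health
misinformation; source type), one can ask how much of the network surface
around each video is misinformation: does following recommendations pull a
viewer toward antivaccine content?

`netexposure` implements that analysis end to end: network construction and
cleaning, a synthetic crawl generator for testing, descriptive network
statistics, the network exposure model, and case-control odds ratios of
exposure by video type.

## The network exposure model

The core statistic comes from the diffusion-of-innovations literature
(Valente's unweighted formulation). For node $i$ with degree $d_i$ in a simple
undirected graph, and an attribute indicator $y_j \in \{0,1\}$ over nodes, the
exposure of $i$ to the attribute is

$$E_i = \frac{\sum_{j \in N(i)} y_j}{d_i}, \qquad E_i = 0 \text{ when } d_i = 0,$$

the fraction of $i$'s ties leading to attribute-bearing nodes. A node with
four neighbours, three of which carry misinformation, has $E = 3/4 = 0.75$; a
node with four clean neighbours has $E = 0$.

Conventions, chosen because summary tables must be total over all nodes:

* **Isolated nodes** get $E_i = 0$ and count as unexposed, so exposed +
  unexposed = node count for every network.
* **Self-attributes do not count**: a video carrying the attribute itself has
  its exposure defined by its neighbours only (the standard formulation; the
  question is what surrounds a node, not what it is).
* **Unweighted adjacency**: recommendation edges carry no meaningful weights,
  so the pipeline uses the 0/1 adjacency. `network_exposure(weights =)`
  exposes the weighted generalization for other uses.
* Neighbour counts are accumulated as integers and divided once, so the
  conservation identity $\sum_i E_i d_i = \sum_{j: y_j = 1} d_j$ holds exactly
  (it is a property test in the suite).

A node is **exposed** when $E_i > 0$, i.e. at least one neighbour carries the
attribute. `exposure_summary()` reports the mean and sample (n−1) standard
deviation of $E$ over all nodes, the exposed count and percentage, and the
min–max of $E$ over exposed nodes only (the only reading under which a
network whose four exposed nodes all have $E = 1$ reports range 1–1 alongside
a mean of 0.01).

## Case-control odds ratios

For each video type $T$ (nonvaccine, vaccine-related, provaccine,
antivaccine, autism, health, accurate-health, health-misinformation), the
network's nodes are cross-tabulated:

|            | exposed | unexposed |
|------------|---------|-----------|
| type $T$   | $a$     | $b$       |
| all others | $c$     | $d$       |

with the case-control odds ratio $\widehat{OR} = ad/bc$. Zero cells are
reported as 0 or $\infty$, never Haldane-corrected silently.

Three interval methods are provided:

* `woolf_ci()` — the large-sample interval
  $\exp(\ln OR \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$; refuses zero
  cells.
* `exact_ci()` — the primary method. Conditional on all margins, $a$ follows
  Fisher's noncentral hypergeometric distribution with odds parameter
  $\psi$; the equal-tail limits invert $P_\psi(X \ge a) = \alpha/2$ (lower)
  and $P_\psi(X \le a) = \alpha/2$ (upper) by root-finding on $\log\psi$.
  This is the construction usable with zero cells: $a = 0$ yields a lower
  limit of exactly 0 with a finite upper limit. "Cornfield exact" intervals
  in epidemiology software are this construction; it is made the default
  precisely because zero-cell rows carry informative one-sided bounds that
  only the exact inversion produces. A mid-P variant sits behind
  `midp = TRUE` (narrower, not guaranteed to cover).
* `cornfield_ci()` — Cornfield's iterative large-sample approximation to the
  exact limits (margin-preserving fitted cell, continuity correction by
  default), kept as a secondary method flag.

Numerical notes: tails are computed from log-binomial coefficients
(normalized against the maximum) so large margins do not overflow;
root-finding brackets $\log\psi \in [-80, 80]$; the Cornfield quadratic
discriminant is clamped at 0 against catastrophic cancellation at extreme
$\psi$. The test suite checks the exact limits against a grid-search
inversion oracle to $10^{-6}$, against `fisher.test()`'s independent
implementation (loosely — its root tolerance is coarser), and for ≥93%
empirical coverage at $\psi \in \{1, 5\}$ under two-arm binomial sampling.

## The synthetic crawl generator

The platform's real recommendation algorithm is proprietary and
unobservable, so testing rests on a generator that emulates only the
features the analysis depends on:

* **Breadth-first expansion**: `n_seeds` start videos; every video at level
  $k < d$ emits $b$ recommendations. The study design is $b = 6$ (one screen
  of recommendations) and $d = 3$ levels; the two search networks start from
  key-phrase search hits, the conspiracy playlist from 16 seeds, and the
  antivaccine-expert playlist from 8 seeds.
* **Re-attachment**: each recommendation points to a uniformly chosen
  existing video with probability $\rho$, otherwise it creates a new one.
  This is the simplest stand-in for the deduplication-induced shrinkage a
  real crawl shows (observed networks of 283–551 nodes against a no-reuse
  maximum of $6 \cdot (1 + 6 + 36 + 216) = 1554$), and it is what creates
  cross-links and triangles.
* **First-order category homophily**: a new video's category is drawn from a
  row-stochastic transition matrix $H$ conditioned on its parent's category.
  First-order is enough because the exposure statistic is itself first-order
  over edges.

The category space is the partition implied by the annotation scheme:
`provaccine`, `antivaccine`, `autism_nonvax`, `health_accurate`,
`health_misinformation`, `other`.

`preset_scenario()` returns configurations calibrated to the four study
networks. The expected node count is matched by solving
$s(1 + q + q^2 + q^3) = n_{\text{obs}}$ with $q = b(1-\rho)$ for $\rho$
(each recommendation creates a new node with probability $1-\rho$, so
expected new nodes per level form a geometric progression). The transition
matrix is $H = \lambda I + (1-\lambda)\mathbf{1}\pi^\top$ with $\pi$ the
network's annotated category composition: if parents are distributed as
$\pi$, children are too, so the expected composition equals the published
one at every level while parent–child persistence stays tunable through the
homophily weight $\lambda$ (default 0.35 — enough persistence to make
homophily recovery a meaningful test without distorting composition; the
value is a modelling choice, not an estimate). Seed categories follow the
scenario: the two playlist-seeded configurations start from antivaccine
videos, the search configurations from the composition itself. The search
presets use 6 start videos; the study merged the top-6 hits of four key
phrases without reporting the merged start-set size, so the preset treats it
as configurable and defaults to one screenful.

Everything is reproducible from `rng_seed` alone, and the generator restores
the caller's RNG state.

**What the generator does not emulate.** Uniform re-attachment preserves
node counts but not edge counts: simulated seed networks run to average
degree ≈ 4 where the observed networks sit at 2.3–2.4, because a real
crawl's global deduplication collapses recommendation lists more
aggressively than uniform reuse does. Degree distributions, clustering
levels and diameters are therefore only qualitatively comparable, and the
observed descriptive statistics (diameters 8–14, clustering 0.06–0.415) are
plausibility context, not targets. Passing tests show the pipeline computes
its statistics correctly on networks with the study's crawl structure — not
that the generator reproduces the platform's recommendation behaviour.

## Descriptive statistics

* `average_degree()` is $2E/N$, unrounded; report layers round to one
  decimal (283 nodes and 342 edges print as 2.4; 483 and 551 as 2.3).
* `net_diameter()` is the maximum finite shortest-path length. Crawled
  networks can disconnect after cleaning, and the published tables print a
  single finite number, so the diameter is taken over the largest connected
  component (by node count); edgeless graphs report 0.
* `average_clustering()` averages local clustering over all nodes with
  degree < 2 contributing 0 — the convention of the network tool behind the
  published tables. Because that choice is not universal, a flag
  (`include_low_degree = FALSE`) switches to averaging over degree ≥ 2 nodes
  only.

## Annotation-stage utilities

* `recode_stance()` harmonizes annotation batches coded under different
  schemes: vaccine-related videos containing misinformation are recoded as
  antivaccine, remaining vaccine-related videos as provaccine; the rule
  never touches non-vaccine videos or health flags.
* `krippendorff_alpha()` implements nominal-level Krippendorff's alpha via
  the coincidence-matrix formulation, with missing ratings allowed (units
  need at least two pairable values). It is checked against an independent
  pair-enumeration oracle and a hand-computed matrix. Worth knowing: a
  constant coder paired with a random coder does not give $\alpha \approx 0$
  but $\alpha \to -1/3$ — the skewed marginals shrink the expected
  disagreement. Chance-level coding means *independent* coders.
* `systematic_sample()` draws the reliability subsample: interval
  $k = \mathrm{round}(1/f)$, seeded random start, every $k$-th item; a 10%
  sample of 538 items has 53 or 54 items depending on the start.
* `pct()` rounds half-up, not half-even: a 25-of-40 cell must print 63, and
  banker's rounding would print 62. A $10^{-9}$ guard absorbs binary
  representation error in exact .5 ties. Composition tables print integer
  percentages; exposure tables one decimal; mean/SD two decimals.

## Cleaning contract

`build_network()` fixes the network-construction conventions in one place:
repeated video ids collapse to one node; reciprocal and parallel directed
records collapse to one undirected edge (multiplicity kept as `weight`,
minimum crawl level as `depth`, both provenance-only — exposure is
unweighted); self-loops are dropped; videos flagged for language exclusion
are removed, with incident edges, *before* any analysis (the alternative —
excluding after construction — would let excluded videos still carry
exposure through their edges; the earlier point is the defensible one and is
applied uniformly). Node ids are opaque case-sensitive strings. In lenient
mode unannotated endpoints get default annotations with a warning;
`strict = TRUE` upgrades every recoverable problem to an error naming the
offender.

## A worked run

```{r report, eval = FALSE}
nets <- list(
  conspiracy = simulate_crawl(preset_scenario("conspiracy_seed",
                                              rng_seed = 17))$network,
  expert     = simulate_crawl(preset_scenario("expert_seed",
                                              rng_seed = 17))$network
)
bundle <- run_report(nets)                 # exposure to stance=anti
write_report(bundle, "seed_networks")      # CSVs + JSON with conventions
```

The bundle records every convention in effect (CI method, clustering flag,
rounding mode, SD convention) so any printed number can be traced to a
module output.

## Problem sizes and determinism

The test suite runs entirely on generated data: random graphs up to 200
nodes for the exposure oracles, 200 graphs for the conservation law, 50
small tables for the exact-CI inversion oracle, 2,000 seeded replicates per
$\psi$ for coverage, and 50 replicates of the provaccine-search preset for
the composition check. These sizes make the full suite complete in well
under a minute while leaving the Monte-Carlo tolerances (3 binomial SEs, ±3
percentage points) meaningful. All stochastic tests fix their seeds; the
report pipeline itself is deterministic given its inputs.

## Known limitations

* The generator's re-attachment model matches node counts, not edge counts
  (see above); fitted comparisons of degree/clustering against the observed
  networks are out of scope.
* Exposure is structural: it measures what the recommendation graph makes
  adjacent, not what any user watches, and ignores personalization by
  design (the underlying crawl API does not factor in viewing histories).
* Published odds-ratio values for the real networks cannot be reproduced
  because the joint exposed-by-type counts were never published; the
  case-control machinery is validated against oracles and coverage instead.
* GEXF support targets the 1.2 static dialect with typed attvalues — enough
  for interchange with common network tools, not a full implementation of
  the specification's dynamics or hierarchy features.
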