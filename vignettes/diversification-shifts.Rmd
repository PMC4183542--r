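---
title: "Detecting diversification-rate shifts on dated higher-taxon phylogenies"
author: "cladeshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversification-rate shifts on dated higher-taxon phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data

Large radiations such as the insects are usually analysed at the family or
superfamily level: a dated, ultrametric phylogeny whose terminals are higher
taxa, each carrying a count of extant species. Such a *richness tree* mixes
two kinds of information about diversification — the ages of the observed
deep splits, and the sizes the terminal clades have reached since their stem
origins. `cladeshift` fits constant-rate birth–death regimes to this combined
evidence, searches for points on the tree where the regime changes, compares
alternative placements of a single change, expresses each shift as an
observed/expected richness ratio, and measures how robust the shifts are to
node-age uncertainty.

## The model

A regime is a constant-rate birth–death process with speciation rate
$\lambda$ and extinction rate $\mu$, parameterized here by the net
diversification rate $r = \lambda - \mu$ (per Ma) and the turnover
$\varepsilon = \mu/\lambda \in [0, 1)$. For a single lineage observed $t$ Ma
before the present, with $E = e^{-rt}$:

$$\beta(t) = \frac{1 - E}{1 - \varepsilon E}, \qquad
  \alpha(t) = \varepsilon\,\beta(t), \qquad
  P_s(t) = \frac{1 - \varepsilon}{1 - \varepsilon E},$$

where $\beta$ is the geometric parameter of the clade-size distribution,
$\alpha$ the probability of total extinction, and $P_s$ the probability of
leaving at least one extant descendant. The number of extant species
descending from a surviving lineage of age $t$ is geometric,
$P(n) = (1-\beta)\beta^{n-1}$, with survival-conditioned mean
$e^{rt}/(1-\alpha)$ and closed-form quantiles (smallest $n$ with
$1 - \beta^n \ge q$). All of these are evaluated in $e^{-rt}$ form with
`log1p`/`expm1`, so they remain accurate for $rt$ far beyond the overflow
point of $e^{rt}$.

### The combined likelihood

The log-likelihood of a richness tree under a set of regimes is the sum of

* an **internal** part — the reconstructed-process (Nee) likelihood of the
  observed split times, written per branch so that regimes partition
  cleanly. A branch that starts at age $t_1$ and ends in an observed split
  at age $t_2$ contributes
  $\log\lambda + \log P_s(t_2) + \log P(1 \to 1 \text{ reconstructed})$,
  which collapses to the stable form
  $\log r - r\,(t_1 - t_2) - \log(1 - \varepsilon e^{-r t_1})$.
  The root split is conditioned upon and contributes nothing; the empty
  regime contributes 0; and
* a **terminal** part — for each higher-taxon terminal with richness $n_i$
  and stem age $t_i$ (the age of its parent node), the survival-conditioned
  geometric mass $\log[(1-\beta(t_i))\beta(t_i)^{n_i-1}]$. A sampled terminal
  is observed and therefore extant, hence the survival conditioning.

When every terminal is a single species this sum reproduces, exactly, the
crown-conditioned Nee likelihood (without the parameter-free labelling
constant); the test suite verifies the identity on random trees over a grid
of $(r, \varepsilon)$. All model comparisons use likelihood differences,
which are invariant to any additive constant convention.

One approximation is inherited from the stepwise-search tradition: each
regime's survival probabilities are evaluated under its own parameters all
the way to the present, even where nested regimes with different rates lie
downstream. Treating regimes as independent keeps the likelihood additive
over the partition, which the search exploits.

### Fitting

Each regime is optimized independently on $(\log r,\ \mathrm{logit}\,
\varepsilon)$ with `nlminb`, bounds $r \in [10^{-8}, 10]$ per Ma and
$\varepsilon \in [0, 0.999]$, from five fixed deterministic starts (plus a
warm start when one is available); convergence tolerance $10^{-12}$ on the
objective. With turnover fixed, a one-dimensional golden-section fit of
$\log r$ is used instead. A regime with no internal splits and only
monotypic terminals carries no information about $r$ (the likelihood runs to
the $r \to 0$ boundary) and is reported as infeasible rather than fitted.

## Stepwise shift detection

The search is greedy forward selection. Starting from the homogeneous model
($k = 2$), every non-root node is evaluated as a candidate regime origin:
the clade (including its stem branch — "cut at stem"; a node-cut variant is
available) becomes a new regime, and the new regime and its donor are
refit. Candidate scanning uses a single warm-started optimization per
candidate; the winning candidate is then re-polished from the full start
set before acceptance. A shift costs three parameters ($r$, $\varepsilon$,
and the location), so a model with $s$ shifts has $k = 2 + 3s$ and
$\mathrm{AIC} = 2k - 2\,\mathrm{lnL}$. A shift is accepted when it improves
AIC by at least the threshold (default 4); ties are broken by a canonical
node id that depends only on the labelled topology, so results do not
depend on how the input file happens to order its clades. Each accepted
shift is classified as an upshift or downshift by whether the clade's
corrected richness exceeds its expectation under the parental regime.

The default threshold of 4 is a conventional fixed-AIC choice; the
published stepwise literature also uses sample-size-calibrated thresholds,
and the threshold is an explicit argument logged with every run. Greedy
selection over hundreds of candidate nodes is anticonservative by
construction — see *Known limitations*.

## Single-shift placement comparison

To compare named alternative placements of the first shift, the tree is
split at each candidate into a root-side and a clade-side regime, turnover
is fixed for both at the homogeneous-model estimate, and only the two net
rates are free. Candidates are ranked by log-likelihood;
$\chi^2 = 2\,\Delta\mathrm{lnL}$ with caller-supplied degrees of freedom
(default 3 against the uniform model and 1 between alternative placements,
mirroring the published table's accounting without endorsing its
derivation). Candidate clades are specified as tip-label sets, never as
node numbers.

## Richness ratios

Each shift is summarized as observed/expected richness at its stem age
under the parental regime. "Observed" is corrected for nested shifts:
terminals belonging to nested regimes are excluded and each immediately
nested radiation is counted as a single lineage at its origin — the
correction rule is isolated in `corrected_richness()` so alternatives can
be swapped in. The 95% interval transforms the 2.5% and 97.5% clade-size
quantiles (observed/upper, observed/lower); the interval is on clade size
first and the ratio second, one of two defensible readings of a CI "on the
outcome of the stochastic process".

## Ensemble robustness

Node-age uncertainty is propagated by re-running the identical search on an
ensemble of dated trees with fixed topology (posterior samples in the
original analyses; here, pseudo-posterior jitter). Shifts are matched across
trees by exact clade leafset — exactness is auditable, and a near-miss
diagnostic reports recovery at the parent or a child of each reference
clade separately. Recovery fractions are binned at 0.8/0.5/0.3 into the
four robustness classes used for figure annotation.

## The synthetic-data generator

`simulate_bd` / `simulate_with_shift` are forward Gillespie simulations
(exponential waiting times per lineage), pruned of extinct lineages to give
the reconstructed chronogram. Crown-age simulations condition on both crown
lineages surviving (resimulate-until-success); fixed-size simulations stop
when the target count of coexisting lineages is reached, with the present
drawn uniformly inside the interval during which that count persists.
`collapse_to_higher_taxa` slices the reconstructed tree at a collapse age:
terminals are the lineages crossing that age, each carrying its extant
descendant count, with deterministic labels (`T0001`, ...) and a sidecar
truth table for scoring. `pseudo_posterior` perturbs internal node ages by
median-unbiased lognormal factors and restores parent-before-child order by
rescaling violations; it emulates only what the ensemble machinery needs
(ages vary, topology fixed), not a real dating posterior. `simulate_bd_counts`
is a count-only simulator used as the Monte-Carlo oracle for the analytic
transients — oracle and likelihood code share no formulas.

The generator's default study system is a desk-scale analogue of the
published hexapod analysis: crown age 474 Ma, turnover 0.5, higher-taxon
collapse at 50 Ma, a single upshift whose 3.1-fold net-rate contrast matches
the published two-partition fit ($0.0104 \to 0.0326$ per Ma, shift origin
150 Ma), conditioned on the shifted lineage persisting as a clade of at
least 15 collapsed terminals, and a pseudo-posterior of node-age jitter
$\sigma = 0.035$ (matching a ±7% crown-age credible interval). The absolute rates and the
shift age are rescaled rather than copied: at the published absolute rates
the signal lives in 874 terminals carrying millions of species, and a
faithful miniature would rarely contain a detectable shift at all. What the generator does *not* emulate:
taxonomy-driven terminal definitions (see below), non-constant rates within
regimes, topological uncertainty, and incomplete species sampling — so
passing tests show the machinery is correct under the stated model, not that
real higher-taxon data satisfy it.

## Problem sizes in the default test runs

The test suite and the acceptance script size their simulations as: rate
recovery on 100 collapsed pure-birth trees of about 200 terminals (about
20,000 species each, collapsed halfway down the tree); shift-detection power
on 100 species-level trees whose shifted clade is conditioned to its design
size (25–100 terminals around the 50-terminal target) and false-positive
rates on 100 no-shift trees of 200 terminals;
interval coverage on 1000 simulated clades; Monte-Carlo oracles at 10,000
replicates; ensemble demonstrations at 20–100 trees (the published analyses
used 500). These sizes give Monte-Carlo standard errors comfortably inside
the asserted tolerances.

## Known limitations

* **The stem-age terminal likelihood is not the exact likelihood of
  age-sliced data.** For terminals defined by slicing the tree at a fixed
  collapse age, the exact terminal contribution would condition on the
  absence of reconstructed splits between the stem age and the slice and
  evaluate the geometric mass at the slice age; the conventional treatment
  evaluates it at the stem age. The discrepancy grows with the gap between
  stem age and slice (stem gaps are approximately exponential with rate $r$,
  independent of the slice depth). On deeply collapsed trees this biases
  the net-rate estimate downward by several percent and inflates the
  stepwise false-positive rate; the test suite measures both honestly
  rather than hiding them. The convention is retained deliberately — it is
  the one under which the published likelihoods and rate estimates are
  defined, and for real taxonomy-defined terminals (whose clade membership
  is not an age slice) it is the natural marginal model.
* Greedy stepwise AIC selection over all nodes is anticonservative at fixed
  thresholds; robustness across a dated-tree ensemble, not the single-tree
  shift list, is the unit of inference to trust.
* One regime change per node, rate constancy within regimes, complete
  sampling at the species level within terminals.

## Interfaces

Everything is driven from R. The `analysis/` directory holds the numbered
workflow scripts (simulate the study system, fit the uniform model, search
for shifts, compare placements, tabulate richness ratios, tally ensemble
robustness, compute lineage-through-time tables); each is a thin driver over
the exported functions and writes delimited tables, JSON reports and
annotated NEXUS trees under `results/`, including a manifest of seeds and
configuration. `scripts/acceptance.R` recomputes the headline quantities
from scratch with a caller-supplied seed.
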