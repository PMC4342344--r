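---
title: "The neutral molecular clock on structured populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neutral molecular clock on structured populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molclock)
```

## The model

`molclock` works with a minimal class of neutral evolutionary models on a
fixed spatial structure. A population occupies `N` sites, one haploid
individual per site. At every time-step a *replacement event* `(R, alpha)`
occurs: the occupants of the sites in `R` die and are replaced by offspring,
and `alpha` maps each replaced site to the site of its parent. The
probability distribution over events — the *replacement rule* — is fixed and,
because all mutations considered are neutral, independent of who currently
occupies which site. Spatial Moran processes (one birth per step) and
spatial Wright–Fisher processes (everyone replaced each step) are the two
familiar corners of this class; `replacement_rule()` accepts anything in
between.

Most quantities of interest depend on the rule only through its marginal
replacement probabilities `e[i, j]` — the per-step probability that the
offspring of site `i` displaces the occupant of site `j`. Row sums give the
birth rate `b_i`, column sums the turnover (death) rate `d_i`, and
`B = sum(b) = sum(d)` is the expected number of births per step. A
*generation* is `N/B` steps, so each site is replaced once per generation on
average.

The probability `rho_i` that a mutant arising at site `i` ancestors the whole
population solves the linear system

```
d_i * rho_i = sum_j e[i, j] * rho_j      (i = 1..N)
sum_i rho_i = 1
```

`rho_i` is also the reproductive value of site `i`. Because each reproduction
is an independent mutation opportunity, mutations arrive at site `i` in
proportion to `d_i`, and the clock rate per generation is `K = N * u * rho`
with `rho = (1/B) * sum_i d_i * rho_i` and `u` the mutation probability per
reproduction. `clock_rates()` reports the dimensionless `K/u` together with
the per-time-step version `B * rho`.

Four structural facts organize everything the package tests:

1. uniform turnover (`d_i` constant) forces `K = u`;
2. balanced sites (`b_i = d_i` everywhere, a *circulation*) force
   `rho_i = 1/N` and `K = u`, and conversely;
3. uniform birth rates force `K <= u`, with equality only under uniform
   turnover;
4. with no constraints, `K/u` can take any value in `[0, N)` — realized
   entirely by the hub-and-leaves family `builtin_structure("hub_leaf")`.

`classify_structure()` checks the hypotheses at tolerance `1e-9 * B`,
predicts the implied relation, and cross-checks it against the solved value;
a disagreement is raised as an internal error rather than returned, since it
can only mean a solver defect.

## Tunable parameters

* `builtin_structure()` families take their natural parameters: sizes
  (`N`, `n`, `n_up`, `n_down`), edge weights per time-step (`w`, `a`,
  `e_up`, `e_down`, `e_fwd`, `e_back`, `B`). Weights are per-time-step
  probabilities and therefore dimensionless; attaching `time_unit` (as the
  crypt model does with days) only relabels the per-step rate.
* The crypt default — five stem cells on a cycle with `0.05/day` between
  neighbors, hence `d_i = 0.1/day` — encodes the published turnover
  estimates for murine proximal small-intestine crypts; with
  `u = 1.1e-4` per division it yields `1.1e-5` substitutions per crypt per
  day, ten times slower than a well-mixed 250-cell crypt with daily
  replacement.
* `clock_rates(u =)` only scales outputs; `u` must be small for the
  underlying weak-mutation argument (fixation or loss completes between
  successive successful mutations), and the function warns above `u = 0.1`.
* `random_structure(density =)` controls sparsity of the unconstrained
  draws; constrained draws rescale rows/columns (uniform birth/death) or
  accumulate random directed cycles (circulations), which preserves
  non-negativity by construction.

## Numerical choices

The fixation system is homogeneous with a one-dimensional null space under
the out-connectedness assumption, so `solve_fixation()` replaces the last
equation with the normalization and does a dense direct solve. Which row is
replaced is immaterial because the residuals of *all* `N` original equations
are verified at `1e-10 * B` afterwards. If the replaced system is singular
or leaves a large residual (nearly reducible graphs), the null vector is
recovered from the SVD of the original operator and renormalized. Components
in `[-1e-12, 0)` are clipped to zero and the vector renormalized; anything
more negative, or any residual above tolerance, is an error rather than a
warning — a silently wrong reproductive value would poison every downstream
rate. Matrices are dense throughout; the intended scale is `N` up to a few
thousand, far below where sparsity would matter for a one-off solve.

Out-connectedness is decided exactly on the positive-support digraph: the
structure is solvable if and only if its condensation has a unique source
strongly-connected component (`assert_fixation_possible()` returns its
members, e.g. just the hub for `hub_leaf`). Note the boundary case
`hub_leaf(a = 0)`: the closed form `hub_leaf_rates()` extends continuously
to `a = 0` (`K/u -> N`), but the generated structure there has no edges out
of the hub and is rejected by the solver — the sweep tests therefore start
at small positive `a`.

Closed forms (`fixation_n2()`, `fixation_n3()`, `star_rates()`,
`hub_leaf_rates()`, `updown_rates()`) are implemented from the printed
rational expressions without algebraic simplification, precisely so they
remain independent oracles for the solver; `updown_rates()` instantiates
the matrix via `builtin_structure()` to obtain `d_up`, `d_down`, `B`, so
the self-pair convention enters both routes identically. For the well-mixed
subpopulation families (`complete`, `upstream_downstream`) self-pairs
`i = j` carry the same weight as ordered pairs `i != j`; this choice affects
turnover rates (hence absolute `K`) but not the `rho` values, which depend
only on off-diagonal structure.

## The simulator

`estimate_fixation()` simulates the *ancestral* chain: sites start labelled
`1..N` and the run absorbs when one founder's label occupies everything.
One run therefore estimates all `N` site probabilities at once — an `N`-fold
variance saving over single-mutant runs — and the estimates sum to one
exactly. The evolutionary (mutant/resident) chain is kept for set-initialized
runs (`estimate_fixation_from_set()`), which is how additivity over initial
mutant sets is checked. The inner loop is compiled (Rcpp) and consumes R's
RNG, so a single `seed` argument makes any call bit-reproducible; runs
within a call are drawn sequentially from that one stream, which is the
simplest protocol that delivers determinism for a serial engine. Mutation is
never simulated: `K` is always assembled analytically from `rho` and the
turnover rates, as the weak-mutation derivation requires. `max_steps`
defaults to `1e6 * N` as a cheap guard; hitting it signals an invalid rule
(e.g. two isolated self-replacing sites), not a tight estimate of absorption
time, and reported step counts are a diagnostic only.

## The network pipeline

For idea spread on a directed follower network, edges are oriented
followee-to-follower (the direction information travels), self-loops
dropped, duplicates collapsed to weight one, and each of the `L` surviving
links is chosen uniformly per step: `e[i, j] = 1/L` on each flow edge, so
`B = 1` and `d_i` is the in-degree over `L`. `K/u` then depends only on
topology.

To guarantee a solvable structure, the pipeline keeps the node with the
greatest eigenvector centrality and everything reachable from it along
outgoing links. Centrality is computed by power iteration where a node's
score is the sum of the scores of the nodes it feeds — i.e. influential
*sources* of information rank highest. The alternative (scoring by
in-neighbors) would crown pure sinks, whose out-reachable set is just
themselves, and pruning would routinely collapse networks that are perfectly
solvable from their hub; scoring by out-links keeps, for example, an
out-star intact with the hub as root. A uniform teleport term of `1e-8`
ensures convergence on reducible graphs, and centrality ties break to the
smallest original node id. The convention is a genuine design choice —
several eigenvector variants exist — and is logged on the returned object
(`root_id`) so alternatives can be compared.

`ensemble_summary()` reports per-network `K/u`, the ensemble mean and sample
(`n-1`) standard deviation, the strict count of accelerating networks
(`K/u > 1`), the OLS slope of `K/u` on `N` with a seeded percentile
bootstrap over networks (default `10^4` replicates), the Pearson
correlation, and supports a minimum-size filter for robustness re-runs.
Networks that prune to a single node are skipped with a message and counted.

## What the synthetic generators do and do not emulate

`random_structure()` produces matrices that satisfy a constraint class
*exactly* (to `1e-12`), which is what the structural theorems quantify over;
it makes no attempt to mimic ecological dispersal kernels.
`random_ego_network()` produces uniform random digraphs: right format,
wrong degree distribution — real follower networks are heavy-tailed and
reciprocal. Tests on these ensembles therefore establish the pipeline's
invariants (unit total rate, simplex profiles, the `K/u < N` bound, the
well-mixed rate on uniform in-degree, bit-for-bit determinism), not the
published ensemble statistics for Twitter ego networks, which require the
external data download and are additionally sensitive to preprocessing
conventions (centrality variant, duplicate handling) that the description
of that analysis leaves open.

## Problem sizes

The default test suite solves ~1,500 random structures at `N` in 2..8 for
the three constraint classes, compares the solver with the exact two- and
three-site forms on 10,000 random draws at `1e-10`, validates the solver
against a brute-force absorption analysis of the full `2^N`-state chain at
`N <= 4`, and runs the ancestral-chain oracle at `10^5` runs per builtin
structure (all `N <= 8`), asserting agreement within four binomial standard
errors with deterministic sites exact. Synthetic ensembles use 50 networks
of 4–13 nodes. These sizes make the statistical checks sharp at desk scale
while keeping the suite quick.

## Limitations

* Fixation *times* are outside the model: the clock formula assumes
  absorption completes before the next successful mutation arrives, which
  fails when `N * u * rho` is not small.
* Mutation is taken as constant per reproduction. Under the alternative
  convention — constant per individual per unit time — mutations arrive
  uniformly over sites and `K = u` for every structure; the package
  documents but does not implement that mode.
* Population size and structure are fixed over time; there is no selection,
  no recurrent mutation, and no polymorphic coexistence.
* Sparse-matrix and very-large-`N` performance is a non-goal; everything is
  dense and exact.
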