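---
title: "Hyperedge-swapping null models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperedge-swapping null models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypernull)
```

## The model

A hypergraph `H = (V, E)` has `n` nodes and `m` hyperedges, each hyperedge a
non-empty node subset whose union covers `V`. Everything in this package runs
off the `n x m` binary incidence matrix `C` (`C[i, j] = 1` iff node `i` is in
hyperedge `j`): row sums are node *hyperdegrees*, column sums are *hyperedge
degrees*, `A = C C' - D` counts co-memberships between nodes (zero diagonal),
and `B = C'C - De` counts nodes shared between hyperedges.

A *null model* here is a randomized surrogate produced by repeatedly applying
small in-place swaps to `C`, each swap preserving a chosen set of constraints
exactly while scrambling everything else. Because the surrogate is obtained
by perturbing the original network (rather than being rebuilt from scratch
from sampled stubs), duplicate hyperedges are allowed to arise, and no
rejection of "errors" beyond the constraint set is performed. Six generators
form a hierarchy of increasing retained structure:

| model    | swap move                                   | preserved exactly                              |
|----------|---------------------------------------------|------------------------------------------------|
| H0k      | move one membership between two hyperedges  | `n`, `m`, total memberships (mean hyperdegree) |
| H1k-HD   | move a node between two hyperedges          | hyperdegree vector                             |
| H1k-HED  | replace a member by a non-member            | hyperedge-degree vector                        |
| HD-HED   | 2x2 checkerboard swap                       | both degree vectors                            |
| H2k      | exchange two equal-hyperdegree nodes        | + per-hyperedge joint hyperdegree signature    |
| H2.25k   | H2k move kept only if clustering unchanged  | + mean clustering coefficient                  |

Every candidate swap is additionally rejected if it would empty a hyperedge
or drop a node out of all hyperedges, so the hypergraph invariants hold at
every observable point. H2k's move exchanges one non-common node from each of
two hyperedges only when the two nodes have equal hyperdegree; that keeps
each hyperedge's multiset of member hyperdegrees fixed, which is the sense in
which the joint hyperdegree distribution is preserved. The hierarchy is
`H0k <= {H1k-HD, H1k-HED} <= HD-HED <= H2k <= H2.25k <= H` (the two 1k models
are incomparable with each other).

### Candidate selection

The generating procedure for each move is "pick random column(s), pick
entries, swap if the entries differ". Sampling entry positions uniformly and
rejecting equal-valued pairs is equivalent to sampling uniformly among the
eligible (distinct-valued) pairs for the chosen columns, but the former
collapses at realistic incidence densities: at ~3% density a uniformly drawn
2x2 submatrix is a checkerboard with probability ~2e-3, so HD-HED would burn
its whole attempt budget before accepting a single swap. The engine therefore
draws directly from the eligible sets (members vs non-members, symmetric
differences of member sets), with orientation weighted by the number of
eligible pairs on each side so the proposal stays uniform over eligible
pairs. Structural rejections (would-empty, would-uncover, unequal
hyperdegrees, clustering change) remain ordinary attempt outcomes and are
tallied in the swap log.

### Counting swaps

"Number of swaps" counts *accepted* swaps (default `10 * m`, the point past
which ensemble randomness has plateaued on all fixtures we generate), because
a swap that changes nothing does not advance the randomization. Each accepted
swap is allowed at most `max_attempts_per_swap` candidates (default 100); if
the budget is exhausted the partial surrogate is returned with a warning and
a `swap_log` that accounts for every attempt
(`accepted + rejections = attempted`).

### H2.25k mixes slowly by construction

With the default tolerance `1e-12` an H2.25k move must leave the network
mean clustering numerically unchanged. Such moves exist (e.g. exchanging two
hyperdegree-1 nodes relabels the projection and is accepted), but on a
generic random hypergraph they are rare, so H2.25k often exhausts its attempt
budget after few accepted swaps. That is the intended reading of the model:
it sits closest to the original network in the hierarchy, and its randomness
gain is correspondingly minimal. Real datasets with many structurally
equivalent nodes (metabolites participating in identical reaction sets) give
it more room to move. The tolerance is a parameter; `cc_tolerance = 1`
reduces H2.25k to H2k, which is a useful upper bound in sensitivity checks.

## Statistics

"Degree" of a node is its number of distinct neighbors in the unweighted
clique projection (two nodes adjacent iff they share at least one
hyperedge); "hyperdegree" is the incidence row sum. Clustering, neighbor
averages and assortativity are evaluated on that unweighted projection, so
multi-shared hyperedges count once; this keeps clustering in `[0, 1]` and
matches how summary tables report both a degree and a hyperdegree column.
Nodes with fewer than two projection neighbors contribute clustering 0 and
are included in the mean (the mean is over *all* nodes). The assortativity
is Newman's edge-end degree correlation over the `M` projection edges;
endpoint degrees are projection degrees by default, with
`endpoint = "hyperdegree"` available because the definition does not dictate
the choice; it returns `NaN` with a warning on degree-regular projections
(zero variance).

A *hypertriangle* is a node triple whose three pairs are covered by three
pairwise-distinct hyperedges, excluding triples lying inside a single
hyperedge; distinct covering edges are found via Hall's condition on the
three pair-cover sets, and since any hyperedge covering two of the pairs
contains all three nodes, the exclusion test is simply a non-empty
intersection of two cover sets.

The randomness measure is the Shannon entropy of the normalized hyperdegree
weights `p_i = d_i^t / sum(d_j^t)` (natural log; base is a flag since
orderings are base-invariant). The exponent `t` defaults to 1, reading the
measure as the entropy of each node's share of memberships; it is exposed as
a parameter rather than interpreted further. Any generator that preserves
the hyperdegree vector leaves this entropy bit-identical, which the tests
assert literally (`identical()` on the doubles).

```{r entropy-example, eval = FALSE}
H <- generate_synthetic_hypergraph(
  n = 100, m = 200, size_probs = c("2" = .4, "3" = .3, "4" = .3),
  node_weight_exponent = 1, rng_seed = 1)
tr <- entropy_trajectory(H, "H0k", n_realizations = 10, rng_seed = 2)
```

On a hyperdegree-heterogeneous hypergraph the H0k mean entropy rises from
the original value and plateaus well before `10 * m` accepted swaps, with
`H0k >= H1k-HED >= original` at the plateau; hyperdegree-preserving models
give exactly flat curves.

## Dynamics

**Dismantling** ranks nodes by hyperdegree (or hyperedges by hyperedge
degree) once, on the intact network, descending with ties broken by index,
and removes greedily until the giant connected component of the projection
falls below `target_fraction * n` (default 0.01). Connectivity is computed
on the node-hyperedge bipartite expansion, which has the same node
components as the clique projection without materializing cliques; isolated
survivors count as size-1 components. The reported AUC is the plain sum of
the per-step GCC fractions (no trapezoid correction), so it is bounded by
the number of steps. Adaptive re-ranking after each removal is deliberately
out of scope. Note that `0.01 * n` must exceed 1 for the stopping rule to be
meaningful; below that the node-removal variant runs to exhaustion because a
single surviving node is a size-1 component.

**Threshold SIR.** Synchronous discrete time, all transitions evaluated from
the state at the start of the step: a hyperedge is infectious when its
infectious-member count strictly exceeds `theta` (default 5); a susceptible
node `i` is infected with probability `1 - exp(-beta * n_all)`, where
`n_all` sums the infectious members of `i`'s infectious hyperedges *with
multiplicity* (a node infectious in two shared infectious hyperedges counts
twice); infectious nodes recover with probability `gamma` (default 1), and a
node infected at step `t` cannot recover at `t`. Runs end at the absorbing
state (no infectious nodes) and the recovered fraction is averaged over
`n_runs` (default 100). Both ambiguous readings are configurable:
`threshold_strict = FALSE` switches to `>= theta`, and
`nall_mode = "distinct"` counts distinct infectious co-members instead.

With `gamma = 1` the seeds are infectious for exactly one step, which gives
closed-form checks: one hyperedge of 10 nodes with 6 seeds and `theta = 5`
yields `recovered = 6 + Binomial(4, 1 - exp(-6 beta))` exactly, which the
test suite verifies against simulation at 10^4 runs.

A scale effect worth knowing: with `0.01 * n` top-hyperdegree seeds and the
strict threshold, ignition requires more than `theta` seeds to co-occur in
one hyperedge. On desk-scale synthetic data randomization (H0k) *dilutes*
hub co-membership, so the original network spreads farther than its H0k
surrogate; at `theta = 1` (pairwise-like contagion, no ignition bottleneck)
the ordering flips to the randomness-enhances-spreading regime. Conclusions
about spreading on real data should therefore fix the threshold regime
first.

## Synthetic data

`generate_synthetic_hypergraph()` draws `m` hyperedge sizes (constant, or
from a named discrete distribution), fills each hyperedge by sampling
members without replacement, appends any uncovered node to a random
hyperedge (so the union invariant holds), and caps sizes at `n` after 100
resampling attempts, with a warning. Member sampling is uniform by default;
`node_weight_exponent = g` weights node `i` by `i^-g`, giving
Zipf-heterogeneous hyperdegrees. The generator emulates the gross features
that the null models and dynamics react to — degree heterogeneity, hyperedge
size mixtures, sparse co-membership — but not community structure, nested
reactions, or degree-size correlations of real biological and social
hypergraphs, so passing tests demonstrate correctness of the machinery, not
fidelity of any particular empirical claim.

Default test conditions are `n = 100, m = 200` with sizes 2-6 (probabilities
.3/.3/.2/.1/.1); the dynamics demonstrations in `scripts/acceptance.R` use
`n = 1000, m = 800` with a `s^-2` size tail up to 50, chosen so that the
`0.01 * n` GCC target exceeds one node and hyperedges are large enough for
`theta = 5` to engage.

## Numerical choices and edge cases

* Node labels are kept verbatim and sorted; all internal math uses 1-based
  integer indices against that label map. The simplex (nverts/simplices)
  format stores 1-based ids on disk, which become the labels on reading.
* Matrices switch to sparse storage above 10^6 cells; all contracts are
  value-level.
* Ties in removal and seed rankings break by node/hyperedge index,
  ascending, making dismantling and ranked seeding fully deterministic.
* `significance_mu` (null statistic / original statistic) warns and returns
  `NA` when the original statistic is zero.
* Reproducibility: every stochastic entry point takes `rng_seed`; the C++
  swap engine draws from R's RNG stream, so `set.seed()` governs it too, and
  equal seeds give bit-identical surrogates.
* Swap-log accounting (`accepted + rejected_* = attempted`) is asserted in
  the test suite, as is the ergodicity smoke test that HD-HED reaches
  multiple distinct incidence matrices with identical margins on a toy
  example.

## Known limitations

* H2.25k under a tight tolerance is diffusion-limited (see above); its
  entropy trajectory is essentially flat and its ensemble is small.
* The unweighted projection discards co-membership multiplicity in
  clustering and assortativity; a weighted-projection variant is out of
  scope.
* Directed, weighted, or multilayer hyperedges are not modeled; dismantling
  uses static rankings only.
* The giant component is defined through the projection; other connectivity
  notions (s-connectivity, higher-order walks) are not implemented.
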