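---
title: "Weighted consensus of tumor evolutionary trees: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted consensus of tumor evolutionary trees: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Methods that reconstruct a tumor's evolutionary history from sequencing
data routinely disagree: run several inference tools (or one tool on
several data types) on the same patient and you get several different
trees. Each tree is an *m-tumor tree*: a rooted tree whose nodes are
clones, labelled by disjoint clusters of somatic mutations that together
partition the patient's m mutations. Edges point from parent clones to the
child clones that descend from them.

This package summarises such a collection into a single consensus tree,
letting the user assign each input a confidence weight (e.g. higher weight
for the tree inferred from deeper sequencing). Formally, given input trees
$T_1, \dots, T_n$ over the same mutation set, a weight function $w$ with
$\sum_i w(T_i) = 1$, and a tree distance $d$, the consensus is

$$T^{*} = \arg\min_{T \in \mathcal{T}_m} \sum_{i=1}^{n} w(T_i)\, d(T, T_i),$$

the weighted median of the inputs over the space $\mathcal{T}_m$ of *all*
m-tumor trees — every mutation clustering and every topology, not just the
clusterings seen in the inputs.

## The ancestor-descendant distance

The distance we optimise is the ancestor-descendant (AD) distance.
Mutation $a$ is *ancestral to* $b$ in a tree when $a$ labels a node on the
path from the root to the node containing $b$; mutations sharing a node
are mutually ancestral, because their relative order inside the clone is
unobservable. Writing $\phi_{AD}(T)$ for the set of ordered ancestral
pairs of $T$, the distance between two trees is the size of the symmetric
difference

$$AD(T_1, T_2) = |\phi_{AD}(T_1) \setminus \phi_{AD}(T_2)| +
  |\phi_{AD}(T_2) \setminus \phi_{AD}(T_1)|.$$

AD is a metric, and unlike the commonly used parent-child (PC) distance it
registers long-range ancestry: an ancestral mutation is inherited by all
descendants, not only by its children. The package also provides the PC
distance for comparison; for mutations sharing a node we apply the same
mutual-pair convention as for AD (the literature leaves this case
undefined; treating co-clustered mutations symmetrically keeps
`pc_pairs(t)` a subset of `ad_pairs(t)` for every tree, which we assert in
the test suite).

## The integer linear program

Minimising over $\mathcal{T}_m$ directly is hopeless (16 trees at $m=3$,
133 at $m=4$, super-exponential growth). Instead we optimise over the
*transitive closure* of the tree: binary variables $x_{ab}$ for every
ordered pair of distinct mutations ($x_{ab} = 1$ iff $a$ ancestral to
$b$), and $r_a$ marking root mutations. Constraints force a valid
closure:

* **transitivity** — $x_{ac} \ge x_{ab} + x_{bc} - 1$ for all distinct
  triples;
* **single lineage** — $x_{ab} + x_{ba} \ge x_{ac} + x_{bc} - 1$: two
  ancestors of the same mutation must be comparable (ancestry is a chain
  up the tree);
* **rootedness** — $\sum_a r_a \ge 1$, with coupling constraints
  $\sum_b x_{ab} \ge (m-1) r_a$ and $\sum_b x_{ab} - (m-2) \le r_a$ so
  that $r_a = 1$ exactly when $a$ is ancestral to all other $m-1$
  mutations.

Writing $s_{ab} = \sum_i w(T_i)\,\delta(T_i, a, b)$ for the weighted
support of pair $(a,b)$ among the inputs ($\delta$ the ancestral
indicator), the total weighted AD distance of the solution tree is

$$\sum_i w(T_i)\,|\phi_{AD}(T_i)| + \sum_{a \ne b} x_{ab}\,(1 - 2 s_{ab}),$$

a linear objective: a pair included against the majority of the weight
costs, a pair included with majority support gains. The first term is a
constant tracked outside the solver and added back when reporting.

The solved relation is turned back into a tree by `relation_to_dag()`
(mutually ancestral mutations merge into one clone; edges follow the
relation) followed by `transitive_reduction()`. The reduction of a DAG is
unique, and for any relation satisfying the constraints above it is an
arborescence — a rooted tree with exactly one path from the root to every
node. We do not take this on faith at run time: every solve re-checks the
constraints in integer arithmetic (`audit_relation_solution()`), checks
acyclicity of the DAG, checks the arborescence property of the reduction,
and checks that the reduced tree's AD pairs reproduce the solved relation
exactly. Any violation is raised as an internal invariant error, because
it can only mean a bug, not a bad input.

### Enumerating co-optimal trees

Consensus problems often have ties, and the tie structure is informative
(see the weight sweep below). After the first solve, `enumerate_optima()`
appends a *no-good cut* — a linear constraint excluding exactly the found
0/1 assignment of the $x$ variables — and re-solves until the objective
strictly worsens or a caller-supplied limit is reached. Feasible
$x$-assignments are in bijection with m-tumor trees (the closure of a tree
is unique, and the reduction of a closure is unique), so cutting raw
assignments enumerates distinct trees; no isomorphism filtering is
needed. When the limit is reached, one extra solve decides whether more
optima exist, reported as a `truncated` flag. Results are reported in
canonical-serialization order so output lists are deterministic even
though the solver's own tie-breaking is not.

### Numerical choices

The backend is the HiGHS branch-and-bound solver, called through a small
batched worker process; variable values are rounded to {0,1} before the
integer audit. Objective ties during enumeration are compared with an
absolute tolerance of 1e-6, far below the smallest meaningful objective
difference at the weight precisions used in practice (two decimal places
in the weighting experiments). Batching matters: one worker invocation
solves the hundreds of per-trial models of a simulation study, so solver
startup is paid once. For $m = 1$ the ILP is skipped outright — the
single-node tree is the only 1-tumor tree — which also avoids the
degenerate $m-1$ divisor in the root constraints.

Weights must be nonnegative and sum to 1 within 1e-9; `normalize = TRUE`
opts into rescaling, so silently renormalised weights can never surprise a
caller who meant them exactly.

## Inputs over different mutation sets

Real input trees rarely agree on the mutation set. The package follows a
strict majority rule: a mutation enters the consensus only when it occurs
in more than half of the input trees. Each input is then restricted to the
majority set: mutations outside it are deleted, emptied nodes are
contracted, and the ancestral relations among kept mutations are preserved
exactly (`restrict_ad_pairs(t, keep)` equals `ad_pairs(t)` intersected
with `keep × keep` — the defining contract, tested exhaustively for small
m over all keep-subsets).

One corner case has no valid tree: if a tree's entire root label is
removed and the surviving branches share no ancestor, the restriction is a
forest. We deliberately do not invent an artificial root. The ILP
objective only consumes the per-input ancestral indicators
$\delta(T_i, a, b)$, which are perfectly well defined for a forest, so
harmonized consensus operates on restricted pair relations directly and
never needs a valid tree per input. The user-facing `restrict_tree()`
raises a classed error (`mtt_forest_error`) in this case rather than
guessing a root.

## The simulator

`generate_trial()` emulates the benchmark conditions used to evaluate
distance-based consensus methods:

1. **clustering** — each mutation after the first opens a new cluster
   with probability 3/4, else joins a uniformly chosen existing one, so
   the expected cluster count is $1 + \tfrac{3}{4}(m-1)$ (the stated
   design target; only the expectation is specified, and this sequential
   scheme is the simplest process matching it by linearity).
2. **topology** — clusters attach in random order to uniformly chosen
   existing nodes with fewer than three children.
3. **frequencies** — the root clone has cellular frequency 1; each
   clone's children receive a symmetric Dirichlet(1) share of the
   parent's frequency with one share retained, so the *sum rule* (a
   clone's frequency is at least the sum of its children's) holds by
   construction rather than by rejection.
4. **input trees** — each of the n inputs is an independently perturbed
   copy of the truth: subtree moves to a grandparent or sibling with
   probability 1/3, edge collapses with probability
   $f(\text{child})/f(\text{parent})$ (clones with similar frequencies
   are the ones real inference methods cannot separate, so they merge
   most often), and expansion of multi-mutation nodes into a
   parent/child split with probability 1/3. Operators run in that order,
   each in one breadth-first pass over the nodes present when the pass
   starts. A modification is accepted only if the sum rule still holds
   and no node exceeds four children (rejected moves are re-drawn up to
   ten times, then skipped); the branching cap keeps the generated trees
   within the input domain of the partition-based consensus tools used as
   comparators in this literature.

What the simulator does *not* emulate: read-count or variant-allele-
frequency noise, mutation call errors (every input carries exactly the
true mutation set), and any correlation between the n inputs (real
inference methods fail in correlated ways; our inputs err independently).
Passing the simulation-based tests therefore shows the optimizer and the
evaluation pipeline are correct under controlled noise — it does not
certify accuracy on real cohorts.

The collapse-probability formula and the frequency distribution are this
package's own design choices, fixed once at the values documented here.
They set a high noise level: a single-child edge collapses with mean
probability about one half, so input trees sit much farther from the
truth than the gentler perturbation settings common in this benchmark
literature, and absolute consensus-to-truth distances are correspondingly
several-fold larger than the reference means our evaluation protocol
compares against. The noise is also *correlated* across the n inputs of
a trial: collapse probabilities depend only on the shared true
frequencies, so the same easy-to-collapse edges tend to merge in a
majority of inputs, and the median tree inherits those shared errors.
Two measurable consequences follow and are asserted as-is in the test
suite: the linear scheme still beats constant weighting, but equal-weight
consensus no longer reliably beats the naive closest-input baseline at
this noise level, and exact truth recovery at m = 30 is essentially
zero. The comparisons against the reference means are kept at their
stated tolerances, and the ones this noise model cannot meet fail
visibly rather than being relaxed to fit.

## Evaluation protocol

`weighting_scheme()` ranks inputs by ascending AD distance to the truth
(ties broken by canonical serialization, for determinism) and assigns:
**constant** — $1/n$ each; **naive** — all weight on the closest input;
**linear** — weights decreasing linearly with rank, $0.30$ down to $0.10$
in steps of $0.05$ for $n=5$, and $0.15$ down by $0.0111$ per rank for
$n=10$. The published $n=10$ step makes the raw weights sum to 1.0005, so
we renormalise exactly to 1 (the objective requires it); other n require
an explicit start and step. Because any input weighted above one half is
the unique minimiser of a weighted sum of metric distances, the naive
scheme provably returns the closest input; `run_experiment()` therefore
evaluates it by direct selection, and a test cross-checks that the ILP
agrees.

`weight_sweep()` enumerates the weight simplex on a grid (66 points for
three trees at step 0.1), runs all-optima consensus at each point, and
groups grid points by their optimum set — the data behind ternary maps of
how the consensus shifts with confidence, including the dominance corners
(max weight > 0.5) and the tie stripes between them.

`percent_change(d_cand, d_ref)` is the standard comparison statistic
$100\,(d_{cand} - d_{ref})/d_{ref}$; both distances zero gives 0, a zero
reference with a nonzero candidate is NaN with a warning.

## Problem sizes and the oracle

The test suite validates the ILP against `brute_force_consensus()`, which
enumerates $\mathcal{T}_m$ exactly (every set partition crossed with every
rooted labelled tree on its blocks; 1, 3, 16, 133 trees for
$m = 1 \dots 4$) and evaluates the objective on each tree. The two routes
share no code beyond the distance definition. Oracle equivalence is
checked on ~200 random instances at $m \le 4$, the structural guarantees
on 500 simulated trials at $m = 10$, and the weighting-scheme experiment
at $m = 10$ with 100 trials per configuration and at $m = 30$ with 20
trials — sizes chosen so the whole suite runs on a laptop-class single
core in minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The ILP has $\Theta(m^3)$ constraints; $m = 30$ solves in seconds, but
  the approach is not intended for hundreds of mutations.
* Only the AD distance is optimised exactly; PC, CASet or DISC medians
  would need different formulations (PC distance is provided for
  measurement only).
* Weights express relative confidence but the package offers no guidance
  on choosing them from data quality; the weighting schemes here need the
  ground truth and exist for benchmarking.
* The majority-rule harmonizer drops minority mutations entirely; it does
  not impute their placement back into the consensus.
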