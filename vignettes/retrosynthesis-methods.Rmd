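---
title: "Methods: template-based retrosynthesis planning in retrosynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based retrosynthesis planning in retrosynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosynth)
```

## The problem

Retrosynthesis planning asks: given a target small molecule, which sequence
of known reaction types decomposes it into purchasable building blocks?
`retrosynth` implements the template-based formulation.  A *retro template*
is a reaction SMARTS pattern, written product-side first; applied to a
molecule that contains the product substructure it proposes a set of
precursors.  Applied recursively, template proposals span a search space
whose terminal states are sets of molecules found in a building-block
*stock*; a path from the target to such a state is a synthetic route,
represented as a bipartite tree of alternating molecule and reaction nodes.

The package separates four concerns, mirroring how production planners are
organised: *policies* (which disconnections to propose, and which to veto),
*stock* (when to stop), *search* (how to explore), and *analysis* (how to
rank, serialize, compare and cluster the resulting routes).

## Chemistry layer

Molecular identity is delegated to OpenBabel (via ChemmineOB): a molecule is
its canonical SMILES plus its 27-character InChI key, and two molecules are
equal exactly when their InChI keys are equal.  That convention matches how
building-block stocks are indexed in practice and keeps stereochemistry from
collapsing distinct isomers.  Standardization beyond canonicalization
(tautomer or charge normalization) is deliberately not applied before key
computation; stocks indexed under a different standardization scheme would
need their keys rebuilt with the same convention.

Template application itself is implemented in the package on an explicit
molecular graph: the supported SMARTS dialect covers element (including
`#n` atomic-number primitives with unspecified aromaticity), aromaticity by
letter case, H-counts, connection counts (`X4`), formal charges, atom maps,
bond orders, and ring/non-ring bond constraints (`@` / `!@`).  A match of
the product pattern drives a graph rewrite: bonds present on one side of the
template but not the other are broken or formed, product-side-only atoms are
deleted, reactant-side-only atoms are introduced, and hydrogens are
recomputed from standard valences.  Outcomes that violate valence rules or
fail re-canonicalization are dropped and counted — templates over-generate
by design, and the filter layer assumes invalid suggestions are removable.
Reactant tuples are sorted by canonical SMILES and de-duplicated by their
InChI-key multiset.  Running the same machinery with the template sides
swapped replays a reaction in the *forward* direction, which is how every
route the package emits can be re-validated end to end.

Fingerprints are circular (Morgan-style) bit vectors, radius 2 over 2048
bits by default, hashed with a fixed integer mix so they are reproducible
across platforms.  Only relative Tanimoto similarities are consumed
downstream (tree-edit-distance substitution costs), so the hash family
matters less than its determinism.

## Policies

An expansion strategy returns, per molecule, a ranked list of lazy
proposals `(template, prior)`.  The package ships two prior models behind
one contract — a *frequency prior* (probability proportional to each
template's literature example count, molecule-independent) and an
exact-match *lookup prior* — precisely so that a trained single-step model
can be plugged in later without touching the search code.  Proposals are
truncated to the `top_k = 50` most probable and by a cumulative-probability
cutoff `cutoff_cumulative = 0.995`; the proposal that first reaches the
cutoff is kept (inclusive rule), guaranteeing at least one proposal under
flat priors.  Results are memoized by (strategy id, InChI key) and template
application is deferred until a proposal is actually instantiated; both
choices exist because tree searches revisit the same molecules constantly.
Multiple strategies combine in two modes: `"all"` merges proposals and
re-sorts by raw prior without cross-strategy rescaling (priors from
different models are not on a common scale, and silently rescaling them
would hide that), and `"first"` returns the proposals of the first strategy
that answers.

Filters are pure predicates on an instantiated reaction.  Two are provided:
the reactant-count filter (rejects, e.g., an intramolecular match of a
bimolecular template, which produces one fragment where two patterns were
expected) and a score-threshold feasibility filter with a configurable
cutoff, defaulting to 0.05, wrapping any reaction-scoring function.

## Stock and scoring

A stock source is a named set of InChI keys with optional per-key price and
amount; several sources act as a logical OR with per-source evaluation of
the stop criteria (maximum price, minimum amount).  Entries without
price/amount data pass the corresponding criterion, because the criteria
are optional refinements, not gatekeepers.  When a molecule is priced in
several sources, cost-based scoring uses the minimum price.

The default node/route score is a bounded linear blend,

$$\mathrm{score} = w_\mathrm{stock}\cdot f + w_\mathrm{len}\cdot
\left(1 - \frac{\min(n, L_{\max})}{L_{\max}}\right),$$

with $f$ the fraction of molecules (or route leaves) in stock, $n$ the
transform depth (for a route, its longest linear sequence), and defaults
$w_\mathrm{stock} = 0.95$, $w_\mathrm{len} = 0.05$, $L_{\max}$ the
configured `max_transforms`.  It is exactly 1 for a solved zero-step state,
0 at the fully-unsolved depth limit, and monotone in both arguments.  A
sigmoidal depth squash would share these anchors; the linear form was chosen
because it is the simplest function with the required monotonicity and a
testable closed form.  Route cost follows the Badowski-style additive model:
a flat cost per reaction (default 1) plus a flat penalty (default 10) per
starting material not in stock, optionally substituting actual stock prices.

## Search

**MCTS** runs on the super-node representation: a state is the full multiset
of molecules reachable at that point, each with its own transform count and
ancestor set.  Each iteration selects by UCT ($Q + c\sqrt{\ln N/n}$,
$c = 1.4$, ties to the first-created child), expands one action (single-child
expansion), performs a greedy prior-guided rollout that is not persisted in
the tree, and backpropagates the *terminal* rollout state's score.  Using
the terminal score rather than the maximum along the rollout keeps the
reward attributable to a concrete recordable state; the alternative is noted
as a variant.  Actions for a state are generated in one batched policy call
over all expandable molecules and pooled in prior order (sibling
node-expansion).  A molecule that reaches `max_transforms` retro steps is
frozen rather than discarded, so partially solved deep states still score.
Dead-end nodes (all actions rejected) backpropagate reward 0.  Every solved
state encountered — in the tree or at the end of a rollout — is recorded as
a route; terminal unsolved states are recorded as partial routes for
diagnostics and unsolved-target statistics.

**Breadth-first search** and **Retro\*** operate on AND/OR trees whose OR
nodes are molecule instances carrying their own path ancestors and depth
(tree, not graph, semantics: a molecule reachable along two paths appears
twice).  This makes the per-path depth limit and cycle guard exact and lets
small instances be compared 1:1 against brute-force enumeration; the price
is re-expansion of repeated molecules, which the policy/application caches
absorb.  BFS expands level by level to `max_transforms` and enumerates every
solved route.  Retro* is implemented in its zero-heuristic variant
(Retro*-0): reaction cost $-\ln(\max(p, 10^{-10}))$, in-stock and unexpanded
molecules valued 0, each iteration expanding the first unexpanded molecule
in the current minimum-cost partial route.  With an admissible (optimistic)
zero heuristic the first proven route is cost-optimal, which the tests
verify against exhaustive enumeration.

Cycle prevention rejects any reaction whose reactant regenerates a molecule
on the path from the target to the acted-on molecule (including the product
itself).  Time limits are checked between iterations only, so a run under an
iteration limit is exactly reproducible; all tie-breaks (prior, state
position, template index, creation order) are deterministic, and a fixed
seed plus configuration reproduces results bit for bit.

## Routes, distances, clustering

Routes serialize to a nested JSON schema (`"type": "mol" | "reaction"`,
`smiles`, `in_stock`, `metadata`, `children`) with fixed key order, so two
serializations of the same tree are byte-identical; unknown keys survive a
round-trip.  Metrics: step count, longest linear sequence (LLS), number of
starting materials, solved, and *convergent*, defined structurally as some
reaction joining at least two branches that each contain further reactions
(with that definition, LLS equals the step count exactly on non-convergent
routes).

Route similarity is an ordered tree edit distance (Zhang–Shasha) computed
after sorting children into a canonical order by subtree serialization.
Costs: insertion/deletion 1 per node; substitution $1 - T$ for
molecule/molecule pairs (Tanimoto between fingerprints), $1 - T$ between
reaction *difference* fingerprints (product bits XOR the union of reactant
bits) for reaction/reaction pairs, and 1 for mixed pairs.  Note one
consequence: swapping a single leaf changes both the leaf's own cost term
and the adjacent reaction's difference fingerprint, so the minimal edit
script costs the sum of the two substitutions.  All three cost choices
(fingerprint kind, ordered-tree assumption, canonical child ordering) are
parameters of the implementation rather than fixed doctrine.

Clustering is agglomerative with average linkage on the precomputed
distance matrix; the number of clusters is chosen in
$[2, \min(\texttt{max\_k}, n-1)]$ (default `max_k = 8`) by maximum mean
silhouette width on those same distances.  Degenerate inputs short-circuit:
fewer than two routes, or an all-zero distance matrix, yield a single
cluster; exactly two distinct routes are a forced 2-split (the silhouette is
undefined at $k = n$).

## The synthetic universe

Because trained expansion models and vendor stocks cannot ship with a
library, validation uses a generated reaction universe with *planted ground
truth*.  Targets are composed forward from a fixed catalogue of simple
building blocks — amines, carboxylic acids, alcohols, alkyl and aryl
bromides, arylboronic acids, including bromo-substituted bifunctional
members that keep multi-step chains alive — using four invertible coupling
chemistries: amide formation, esterification, Williamson-type
etherification, and Suzuki biaryl coupling.  Each forward step is literally
the inverse of a retro template in the emitted library, so each planted
route replays exactly and breadth-first search at the planted depth must
rediscover it (closure).  Template example counts are drawn uniformly from
1–1000 so frequency priors have structure, and an adversarial mode adds
decoy templates that match targets but lead away from stock (fluorinative
cleavages) or trigger the reactant-count filter (ring cleavage).

What this emulates: a planner whose single-step model proposes a mix of
productive, unproductive and invalid disconnections with informative but
imperfect priors, over a stock that terminates search at realistic depths
(1–3 steps, convergent and linear).  What it does not emulate: the breadth
of real reaction chemistry (four reaction classes versus tens of thousands
of templates), prior quality learned from data, selectivity and protecting
group logic, or stock sets of millions of compounds.  Passing tests
therefore demonstrate that the *algorithms* are correct and internally
consistent, not that route quality on real drug-like molecules matches a
production system.

## Numerical and design choices

* Problem sizes in the test-suite and acceptance computations: universes of
  12 building blocks, depths 1–3, 20 planted targets for the recovery
  experiment, MCTS at 1000 iterations, exhaustive-comparison budgets of ≤4
  transforms, 100 sampled triples for the metric axioms.  These sizes make
  brute-force oracles exact while exercising every code path.
* Batch records set `wall_time` to 0 unless `report_timings: true`:
  real timings are not reproducible, and the batch contract (fixed seed ⇒
  byte-identical output, resume ⇒ identical concatenation) takes precedence.
  Equally, JSON-lines records carry only the seed-deterministic diagnostic
  counters; cache-hit counts depend on session history.
* Checkpoints are written atomically (temp file + rename) after every
  target and store a digest of the configuration; resuming under a changed
  configuration is refused rather than silently blended.
* Per-target seeds are derived as `seed + 1009 * index`, so a target's
  result does not depend on where in the batch it ran.
* Known limitations: the SMARTS dialect is the subset the template
  machinery needs (no recursive SMARTS, no explicit-H atoms as graph
  nodes); aromaticity handling assumes benzenoid rings as produced by the
  catalogue; Depth-First Proof-Number search and learned value functions
  are out of scope; route extraction caps recorded routes (default 10000)
  to bound memory on pathological universes.
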