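# retrosynth

Template-based multi-step retrosynthesis planning in R.

`retrosynth` answers the chemist's question "how do I make this molecule
from things I can buy?" by recursively disconnecting a target with retro
reaction templates (reaction SMARTS) until every precursor is found in a
building-block stock.  It is aimed at computational chemists and method
developers who want a complete, deterministic, fully testable planning
stack — expansion and filter policies, stocks with stop criteria, three
search algorithms, route scoring, serialization, and route clustering —
without depending on trained models or vendor catalogues.

## The method

A **retro template** `product >> reactant1.reactant2` proposes precursors
for any molecule containing the product substructure.  An **expansion
policy** ranks templates for a molecule by a prior probability
(frequency-based or look-up; the contract accepts any model), truncated to
the top *k* = 50 proposals and a cumulative-probability cutoff of 0.995.
**Filter policies** veto proposed reactions (reactant-count mismatches,
feasibility scores below a cutoff).  A molecule terminates a branch when its
InChI key is in a **stock**; optional stop criteria bound price and amount.

Three search engines share those components:

* **MCTS** (default) on the super-node state — the multiset of all
  molecules at a point in the search — with UCT selection
  (Q + c·√(ln N / n), c = 1.4), single-action expansion, greedy
  policy-guided rollouts, and rewards from the state score
  `0.95 · frac_in_stock + 0.05 · (1 − depth/max_transforms)`.
* **Retro\*** (zero-heuristic variant) best-first on AND/OR trees with
  reaction cost −ln(prior); provably returns the minimum-cost route.
* **Breadth-first search**, exhaustive to a transform limit; the reference
  for oracle comparisons.

Extracted routes are bipartite molecule/reaction trees (JSON-serializable),
scored and ranked, compared by an ordered tree edit distance with
fingerprint-based substitution costs, and clustered by average-linkage
agglomeration with silhouette-selected k.  A bundled synthetic
reaction-universe generator (amide, ester, ether, Suzuki chemistry over a
small building-block catalogue) plants ground-truth routes so every
algorithm is validated end to end with no external data.

## Worked example

```r
library(retrosynth)

u <- generate_universe(n_blocks = 12, depth = 2, branching = 2,
                       seed = 7, n_targets = 4)
target <- u$targets[[2]]
expansion <- template_expansion(u$templates)   # frequency prior
filters <- list(reactant_count_filter())

res <- mcts_search(target$mol, search_config("mcts", iteration_limit = 400),
                   expansion, filters, list(u$stock))
res
#> <search_result> mcts on Brc1cccc(c1)C(=O)OCCc1ccc(cc1)c1ccccc1
#>   solved: TRUE  iterations: 400  routes recorded: 2  wall time: 0.31s

routes <- extract_routes(res, top_n = 5)
compute_metrics(routes$routes[[1]])
#> steps: 2  lls: 2  starting materials: 3  solved: TRUE  convergent: FALSE
```

The target (an aryl-bromide ester) is solved in two steps: a Suzuki
disconnection of the biaryl bond (prior 0.59 under the frequency prior)
followed by an ester disconnection, ending in three building blocks —
3-bromobenzoic acid, 2-(4-bromophenyl)ethanol and phenylboronic acid — all
flagged `in_stock`.  `route_to_json(routes$routes[[1]])` serializes the
tree with each reaction's template label, example count and prior in its
metadata; `cluster_routes(route_distance_matrix(...))` groups alternative
routes by tree edit distance.

Batch planning from the shell mirrors the library API:

```sh
Rscript inst/cli/retroplan.R plan --config config.yml \
    --targets targets.smi --output out.jsonl --checkpoint ck.json --seed 1
Rscript inst/cli/retroplan.R expand --config config.yml --smiles "CC(=O)NC"
Rscript inst/cli/retroplan.R stats --input out.jsonl
```

One JSON record is appended per target; the checkpoint makes interrupted
runs resume exactly (byte-identical concatenated output for a fixed seed),
and refuses to resume under a changed configuration.

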