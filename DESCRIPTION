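Package: retrosynth
Title: Template-Based Multi-Step Retrosynthesis Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multi-step retrosynthesis planning for small organic molecules.
    Ranked retro reaction templates (reaction SMARTS) are applied recursively to
    a target molecule until purchasable building blocks are reached, using Monte
    Carlo tree search on a super-node state representation, Retro* best-first
    search, or breadth-first search on AND/OR trees.  Includes expansion and
    filter policies with pluggable prior models, multi-source building-block
    stocks with price and amount stop criteria, node and route scoring, reaction
    tree serialization, route metrics, tree-edit-distance clustering, a batch
    interface with restart-safe checkpointing, and a synthetic reaction-universe
    generator with planted ground-truth routes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    jsonlite,
    yaml,
    cluster,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
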