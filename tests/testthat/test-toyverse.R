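# Synthetic universe generator: determinism, ground-truth consistency,
# closure under search, and adversarial decoys.

test_that("universes are reproducible byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  u1 <- generate_universe(n_blocks = 10L, depth = 2L, branching = 2L,
                          seed = 3L, n_targets = 3L)
  u2 <- generate_universe(n_blocks = 10L, depth = 2L, branching = 2L,
                          seed = 3L, n_targets = 3L)
  write_universe(u1, d1)
  write_universe(u2, d2)
  for (f in c("templates.csv", "stock.csv", "targets.smi", "routes.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed gives different targets
  u3 <- generate_universe(n_blocks = 10L, depth = 2L, branching = 2L,
                          seed = 4L, n_targets = 3L)
  expect_false(identical(vapply(u1$targets, function(t) t$mol$smiles,
                                character(1)),
                         vapply(u3$targets, function(t) t$mol$smiles,
                                character(1))))
})

test_that("planted routes are solved against the emitted stock", {
  u <- fixture_universe(depth = 3L, seed = 11L, n_targets = 3L)
  for (tgt in u$targets) {
    m <- compute_metrics(tgt$route)
    expect_true(m$solved)
    expect_identical(m$longest_linear_sequence, 3L)
    expect_lte(m$n_steps, 7L)    # binary-tree bound at depth 3
    for (l in retrosynth:::route_leaves(tgt$route))
      expect_true(in_stock(canonicalize(l$smiles), list(u$stock)))
  }
})

test_that("depth-1 universes are fully solved by one-level search", {
  u <- fixture_universe(depth = 1L, seed = 5L, n_targets = 3L)
  exp <- fixture_expansion(u)
  for (tgt in u$targets) {
    res <- breadth_first_search(tgt$mol,
                                search_config("breadth_first",
                                              max_transforms = 1L),
                                exp, default_filters(), list(u$stock))
    expect_true(res$solved)
    expect_true(retrosynth:::route_signature(tgt$route) %in%
                  vapply(res$recorded, retrosynth:::route_signature,
                         character(1)))
  }
})

test_that("closure: BFS at the planted depth finds every planted route", {
  u <- fixture_universe()  # depth 2
  exp <- fixture_expansion(u)
  for (tgt in u$targets) {
    res <- breadth_first_search(tgt$mol,
                                search_config("breadth_first",
                                              max_transforms = u$depth),
                                exp, default_filters(), list(u$stock))
    expect_true(retrosynth:::route_signature(tgt$route) %in%
                  vapply(res$recorded, retrosynth:::route_signature,
                         character(1)))
  }
})

test_that("universe files load back through the standard loaders", {
  d <- withr::local_tempdir()
  u <- fixture_universe()
  write_universe(u, d)
  tpls <- load_templates(file.path(d, "templates.csv"))
  expect_length(tpls, length(u$templates))
  expect_identical(vapply(tpls, function(t) t$smarts, character(1)),
                   vapply(u$templates, function(t) t$smarts, character(1)))
  stk <- load_stock(file.path(d, "stock.csv"), "bb")
  expect_setequal(stk$keys, u$stock$keys)
  smis <- readLines(file.path(d, "targets.smi"))
  expect_length(smis, length(u$targets))
  routes <- jsonlite::fromJSON(file.path(d, "routes.json"),
                               simplifyVector = FALSE)
  tr <- retrosynth:::list_to_tree(routes[[1]])
  expect_identical(retrosynth:::route_signature(tr),
                   retrosynth:::route_signature(u$targets[[1]]$route))
})

test_that("decoy-only libraries solve nothing; mixed libraries still solve", {
  u <- fixture_universe()
  all_tpls <- adversarial_templates(u, n_decoys = 4L, seed = 9L)
  decoys <- all_tpls[(length(u$templates) + 1L):length(all_tpls)]
  decoy_exp <- template_expansion(decoys, id = "decoys-only")
  mixed_exp <- template_expansion(all_tpls, id = "mixed")
  tgt <- u$targets[[1]]
  res_d <- mcts_search(tgt$mol,
                       search_config("mcts", iteration_limit = 100L),
                       decoy_exp, default_filters(), list(u$stock))
  expect_false(res_d$solved)
  res_m <- mcts_search(tgt$mol,
                       search_config("mcts", iteration_limit = 600L),
                       mixed_exp, default_filters(), list(u$stock))
  expect_true(res_m$solved)
  expect_true(retrosynth:::route_signature(tgt$route) %in%
                vapply(Filter(function(t) compute_metrics(t)$solved,
                              res_m$recorded),
                       retrosynth:::route_signature, character(1)))
  # the ring-cleavage decoy triggers the reactant-count filter somewhere
  ring_target <- canonicalize("OC1CCCCC1")
  res_r <- mcts_search(ring_target,
                       search_config("mcts", iteration_limit = 20L),
                       template_expansion(decoys, id = "decoys-ring"),
                       default_filters(), list())
  expect_gt(res_r$diagnostics$filtered_reactions, 0L)
})
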