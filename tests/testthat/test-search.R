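# Search engines: UCT mechanics, cycle prevention, rollout, MCTS, BFS,
# Retro*, and the cross-algorithm consistency properties.

mk_node <- function(visits, total, parent = NULL) {
  n <- new.env(parent = emptyenv())
  n$visits <- visits; n$total <- total
  n$children <- list(); n$parent <- parent
  n
}

test_that("uct_select maximises Q + c*sqrt(ln N / n) with stable ties", {
  parent <- mk_node(10L, 0)
  a <- mk_node(5L, 0.8 * 5)   # Q = 0.8
  b <- mk_node(1L, 0.5)       # Q = 0.5
  parent$children <- list(a, b)
  # UCT_A = 0.8 + 1.4*sqrt(ln 10 / 5) ~ 1.750; UCT_B ~ 2.624
  expect_identical(uct_select(parent, 1.4), b)
  # pure exploitation picks the higher Q
  a2 <- mk_node(3L, 0.9 * 3); b2 <- mk_node(3L, 0.3 * 3)
  parent$children <- list(a2, b2)
  expect_identical(uct_select(parent, 0), a2)
  # identical statistics: first-created child wins
  c1 <- mk_node(2L, 1); c2 <- mk_node(2L, 1)
  parent$children <- list(c1, c2)
  expect_identical(uct_select(parent, 1.4), c1)
  parent$children <- list()
  expect_error(uct_select(parent), "children")
})

test_that("backpropagation accumulates along the ancestor chain", {
  root <- mk_node(0L, 0)
  mid <- mk_node(0L, 0, root)
  leaf <- mk_node(0L, 0, mid)
  backpropagate(leaf, 1.0)
  for (n in list(root, mid, leaf)) {
    expect_identical(n$visits, 1L)
    expect_equal(n$total / n$visits, 1.0)
  }
  backpropagate(leaf, 0.0)
  expect_equal(leaf$total / leaf$visits, 0.5)
})

test_that("the cycle guard rejects regenerated ancestors and identity", {
  tpl <- amide_template()
  rx <- retrosynth:::instantiate_proposal(
    list(template = tpl, prior = 1, strategy_id = "x",
         product = canonicalize("CC(=O)NC")))[[1]]
  expect_true(prevent_cycle(rx, character(0)))
  # a reactant that equals an ancestor is rejected
  expect_false(prevent_cycle(rx, canonicalize("CN")$inchi_key))
  # a reactant equal to the product itself is rejected
  fake <- rx
  fake$reactants <- list(rx$product)
  expect_false(prevent_cycle(fake, character(0)))
})

test_that("expansion queues one action per reactant tuple, prior first", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  # benzyl methyl ether: the ether template yields two disconnections
  mol <- canonicalize("COCc1ccccc1")
  props <- get_actions(exp, list(mol))[[1]]
  ether <- Filter(function(p) grepl("ether", p$template$label), props)
  expect_length(ether, 1L)
  rxns <- retrosynth:::instantiate_proposal(ether[[1]])
  expect_length(rxns, 2L)
  priors <- vapply(props, function(p) p$prior, numeric(1))
  expect_true(all(diff(priors) <= 0))
})

test_that("greedy rollout reaches stock on one-step targets and stops on
          dead ends", {
  u <- fixture_universe(depth = 1L, seed = 5L, n_targets = 3L)
  exp <- fixture_expansion(u)
  stock_fn <- function(m) in_stock(m, list(u$stock))
  idc <- new.env(); idc$n <- 1L
  mk_state <- function(mol) retrosynth:::state_new(list(list(
    mol = mol, id = 1L, depth = 0L, in_stock = stock_fn(mol),
    ancestors = character(0))))
  # already solved state is returned unchanged
  solved <- mk_state(u$building_blocks[[1]]$mol)
  ro <- retrosynth:::mcts_rollout(solved, exp, default_filters(), stock_fn,
                                  6L, idc, retrosynth:::new_diagnostics())
  expect_length(ro$actions, 0L)
  expect_true(retrosynth:::state_solved(ro$state))
  # one greedy step solves a depth-1 target
  tgt <- mk_state(u$targets[[1]]$mol)
  ro2 <- retrosynth:::mcts_rollout(tgt, exp, default_filters(), stock_fn,
                                   6L, idc, retrosynth:::new_diagnostics())
  expect_true(retrosynth:::state_solved(ro2$state))
  expect_length(ro2$actions, 1L)
  # a molecule matching no template terminates immediately, unsolved
  inert <- mk_state(canonicalize("c1ccccc1"))
  ro3 <- retrosynth:::mcts_rollout(inert, exp, default_filters(), stock_fn,
                                   6L, idc, retrosynth:::new_diagnostics())
  expect_false(retrosynth:::state_solved(ro3$state))
  expect_length(ro3$actions, 0L)
})

test_that("MCTS solves planted targets and honours its boundaries", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  tgt <- u$targets[[1]]
  res <- mcts_search(tgt$mol, search_config("mcts", iteration_limit = 400L),
                     exp, default_filters(), list(u$stock))
  expect_true(res$solved)
  sigs <- vapply(res$recorded, retrosynth:::route_signature, character(1))
  expect_true(retrosynth:::route_signature(tgt$route) %in% sigs)
  # a target already in stock is trivially solved with a zero-step route
  triv <- mcts_search(u$building_blocks[[1]]$mol, search_config("mcts"),
                      exp, default_filters(), list(u$stock))
  expect_true(triv$solved)
  expect_identical(compute_metrics(triv$recorded[[1]])$n_steps, 0L)
  # iteration_limit 1 on an unsolvable target uses exactly 1 iteration
  hard <- mcts_search("c1ccccc1",
                      search_config("mcts", iteration_limit = 1L),
                      exp, default_filters(), list(u$stock))
  expect_false(hard$solved)
  expect_identical(hard$iterations_used, 1L)
})

test_that("identical seed and configuration reproduce the search verbatim", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  cfg <- search_config("mcts", iteration_limit = 150L)
  ser <- function(r) paste(c(r$solved, r$iterations_used,
                             vapply(r$recorded, route_to_json,
                                    character(1))), collapse = "\n")
  r1 <- mcts_search(u$targets[[2]]$mol, cfg, exp, default_filters(),
                    list(u$stock))
  # second run hits warm caches everywhere; results must be unchanged
  r2 <- mcts_search(u$targets[[2]]$mol, cfg, exp, default_filters(),
                    list(u$stock))
  expect_identical(ser(r1), ser(r2))
})

test_that("breadth-first search equals the recursive enumerator", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  for (tgt in u$targets[1:2]) {
    bfs <- breadth_first_search(tgt$mol,
                                search_config("breadth_first",
                                              max_transforms = 3L),
                                exp, default_filters(), list(u$stock))
    want <- oracle_enumerate(tgt$mol, exp, default_filters(),
                             list(u$stock), 3L)
    expect_identical(oracle_signatures(bfs$recorded),
                     oracle_signatures(want))
    # deepening the budget never removes previously found routes
    bfs4 <- breadth_first_search(tgt$mol,
                                 search_config("breadth_first",
                                               max_transforms = 4L),
                                 exp, default_filters(), list(u$stock))
    expect_true(all(oracle_signatures(bfs$recorded) %in%
                      oracle_signatures(bfs4$recorded)))
  }
  # max_transforms 0: solved iff the target is already in stock
  b0 <- breadth_first_search(u$targets[[1]]$mol,
                             search_config("breadth_first",
                                           max_transforms = 0L),
                             exp, default_filters(), list(u$stock))
  expect_false(b0$solved)
  s0 <- breadth_first_search(u$building_blocks[[1]]$mol,
                             search_config("breadth_first",
                                           max_transforms = 0L),
                             exp, default_filters(), list(u$stock))
  expect_true(s0$solved)
})

test_that("Retro* finds the minimum-cost route", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  for (tgt in u$targets[1:2]) {
    rs <- retrostar_search(tgt$mol,
                           search_config("retrostar",
                                         iteration_limit = 500L,
                                         max_transforms = 3L),
                           exp, default_filters(), list(u$stock))
    bfs <- breadth_first_search(tgt$mol,
                                search_config("breadth_first",
                                              max_transforms = 3L),
                                exp, default_filters(), list(u$stock))
    expect_true(rs$solved)
    want <- min(vapply(bfs$recorded, retrosynth:::route_cost, numeric(1)))
    expect_equal(rs$best_cost, want, tolerance = 1e-9)
  }
  # in-stock target: cost 0, zero-step route
  triv <- retrostar_search(u$building_blocks[[1]]$mol,
                           search_config("retrostar"), exp,
                           default_filters(), list(u$stock))
  expect_true(triv$solved)
  expect_equal(triv$best_cost, 0)
})

test_that("every emitted route replays forward and repeats no ancestor", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  tgt <- u$targets[[3]]
  results <- list(
    mcts_search(tgt$mol, search_config("mcts", iteration_limit = 200L),
                exp, default_filters(), list(u$stock)),
    breadth_first_search(tgt$mol,
                         search_config("breadth_first", max_transforms = 3L),
                         exp, default_filters(), list(u$stock)),
    retrostar_search(tgt$mol,
                     search_config("retrostar", iteration_limit = 300L,
                                   max_transforms = 3L),
                     exp, default_filters(), list(u$stock)))
  for (res in results) {
    solved_routes <- Filter(function(t) compute_metrics(t)$solved,
                            res$recorded)
    expect_gte(length(solved_routes), 1L)
    for (r in solved_routes) {
      expect_true(isTRUE(replay_route(r, u$templates, list(u$stock))))
    }
  }
  # MCTS solved routes are a subset of the exhaustive enumeration
  mcts_solved <- Filter(function(t) compute_metrics(t)$solved,
                        results[[1]]$recorded)
  mcts_shallow <- Filter(function(t)
    compute_metrics(t)$longest_linear_sequence <= 3L, mcts_solved)
  want <- oracle_signatures(oracle_enumerate(tgt$mol, exp,
                                             default_filters(),
                                             list(u$stock), 3L))
  expect_true(all(oracle_signatures(mcts_shallow) %in% want))
})
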