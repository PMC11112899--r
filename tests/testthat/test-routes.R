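# Reaction trees: metrics, JSON round-trips, extraction ranking, tree edit
# distance, clustering.

test_that("route metrics match hand counts", {
  m0 <- compute_metrics(linear_route(0))
  expect_identical(m0$n_steps, 0L)
  expect_identical(m0$longest_linear_sequence, 0L)
  expect_identical(m0$n_starting_materials, 1L)
  expect_true(m0$solved)
  m3 <- compute_metrics(linear_route(3))
  expect_identical(m3$n_steps, 3L)
  expect_identical(m3$longest_linear_sequence, 3L)
  expect_false(m3$convergent)
  mc <- compute_metrics(convergent_route())
  expect_identical(mc$n_steps, 3L)
  expect_identical(mc$longest_linear_sequence, 2L)
  expect_identical(mc$n_starting_materials, 4L)
  expect_true(mc$convergent)
  expect_true(mc$solved)
})

test_that("LLS equals step count exactly for non-convergent routes", {
  u <- fixture_universe(depth = 3L, seed = 11L, n_targets = 3L)
  routes <- c(lapply(u$targets, function(t) t$route),
              list(linear_route(2), convergent_route()))
  for (r in routes) {
    m <- compute_metrics(r)
    expect_lte(m$longest_linear_sequence, m$n_steps)
    if (!m$convergent)
      expect_identical(m$longest_linear_sequence, m$n_steps)
    else
      expect_lt(m$longest_linear_sequence, m$n_steps)
  }
})

test_that("JSON round-trip is lossless, stable, and validates", {
  tr <- convergent_route()
  js <- route_to_json(tr)
  tr2 <- route_from_json(js)
  expect_identical(route_to_json(tr2), js)
  expect_identical(retrosynth:::route_signature(tr2),
                   retrosynth:::route_signature(tr))
  # unknown keys survive a round-trip
  tr3 <- tr
  tr3$vendor_note <- "keep me"
  js3 <- route_to_json(tr3)
  expect_match(js3, "keep me")
  expect_identical(route_to_json(route_from_json(js3)), js3)
  # schema violations name the offending path
  expect_error(route_from_json('{"type":"mol","children":[]}'), "smiles")
  expect_error(
    route_from_json(
      '{"type":"mol","smiles":"C","children":[{"type":"mol","smiles":"C"}]}'),
    "alternate")
  # reaction metadata is preserved verbatim
  md <- retrosynth:::route_reactions(
    route_from_json(route_to_json(tr)))[[1]]$metadata
  expect_identical(md$template_label, "amide")
})

test_that("extraction ranking agrees with an independent full sort", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  res <- mcts_search(u$targets[[1]]$mol,
                     search_config("mcts", iteration_limit = 200L),
                     exp, default_filters(), list(u$stock))
  col <- extract_routes(res, top_n = 5L)
  expect_lte(length(col$routes), 5L)
  # brute-force ordering of all recorded routes
  scores <- vapply(res$recorded, function(t)
    retrosynth:::route_score(t, max_transforms = 6L), numeric(1))
  solved <- vapply(res$recorded, function(t) compute_metrics(t)$solved,
                   logical(1))
  steps <- vapply(res$recorded, function(t) compute_metrics(t)$n_steps,
                  integer(1))
  ord <- order(-scores, !solved, steps, seq_along(res$recorded))
  want <- vapply(res$recorded[ord][seq_along(col$routes)],
                 retrosynth:::route_signature, character(1))
  got <- vapply(col$routes, retrosynth:::route_signature, character(1))
  expect_identical(got, want)
  expect_equal(col$scores, scores[ord][seq_along(col$routes)])
  # duplicates from different iterations were de-duplicated at recording
  expect_identical(anyDuplicated(vapply(res$recorded,
                                        retrosynth:::route_signature,
                                        character(1))), 0L)
})

test_that("tree edit distance is a metric on canonicalized routes", {
  u <- fixture_universe()
  exp <- fixture_expansion(u)
  routes <- list()
  for (tgt in u$targets) {
    res <- breadth_first_search(tgt$mol,
                                search_config("breadth_first",
                                              max_transforms = 2L),
                                exp, default_filters(), list(u$stock))
    routes <- c(routes, res$recorded)
  }
  routes <- c(routes, lapply(u$targets, function(t) t$route))
  expect_gte(length(routes), 4L)
  # identity, symmetry, non-negativity on pairs; triangle on triples
  set.seed(1)
  n <- length(routes)
  for (r in routes) expect_equal(tree_edit_distance(r, r), 0)
  for (rep in 1:15) {
    ijk <- sample.int(n, 3L, replace = TRUE)
    dij <- tree_edit_distance(routes[[ijk[1]]], routes[[ijk[2]]])
    dji <- tree_edit_distance(routes[[ijk[2]]], routes[[ijk[1]]])
    dik <- tree_edit_distance(routes[[ijk[1]]], routes[[ijk[3]]])
    dkj <- tree_edit_distance(routes[[ijk[3]]], routes[[ijk[2]]])
    expect_gte(dij, 0)
    expect_equal(dij, dji)
    expect_lte(dij, dik + dkj + 1e-9)
  }
  # swapping one leaf building block costs the leaf substitution plus the
  # induced change in the adjacent reaction's difference fingerprint
  leaf <- function(s) retrosynth:::mol_node(s, TRUE)
  mk <- function(last) retrosynth:::mol_node("CC(=O)NC", FALSE, list(
    retrosynth:::reaction_node("CC(=O)NC>>CC(=O)O.CN", list(),
                               list(leaf("CC(=O)O"), leaf(last)))))
  a <- mk("CN"); b <- mk("CCN")
  leaf_cost <- 1 - tanimoto(mol_fingerprint("CN"), mol_fingerprint("CCN"))
  prod <- canonicalize("CC(=O)NC")
  rxn_cost <- 1 - tanimoto(
    retrosynth:::reaction_fingerprint(prod, list(canonicalize("CC(=O)O"),
                                                 canonicalize("CN"))),
    retrosynth:::reaction_fingerprint(prod, list(canonicalize("CC(=O)O"),
                                                 canonicalize("CCN"))))
  expect_equal(tree_edit_distance(a, b), leaf_cost + rxn_cost)
  expect_gte(tree_edit_distance(a, b), leaf_cost)
})

test_that("clustering recovers duplicated route pairs", {
  u <- fixture_universe()
  base <- lapply(u$targets[1:3], function(t) t$route)
  routes <- c(base, base)[c(1, 4, 2, 5, 3, 6)]  # 3 exact-duplicate pairs
  col <- structure(list(routes = routes, scores = rep(1, 6),
                        distance_matrix = NULL, cluster_labels = NULL),
                   class = "route_collection")
  col <- cluster_routes(col, max_k = 8L)
  d <- col$distance_matrix
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_identical(col$k, 3L)
  expect_identical(col$cluster_labels[1], col$cluster_labels[2])
  expect_identical(col$cluster_labels[3], col$cluster_labels[4])
  expect_identical(col$cluster_labels[5], col$cluster_labels[6])
  expect_identical(sort(unique(col$cluster_labels)), 0:2)
  # silhouette choice cross-checked against a hand-coded oracle
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  sil <- vapply(2:5, function(k)
    oracle_silhouette(stats::cutree(hc, k = k), d), numeric(1))
  expect_identical((2:5)[which.max(sil)], 3L)
  # degenerate cases
  same <- structure(list(routes = base[c(1, 1, 1)], scores = rep(1, 3),
                         distance_matrix = NULL, cluster_labels = NULL),
                    class = "route_collection")
  expect_identical(cluster_routes(same)$k, 1L)
  two <- structure(list(routes = base[1:2], scores = rep(1, 2),
                        distance_matrix = NULL, cluster_labels = NULL),
                   class = "route_collection")
  col2 <- cluster_routes(two)
  expect_identical(col2$k, 2L)
  expect_identical(col2$cluster_labels, c(0L, 1L))
})
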