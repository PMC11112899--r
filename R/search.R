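# Tree-search engines.
#
# MCTS operates on the super-node representation: each search node holds the
# full multiset of molecules (solved and unsolved) reachable at that point,
# with per-molecule transform counts.  Retro* and breadth-first search
# operate on AND/OR trees where molecule (OR) nodes are solved by any one
# reaction and reaction (AND) nodes require all their reactants solved.
# All engines share the expansion/filter policies, the cycle guard, and the
# per-molecule depth bookkeeping: a molecule at `max_transforms` retro steps
# from the target is frozen rather than expanded.

#' Search configuration
#'
#' @param algorithm One of `"mcts"`, `"retrostar"`, `"breadth_first"`.
#' @param iteration_limit Maximum number of search iterations (default 100).
#' @param time_limit Wall-time limit in seconds, checked between iterations
#'   (default 120).
#' @param max_transforms Maximum number of retro steps per molecule
#'   (default 6).
#' @param exploration_c UCT exploration constant (default 1.4).
#' @param return_first Stop at the first solution (default FALSE).
#' @param seed Integer seed (default 1); searches are deterministic, the seed
#'   is part of the configuration for reproducibility bookkeeping.
#' @param top_n Number of routes kept at extraction (default 20).
#' @param max_routes Cap on enumerated routes per target (default 10000).
#' @return A `search_config`.
#' @export
search_config <- function(algorithm = c("mcts", "retrostar", "breadth_first"),
                          iteration_limit = 100L, time_limit = 120,
                          max_transforms = 6L, exploration_c = 1.4,
                          return_first = FALSE, seed = 1L, top_n = 20L,
                          max_routes = 10000L) {
  algorithm <- match.arg(algorithm)
  stopifnot(iteration_limit >= 1, time_limit > 0, max_transforms >= 0,
            exploration_c >= 0)
  structure(list(algorithm = algorithm,
                 iteration_limit = as.integer(iteration_limit),
                 time_limit = time_limit,
                 max_transforms = as.integer(max_transforms),
                 exploration_c = exploration_c,
                 return_first = isTRUE(return_first),
                 seed = as.integer(seed),
                 top_n = as.integer(top_n),
                 max_routes = as.integer(max_routes)),
            class = "search_config")
}

#' Cycle guard for retro reactions
#'
#' Rejects a reaction if any reactant regenerates a molecule already on the
#' path from the target to the acted-on molecule (or the product itself).
#'
#' @param reaction A `retro_reaction`.
#' @param ancestors Character vector of InChI keys on the path from the root
#'   to the reaction's product.
#' @return TRUE to keep, FALSE to reject.
#' @export
prevent_cycle <- function(reaction, ancestors) {
  banned <- c(ancestors, reaction$product$inchi_key)
  for (r in reaction$reactants) {
    if (r$inchi_key %in% banned) return(FALSE)
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Shared plumbing.

new_diagnostics <- function() {
  d <- new.env(parent = emptyenv())
  d$filtered_reactions <- 0L
  d$cycles_prevented <- 0L
  d$invalid_outcomes <- 0L
  d
}

diagnostics_list <- function(diag, expansion) {
  out <- list(filtered_reactions = diag$filtered_reactions,
              cycles_prevented = diag$cycles_prevented,
              invalid_outcomes = diag$invalid_outcomes)
  if (!is.null(expansion$counters)) {
    out$prior_evaluations <- expansion$counters$prior_evals
    out$expansion_cache_hits <- expansion$counters$cache_hits
  }
  out
}

# Instantiate a proposal and keep the reactions that pass the cycle guard
# and all filters.
accepted_reactions <- function(proposal, ancestors, filters, diag) {
  rxns <- instantiate_proposal(proposal, diag)
  keep <- list()
  for (rx in rxns) {
    if (!prevent_cycle(rx, ancestors)) {
      diag$cycles_prevented <- diag$cycles_prevented + 1L
      next
    }
    verdict <- apply_filters(rx, filters, diag)
    if (!verdict$keep) next
    if (length(verdict$scores) > 0)
      rx$metadata$filter_scores <- verdict$scores
    keep[[length(keep) + 1L]] <- rx
  }
  keep
}

# Build a reaction tree from a chain of action records.  Each record:
# list(product_id, product, reactants, reactant_ids, prior, metadata).
actions_to_tree <- function(target, target_id, actions, stock_fn) {
  by_product <- list()
  for (a in actions) by_product[[as.character(a$product_id)]] <- a
  build <- function(mol, id) {
    a <- by_product[[as.character(id)]]
    if (is.null(a)) return(mol_node(mol$smiles, stock_fn(mol)))
    kids <- lapply(seq_along(a$reactants), function(k)
      build(a$reactants[[k]], a$reactant_ids[k]))
    rsmi <- paste(vapply(a$reactants, function(m) m$smiles, character(1)),
                  collapse = ".")
    md <- a$metadata
    md$prior <- a$prior
    rn <- reaction_node(paste0(mol$smiles, ">>", rsmi), md, kids)
    mol_node(mol$smiles, FALSE, list(rn))
  }
  build(target, target_id)
}

search_result <- function(target, solved, recorded, iterations, wall_time,
                          diag, config, algorithm, expansion,
                          best_cost = NA_real_) {
  structure(list(target = target, solved = solved, recorded = recorded,
                 iterations_used = iterations, wall_time = wall_time,
                 diagnostics = diagnostics_list(diag, expansion),
                 config = config, algorithm = algorithm,
                 best_cost = best_cost),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", x$algorithm, " on ", x$target$smiles,
      "\n  solved: ", x$solved, "  iterations: ", x$iterations_used,
      "  routes recorded: ", length(x$recorded),
      "  wall time: ", sprintf("%.2fs", x$wall_time), "\n", sep = "")
  invisible(x)
}

# Route recorder with signature de-duplication and a size cap.
new_recorder <- function(cap) {
  env <- new.env(parent = emptyenv())
  env$routes <- list()
  env$sigs <- character(0)
  env$cap <- cap
  env
}

record_route <- function(rec, tree) {
  sig <- route_signature(tree)
  if (sig %in% rec$sigs) return(invisible(FALSE))
  if (length(rec$routes) >= rec$cap) return(invisible(FALSE))
  rec$sigs <- c(rec$sigs, sig)
  rec$routes[[length(rec$routes) + 1L]] <- tree
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# MCTS.

# State: list of entries, each list(mol, id, depth, in_stock, ancestors),
# sorted by (inchi_key, id).
state_new <- function(entries) {
  if (length(entries) > 1) {
    keys <- vapply(entries, function(e) e$mol$inchi_key, character(1))
    ids <- vapply(entries, function(e) e$id, integer(1))
    entries <- entries[order(keys, ids)]
  }
  entries
}

state_solved <- function(state) {
  all(vapply(state, function(e) e$in_stock, logical(1)))
}

state_frac <- function(state) {
  if (length(state) == 0) return(1)
  mean(vapply(state, function(e) e$in_stock, logical(1)))
}

state_depth <- function(state) {
  if (length(state) == 0) return(0L)
  max(vapply(state, function(e) e$depth, integer(1)))
}

state_expandable <- function(state, max_transforms) {
  which(vapply(state, function(e)
    !e$in_stock && e$depth < max_transforms, logical(1)))
}

state_reward <- function(state, max_transforms) {
  state_score(state_frac(state), state_depth(state),
              max_transforms = max_transforms)
}

# Apply an accepted reaction to a state: the acted entry is replaced by the
# reactants with incremented transform counts.
state_apply <- function(state, entry_idx, reaction, stock_fn, id_counter) {
  e <- state[[entry_idx]]
  anc <- c(e$ancestors, e$mol$inchi_key)
  new_entries <- lapply(reaction$reactants, function(m) {
    id_counter$n <- id_counter$n + 1L
    list(mol = m, id = id_counter$n, depth = e$depth + 1L,
         in_stock = stock_fn(m), ancestors = anc)
  })
  rest <- state[-entry_idx]
  list(state = state_new(c(rest, new_entries)),
       action = list(product_id = e$id, product = e$mol,
                     reactants = reaction$reactants,
                     reactant_ids = vapply(new_entries, function(x) x$id,
                                           integer(1)),
                     prior = reaction$prior,
                     metadata = reaction$metadata))
}

new_mcts_node <- function(state, parent, action, expansion, max_transforms) {
  node <- new.env(parent = emptyenv())
  node$state <- state
  node$parent <- parent
  node$action <- action
  node$children <- list()
  node$visits <- 0L
  node$total <- 0
  node$solved <- state_solved(state)
  node$dead <- FALSE
  # pooled untried actions: one batched policy call for all expandable
  # molecules (sibling node-expansion)
  exp_idx <- state_expandable(state, max_transforms)
  queue <- list()
  if (!node$solved && length(exp_idx) > 0) {
    props <- get_actions(expansion, lapply(exp_idx, function(i)
      state[[i]]$mol))
    for (j in seq_along(exp_idx)) {
      for (p in props[[j]]) {
        queue[[length(queue) + 1L]] <-
          list(kind = "lazy", proposal = p, entry = exp_idx[j])
      }
    }
    if (length(queue) > 1) {
      pr <- vapply(queue, function(q) q$proposal$prior, numeric(1))
      ent <- vapply(queue, function(q) q$entry, numeric(1))
      tix <- vapply(queue, function(q) q$proposal$template$index, numeric(1))
      queue <- queue[order(-pr, ent, tix)]
    }
  }
  node$queue <- queue
  node
}

#' UCT child selection
#'
#' Returns the child maximising `Q + c * sqrt(ln(N) / n)` where `Q` is the
#' child's mean reward, `N` the parent's visit count and `n` the child's.
#' Ties are broken by child creation order.
#'
#' @param node An MCTS node with at least one visited child.
#' @param c Exploration constant.
#' @return The selected child node.
#' @export
uct_select <- function(node, c = 1.4) {
  kids <- node$children
  if (length(kids) == 0) stop("uct_select: node has no children",
                              call. = FALSE)
  n_parent <- max(node$visits, 1L)
  best <- NULL; best_val <- -Inf
  for (ch in kids) {
    q <- if (ch$visits > 0) ch$total / ch$visits else 0
    u <- q + c * sqrt(log(n_parent) / max(ch$visits, 1L))
    if (u > best_val + 1e-12) { best_val <- u; best <- ch }
  }
  best
}

#' Backpropagate a reward
#'
#' Increments the visit count and accumulated reward of a node and all of
#' its ancestors.
#'
#' @param node An MCTS node.
#' @param reward Reward in `[0, 1]`.
#' @export
backpropagate <- function(node, reward) {
  while (!is.null(node)) {
    node$visits <- node$visits + 1L
    node$total <- node$total + reward
    node <- node$parent
  }
  invisible(NULL)
}

# Pop the next acceptable action from a node's queue; returns the accepted
# reaction + entry index or NULL if the queue is exhausted.
next_accepted_action <- function(node, filters, diag) {
  while (length(node$queue) > 0) {
    item <- node$queue[[1]]
    node$queue <- node$queue[-1]
    if (item$kind == "lazy") {
      e <- node$state[[item$entry]]
      rxns <- accepted_reactions(item$proposal, e$ancestors, filters, diag)
      if (length(rxns) == 0) next
      if (length(rxns) > 1) {
        extra <- lapply(rxns[-1], function(rx)
          list(kind = "concrete", reaction = rx, entry = item$entry))
        node$queue <- c(extra, node$queue)
      }
      return(list(reaction = rxns[[1]], entry = item$entry))
    }
    return(list(reaction = item$reaction, entry = item$entry))
  }
  NULL
}

# Greedy policy rollout; returns the terminal state and the actions taken.
mcts_rollout <- function(state, expansion, filters, stock_fn, max_transforms,
                         id_counter, diag, max_steps = 100L) {
  actions <- list()
  for (step in seq_len(max_steps)) {
    if (state_solved(state)) break
    exp_idx <- state_expandable(state, max_transforms)
    if (length(exp_idx) == 0) break
    idx <- exp_idx[1]
    e <- state[[idx]]
    props <- get_actions(expansion, list(e$mol))[[1]]
    applied <- FALSE
    for (p in props) {
      rxns <- accepted_reactions(p, e$ancestors, filters, diag)
      if (length(rxns) == 0) next
      res <- state_apply(state, idx, rxns[[1]], stock_fn, id_counter)
      state <- res$state
      actions[[length(actions) + 1L]] <- res$action
      applied <- TRUE
      break
    }
    if (!applied) break
  }
  list(state = state, actions = actions)
}

path_actions <- function(node) {
  acts <- list()
  while (!is.null(node$parent)) {
    acts <- c(list(node$action), acts)
    node <- node$parent
  }
  acts
}

#' Monte Carlo tree search for retrosynthesis
#'
#' Runs select / expand / rollout / backpropagate iterations on the
#' super-node state representation until the iteration or time limit is
#' reached (or the first solution, with `return_first`).  The reward is the
#' state score of the rollout's terminal state.  Every solved state
#' encountered is recorded as a route; terminal unsolved states are recorded
#' as partial routes.
#'
#' @param target Target molecule (`molecule` or SMILES).
#' @param config A `search_config`.
#' @param expansion An `expansion_strategy`.
#' @param filters List of `filter_strategy` objects.
#' @param stock List of `stock_source` objects.
#' @param criteria Optional `stop_criteria`.
#' @return A `search_result`.
#' @export
mcts_search <- function(target, config = search_config(), expansion,
                        filters = list(), stock = list(), criteria = NULL) {
  if (is.character(target)) target <- canonicalize(target)
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  diag <- new_diagnostics()
  stock_fn <- function(m) in_stock(m, stock, criteria)
  id_counter <- new.env(parent = emptyenv()); id_counter$n <- 1L
  recorder <- new_recorder(config$max_routes)
  root_state <- state_new(list(list(mol = target, id = 1L, depth = 0L,
                                    in_stock = stock_fn(target),
                                    ancestors = character(0))))
  root <- new_mcts_node(root_state, NULL, NULL, expansion,
                        config$max_transforms)
  if (root$solved) {
    # target itself purchasable: zero-step route
    record_route(recorder, mol_node(target$smiles, TRUE))
    wall <- proc.time()[["elapsed"]] - t0
    res <- search_result(target, TRUE, recorder$routes, 0L, wall, diag,
                         config, "mcts", expansion)
    return(res)
  }
  maybe_record <- function(node, rollout_actions, rollout_state) {
    st <- rollout_state
    if (state_solved(st) || length(state_expandable(st, config$max_transforms)) == 0) {
      acts <- c(path_actions(node), rollout_actions)
      tree <- actions_to_tree(target, 1L, acts, stock_fn)
      record_route(recorder, tree)
      return(state_solved(st))
    }
    FALSE
  }
  solved_any <- FALSE
  iterations <- 0L
  for (i in seq_len(config$iteration_limit)) {
    if (proc.time()[["elapsed"]] - t0 > config$time_limit) break
    iterations <- i
    node <- root
    repeat {
      if (node$solved) {
        backpropagate(node, state_reward(node$state, config$max_transforms))
        break
      }
      if (node$dead && length(node$children) == 0) {
        backpropagate(node, 0)
        break
      }
      if (length(node$queue) > 0) {
        nxt <- next_accepted_action(node, filters, diag)
        if (!is.null(nxt)) {
          res <- state_apply(node$state, nxt$entry, nxt$reaction, stock_fn,
                             id_counter)
          child <- new_mcts_node(res$state, node, res$action, expansion,
                                 config$max_transforms)
          node$children[[length(node$children) + 1L]] <- child
          ro <- mcts_rollout(child$state, expansion, filters, stock_fn,
                             config$max_transforms, id_counter, diag)
          if (maybe_record(child, ro$actions, ro$state)) solved_any <- TRUE
          backpropagate(child,
                        state_reward(ro$state, config$max_transforms))
          break
        }
        # queue exhausted; fall through to children / dead-end handling
      }
      if (length(node$children) > 0) {
        node <- uct_select(node, config$exploration_c)
      } else {
        node$dead <- TRUE
        if (maybe_record(node, list(), node$state)) solved_any <- TRUE
        backpropagate(node, 0)
        break
      }
    }
    if (config$return_first && solved_any) break
  }
  wall <- proc.time()[["elapsed"]] - t0
  solved <- any(vapply(recorder$routes, function(t)
    compute_metrics(t)$solved, logical(1)))
  res <- search_result(target, solved, recorder$routes, iterations, wall,
                       diag, config, "mcts", expansion)
  # visit-count conservation: the root absorbs one backpropagation per
  # completed iteration
  res$diagnostics$root_visits <- root$visits
  res
}

# ---------------------------------------------------------------------------
# AND/OR tree shared by breadth-first search and Retro*.

new_andor <- function(target, stock_fn) {
  a <- new.env(parent = emptyenv())
  a$or <- list(list(mol = target, depth = 0L, ancestors = character(0),
                    expanded = FALSE, reactions = integer(0),
                    in_stock = stock_fn(target)))
  a$and <- list()
  a
}

andor_expand <- function(arena, oi, expansion, filters, stock_fn, diag) {
  node <- arena$or[[oi]]
  props <- get_actions(expansion, list(node$mol))[[1]]
  rx_ids <- integer(0)
  for (p in props) {
    rxns <- accepted_reactions(p, node$ancestors, filters, diag)
    for (rx in rxns) {
      kid_ids <- integer(0)
      anc <- c(node$ancestors, node$mol$inchi_key)
      for (m in rx$reactants) {
        arena$or[[length(arena$or) + 1L]] <-
          list(mol = m, depth = node$depth + 1L, ancestors = anc,
               expanded = FALSE, reactions = integer(0),
               in_stock = stock_fn(m))
        kid_ids <- c(kid_ids, length(arena$or))
      }
      arena$and[[length(arena$and) + 1L]] <-
        list(reaction = rx, parent = oi, children = kid_ids,
             cost = -log(max(rx$prior, 1e-10)))
      rx_ids <- c(rx_ids, length(arena$and))
    }
  }
  node$expanded <- TRUE
  node$reactions <- rx_ids
  arena$or[[oi]] <- node
  length(rx_ids)
}

# Enumerate solved reaction trees below an OR node, with a per-path depth
# budget.  Returns a list of reaction_tree objects (possibly empty).
andor_routes <- function(arena, oi, budget, cap = Inf) {
  node <- arena$or[[oi]]
  if (node$in_stock) return(list(mol_node(node$mol$smiles, TRUE)))
  if (budget <= 0L || !node$expanded || length(node$reactions) == 0)
    return(list())
  out <- list()
  for (ai in node$reactions) {
    an <- arena$and[[ai]]
    per_child <- lapply(an$children, function(ci)
      andor_routes(arena, ci, budget - 1L, cap))
    if (any(vapply(per_child, length, integer(1)) == 0)) next
    combos <- list(list())
    for (pc in per_child) {
      nxt <- list()
      for (base in combos) for (t in pc)
        nxt[[length(nxt) + 1L]] <- c(base, list(t))
      combos <- nxt
    }
    rx <- an$reaction
    rsmi <- paste(vapply(rx$reactants, function(m) m$smiles, character(1)),
                  collapse = ".")
    md <- rx$metadata
    md$prior <- rx$prior
    for (kids in combos) {
      rn <- reaction_node(paste0(node$mol$smiles, ">>", rsmi), md, kids)
      out[[length(out) + 1L]] <- mol_node(node$mol$smiles, FALSE, list(rn))
      if (length(out) >= cap) return(out)
    }
  }
  out
}

#' Breadth-first retrosynthesis search
#'
#' Exhaustively expands the AND/OR tree level by level down to
#' `max_transforms`, subject to the expansion policy's top-k/cumulative
#' truncation and the filters, then enumerates all solved routes.
#'
#' @inheritParams mcts_search
#' @return A `search_result`.
#' @export
breadth_first_search <- function(target, config = search_config("breadth_first"),
                                 expansion, filters = list(), stock = list(),
                                 criteria = NULL) {
  if (is.character(target)) target <- canonicalize(target)
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  diag <- new_diagnostics()
  stock_fn <- function(m) in_stock(m, stock, criteria)
  arena <- new_andor(target, stock_fn)
  iterations <- 0L
  for (level in seq_len(config$max_transforms)) {
    if (proc.time()[["elapsed"]] - t0 > config$time_limit) break
    frontier <- which(vapply(arena$or, function(n)
      n$depth == level - 1L && !n$expanded && !n$in_stock, logical(1)))
    if (length(frontier) == 0) break
    for (oi in frontier) {
      andor_expand(arena, oi, expansion, filters, stock_fn, diag)
      iterations <- iterations + 1L
    }
  }
  routes <- andor_routes(arena, 1L, config$max_transforms,
                         cap = config$max_routes)
  wall <- proc.time()[["elapsed"]] - t0
  search_result(target, length(routes) > 0, routes, iterations, wall, diag,
                config, "breadth_first", expansion)
}

# Retro* value of an OR node under the zero heuristic.
retrostar_value <- function(arena, oi, max_transforms) {
  node <- arena$or[[oi]]
  if (node$in_stock) return(0)
  if (node$depth >= max_transforms) return(Inf)
  if (!node$expanded) return(0)
  if (length(node$reactions) == 0) return(Inf)
  best <- Inf
  for (ai in node$reactions) {
    an <- arena$and[[ai]]
    v <- an$cost
    for (ci in an$children) {
      v <- v + retrostar_value(arena, ci, max_transforms)
      if (v >= best) break
    }
    if (v < best) best <- v
  }
  best
}

# Walk the current minimum-cost partial route and collect its unexpanded
# molecule nodes (first one is the expansion frontier).
retrostar_frontier <- function(arena, oi, max_transforms) {
  node <- arena$or[[oi]]
  if (node$in_stock) return(integer(0))
  if (!node$expanded) return(oi)
  if (length(node$reactions) == 0) return(integer(0))
  vals <- vapply(node$reactions, function(ai) {
    an <- arena$and[[ai]]
    an$cost + sum(vapply(an$children, function(ci)
      retrostar_value(arena, ci, max_transforms), numeric(1)))
  }, numeric(1))
  ai <- node$reactions[[which.min(vals)]]
  out <- integer(0)
  for (ci in arena$and[[ai]]$children) {
    out <- c(out, retrostar_frontier(arena, ci, max_transforms))
  }
  out
}

#' Retro* best-first retrosynthesis search
#'
#' Best-first search on the AND/OR tree in the zero-heuristic (Retro*-0)
#' variant: reaction cost is `-ln(prior)`, unexpanded molecules are valued
#' optimistically at 0 and in-stock molecules at 0.  Each iteration expands
#' the first unexpanded molecule in the current minimum-cost partial route
#' and updates the cost bounds.  Terminates when the best route is proven
#' (no unexpanded molecule in it), or on the iteration/time limit.
#'
#' @inheritParams mcts_search
#' @return A `search_result`; `best_cost` holds the proven route cost.
#' @export
retrostar_search <- function(target, config = search_config("retrostar"),
                             expansion, filters = list(), stock = list(),
                             criteria = NULL) {
  if (is.character(target)) target <- canonicalize(target)
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  diag <- new_diagnostics()
  stock_fn <- function(m) in_stock(m, stock, criteria)
  arena <- new_andor(target, stock_fn)
  iterations <- 0L
  proven <- FALSE
  repeat {
    if (iterations >= config$iteration_limit) break
    if (proc.time()[["elapsed"]] - t0 > config$time_limit) break
    root_v <- retrostar_value(arena, 1L, config$max_transforms)
    if (is.infinite(root_v)) break
    frontier <- retrostar_frontier(arena, 1L, config$max_transforms)
    if (length(frontier) == 0) { proven <- TRUE; break }
    andor_expand(arena, frontier[1], expansion, filters, stock_fn, diag)
    iterations <- iterations + 1L
  }
  best_cost <- retrostar_value(arena, 1L, config$max_transforms)
  routes <- andor_routes(arena, 1L, config$max_transforms,
                         cap = config$max_routes)
  wall <- proc.time()[["elapsed"]] - t0
  search_result(target, length(routes) > 0, routes, iterations, wall, diag,
                config, "retrostar", expansion,
                best_cost = if (is.finite(best_cost)) best_cost else NA_real_)
}

#' Run the search algorithm selected by the configuration
#'
#' @inheritParams mcts_search
#' @return A `search_result`.
#' @export
run_search <- function(target, config = search_config(), expansion,
                       filters = list(), stock = list(), criteria = NULL) {
  switch(config$algorithm,
         mcts = mcts_search(target, config, expansion, filters, stock,
                            criteria),
         retrostar = retrostar_search(target, config, expansion, filters,
                                      stock, criteria),
         breadth_first = breadth_first_search(target, config, expansion,
                                              filters, stock, criteria))
}

# ---------------------------------------------------------------------------
# Route extraction.

#' Extract a ranked route collection from a search result
#'
#' Routes are de-duplicated by structural signature, scored, and ranked:
#' score descending, solved routes before unsolved at equal score, then
#' fewer reactions, then first-found order.
#'
#' @param result A `search_result`.
#' @param top_n Number of routes to keep (default from the search config).
#' @param scorer Optional scoring function `f(tree) -> numeric` (maximized);
#'   defaults to the state score of the route.
#' @return A `route_collection`.
#' @export
extract_routes <- function(result, top_n = NULL, scorer = NULL) {
  if (is.null(top_n)) top_n <- result$config$top_n
  stopifnot(top_n >= 1)
  routes <- result$recorded
  if (length(routes) == 0) {
    return(structure(list(routes = list(), scores = numeric(0),
                          distance_matrix = NULL, cluster_labels = NULL),
                     class = "route_collection"))
  }
  if (is.null(scorer)) {
    mt <- result$config$max_transforms
    scorer <- function(tree) route_score(tree, max_transforms = mt)
  }
  scores <- vapply(routes, scorer, numeric(1))
  solved <- vapply(routes, function(t) compute_metrics(t)$solved, logical(1))
  steps <- vapply(routes, function(t) compute_metrics(t)$n_steps, integer(1))
  ord <- order(-scores, !solved, steps, seq_along(routes))
  ord <- ord[seq_len(min(top_n, length(ord)))]
  structure(list(routes = routes[ord], scores = scores[ord],
                 distance_matrix = NULL, cluster_labels = NULL),
            class = "route_collection")
}

#' @export
print.route_collection <- function(x, ...) {
  cat("<route_collection> ", length(x$routes), " routes\n", sep = "")
  if (length(x$routes) > 0) {
    for (i in seq_len(min(5, length(x$routes)))) {
      m <- compute_metrics(x$routes[[i]])
      cat(sprintf("  [%d] score %.4f steps %d lls %d solved %s\n", i,
                  x$scores[i], m$n_steps, m$longest_linear_sequence,
                  m$solved))
    }
    if (length(x$routes) > 5) cat("  ...\n")
  }
  invisible(x)
}
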