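# Shared fixtures and independent oracles.  Everything is generated in code;
# expensive objects are memoized across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixture_cache)
  val
}

# The amide retro template of the worked examples.
amide_template <- function() {
  retro_template(
    "[C:1](=[O:2])[NH1:3][C:4]>>[C:1](=[O:2])[OH1].[NH2:3][C:4]",
    label = "amide", n_examples = 100L, index = 0L)
}

fixture_universe <- function(depth = 2L, seed = 7L, n_targets = 4L,
                             n_blocks = 12L, branching = 2L) {
  memo_fixture(paste("universe", depth, seed, n_targets, n_blocks, branching),
               generate_universe(n_blocks = n_blocks, depth = depth,
                                 branching = branching, seed = seed,
                                 n_targets = n_targets))
}

fixture_expansion <- function(universe) {
  memo_fixture(paste("expansion", universe$seed, universe$depth,
                     length(universe$templates)),
               template_expansion(universe$templates))
}

default_filters <- function() list(reactant_count_filter())

# ---------------------------------------------------------------------------
# Independent recursive route enumerator (oracle for the AND/OR searches).
# Plain depth-first recursion over the expansion proposals; shares only the
# policy layer with the engines under test, not their tree machinery.

oracle_enumerate <- function(mol, expansion, filters, stock, budget,
                             ancestors = character(0)) {
  if (in_stock(mol, stock)) {
    return(list(retrosynth:::mol_node(mol$smiles, TRUE)))
  }
  if (budget <= 0) return(list())
  out <- list()
  props <- get_actions(expansion, list(mol))[[1]]
  for (p in props) {
    for (rx in retrosynth:::instantiate_proposal(p)) {
      if (!prevent_cycle(rx, ancestors)) next
      if (!retrosynth:::apply_filters(rx, filters)$keep) next
      anc <- c(ancestors, mol$inchi_key)
      per_child <- lapply(rx$reactants, function(m)
        oracle_enumerate(m, expansion, filters, stock, budget - 1L, anc))
      if (any(vapply(per_child, length, integer(1)) == 0)) next
      combos <- list(list())
      for (pc in per_child) {
        nxt <- list()
        for (base in combos) for (t in pc)
          nxt[[length(nxt) + 1L]] <- c(base, list(t))
        combos <- nxt
      }
      rsmi <- paste(vapply(rx$reactants, function(m) m$smiles, character(1)),
                    collapse = ".")
      for (kids in combos) {
        rn <- retrosynth:::reaction_node(
          paste0(mol$smiles, ">>", rsmi),
          c(rx$metadata, list(prior = rx$prior)), kids)
        out[[length(out) + 1L]] <-
          retrosynth:::mol_node(mol$smiles, FALSE, list(rn))
      }
    }
  }
  out
}

oracle_signatures <- function(routes) {
  sort(vapply(routes, retrosynth:::route_signature, character(1)))
}

# Hand-coded mean silhouette width on a precomputed distance matrix.
oracle_silhouette <- function(labels, d) {
  n <- length(labels)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { widths[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(widths)
}

# Small hand-built route trees.
linear_route <- function(n_steps, in_stock_leaf = TRUE) {
  # target <- i1 <- i2 <- ... <- leaf, one reaction per level
  node <- retrosynth:::mol_node(paste0("C", strrep("C", n_steps), "O"),
                                in_stock_leaf)
  if (n_steps == 0) return(node)
  for (i in seq_len(n_steps)) {
    smi <- paste0("C", strrep("C", n_steps - i), "O")
    rn <- retrosynth:::reaction_node(paste0(smi, ">>x"),
                                     list(template_label = paste0("t", i),
                                          n_examples = 10 * i, prior = 0.5),
                                     list(node))
    node <- retrosynth:::mol_node(smi, FALSE, list(rn))
  }
  node
}

# Convergent route: final coupling of two fragments, each made in one step.
convergent_route <- function() {
  leaf <- function(s) retrosynth:::mol_node(s, TRUE)
  frag1 <- retrosynth:::mol_node(
    "CC(=O)O", FALSE,
    list(retrosynth:::reaction_node("CC(=O)O>>CC=O.O",
                                    list(template_label = "ox", prior = 0.9),
                                    list(leaf("CC=O"), leaf("O")))))
  frag2 <- retrosynth:::mol_node(
    "CCN", FALSE,
    list(retrosynth:::reaction_node("CCN>>CC=O.N",
                                    list(template_label = "ra", prior = 0.8),
                                    list(leaf("CC=O"), leaf("N")))))
  retrosynth:::mol_node(
    "CCNC(C)=O", FALSE,
    list(retrosynth:::reaction_node("CCNC(C)=O>>CC(=O)O.CCN",
                                    list(template_label = "amide",
                                         prior = 0.7),
                                    list(frag1, frag2))))
}
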