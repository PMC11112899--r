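# Synthetic reaction universe with planted ground-truth routes.
#
# Targets are composed forward from a catalogue of simple building blocks
# (amines, carboxylic acids, alcohols, alkyl/aryl bromides, boronic acids)
# using four invertible coupling reactions: amide formation, Fischer-type
# esterification, Williamson-type etherification, and Suzuki biaryl
# coupling.  Each forward step is the inverse of a retro template, so every
# planted route replays exactly and every algorithm can be validated against
# known ground truth without any external data.

.toy_blocks <- list(
  list(smiles = "CN",                  class = "amine"),
  list(smiles = "CCN",                 class = "amine"),
  list(smiles = "Nc1ccccc1",           class = "amine"),
  list(smiles = "NC1CC1",              class = "amine"),
  list(smiles = "CC(=O)O",             class = "acid"),
  list(smiles = "CCC(=O)O",            class = "acid"),
  list(smiles = "OC(=O)c1ccccc1",      class = "acid"),
  list(smiles = "CO",                  class = "alcohol"),
  list(smiles = "CC(C)O",              class = "alcohol"),
  list(smiles = "OCc1ccccc1",          class = "alcohol"),
  list(smiles = "OC1CCCCC1",           class = "alcohol"),
  list(smiles = "CBr",                 class = "alkyl_br"),
  list(smiles = "CCBr",                class = "alkyl_br"),
  list(smiles = "BrCc1ccccc1",         class = "alkyl_br"),
  list(smiles = "Brc1ccccc1",          class = "aryl_br"),
  list(smiles = "Cc1ccc(Br)cc1",       class = "aryl_br"),
  list(smiles = "OB(O)c1ccccc1",       class = "boronic"),
  list(smiles = "Cc1ccc(B(O)O)cc1",    class = "boronic"),
  # bromo-substituted bifunctional blocks keep chains alive beyond one step
  list(smiles = "Nc1ccc(Br)cc1",       class = "amine_br"),
  list(smiles = "NCc1ccc(Br)cc1",      class = "amine_br"),
  list(smiles = "OC(=O)c1ccc(Br)cc1",  class = "acid_br"),
  list(smiles = "OC(=O)c1cccc(Br)c1",  class = "acid_br"),
  list(smiles = "OCc1ccc(Br)cc1",      class = "alcohol_br"),
  list(smiles = "OCCc1ccc(Br)cc1",     class = "alcohol_br")
)

.toy_reactions <- list(
  list(label = "amide formation",
       retro = "[C:1](=[O:2])[NH1:3][#6:4]>>[C:1](=[O:2])[OH1].[NH2:3][#6:4]"),
  list(label = "ester formation",
       retro = "[C:1](=[O:2])[O:3][CX4:4]>>[C:1](=[O:2])[OH1].[OH1:3][CX4:4]"),
  list(label = "ether formation",
       retro = "[CX4:1]!@[O:2]!@[CX4:3]>>[Br][CX4:1].[OH1:2][CX4:3]"),
  list(label = "suzuki coupling",
       retro = "[c:1]-!@[c:2]>>[Br][c:1].[OH1][B]([OH1])[c:2]")
)

.toy_decoys <- list(
  list(label = "decoy fluorinative C-C cleavage",
       retro = "[CX4:1]!@[#6:2]>>[F][CX4:1].[F][#6:2]"),
  list(label = "decoy C-N fluorination",
       retro = "[N:1]!@[#6:2]>>[F][N:1].[F][#6:2]"),
  list(label = "decoy ring cleavage",
       retro = "[CX4:1]@[CX4:2]>>[CX4:1].[CX4:2]"),
  list(label = "decoy aromatic fluorination",
       retro = "[c:1]-!@[#6:2]>>[F][#6:2].[c:1][F]")
)

#' Generate a synthetic reaction universe
#'
#' Samples building blocks from a fixed catalogue, composes targets by
#' applying forward reactions up to `depth` levels, and returns the universe
#' together with one planted ground-truth route per target.  Fully
#' reproducible from the seed.
#'
#' @param n_blocks Number of building blocks to sample (>= 2; the sample is
#'   stratified so every reaction type stays feasible when `n_blocks` allows).
#' @param depth Number of forward reaction levels (>= 1); the planted route
#'   of every target has longest linear sequence `depth`.
#' @param branching Maximum branching: with `branching >= 2` the second
#'   reactant of a step may itself be a composed intermediate (convergent
#'   routes), otherwise it is always a building block (linear routes).
#' @param seed Integer seed.
#' @param n_targets Number of targets to compose (default 5).
#' @param max_attempts Bounded retries for infeasible compositions.
#' @return A `toy_universe` with fields `building_blocks`, `templates`,
#'   `targets` (list of `list(mol, route)`), `stock`, and `seed`.
#' @export
generate_universe <- function(n_blocks = 12L, depth = 2L, branching = 2L,
                              seed = 1L, n_targets = 5L,
                              max_attempts = 200L) {
  stopifnot(n_blocks >= 2, depth >= 1, n_targets >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  # stratified sample: one block per class first, remainder uniform
  classes <- vapply(.toy_blocks, function(b) b$class, character(1))
  picked <- integer(0)
  for (cl in unique(classes)) {
    cand <- which(classes == cl)
    picked <- c(picked, cand[sample.int(length(cand), 1L)])
  }
  if (length(picked) > n_blocks) picked <- picked[seq_len(n_blocks)]
  remaining <- setdiff(seq_along(.toy_blocks), picked)
  extra <- n_blocks - length(picked)
  if (extra > 0 && length(remaining) > 0) {
    picked <- c(picked, remaining[sample.int(length(remaining),
                                             min(extra, length(remaining)))])
  }
  blocks <- lapply(.toy_blocks[sort(picked)], function(b) {
    list(mol = canonicalize(b$smiles), class = b$class)
  })
  n_examples <- sample.int(1000L, length(.toy_reactions), replace = TRUE)
  templates <- lapply(seq_along(.toy_reactions), function(i) {
    retro_template(.toy_reactions[[i]]$retro, .toy_reactions[[i]]$label,
                   n_examples = n_examples[i], index = i - 1L)
  })
  block_keys <- vapply(blocks, function(b) b$mol$inchi_key, character(1))

  n_retries <- 0L
  couple <- function(main, partner) {
    # try every template/side assignment the two molecules can satisfy
    for (ti in sample.int(length(templates))) {
      tpl <- templates[[ti]]
      for (pair in list(list(main, partner), list(partner, main))) {
        if (!matches_reactant_side(tpl, 1L, pair[[1]]$mol)) next
        if (!matches_reactant_side(tpl, 2L, pair[[2]]$mol)) next
        prods <- apply_forward_template(tpl, list(pair[[1]]$mol,
                                                  pair[[2]]$mol))
        if (length(prods) == 0) next
        prod <- prods[[1]]
        kids <- list(pair[[1]]$tree, pair[[2]]$tree)
        ord <- order(vapply(kids, function(k) k$smiles, character(1)))
        kids <- kids[ord]
        rsmi <- paste(vapply(kids, function(k) k$smiles, character(1)),
                      collapse = ".")
        rn <- reaction_node(paste0(prod$smiles, ">>", rsmi),
                            list(template_label = tpl$label,
                                 n_examples = tpl$n_examples,
                                 policy_id = "planted"),
                            kids)
        return(list(mol = prod,
                    tree = mol_node(prod$smiles, FALSE, list(rn))))
      }
    }
    NULL
  }
  compose <- function(d) {
    # returns list(mol, tree) or NULL
    if (d == 0L) {
      b <- blocks[[sample.int(length(blocks), 1L)]]
      return(list(mol = b$mol, tree = mol_node(b$mol$smiles, TRUE)))
    }
    for (attempt in seq_len(10L)) {
      main <- compose(d - 1L)
      if (is.null(main)) next
      partner_depth <- if (branching >= 2L && d > 1L &&
                           stats::runif(1) < 0.5) {
        sample.int(d - 1L, 1L) - 1L
      } else 0L
      partner <- compose(partner_depth)
      if (is.null(partner)) next
      if (partner$mol$inchi_key == main$mol$inchi_key) next
      res <- couple(main, partner)
      if (!is.null(res)) return(res)
      # second chance: couple with a random plain building block
      b <- blocks[[sample.int(length(blocks), 1L)]]
      if (b$mol$inchi_key != main$mol$inchi_key) {
        res <- couple(main, list(mol = b$mol,
                                 tree = mol_node(b$mol$smiles, TRUE)))
        if (!is.null(res)) return(res)
      }
      n_retries <<- n_retries + 1L
    }
    NULL
  }

  targets <- list()
  attempts <- 0L
  while (length(targets) < n_targets) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("could not compose %d targets at depth %d after ",
                          "%d attempts (%d retries)"),
                   n_targets, depth, max_attempts, n_retries), call. = FALSE)
    res <- compose(depth)
    if (is.null(res)) next
    # a target that is itself purchasable is degenerate
    if (res$mol$inchi_key %in% block_keys) next
    m <- compute_metrics(res$tree)
    if (m$longest_linear_sequence != depth) next
    targets[[length(targets) + 1L]] <- list(mol = res$mol, route = res$tree)
  }
  stock <- stock_source("building-blocks",
                        lapply(blocks, function(b) b$mol))
  structure(list(building_blocks = blocks, templates = templates,
                 targets = targets, stock = stock, seed = as.integer(seed),
                 depth = as.integer(depth), n_retries = n_retries),
            class = "toy_universe")
}

#' @export
print.toy_universe <- function(x, ...) {
  cat("<toy_universe> seed ", x$seed, ": ", length(x$building_blocks),
      " building blocks, ", length(x$templates), " templates, ",
      length(x$targets), " targets (depth ", x$depth, ")\n", sep = "")
  invisible(x)
}

#' Add adversarial decoy templates to a universe's library
#'
#' Decoy retro templates match the composed targets but their products can
#' never reach the building-block stock; one decoy cleaves ring bonds and
#' triggers the reactant-count filter.  Decoys receive low example counts so
#' frequency priors rank true chemistry first.
#'
#' @param universe A `toy_universe`.
#' @param n_decoys Number of decoys to add (recycled from a fixed list).
#' @param seed Seed for the decoy example counts.
#' @return List of `retro_template`: the universe's templates followed by
#'   the decoys (indices continue the library order).
#' @export
adversarial_templates <- function(universe, n_decoys = 4L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  picks <- rep(seq_along(.toy_decoys), length.out = n_decoys)
  base <- universe$templates
  decoys <- lapply(seq_along(picks), function(j) {
    d <- .toy_decoys[[picks[j]]]
    retro_template(d$retro,
                   if (n_decoys > length(.toy_decoys))
                     paste0(d$label, " #", j) else d$label,
                   n_examples = sample.int(10L, 1L),
                   index = length(base) + j - 1L)
  })
  c(base, decoys)
}

#' Write a universe to disk in the pipeline's file formats
#'
#' Emits `templates.csv` (template library), `stock.csv` (building blocks
#' with synthetic prices/amounts), `targets.smi` (one SMILES per line) and
#' `routes.json` (planted routes, one JSON array).
#'
#' @param universe A `toy_universe`.
#' @param dir Output directory (created if missing).
#' @param templates Optional template list overriding the universe's own
#'   (e.g. from [adversarial_templates()]).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir, templates = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tpls <- templates %||% universe$templates
  df <- data.frame(template_smarts = vapply(tpls, function(t) t$smarts,
                                            character(1)),
                   label = vapply(tpls, function(t) t$label, character(1)),
                   n_examples = vapply(tpls, function(t) t$n_examples,
                                       integer(1)))
  utils::write.csv(df, file.path(dir, "templates.csv"), row.names = FALSE)
  blocks <- universe$building_blocks
  sdf <- data.frame(smiles = vapply(blocks, function(b) b$mol$smiles,
                                    character(1)),
                    price = round(seq(5, 100,
                                      length.out = length(blocks)), 2),
                    amount = 1000)
  utils::write.csv(sdf, file.path(dir, "stock.csv"), row.names = FALSE)
  writeLines(vapply(universe$targets, function(t) t$mol$smiles, character(1)),
             file.path(dir, "targets.smi"))
  routes <- lapply(universe$targets, function(t) tree_to_list(t$route))
  jsonlite::write_json(routes, file.path(dir, "routes.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replay a route forward and check that it regenerates its products
#'
#' Every reaction of the route is replayed in the forward direction using
#' the inverse of its retro template (matched by label).  The route is valid
#' if each recorded product is among the forward outcomes of its recorded
#' reactants and no InChI key repeats along any root-to-leaf path.
#'
#' @param tree A `reaction_tree`.
#' @param templates List of `retro_template` covering the route's labels.
#' @param stock Optional stock sources; when given, leaves must be in stock.
#' @param criteria Optional `stop_criteria`.
#' @return TRUE if the route replays, otherwise FALSE with attribute
#'   `"reason"`.
#' @export
replay_route <- function(tree, templates, stock = NULL, criteria = NULL) {
  labels <- vapply(templates, function(t) t$label, character(1))
  fail <- function(reason) structure(FALSE, reason = reason)
  check <- function(node, path_keys) {
    mol <- canonicalize(node$smiles)
    if (mol$inchi_key %in% path_keys) return(fail("cycle on path"))
    keys <- c(path_keys, mol$inchi_key)
    if (length(node$children) == 0) {
      if (!is.null(stock) && !in_stock(mol, stock, criteria))
        return(fail(paste("leaf not in stock:", node$smiles)))
      return(TRUE)
    }
    rn <- node$children[[1]]
    tpl_idx <- match(rn$metadata$template_label, labels)
    if (is.na(tpl_idx)) return(fail("unknown template label"))
    reactants <- lapply(rn$children, function(k) canonicalize(k$smiles))
    prods <- apply_forward_template(templates[[tpl_idx]], reactants)
    if (!mol$inchi_key %in% vapply(prods, function(p) p$inchi_key,
                                   character(1)))
      return(fail(paste("forward replay failed at", node$smiles)))
    for (k in rn$children) {
      r <- check(k, keys)
      if (!isTRUE(r)) return(r)
    }
    TRUE
  }
  check(tree, character(0))
}
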