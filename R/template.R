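# Retro reaction templates: parsing, substructure matching, application.
#
# A retro template is a reaction SMARTS "product_pattern>>reactant_patterns".
# Applying it to a product molecule enumerates substructure matches of the
# product pattern and rewrites the molecular graph according to the atom maps:
# bonds present on one side but not the other are broken or formed, atoms
# unmapped on the product side are removed, atoms unmapped on the reactant
# side are introduced.  The same machinery run with the sides swapped replays
# a reaction in the forward direction, which is how routes are validated.
#
# The supported pattern dialect covers element (upper/lower case or #n),
# H-count (H1), connection count (X4), charge, atom maps, bond orders
# (- = # :) and ring-membership bond constraints (@ / !@).

parse_pattern_side <- function(s) {
  p <- parse_smiles(s, pattern = TRUE)
  comp <- mg_components(p$graph)
  p$comp <- comp
  p$n_components <- max(comp)
  p
}

#' Create a retro reaction template
#'
#' @param smarts Retro reaction SMARTS (`product>>reactant1.reactant2`), with
#'   atom maps linking the two sides.
#' @param label Template identifier.
#' @param n_examples Number of literature reactions the template was derived
#'   from; used by frequency priors.
#' @param index Position of the template in its library (0-based).
#' @return An object of class `retro_template`.
#' @export
retro_template <- function(smarts, label = smarts, n_examples = 0L,
                           index = 0L) {
  sides <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop(sprintf("template '%s': expected exactly one '>>'", label),
         call. = FALSE)
  prod <- tryCatch(parse_pattern_side(sides[1]), error = function(e)
    stop(sprintf("template '%s': %s", label, conditionMessage(e)),
         call. = FALSE))
  reac <- tryCatch(parse_pattern_side(sides[2]), error = function(e)
    stop(sprintf("template '%s': %s", label, conditionMessage(e)),
         call. = FALSE))
  if (prod$n_components != 1)
    stop(sprintf("template '%s': product side must be a single pattern",
                 label), call. = FALSE)
  if (n_examples < 0)
    stop(sprintf("template '%s': n_examples must be >= 0", label),
         call. = FALSE)
  pm <- prod$map[prod$map > 0]
  rm_ <- reac$map[reac$map > 0]
  if (anyDuplicated(pm) || anyDuplicated(rm_))
    stop(sprintf("template '%s': duplicated atom map", label), call. = FALSE)
  prod <- annotate_default_bonds(prod)
  reac <- annotate_default_bonds(reac)
  prod$plans <- lapply(seq_len(prod$n_components), function(cid) {
    p <- prod; p$plans <- NULL; pattern_plan(p, cid)
  })
  reac$plans <- lapply(seq_len(reac$n_components), function(cid) {
    p <- reac; p$plans <- NULL; pattern_plan(p, cid)
  })
  structure(list(smarts = smarts, label = label,
                 n_examples = as.integer(n_examples),
                 index = as.integer(index),
                 product_side = prod, reactant_side = reac,
                 n_reactant_patterns = reac$n_components),
            class = "retro_template")
}

#' @export
print.retro_template <- function(x, ...) {
  cat("<retro_template> ", x$label, "\n  ", x$smarts,
      "\n  n_examples: ", x$n_examples, "\n", sep = "")
  invisible(x)
}

#' Load a template library from CSV
#'
#' The file must have a header `template_smarts,label,n_examples`; row order
#' defines the template index.  Malformed SMARTS fail here, at load time.
#'
#' @param path Path to the CSV file.
#' @return List of `retro_template` objects.
#' @export
load_templates <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("template_smarts", "label", "n_examples")
  if (!all(need %in% names(df)))
    stop("template CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    retro_template(df$template_smarts[i], df$label[i], df$n_examples[i],
                   index = i - 1L)
  })
}

# ---------------------------------------------------------------------------
# Pattern matching: backtracking subgraph isomorphism.

pattern_atom_matches <- function(pat, pi, g, hc, deg, i) {
  if (pat$graph$elem[pi] != g$elem[i]) return(FALSE)
  if (!pat$arom_any[pi] && pat$graph$arom[pi] != g$arom[i]) return(FALSE)
  if (!is.na(pat$hcount[pi]) && hc[i] != pat$hcount[pi]) return(FALSE)
  if (!is.na(pat$degree[pi]) && deg[i] != pat$degree[pi]) return(FALSE)
  if (!pat$charge_any[pi] && pat$graph$charge[pi] != g$charge[i]) return(FALSE)
  TRUE
}

pattern_bond_matches <- function(pat, pb, g, mb_order, mb_arom, mb_ring) {
  ring <- pat$bond_ring[pb]
  if (!is.na(ring) && as.logical(ring) != mb_ring) return(FALSE)
  spec_order <- pat$graph$bonds[pb, 3]
  spec_arom <- pat$graph$bonds[pb, 4] == 1L
  # a default single bond written between two pattern atoms with unspecified
  # aromaticity matches either a single or an aromatic molecule bond; explicit
  # '=' '#' ':' are exact
  if (spec_arom) return(mb_arom)
  if (spec_order == 1L) {
    if (pat$default_bond[pb]) return(mb_arom || (mb_order == 1L))
    return(!mb_arom && mb_order == 1L)
  }
  (!mb_arom) && mb_order == spec_order
}

# Precompute matching order for one pattern component: a DFS order in which
# every atom after the first is adjacent to an earlier atom.
pattern_plan <- function(pat, comp_id) {
  if (!is.null(pat$plans) && length(pat$plans) >= comp_id)
    return(pat$plans[[comp_id]])
  atoms <- which(pat$comp == comp_id)
  g <- pat$graph
  adj <- mg_adjacency(g)
  order <- atoms[1]
  placed <- atoms[1]
  anchor <- list(0L)   # bond row used to anchor each atom (0 for root)
  while (length(placed) < length(atoms)) {
    found <- FALSE
    for (a in setdiff(atoms, placed)) {
      rows <- adj[[a]]
      if (is.null(rows)) next
      hit <- rows[rows[, 1] %in% placed, , drop = FALSE]
      if (nrow(hit) > 0) {
        order <- c(order, a)
        placed <- c(placed, a)
        anchor[[length(anchor) + 1L]] <- hit[1, 4]
        found <- TRUE
        break
      }
    }
    if (!found) stop("disconnected pattern component", call. = FALSE)
  }
  list(order = order, anchor = anchor, atoms = atoms)
}

# Precomputed matching context for a molecule graph.
graph_context <- function(g) {
  hc <- mg_hcounts(g)
  adj <- mg_adjacency(g)
  deg <- vapply(seq_len(mg_n_atoms(g)), function(i) {
    d <- if (is.null(adj[[i]])) 0L else nrow(adj[[i]])
    d + hc[i]
  }, integer(1))
  list(g = g, hc = hc, adj = adj, deg = deg, ring = mg_ring_bonds(g))
}

# Cached context for a molecule's canonical SMILES.
mol_context <- function(smiles) {
  key <- paste0("ctx\r", smiles)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  ctx <- graph_context(parse_smiles(smiles))
  assign(key, ctx, envir = .chem_cache)
  ctx
}

# All injective matches of one pattern component in a molecule graph (given
# as a graph context).  Returns list of integer maps: pattern atom index ->
# molecule atom index.  With first_only, stops at the first match.
match_component <- function(pat, comp_id, ctx, exclude = integer(0),
                            first_only = FALSE) {
  g <- ctx$g; hc <- ctx$hc; adjm <- ctx$adj; deg <- ctx$deg; ring <- ctx$ring
  plan <- pattern_plan(pat, comp_id)
  pg <- pat$graph
  padj <- mg_adjacency(pg)
  results <- list()
  n_atoms <- mg_n_atoms(g)
  assign_ <- integer(mg_n_atoms(pg))  # 0 = unassigned

  bond_between <- function(i, j) {
    rows <- adjm[[i]]
    if (is.null(rows)) return(NULL)
    hit <- which(rows[, 1] == j)
    if (length(hit) == 0) return(NULL)
    rows[hit[1], ]
  }

  try_atom <- function(k) {
    if (first_only && length(results) > 0) return(invisible(NULL))
    if (k > length(plan$order)) {
      results[[length(results) + 1L]] <<- assign_
      return(invisible(NULL))
    }
    pa <- plan$order[k]
    for (cand in seq_len(n_atoms)) {
      if (cand %in% exclude) next
      if (cand %in% assign_) next
      if (!pattern_atom_matches(pat, pa, g, hc, deg, cand)) next
      # check all pattern bonds from pa to already-assigned atoms
      ok <- TRUE
      rows <- padj[[pa]]
      if (!is.null(rows)) {
        for (r in seq_len(nrow(rows))) {
          pnbr <- rows[r, 1]
          if (assign_[pnbr] == 0L) next
          mb <- bond_between(cand, assign_[pnbr])
          if (is.null(mb)) { ok <- FALSE; break }
          if (!pattern_bond_matches(pat, rows[r, 4], g,
                                    mb[2], mb[3] == 1L, ring[mb[4]])) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      assign_[pa] <<- cand
      try_atom(k + 1L)
      assign_[pa] <<- 0L
    }
    invisible(NULL)
  }
  try_atom(1L)
  results
}

# Mark which pattern bonds were written without an explicit symbol; needed for
# default-bond match semantics.  Stored on the pattern at parse time.
annotate_default_bonds <- function(pat) {
  nb <- nrow(pat$graph$bonds)
  # parse_smiles records explicit specs by setting order/arom away from the
  # default single/nonaromatic OR by a 'set' flag we do not keep; recover the
  # conservative rule: a single non-aromatic bond between atoms of unspecified
  # aromaticity is treated as "single or aromatic"
  def <- logical(nb)
  if (nb > 0) {
    for (b in seq_len(nb)) {
      a1 <- pat$graph$bonds[b, 1]; a2 <- pat$graph$bonds[b, 2]
      def[b] <- pat$graph$bonds[b, 3] == 1L && pat$graph$bonds[b, 4] == 0L &&
        (pat$arom_any[a1] || pat$arom_any[a2])
    }
  }
  pat$default_bond <- def
  pat
}

# ---------------------------------------------------------------------------
# Transform application.

# Apply the graph rewrite defined by (from_side -> to_side) to molecule graph
# g under a match `m` (from-side pattern atom -> atom of g).  Returns a list
# of component graphs (as SMILES strings) or NULL if the outcome is invalid.
apply_transform_match <- function(from, to, g, m) {
  fmap <- from$map; tmap <- to$map
  # to-side atom for each map id
  to_of_map <- integer(0)
  for (ti in seq_along(tmap)) if (tmap[ti] > 0) to_of_map[tmap[ti]] <- ti
  # molecule atom for each map id
  mol_of_map <- integer(0)
  for (fi in seq_along(fmap)) if (fmap[fi] > 0) mol_of_map[fmap[fi]] <- m[fi]

  g2 <- g
  # 1. clear explicit-H constraints on touched atoms (recomputed implicitly)
  touched <- m[m > 0]
  g2$hexp[touched] <- NA_integer_

  # 2. drop bonds of g matched by from-side bonds that are absent on the
  #    to side, and adjust orders that differ
  fb <- from$graph$bonds
  keep_bond <- rep(TRUE, nrow(g2$bonds))
  find_gbond <- function(a1, a2) {
    which((g2$bonds[, 1] == a1 & g2$bonds[, 2] == a2) |
          (g2$bonds[, 1] == a2 & g2$bonds[, 2] == a1))
  }
  to_bond_between_maps <- function(m1, m2) {
    if (m1 > length(to_of_map) || m2 > length(to_of_map)) return(NULL)
    t1 <- to_of_map[m1]; t2 <- to_of_map[m2]
    if (is.na(t1) || is.na(t2) || t1 == 0L || t2 == 0L) return(NULL)
    tb <- to$graph$bonds
    hit <- which((tb[, 1] == t1 & tb[, 2] == t2) | (tb[, 1] == t2 & tb[, 2] == t1))
    if (length(hit) == 0) return(NULL)
    tb[hit[1], ]
  }
  if (nrow(fb) > 0) {
    for (b in seq_len(nrow(fb))) {
      f1 <- fb[b, 1]; f2 <- fb[b, 2]
      m1 <- fmap[f1]; m2 <- fmap[f2]
      gb <- find_gbond(m[f1], m[f2])
      if (length(gb) == 0) next
      if (m1 == 0L || m2 == 0L) next  # bond to an atom being deleted
      tb <- to_bond_between_maps(m1, m2)
      if (is.null(tb)) {
        keep_bond[gb[1]] <- FALSE
      } else if (tb[3] != g2$bonds[gb[1], 3] && tb[4] == 0L) {
        g2$bonds[gb[1], 3] <- tb[3]
        g2$bonds[gb[1], 4] <- 0L
      }
    }
  }
  g2$bonds <- g2$bonds[keep_bond, , drop = FALSE]

  # 3. delete atoms unmapped on the from side
  del <- m[fmap == 0]

  # 4. add atoms unmapped on the to side
  tg <- to$graph
  new_idx <- integer(mg_n_atoms(tg))
  for (ti in seq_len(mg_n_atoms(tg))) {
    if (tmap[ti] > 0) next
    g2 <- mg_add_atom(g2, tg$elem[ti], tg$arom[ti], tg$charge[ti], NA_integer_)
    new_idx[ti] <- mg_n_atoms(g2)
  }
  mol_atom_of_to <- function(ti) {
    if (tmap[ti] > 0) {
      mid <- tmap[ti]
      if (mid > length(mol_of_map) || is.na(mol_of_map[mid]) ||
          mol_of_map[mid] == 0L) return(0L)
      return(mol_of_map[mid])
    }
    new_idx[ti]
  }

  # 5. add to-side bonds not already present in g2
  tb <- tg$bonds
  if (nrow(tb) > 0) {
    for (b in seq_len(nrow(tb))) {
      a1 <- mol_atom_of_to(tb[b, 1]); a2 <- mol_atom_of_to(tb[b, 2])
      if (a1 == 0L || a2 == 0L) next
      gb <- find_gbond(a1, a2)
      if (length(gb) > 0) next
      g2 <- mg_add_bond(g2, a1, a2, tb[b, 3], tb[b, 4] == 1L)
    }
  }

  # 6. remove deleted atoms, renumber bonds
  if (length(del) > 0) {
    keep <- setdiff(seq_len(mg_n_atoms(g2)), del)
    remap <- integer(mg_n_atoms(g2))
    remap[keep] <- seq_along(keep)
    g2$elem <- g2$elem[keep]; g2$arom <- g2$arom[keep]
    g2$charge <- g2$charge[keep]; g2$hexp <- g2$hexp[keep]
    bk <- g2$bonds[, 1] %in% keep & g2$bonds[, 2] %in% keep
    g2$bonds <- g2$bonds[bk, , drop = FALSE]
    if (nrow(g2$bonds) > 0) {
      g2$bonds[, 1] <- remap[g2$bonds[, 1]]
      g2$bonds[, 2] <- remap[g2$bonds[, 2]]
    }
  }

  if (!mg_valid(g2)) return(NULL)
  comp <- mg_components(g2)
  lapply(seq_len(max(comp)), function(cid) {
    write_smiles(g2, which(comp == cid))
  })
}

#' Apply a retro template to a product molecule
#'
#' Enumerates distinct substructure matches of the template's product pattern
#' and returns one reactant tuple per match.  Chemically invalid outcomes are
#' dropped and counted; tuples identical as a multiset of InChI keys are
#' de-duplicated; tuples containing the product itself are rejected.  Reactant
#' tuples are ordered by canonical SMILES.
#'
#' @param template A `retro_template`.
#' @param product A `molecule`.
#' @return A list with `tuples` (list of lists of `molecule`), and diagnostic
#'   counts `n_matches`, `n_invalid`, `n_self`, `n_duplicate`.
#' @export
apply_retro_template <- function(template, product) {
  key <- paste0("apply\r", template$smarts, "\r", product$inchi_key)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  ctx <- mol_context(product$smiles)
  g <- ctx$g
  from <- template$product_side
  to <- template$reactant_side
  matches <- match_component(from, 1L, ctx)
  tuples <- list()
  seen <- character(0)
  n_invalid <- 0L; n_self <- 0L; n_dup <- 0L
  for (m in matches) {
    frags <- apply_transform_match(from, to, g, m)
    if (is.null(frags)) { n_invalid <- n_invalid + 1L; next }
    mols <- vector("list", length(frags))
    bad <- FALSE
    for (k in seq_along(frags)) {
      mol <- tryCatch(canonicalize(frags[[k]]), error = function(e) NULL)
      if (is.null(mol)) { bad <- TRUE; break }
      mols[[k]] <- mol
    }
    if (bad) { n_invalid <- n_invalid + 1L; next }
    keys <- vapply(mols, function(x) x$inchi_key, character(1))
    if (product$inchi_key %in% keys) { n_self <- n_self + 1L; next }
    ord <- order(vapply(mols, function(x) x$smiles, character(1)))
    mols <- mols[ord]
    sig <- paste(sort(keys), collapse = "|")
    if (sig %in% seen) { n_dup <- n_dup + 1L; next }
    seen <- c(seen, sig)
    tuples[[length(tuples) + 1L]] <- mols
  }
  res <- list(tuples = tuples, n_matches = length(matches),
              n_invalid = n_invalid, n_self = n_self, n_duplicate = n_dup)
  assign(key, res, envir = .chem_cache)
  res
}

#' Replay a template in the forward direction
#'
#' Runs the template right-to-left: the reactant patterns are matched in the
#' supplied molecules (one pattern per molecule, over all assignments) and the
#' product-side rewrite is applied to their union.  Used to validate routes by
#' regenerating each product from its recorded reactants.
#'
#' @param template A `retro_template`.
#' @param reactants List of `molecule` objects.
#' @return List of product `molecule` objects (possibly empty).
#' @export
apply_forward_template <- function(template, reactants) {
  from <- template$reactant_side
  to <- template$product_side
  k <- from$n_components
  if (length(reactants) != k) return(list())
  fkey <- paste0("fwd\r", template$smarts, "\r",
                 paste(vapply(reactants, function(m) m$inchi_key,
                              character(1)), collapse = "|"))
  hit <- .chem_cache[[fkey]]
  if (!is.null(hit)) return(hit)
  # disjoint union of reactant graphs
  gu <- mg_empty()
  offs <- integer(length(reactants))
  for (i in seq_along(reactants)) {
    gi <- parse_smiles(reactants[[i]]$smiles)
    offs[i] <- mg_n_atoms(gu)
    gu$elem <- c(gu$elem, gi$elem); gu$arom <- c(gu$arom, gi$arom)
    gu$charge <- c(gu$charge, gi$charge); gu$hexp <- c(gu$hexp, gi$hexp)
    if (nrow(gi$bonds) > 0) {
      nb <- gi$bonds
      nb[, 1] <- nb[, 1] + offs[i]; nb[, 2] <- nb[, 2] + offs[i]
      gu$bonds <- rbind(gu$bonds, nb)
    }
  }
  comp_of_atom <- mg_components(gu)
  uctx <- graph_context(gu)
  perms <- permutations_of(k)
  out <- list()
  seen <- character(0)
  for (perm in perms) {
    # pattern component c must match inside molecule perm[c]
    partials <- list(integer(mg_n_atoms(from$graph)))
    ok <- TRUE
    for (cid in seq_len(k)) {
      target_mol <- perm[cid]
      allowed <- which(comp_of_atom == target_mol)
      ms <- match_component(from, cid, uctx,
                            exclude = setdiff(seq_len(mg_n_atoms(gu)), allowed))
      if (length(ms) == 0) { ok <- FALSE; break }
      nxt <- list()
      for (base in partials) {
        for (mm in ms) {
          cand <- base
          clash <- FALSE
          for (pi in which(from$comp == cid)) {
            if (mm[pi] %in% cand) { clash <- TRUE; break }
            cand[pi] <- mm[pi]
          }
          if (!clash) nxt[[length(nxt) + 1L]] <- cand
        }
      }
      if (length(nxt) == 0) { ok <- FALSE; break }
      partials <- nxt
    }
    if (!ok) next
    for (m in partials) {
      frags <- apply_transform_match(from, to, gu, m)
      if (is.null(frags)) next
      for (f in frags) {
        mol <- tryCatch(canonicalize(f), error = function(e) NULL)
        if (is.null(mol)) next
        if (mol$inchi_key %in% seen) next
        seen <- c(seen, mol$inchi_key)
        out[[length(out) + 1L]] <- mol
      }
    }
  }
  assign(fkey, out, envir = .chem_cache)
  out
}

# Does the molecule match component `cid` of the template's reactant side?
# Used by the universe generator to pre-screen feasible couplings.
matches_reactant_side <- function(template, cid, mol) {
  key <- paste0("side\r", template$smarts, "\r", cid, "\r", mol$inchi_key)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- length(match_component(template$reactant_side, cid,
                                mol_context(mol$smiles),
                                first_only = TRUE)) > 0
  assign(key, res, envir = .chem_cache)
  res
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  res <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      res[[length(res) + 1L]] <- c(i, rest[p])
    }
  }
  res
}
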