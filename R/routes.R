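# Reaction trees: the bipartite molecule/reaction representation of a single
# synthetic route, its JSON serialization, and route metrics.
#
# A reaction_tree is a nested list mirroring its JSON schema:
#   molecule node: type = "mol", smiles, in_stock, children (reaction nodes)
#   reaction node: type = "reaction", smiles ("product>>r1.r2"), metadata,
#                  children (molecule nodes)
# The root is the target molecule node; leaves are molecule nodes.

mol_node <- function(smiles, in_stock, children = list()) {
  structure(list(type = "mol", smiles = smiles, in_stock = in_stock,
                 children = children),
            class = "reaction_tree")
}

reaction_node <- function(smiles, metadata = list(), children = list()) {
  list(type = "reaction", smiles = smiles, metadata = metadata,
       children = children)
}

is_reaction_tree <- function(x) {
  is.list(x) && identical(x$type, "mol")
}

#' @export
print.reaction_tree <- function(x, ...) {
  m <- compute_metrics(x)
  cat("<reaction_tree> ", x$smiles, "\n  steps: ", m$n_steps,
      "  lls: ", m$longest_linear_sequence,
      "  starting materials: ", m$n_starting_materials,
      "  solved: ", m$solved, "\n", sep = "")
  invisible(x)
}

# All leaf molecule nodes, left to right.
route_leaves <- function(node) {
  if (identical(node$type, "mol")) {
    if (length(node$children) == 0) return(list(node))
    return(do.call(c, lapply(node$children, route_leaves)))
  }
  do.call(c, lapply(node$children, route_leaves))
}

# All reaction nodes.
route_reactions <- function(node) {
  if (identical(node$type, "mol")) {
    if (length(node$children) == 0) return(list())
    return(do.call(c, lapply(node$children, route_reactions)))
  }
  c(list(node), do.call(c, lapply(node$children, route_reactions)))
}

#' Route metrics
#'
#' Computes the step count, longest linear sequence (maximum number of
#' reactions on any root-to-leaf path), number of starting materials, solved
#' flag, and whether the route is convergent (some reaction joins at least
#' two branches that each contain further reactions).
#'
#' @param tree A `reaction_tree`.
#' @return A list of class `route_metrics`.
#' @export
compute_metrics <- function(tree) {
  stopifnot(is_reaction_tree(tree))
  n_steps <- 0L
  n_leaves <- 0L
  solved <- TRUE
  convergent <- FALSE
  # returns max reactions on any path below `node`
  walk <- function(node) {
    if (identical(node$type, "mol")) {
      if (length(node$children) == 0) {
        n_leaves <<- n_leaves + 1L
        if (!isTRUE(node$in_stock)) solved <<- FALSE
        return(0L)
      }
      return(max(vapply(node$children, walk, integer(1))))
    }
    # reaction node
    n_steps <<- n_steps + 1L
    depths <- vapply(node$children, walk, integer(1))
    if (sum(depths > 0L) >= 2L) convergent <<- TRUE
    1L + max(depths)
  }
  lls <- walk(tree)
  structure(list(n_steps = n_steps, longest_linear_sequence = lls,
                 n_starting_materials = n_leaves, solved = solved,
                 convergent = convergent),
            class = "route_metrics")
}

#' @export
print.route_metrics <- function(x, ...) {
  cat("steps: ", x$n_steps, "  lls: ", x$longest_linear_sequence,
      "  starting materials: ", x$n_starting_materials,
      "  solved: ", x$solved, "  convergent: ", x$convergent, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON serialization.  Key order is fixed and children keep their stored
# order, so two serializations of the same tree are byte-identical.

tree_to_list <- function(node) {
  if (identical(node$type, "mol")) {
    out <- list(type = "mol", smiles = node$smiles,
                in_stock = isTRUE(node$in_stock))
  } else {
    md <- node$metadata
    out <- list(type = "reaction", smiles = node$smiles,
                metadata = if (length(md) == 0) stats::setNames(list(), character(0)) else md)
  }
  extra <- setdiff(names(node), c("type", "smiles", "in_stock", "metadata",
                                  "children"))
  for (k in extra) out[[k]] <- node[[k]]
  out$children <- lapply(node$children, tree_to_list)
  if (length(out$children) == 0) out$children <- NULL
  out
}

#' Serialize a reaction tree to JSON
#'
#' @param tree A `reaction_tree`.
#' @param pretty Pretty-print (default FALSE).
#' @return A JSON string.
#' @export
route_to_json <- function(tree, pretty = FALSE) {
  as.character(jsonlite::toJSON(tree_to_list(tree), auto_unbox = TRUE,
                                digits = NA, pretty = pretty,
                                null = "null"))
}

list_to_tree <- function(x, path = "$") {
  if (!is.list(x))
    stop("route JSON: expected an object at ", path, call. = FALSE)
  type <- x$type
  if (is.null(type) || !type %in% c("mol", "reaction"))
    stop("route JSON: missing or bad 'type' at ", path, call. = FALSE)
  if (is.null(x$smiles))
    stop("route JSON: molecule/reaction without 'smiles' at ", path,
         call. = FALSE)
  kids <- x$children
  if (is.null(kids)) kids <- list()
  kids <- lapply(seq_along(kids), function(i)
    list_to_tree(kids[[i]], paste0(path, ".children[", i, "]")))
  for (k in kids) {
    want <- if (type == "mol") "reaction" else "mol"
    if (!identical(k$type, want))
      stop("route JSON: node types must alternate at ", path, call. = FALSE)
  }
  out <- x
  out$children <- kids
  if (type == "mol") {
    out$in_stock <- isTRUE(x$in_stock)
    class(out) <- "reaction_tree"
  }
  out
}

#' Parse a reaction tree from JSON
#'
#' Unknown keys are preserved and survive a round-trip.
#'
#' @param text JSON string (or connection/path accepted by
#'   [jsonlite::fromJSON]).
#' @return A `reaction_tree`.
#' @export
route_from_json <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  tr <- list_to_tree(x)
  if (!identical(tr$type, "mol"))
    stop("route JSON: root must be a molecule node", call. = FALSE)
  tr
}

# Structural signature: serialized form without reaction metadata; used for
# route de-duplication and set comparisons across search algorithms.
route_signature <- function(node) {
  if (identical(node$type, "mol")) {
    kids <- vapply(node$children, route_signature, character(1))
    return(paste0("M(", node$smiles,
                  if (length(kids)) paste0("|", paste(kids, collapse = ",")),
                  ")"))
  }
  kids <- sort(vapply(node$children, route_signature, character(1)))
  paste0("R[", paste(kids, collapse = ","), "]")
}

# Summed reaction cost -ln(prior) over a route (used to compare Retro* with
# enumerated routes).
route_cost <- function(tree, eps = 1e-10) {
  rxns <- route_reactions(tree)
  if (length(rxns) == 0) return(0)
  sum(vapply(rxns, function(r) {
    p <- r$metadata$prior
    if (is.null(p) || is.na(p)) 0 else -log(max(as.numeric(p), eps))
  }, numeric(1)))
}
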