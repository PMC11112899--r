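# Tree edit distance between synthetic routes, and distance-based route
# clustering.
#
# Routes are compared as ordered trees after putting children into a
# canonical order (sorted by subtree serialization), so the ordered-tree
# edit distance (Zhang & Shasha) acts as a metric on canonicalized routes.
# Node costs: insertion/deletion 1; substitution 1 - Tanimoto between
# molecule fingerprints for molecule/molecule pairs, 1 - Tanimoto between
# reaction difference fingerprints for reaction/reaction pairs, and 1 for
# mixed-kind pairs.

# Flatten a route into postorder label records with leftmost-leaf indices.
ted_flatten <- function(tree, radius = 2L, n_bits = 2048L) {
  labels <- list()
  lml <- integer(0)
  canon <- function(node) {
    if (length(node$children) > 0) {
      sigs <- vapply(node$children, route_signature, character(1))
      node$children <- lapply(node$children[order(sigs)], canon)
    }
    node
  }
  walk <- function(node, parent_mol) {
    child_idx <- integer(0)
    this_mol <- if (identical(node$type, "mol")) node$smiles else parent_mol
    for (ch in node$children) child_idx <- c(child_idx, walk(ch, this_mol))
    if (identical(node$type, "mol")) {
      lab <- list(kind = "mol",
                  fp = mol_fingerprint(canonicalize(node$smiles),
                                       radius, n_bits))
    } else {
      prod <- canonicalize(parent_mol)
      reac <- lapply(node$children, function(k) canonicalize(k$smiles))
      lab <- list(kind = "reaction",
                  fp = reaction_fingerprint(prod, reac, radius, n_bits))
    }
    labels[[length(labels) + 1L]] <<- lab
    i <- length(labels)
    lml[i] <<- if (length(child_idx) == 0) i else lml[child_idx[1]]
    i
  }
  walk(canon(tree), NULL)
  list(labels = labels, lml = lml, n = length(labels))
}

ted_sub_cost <- function(a, b) {
  if (!identical(a$kind, b$kind)) return(1)
  1 - tanimoto(a$fp, b$fp)
}

ted_keyroots <- function(lml) {
  n <- length(lml)
  seen <- logical(n + 1L)
  kr <- integer(0)
  for (i in n:1) {
    if (!seen[lml[i]]) {
      kr <- c(kr, i)
      seen[lml[i]] <- TRUE
    }
  }
  sort(kr)
}

#' Tree edit distance between two routes
#'
#' Ordered-tree edit distance with unit insertion/deletion costs and
#' fingerprint-based substitution costs; children are put in a canonical
#' deterministic order before comparison, so the distance is well defined on
#' routes regardless of how their branches were stored.
#'
#' @param a,b `reaction_tree` objects.
#' @param radius,n_bits Fingerprint parameters.
#' @return Distance `>= 0`; 0 exactly for structurally identical routes.
#' @export
tree_edit_distance <- function(a, b, radius = 2L, n_bits = 2048L) {
  ta <- ted_flatten(a, radius, n_bits)
  tb <- ted_flatten(b, radius, n_bits)
  n1 <- ta$n; n2 <- tb$n
  td <- matrix(0, n1, n2)
  kr1 <- ted_keyroots(ta$lml)
  kr2 <- ted_keyroots(tb$lml)
  for (i in kr1) {
    for (j in kr2) {
      li <- ta$lml[i]; lj <- tb$lml[j]
      m <- i - li + 2L; n <- j - lj + 2L
      fd <- matrix(0, m, n)
      for (x in 2:m) fd[x, 1] <- fd[x - 1L, 1] + 1
      for (y in 2:n) fd[1, y] <- fd[1, y - 1L] + 1
      for (x in 2:m) {
        for (y in 2:n) {
          ia <- li + x - 2L; jb <- lj + y - 2L
          if (ta$lml[ia] == li && tb$lml[jb] == lj) {
            cost <- ted_sub_cost(ta$labels[[ia]], tb$labels[[jb]])
            fd[x, y] <- min(fd[x - 1L, y] + 1, fd[x, y - 1L] + 1,
                            fd[x - 1L, y - 1L] + cost)
            td[ia, jb] <- fd[x, y]
          } else {
            xi <- ta$lml[ia] - li + 1L
            yj <- tb$lml[jb] - lj + 1L
            fd[x, y] <- min(fd[x - 1L, y] + 1, fd[x, y - 1L] + 1,
                            fd[xi, yj] + td[ia, jb])
          }
        }
      }
    }
  }
  td[n1, n2]
}

#' Pairwise route distance matrix
#'
#' @param collection A `route_collection` (or list of `reaction_tree`).
#' @param radius,n_bits Fingerprint parameters.
#' @return Symmetric matrix with zero diagonal.
#' @export
route_distance_matrix <- function(collection, radius = 2L, n_bits = 2048L) {
  routes <- if (inherits(collection, "route_collection"))
    collection$routes else collection
  n <- length(routes)
  d <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- tree_edit_distance(routes[[i]], routes[[j]],
                                                 radius, n_bits)
      }
    }
  }
  d
}

#' Cluster routes on their tree-edit-distance matrix
#'
#' Agglomerative clustering (average linkage) on the precomputed distances;
#' the number of clusters is chosen in `[2, min(max_k, n - 1)]` by maximum
#' mean silhouette width.  Labels are contiguous integers from 0 in order of
#' first route appearance.  With fewer than 2 routes, or when all routes are
#' identical, a single cluster is returned.
#'
#' @param collection A `route_collection`; if its `distance_matrix` is NULL
#'   it is computed first.
#' @param max_k Maximum number of clusters considered (default 8).
#' @return The collection with `distance_matrix` and `cluster_labels` filled
#'   in and an attribute-free list field `k` giving the chosen number.
#' @export
cluster_routes <- function(collection, max_k = 8L) {
  routes <- collection$routes
  n <- length(routes)
  if (is.null(collection$distance_matrix))
    collection$distance_matrix <- route_distance_matrix(collection)
  d <- collection$distance_matrix
  if (n < 2 || max(d) < 1e-12) {
    collection$cluster_labels <- rep(0L, n)
    collection$k <- if (n == 0) 0L else 1L
    return(collection)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (n == 2L) {
    # two distinct routes: forced split, silhouette is undefined
    collection$cluster_labels <- c(0L, 1L)
    collection$k <- 2L
    return(collection)
  }
  ks <- 2:min(max_k, n - 1L)
  best_k <- ks[1]; best_sil <- -Inf
  for (k in ks) {
    labels <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(labels, dmatrix = d)
    msil <- mean(sil[, "sil_width"])
    if (msil > best_sil + 1e-12) { best_sil <- msil; best_k <- k }
  }
  labels <- stats::cutree(hc, k = best_k)
  # relabel contiguously in order of first appearance
  relabel <- integer(0)
  out <- integer(n)
  for (i in seq_len(n)) {
    l <- as.character(labels[i])
    if (is.na(match(l, names(relabel)))) {
      relabel[l] <- length(relabel)
    }
    out[i] <- relabel[[l]]
  }
  collection$cluster_labels <- out
  collection$k <- best_k
  collection
}
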