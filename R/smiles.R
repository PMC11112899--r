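# Internal molecular graph engine.
#
# A molgraph is a plain list:
#   elem   character, element symbols ("C", "Br", ...)
#   arom   logical, aromatic flag per atom
#   charge integer formal charge per atom
#   hexp   integer explicit hydrogen count from bracket atoms, NA = implicit
#   bonds  integer matrix with columns a1, a2, order (1/2/3), arom (0/1)
#
# Hydrogens are implicit: the count is derived from default valences, with
# aromatic atoms consuming one extra valence unit for the delocalised system.
# This is the standard organic-subset SMILES model and is sufficient for the
# B/C/N/O/P/S/halogen chemistry this package manipulates; everything that
# leaves the package is re-canonicalized by OpenBabel anyway.

.default_valence <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

mg_empty <- function() {
  list(elem = character(0), arom = logical(0), charge = integer(0),
       hexp = integer(0),
       bonds = matrix(integer(0), ncol = 4,
                      dimnames = list(NULL, c("a1", "a2", "order", "arom"))))
}

mg_n_atoms <- function(g) length(g$elem)

mg_add_atom <- function(g, elem, arom = FALSE, charge = 0L, hexp = NA_integer_) {
  g$elem <- c(g$elem, elem)
  g$arom <- c(g$arom, arom)
  g$charge <- c(g$charge, as.integer(charge))
  g$hexp <- c(g$hexp, as.integer(hexp))
  g
}

mg_add_bond <- function(g, a1, a2, order = 1L, arom = FALSE) {
  g$bonds <- rbind(g$bonds, c(as.integer(a1), as.integer(a2),
                              as.integer(order), as.integer(arom)))
  g
}

# adjacency: list per atom of data rows (nbr, order, arom, bond index)
mg_adjacency <- function(g) {
  n <- mg_n_atoms(g)
  adj <- vector("list", n)
  nb <- nrow(g$bonds)
  if (nb > 0) {
    for (b in seq_len(nb)) {
      a1 <- g$bonds[b, 1]; a2 <- g$bonds[b, 2]
      adj[[a1]] <- rbind(adj[[a1]], c(a2, g$bonds[b, 3], g$bonds[b, 4], b))
      adj[[a2]] <- rbind(adj[[a2]], c(a1, g$bonds[b, 3], g$bonds[b, 4], b))
    }
  }
  adj
}

# Implicit hydrogen count per atom; negative values signal a valence violation.
mg_hcounts <- function(g) {
  n <- mg_n_atoms(g)
  consumed <- numeric(n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      o <- if (g$bonds[b, 4] == 1L) 1L else g$bonds[b, 3]
      consumed[g$bonds[b, 1]] <- consumed[g$bonds[b, 1]] + o
      consumed[g$bonds[b, 2]] <- consumed[g$bonds[b, 2]] + o
    }
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(g$hexp[i])) {
      h[i] <- g$hexp[i]
      next
    }
    val <- .default_valence[[g$elem[i]]]
    if (is.null(val)) { h[i] <- 0L; next }
    val <- val + g$charge[i]
    if (g$arom[i]) val <- val - 1L
    h[i] <- as.integer(val - consumed[i])
  }
  h
}

mg_valid <- function(g) all(mg_hcounts(g) >= 0L)

# Connected components; returns integer component id per atom.
mg_components <- function(g) {
  n <- mg_n_atoms(g)
  comp <- integer(n)
  adj <- mg_adjacency(g)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    stack <- start
    while (length(stack) > 0) {
      a <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[a] != 0L) next
      comp[a] <- cid
      if (!is.null(adj[[a]])) stack <- c(stack, adj[[a]][, 1])
    }
  }
  comp
}

# Ring-bond flags: a bond is in a ring iff removing it leaves its endpoints
# connected.  Molecules handled here are small, so the direct check is fine.
mg_ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  n <- mg_n_atoms(g)
  res <- logical(nb)
  for (b in seq_len(nb)) {
    a1 <- g$bonds[b, 1]; a2 <- g$bonds[b, 2]
    # BFS from a1 avoiding bond b
    seen <- logical(n)
    seen[a1] <- TRUE
    queue <- a1
    while (length(queue) > 0 && !seen[a2]) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (bb in seq_len(nb)) {
        if (bb == b) next
        x <- g$bonds[bb, 1]; y <- g$bonds[bb, 2]
        nxt <- if (x == cur) y else if (y == cur) x else next
        if (!seen[nxt]) { seen[nxt] <- TRUE; queue <- c(queue, nxt) }
      }
    }
    res[b] <- seen[a2]
  }
  res
}

# ---------------------------------------------------------------------------
# SMILES parser (organic subset + bracket atoms; stereo markers are ignored).
# Also used for the SMARTS-subset pattern dialect when `pattern = TRUE`, in
# which case per-atom constraint fields (hcount, degree, map, any-aromaticity)
# and per-bond constraints (ring membership) are collected.

parse_smiles <- function(s, pattern = FALSE) {
  g <- mg_empty()
  # pattern annotations
  pat <- list(map = integer(0), hcount = integer(0), degree = integer(0),
              arom_any = logical(0), charge_any = logical(0))
  bond_ring <- integer(0)   # per bond: NA none, 1 ring, 0 non-ring
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L
  prev <- 0L
  stack <- integer(0)
  pending <- NULL           # pending bond spec: list(order, arom, ring)
  rings <- list()           # digit -> list(atom, spec)
  np <- length(chars)

  take_bond <- function() {
    b <- pending
    pending <<- NULL
    b
  }

  add_parsed_atom <- function(elem, arom, charge, hexp, map, degree,
                              arom_any, charge_any) {
    g <<- mg_add_atom(g, elem, arom, charge, hexp)
    pat$map <<- c(pat$map, as.integer(map))
    pat$hcount <<- c(pat$hcount, as.integer(hexp))
    pat$degree <<- c(pat$degree, as.integer(degree))
    pat$arom_any <<- c(pat$arom_any, arom_any)
    pat$charge_any <<- c(pat$charge_any, charge_any)
    idx <- mg_n_atoms(g)
    if (prev > 0L) {
      b <- take_bond()
      connect(prev, idx, b)
    } else {
      pending <<- NULL
    }
    prev <<- idx
    idx
  }

  connect <- function(a1, a2, spec) {
    if (is.null(spec)) {
      # default bond: aromatic if both atoms aromatic, else single
      if (g$arom[a1] && g$arom[a2]) {
        g <<- mg_add_bond(g, a1, a2, 1L, TRUE)
      } else {
        g <<- mg_add_bond(g, a1, a2, 1L, FALSE)
      }
      bond_ring <<- c(bond_ring, NA_integer_)
    } else {
      g <<- mg_add_bond(g, a1, a2, spec$order, spec$arom)
      bond_ring <<- c(bond_ring, spec$ring)
    }
  }

  parse_err <- function(msg) {
    stop(sprintf("cannot parse %s '%s': %s",
                 if (pattern) "pattern" else "SMILES", s, msg), call. = FALSE)
  }

  while (i <= np) {
    ch <- chars[i]
    if (ch == " ") { i <- i + 1L; next }
    if (ch == ".") {
      prev <- 0L; pending <- NULL; i <- i + 1L; next
    }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (length(stack) == 0) parse_err("unbalanced ')'")
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\", "@", "!")) {
      spec <- if (is.null(pending)) list(order = 1L, arom = FALSE,
                                         ring = NA_integer_, set = FALSE)
              else pending
      if (ch == "=") { spec$order <- 2L; spec$set <- TRUE }
      else if (ch == "#") { spec$order <- 3L; spec$set <- TRUE }
      else if (ch == ":") { spec$arom <- TRUE; spec$set <- TRUE }
      else if (ch == "-") { spec$order <- 1L; spec$arom <- FALSE; spec$set <- TRUE }
      else if (ch == "@") { spec$ring <- 1L; spec$set <- TRUE }
      else if (ch == "!") {
        if (i + 1L <= np && chars[i + 1L] == "@") {
          spec$ring <- 0L; spec$set <- TRUE; i <- i + 1L
        } else parse_err("unsupported '!' expression")
      }
      # '/' and '\' are treated as plain single bonds
      if (ch %in% c("/", "\\")) { spec$order <- 1L; spec$set <- TRUE }
      pending <- spec
      i <- i + 1L; next
    }
    if (ch == "%" || grepl("^[0-9]$", ch)) {
      if (ch == "%") {
        if (i + 2L > np) parse_err("bad %% ring closure")
        num <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (prev == 0L) parse_err("ring closure before any atom")
      key <- num
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        spec <- pending
        if (is.null(spec)) spec <- op$spec
        connect(op$atom, prev, spec)
        pending <- NULL
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, spec = pending)
        pending <- NULL
      }
      next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) parse_err("unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, pattern, parse_err)
      add_parsed_atom(at$elem, at$arom, at$charge, at$hexp, at$map,
                      at$degree, at$arom_any, at$charge_any)
      i <- j + 1L; next
    }
    # bare atom
    two <- if (i + 1L <= np) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_parsed_atom(two, FALSE, 0L, NA_integer_, 0L, NA_integer_, FALSE, TRUE)
      i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_parsed_atom(ch, FALSE, 0L, NA_integer_, 0L, NA_integer_, FALSE, TRUE)
      i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_parsed_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, NA_integer_,
                      FALSE, TRUE)
      i <- i + 1L; next
    }
    parse_err(sprintf("unexpected character '%s'", ch))
  }
  if (length(rings) > 0) parse_err("unmatched ring bond")
  if (length(stack) > 0) parse_err("unbalanced '('")
  if (mg_n_atoms(g) == 0) parse_err("no atoms")
  if (pattern) {
    return(list(graph = g, map = pat$map, hcount = pat$hcount,
                degree = pat$degree, arom_any = pat$arom_any,
                charge_any = pat$charge_any, bond_ring = bond_ring))
  }
  # a bond written between two aromatic atoms defaults to aromatic, but only
  # ring bonds can actually be aromatic (e.g. the biaryl junction is single)
  if (nrow(g$bonds) > 0 && any(g$bonds[, 4] == 1L)) {
    ring <- mg_ring_bonds(g)
    demote <- g$bonds[, 4] == 1L & !ring
    if (any(demote)) {
      g$bonds[demote, 3] <- 1L
      g$bonds[demote, 4] <- 0L
    }
  }
  g
}

# Parse the body of a bracket atom, e.g. "NH2:3", "#6", "CX4", "nH", "O-".
parse_bracket_atom <- function(body, pattern, parse_err) {
  elem <- NULL; arom <- FALSE; arom_any <- FALSE
  charge <- 0L; charge_any <- !pattern
  hexp <- NA_integer_; degree <- NA_integer_; map <- 0L
  i <- 1L
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # optional isotope digits (ignored)
  while (i <= n && grepl("^[0-9]$", chars[i])) i <- i + 1L
  if (i <= n && chars[i] == "#") {
    # atomic-number primitive: element with unspecified aromaticity
    j <- i + 1L
    while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
    z <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
    tbl <- c("5" = "B", "6" = "C", "7" = "N", "8" = "O", "15" = "P",
             "16" = "S", "9" = "F", "17" = "Cl", "35" = "Br", "53" = "I")
    elem <- tbl[[as.character(z)]]
    if (is.null(elem)) parse_err(sprintf("unsupported atomic number %d", z))
    arom_any <- TRUE
    i <- j
  } else if (i <= n) {
    two <- if (i + 1L <= n) paste0(chars[i], chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      elem <- two; i <- i + 2L
    } else if (chars[i] %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elem <- chars[i]; i <- i + 1L
    } else if (chars[i] %in% c("b", "c", "n", "o", "p", "s")) {
      elem <- toupper(chars[i]); arom <- TRUE; i <- i + 1L
    } else parse_err(sprintf("bad bracket atom '[%s]'", body))
  } else parse_err(sprintf("bad bracket atom '[%s]'", body))
  while (i <= n) {
    ch <- chars[i]
    if (ch == "@") { i <- i + 1L; next }   # chirality ignored
    if (ch == "H") {
      j <- i + 1L
      cnt <- 1L
      if (j <= n && grepl("^[0-9]$", chars[j])) {
        cnt <- as.integer(chars[j]); j <- j + 1L
      }
      hexp <- cnt
      i <- j; next
    }
    if (ch == "X") {
      j <- i + 1L
      if (j > n || !grepl("^[0-9]$", chars[j]))
        parse_err("X must be followed by a digit")
      degree <- as.integer(chars[j])
      i <- j + 1L; next
    }
    if (ch == "+" || ch == "-") {
      sgn <- if (ch == "+") 1L else -1L
      j <- i + 1L
      amt <- 1L
      if (j <= n && grepl("^[0-9]$", chars[j])) {
        amt <- as.integer(chars[j]); j <- j + 1L
      } else {
        while (j <= n && chars[j] == ch) { amt <- amt + 1L; j <- j + 1L }
      }
      charge <- sgn * amt
      charge_any <- FALSE
      i <- j; next
    }
    if (ch == ":") {
      mapstr <- paste(chars[(i + 1L):n], collapse = "")
      if (!grepl("^[0-9]+$", mapstr)) parse_err("bad atom map")
      map <- as.integer(mapstr)
      break
    }
    parse_err(sprintf("unsupported bracket token '%s' in '[%s]'", ch, body))
  }
  list(elem = elem, arom = arom, arom_any = arom_any, charge = charge,
       charge_any = charge_any, hexp = hexp, degree = degree, map = map)
}

# ---------------------------------------------------------------------------
# SMILES writer.  Output is syntactically valid input for OpenBabel, which is
# the canonicalization authority; ring closures are assigned per back edge.

write_smiles <- function(g, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(mg_n_atoms(g))
  comp <- mg_components(g)
  parts <- character(0)
  for (cid in unique(comp[atoms])) {
    sel <- atoms[comp[atoms] == cid]
    parts <- c(parts, write_smiles_component(g, sel))
  }
  paste(parts, collapse = ".")
}

write_smiles_component <- function(g, atoms) {
  adj <- mg_adjacency(g)
  hc <- mg_hcounts(g)
  inset <- logical(mg_n_atoms(g)); inset[atoms] <- TRUE
  visited <- logical(mg_n_atoms(g))
  used_bond <- logical(nrow(g$bonds) + 1L)
  ring_num <- 0L
  ring_open <- list()  # bond index -> digit
  # pre-pass: find back edges via DFS
  order <- integer(0)
  back_edges <- integer(0)
  stack <- list(list(a = atoms[1], pb = 0L))
  seen <- logical(mg_n_atoms(g))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (seen[fr$a]) next
    seen[fr$a] <- TRUE
    rows <- adj[[fr$a]]
    if (!is.null(rows)) {
      for (r in seq_len(nrow(rows))) {
        nbr <- rows[r, 1]; bidx <- rows[r, 4]
        if (!inset[nbr] || bidx == fr$pb) next
        if (seen[nbr]) {
          back_edges <- c(back_edges, bidx)
        } else {
          stack[[length(stack) + 1L]] <- list(a = nbr, pb = bidx)
        }
      }
    }
  }
  back_edges <- unique(back_edges)
  is_back <- logical(nrow(g$bonds) + 1L)
  is_back[back_edges] <- TRUE
  ring_digit <- integer(nrow(g$bonds) + 1L)

  bond_sym <- function(b) {
    o <- g$bonds[b, 3]; ar <- g$bonds[b, 4] == 1L
    a1 <- g$bonds[b, 1]; a2 <- g$bonds[b, 2]
    if (ar) return("")
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    # explicit single needed between two aromatic atoms
    if (g$arom[a1] && g$arom[a2]) return("-")
    ""
  }

  atom_token <- function(a) {
    el <- g$elem[a]
    sym <- if (g$arom[a]) tolower(el) else el
    need_bracket <- g$charge[a] != 0L ||
      !(el %in% .organic_subset) ||
      (g$arom[a] && el != "C" && hc[a] > 0L)
    if (!need_bracket) return(sym)
    htxt <- if (hc[a] == 0L) "" else if (hc[a] == 1L) "H" else paste0("H", hc[a])
    ctxt <- if (g$charge[a] == 0L) ""
            else if (g$charge[a] == 1L) "+"
            else if (g$charge[a] == -1L) "-"
            else sprintf("%+d", g$charge[a])
    paste0("[", sym, htxt, ctxt, "]")
  }

  emit <- function(a, pb) {
    out <- character(0)
    if (pb != 0L) out <- c(out, bond_sym(pb))
    out <- c(out, atom_token(a))
    visited[a] <<- TRUE
    rows <- adj[[a]]
    # ring closures at this atom
    if (!is.null(rows)) {
      for (r in seq_len(nrow(rows))) {
        bidx <- rows[r, 4]
        if (!is_back[bidx] || bidx == pb) next
        if (ring_digit[bidx] == 0L) {
          ring_num <<- ring_num + 1L
          ring_digit[bidx] <<- ring_num
          out <- c(out, bond_sym(bidx),
                   if (ring_num > 9) paste0("%", ring_num) else as.character(ring_num))
        } else {
          d <- ring_digit[bidx]
          out <- c(out, if (d > 9) paste0("%", d) else as.character(d))
        }
      }
      kids <- list()
      for (r in seq_len(nrow(rows))) {
        nbr <- rows[r, 1]; bidx <- rows[r, 4]
        if (!inset[nbr] || is_back[bidx] || bidx == pb || visited[nbr]) next
        kids[[length(kids) + 1L]] <- list(a = nbr, b = bidx)
      }
      if (length(kids) > 0) {
        for (k in seq_along(kids)) {
          kid <- kids[[k]]
          if (visited[kid$a]) next
          sub <- emit(kid$a, kid$b)
          if (k < length(kids)) {
            out <- c(out, "(", sub, ")")
          } else {
            out <- c(out, sub)
          }
        }
      }
    }
    paste(out, collapse = "")
  }
  emit(atoms[1], 0L)
}
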