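# Molecule primitives: canonicalization, identity, fingerprints.
#
# Canonical SMILES and InChI keys come from OpenBabel (via ChemmineOB), which
# is the single authority for molecular identity in this package.  Everything
# is cached by input string because searches revisit the same molecules
# constantly.

.chem_cache <- new.env(parent = emptyenv())

ob_convert <- function(smiles, to) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, source = smiles),
    error = function(e) ""
  )
  out <- strsplit(out, "[ \t\n]+")[[1]]
  if (length(out) == 0 || !nzchar(out[1])) return(NA_character_)
  out[1]
}

ob_canonical <- function(smiles) {
  key <- paste0("can\r", smiles)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- ob_convert(smiles, "CAN")
  assign(key, res, envir = .chem_cache)
  res
}

ob_inchikey <- function(smiles) {
  key <- paste0("ik\r", smiles)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- ob_convert(smiles, "INCHIKEY")
  assign(key, res, envir = .chem_cache)
  res
}

#' Canonicalize a SMILES string into a Molecule
#'
#' Parses a SMILES string, derives its canonical form and InChI key, and
#' returns a `molecule` object.  Molecules are value objects: two molecules
#' are the same compound if and only if their InChI keys are equal, which is
#' also the identity used for stock lookups.
#'
#' @param smiles A SMILES string.
#' @return An object of class `molecule` with fields `smiles` (canonical
#'   SMILES) and `inchi_key` (27-character InChI key).
#' @examples
#' m <- canonicalize("OCC")
#' m$smiles      # "CCO"
#' m$inchi_key
#' @export
canonicalize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles))
    stop("'smiles' must be a single character string", call. = FALSE)
  key <- paste0("mol\r", smiles)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  # our own parser first: catches malformed input with a precise message and
  # guarantees the string is within the supported organic subset
  g <- parse_smiles(smiles)
  if (!mg_valid(g))
    stop(sprintf("cannot parse SMILES '%s': valence violation", smiles),
         call. = FALSE)
  can <- ob_canonical(smiles)
  ik <- ob_inchikey(smiles)
  if (is.na(can) || is.na(ik))
    stop(sprintf("cannot parse SMILES '%s'", smiles), call. = FALSE)
  mol <- structure(list(smiles = can, inchi_key = ik), class = "molecule")
  assign(key, mol, envir = .chem_cache)
  assign(paste0("mol\r", can), mol, envir = .chem_cache)
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$smiles, " [", x$inchi_key, "]\n", sep = "")
  invisible(x)
}

is_molecule <- function(x) inherits(x, "molecule")

same_molecule <- function(a, b) identical(a$inchi_key, b$inchi_key)

# ---------------------------------------------------------------------------
# Circular (Morgan-style) fingerprints over the internal graph.  Only relative
# Tanimoto similarities are consumed downstream (tree-edit-distance node
# substitution costs), so a simple deterministic integer hash suffices.

.hash_mix <- function(h, x) (h * 31 + x) %% 2147483647

.atom_seed <- function(g, hc, i) {
  el <- match(g$elem[i], c(.organic_subset, "*"))
  if (is.na(el)) el <- 99
  h <- .hash_mix(17, el)
  h <- .hash_mix(h, as.integer(g$arom[i]))
  h <- .hash_mix(h, g$charge[i] + 10)
  h <- .hash_mix(h, hc[i])
  h
}

#' Circular fingerprint of a molecule
#'
#' Computes a fixed-length bit vector by hashing circular atom environments up
#' to `radius` bonds, in the spirit of ECFP.  Deterministic for a given
#' canonical SMILES.
#'
#' @param mol A `molecule` (or SMILES string).
#' @param radius Environment radius in bonds (default 2).
#' @param n_bits Fingerprint length (default 2048).
#' @return A logical vector of length `n_bits`.
#' @export
mol_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  if (is.character(mol)) mol <- canonicalize(mol)
  stopifnot(radius >= 1L, n_bits >= 64L)
  key <- paste0("fp\r", mol$smiles, "\r", radius, "\r", n_bits)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- parse_smiles(mol$smiles)
  hc <- mg_hcounts(g)
  adj <- mg_adjacency(g)
  n <- mg_n_atoms(g)
  inv <- vapply(seq_len(n), function(i) .atom_seed(g, hc, i), numeric(1))
  bits <- logical(n_bits)
  set_bits <- function(vals) {
    idx <- (vals %% n_bits) + 1L
    bits[idx] <<- TRUE
  }
  set_bits(inv)
  if (n > 0) {
    for (r in seq_len(radius)) {
      nxt <- numeric(n)
      for (i in seq_len(n)) {
        h <- .hash_mix(101, r)
        h <- .hash_mix(h, inv[i])
        rows <- adj[[i]]
        if (!is.null(rows)) {
          codes <- vapply(seq_len(nrow(rows)), function(k) {
            b <- if (rows[k, 3] == 1L && rows[k, 2] == 1L) 4L else rows[k, 2]
            .hash_mix(b, inv[rows[k, 1]])
          }, numeric(1))
          for (cdx in sort(codes)) h <- .hash_mix(h, cdx)
        }
        nxt[i] <- h
      }
      inv <- nxt
      set_bits(inv)
    }
  }
  assign(key, bits, envir = .chem_cache)
  bits
}

#' Tanimoto similarity between two bit vectors
#'
#' @param a,b Logical vectors of equal length (fingerprints).
#' @return Similarity in `[0, 1]`; two empty fingerprints count as identical.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Difference fingerprint of a reaction: symmetric difference between the
# product bits and the union of the reactant bits.
reaction_fingerprint <- function(product, reactants, radius = 2L,
                                 n_bits = 2048L) {
  fp <- mol_fingerprint(product, radius, n_bits)
  racc <- logical(n_bits)
  for (r in reactants) racc <- racc | mol_fingerprint(r, radius, n_bits)
  xor(fp, racc)
}
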