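# Building-block stock: named sources of purchasable molecules, looked up by
# InChI key, with optional price/amount stop criteria.  Multiple sources act
# as a logical OR with per-source criteria evaluation.

#' Create a stock source
#'
#' @param name Source name.
#' @param molecules List of `molecule` objects (or SMILES strings).
#' @param price Optional named numeric vector, InChI key -> price.
#' @param amount Optional named numeric vector, InChI key -> amount (mg).
#' @return A `stock_source`.
#' @export
stock_source <- function(name, molecules, price = NULL, amount = NULL) {
  mols <- lapply(molecules, function(m)
    if (is.character(m)) canonicalize(m) else m)
  keys <- unique(vapply(mols, function(m) m$inchi_key, character(1)))
  keyset <- new.env(parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = keyset)
  if (!is.null(price) && !all(names(price) %in% keys))
    stop("priced keys must be stock members", call. = FALSE)
  if (!is.null(amount) && !all(names(amount) %in% keys))
    stop("amounted keys must be stock members", call. = FALSE)
  structure(list(name = name, keys = keys, keyset = keyset,
                 price = price, amount = amount),
            class = "stock_source")
}

#' @export
print.stock_source <- function(x, ...) {
  cat("<stock_source> ", x$name, ": ", length(x$keys), " molecules\n",
      sep = "")
  invisible(x)
}

#' Load a stock file
#'
#' Accepts either a plain text file of SMILES (one per line) or a CSV with a
#' `smiles` column and optional `price` and `amount` columns.  Unparseable
#' lines are skipped and counted in the `n_skipped` attribute.
#'
#' @param path File path.
#' @param name Source name (defaults to the file name).
#' @return A `stock_source`.
#' @export
load_stock <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("stock file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  is_csv <- grepl(",", first) || grepl("^\\s*smiles\\s*$", first,
                                       ignore.case = TRUE)
  if (is_csv) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df))
      stop("stock CSV must have a 'smiles' column: ", path, call. = FALSE)
    smi <- df$smiles
  } else {
    smi <- readLines(path, warn = FALSE)
    smi <- smi[nzchar(trimws(smi))]
    df <- NULL
  }
  mols <- list(); rows <- integer(0)
  n_skipped <- 0L
  for (i in seq_along(smi)) {
    m <- tryCatch(canonicalize(trimws(smi[i])), error = function(e) NULL)
    if (is.null(m)) { n_skipped <- n_skipped + 1L; next }
    mols[[length(mols) + 1L]] <- m
    rows <- c(rows, i)
  }
  price <- amount <- NULL
  if (!is.null(df)) {
    keys <- vapply(mols, function(m) m$inchi_key, character(1))
    if ("price" %in% names(df)) {
      price <- stats::setNames(as.numeric(df$price[rows]), keys)
      price <- price[!is.na(price)]
      # a molecule listed twice keeps its minimum price
      price <- tapply(price, names(price), min)
      price <- stats::setNames(as.numeric(price), names(price))
    }
    if ("amount" %in% names(df)) {
      amount <- stats::setNames(as.numeric(df$amount[rows]), keys)
      amount <- amount[!is.na(amount)]
      amount <- tapply(amount, names(amount), max)
      amount <- stats::setNames(as.numeric(amount), names(amount))
    }
  }
  src <- stock_source(name, mols, price = price, amount = amount)
  attr(src, "n_skipped") <- n_skipped
  src
}

#' Stop criteria for stock membership
#'
#' @param max_price Optional maximum price for a building block.
#' @param min_amount Optional minimum available amount (mg).
#' @return A `stop_criteria`.
#' @export
stop_criteria <- function(max_price = NULL, min_amount = NULL) {
  if (!is.null(max_price) && (!is.finite(max_price) || max_price <= 0))
    stop("max_price must be finite and positive", call. = FALSE)
  if (!is.null(min_amount) && (!is.finite(min_amount) || min_amount <= 0))
    stop("min_amount must be finite and positive", call. = FALSE)
  structure(list(max_price = max_price, min_amount = min_amount),
            class = "stop_criteria")
}

source_satisfies <- function(source, key, criteria) {
  if (is.null(source$keyset[[key]])) return(FALSE)
  if (is.null(criteria)) return(TRUE)
  if (!is.null(criteria$max_price) && !is.null(source$price)) {
    p <- source$price[[key]]
    if (!is.null(p) && !is.na(p) && p > criteria$max_price) return(FALSE)
  }
  if (!is.null(criteria$min_amount) && !is.null(source$amount)) {
    a <- source$amount[[key]]
    if (!is.null(a) && !is.na(a) && a < criteria$min_amount) return(FALSE)
  }
  TRUE
}

#' Is a molecule a purchasable building block?
#'
#' True iff some source contains the molecule's InChI key and that source's
#' entry satisfies the stop criteria.  Entries without price or amount data
#' pass the corresponding criterion (criteria are optional add-ons).
#'
#' @param mol A `molecule` (or SMILES string).
#' @param sources List of `stock_source` objects (or a single one).
#' @param criteria Optional `stop_criteria`.
#' @return Logical.
#' @export
in_stock <- function(mol, sources, criteria = NULL) {
  if (is.character(mol)) mol <- canonicalize(mol)
  if (inherits(sources, "stock_source")) sources <- list(sources)
  for (s in sources) {
    if (source_satisfies(s, mol$inchi_key, criteria)) return(TRUE)
  }
  FALSE
}

# Minimum price of a molecule across sources; NA if unpriced everywhere.
stock_price <- function(mol, sources) {
  if (inherits(sources, "stock_source")) sources <- list(sources)
  best <- NA_real_
  for (s in sources) {
    if (is.null(s$keyset[[mol$inchi_key]]) || is.null(s$price)) next
    p <- s$price[[mol$inchi_key]]
    if (is.null(p) || is.na(p)) next
    if (is.na(best) || p < best) best <- p
  }
  best
}

#' Per-source availability of a solved route's starting materials
#'
#' For each source, the fraction of the route's leaf molecules found in that
#' source.  A leaf present in several sources counts for each of them.
#'
#' @param tree A solved `reaction_tree`.
#' @param sources List of `stock_source` objects.
#' @param criteria Optional `stop_criteria`.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
availability_profile <- function(tree, sources, criteria = NULL) {
  if (inherits(sources, "stock_source")) sources <- list(sources)
  leaves <- route_leaves(tree)
  if (length(leaves) == 0) stop("route has no leaves", call. = FALSE)
  solved <- all(vapply(leaves, function(l)
    in_stock(canonicalize(l$smiles), sources, criteria), logical(1)))
  if (!solved)
    stop("availability profile requires a solved route", call. = FALSE)
  out <- numeric(length(sources))
  names(out) <- vapply(sources, function(s) s$name, character(1))
  for (j in seq_along(sources)) {
    hits <- vapply(leaves, function(l)
      source_satisfies(sources[[j]], canonicalize(l$smiles)$inchi_key,
                       criteria), logical(1))
    out[j] <- mean(hits)
  }
  out
}
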