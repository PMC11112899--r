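# Expansion and filter policies.
#
# An expansion strategy proposes ranked retro reactions for a molecule; a
# prior model supplies the probability vector over the template library.
# Trained single-step models plug in behind the same prior contract; the
# package ships a frequency prior (probability proportional to each
# template's example count) and an exact-match lookup prior.

#' Frequency prior over a template library
#'
#' Assigns every molecule the same probability vector, proportional to each
#' template's `n_examples`.  If all counts are zero the prior falls back to
#' uniform with a warning.
#'
#' @param templates List of `retro_template` objects.
#' @return A `prior_model`.
#' @export
frequency_prior <- function(templates) {
  stopifnot(length(templates) > 0)
  counts <- vapply(templates, function(t) as.numeric(t$n_examples), numeric(1))
  if (all(counts == 0)) {
    warning("all template example counts are zero; using a uniform prior",
            call. = FALSE)
    counts <- rep(1, length(counts))
  }
  probs <- counts / sum(counts)
  structure(list(id = "frequency",
                 predict = function(mols) {
                   matrix(rep(probs, length(mols)), nrow = length(mols),
                          byrow = TRUE)
                 },
                 n_templates = length(templates)),
            class = "prior_model")
}

#' Lookup prior from a molecule-to-probability table
#'
#' Exact-match lookup by InChI key.  Molecules absent from the table receive
#' an all-zero vector, i.e. no proposals.
#'
#' @param table Named list mapping InChI keys to normalized probability
#'   vectors over the template library.
#' @param n_templates Length of the probability vectors.
#' @return A `prior_model`.
#' @export
lookup_prior <- function(table, n_templates) {
  for (v in table) {
    if (length(v) != n_templates)
      stop("lookup table vectors must have length n_templates", call. = FALSE)
    if (any(v < 0) || (sum(v) > 0 && abs(sum(v) - 1) > 1e-9))
      stop("lookup table vectors must be normalized", call. = FALSE)
  }
  structure(list(id = "lookup",
                 predict = function(mols) {
                   out <- matrix(0, nrow = length(mols), ncol = n_templates)
                   for (i in seq_along(mols)) {
                     v <- table[[mols[[i]]$inchi_key]]
                     if (!is.null(v)) out[i, ] <- v
                   }
                   out
                 },
                 n_templates = n_templates),
            class = "prior_model")
}

#' Template-based expansion strategy
#'
#' Ranks templates for a molecule by prior probability, truncated to the
#' `top_k` most probable proposals and by a cumulative-probability cutoff.
#' The proposal that first reaches the cutoff is kept (inclusive rule), so at
#' least one proposal survives even under flat priors.  Results are memoized
#' by (strategy id, InChI key); template application is deferred until a
#' proposal is instantiated.
#'
#' @param templates List of `retro_template`.
#' @param prior_model A `prior_model`; defaults to `frequency_prior(templates)`.
#' @param top_k Maximum number of proposals per molecule (default 50).
#' @param cutoff_cumulative Cumulative prior cutoff (default 0.995).
#' @param id Strategy identifier.
#' @return An `expansion_strategy`.
#' @export
template_expansion <- function(templates, prior_model = NULL, top_k = 50L,
                               cutoff_cumulative = 0.995,
                               id = "template-expansion") {
  stopifnot(length(templates) > 0, top_k >= 1)
  if (is.null(prior_model)) prior_model <- frequency_prior(templates)
  cache <- new.env(parent = emptyenv())
  counters <- new.env(parent = emptyenv())
  counters$prior_evals <- 0L
  counters$cache_hits <- 0L
  self_id <- id
  propose <- function(mols) {
    missing_idx <- which(vapply(mols, function(m)
      is.null(cache[[m$inchi_key]]), logical(1)))
    if (length(missing_idx) > 0) {
      pm <- prior_model$predict(mols[missing_idx])
      counters$prior_evals <- counters$prior_evals + 1L
      for (j in seq_along(missing_idx)) {
        mol <- mols[[missing_idx[j]]]
        p <- pm[j, ]
        ord <- order(-p, seq_along(p))
        ord <- ord[p[ord] > 0]
        if (length(ord) > top_k) ord <- ord[seq_len(top_k)]
        csum <- cumsum(p[ord])
        keep <- which(csum - p[ord] < cutoff_cumulative)
        ord <- ord[keep]
        props <- lapply(ord, function(ti) {
          list(template = templates[[ti]], prior = p[ti],
               strategy_id = self_id, product = mol)
        })
        assign(mol$inchi_key, props, envir = cache)
      }
    }
    counters$cache_hits <- counters$cache_hits +
      length(mols) - length(missing_idx)
    lapply(mols, function(m) cache[[m$inchi_key]])
  }
  structure(list(id = id, propose = propose, counters = counters,
                 parameters = list(top_k = top_k,
                                   cutoff_cumulative = cutoff_cumulative,
                                   prior = prior_model$id),
                 templates = templates),
            class = "expansion_strategy")
}

#' Ranked proposals for a batch of molecules
#'
#' @param strategy An `expansion_strategy`.
#' @param mols List of `molecule` objects.
#' @return A list (one element per molecule) of proposal lists; each proposal
#'   carries `template`, `prior`, `strategy_id` and `product`.  Proposals are
#'   sorted by prior descending with ties broken by template index.
#' @export
get_actions <- function(strategy, mols) {
  stopifnot(inherits(strategy, "expansion_strategy"), length(mols) > 0)
  strategy$propose(mols)
}

#' Combine several expansion strategies
#'
#' Mode `"all"` merges the proposals of every strategy and re-sorts by raw
#' prior (no cross-strategy rescaling; the strategy id is kept in each
#' proposal).  Mode `"first"` returns, per molecule, the proposals of the
#' first strategy with a non-empty proposal list; later strategies are not
#' queried once one has answered.
#'
#' @param strategies Ordered list of `expansion_strategy` objects.
#' @param mode `"all"` or `"first"`.
#' @return An `expansion_strategy`.
#' @export
combine_expansions <- function(strategies, mode = c("all", "first")) {
  stopifnot(length(strategies) >= 1)
  if (!is.character(mode) || !mode[1] %in% c("all", "first"))
    stop("unknown combination mode: ", mode[1], call. = FALSE)
  mode <- mode[1]
  propose <- function(mols) {
    if (mode == "all") {
      per_strategy <- lapply(strategies, function(s) s$propose(mols))
      lapply(seq_along(mols), function(i) {
        merged <- do.call(c, lapply(per_strategy, function(ps) ps[[i]]))
        if (length(merged) == 0) return(list())
        pr <- vapply(merged, function(p) p$prior, numeric(1))
        merged[order(-pr, seq_along(merged))]
      })
    } else {
      out <- vector("list", length(mols))
      remaining <- seq_along(mols)
      for (s in strategies) {
        if (length(remaining) == 0) break
        props <- s$propose(mols[remaining])
        got <- vapply(props, function(p) length(p) > 0, logical(1))
        out[remaining[got]] <- props[got]
        remaining <- remaining[!got]
      }
      for (i in remaining) out[[i]] <- list()
      out
    }
  }
  structure(list(id = paste0("combined-", mode), propose = propose,
                 parameters = list(mode = mode),
                 strategies = strategies),
            class = "expansion_strategy")
}

# Instantiate a lazy proposal into concrete retro reactions (one per reactant
# tuple).  `diag` is an environment of diagnostic counters, if supplied.
instantiate_proposal <- function(proposal, diag = NULL) {
  res <- apply_retro_template(proposal$template, proposal$product)
  if (!is.null(diag)) {
    diag$invalid_outcomes <- (diag$invalid_outcomes %||% 0L) + res$n_invalid
  }
  lapply(res$tuples, function(tp) {
    structure(list(product = proposal$product, reactants = tp,
                   template = proposal$template, prior = proposal$prior,
                   metadata = list(template_label = proposal$template$label,
                                   n_examples = proposal$template$n_examples,
                                   policy_id = proposal$strategy_id)),
              class = "retro_reaction")
  })
}

#' @export
print.retro_reaction <- function(x, ...) {
  cat("<retro_reaction> ", x$product$smiles, " >> ",
      paste(vapply(x$reactants, function(m) m$smiles, character(1)),
            collapse = "."),
      "  [", x$metadata$template_label, ", prior ",
      format(x$prior, digits = 3), "]\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Filter policies: pure predicates over an instantiated retro reaction.

#' Reactant-count filter
#'
#' Rejects reactions whose number of reactant molecules differs from the
#' number of reactant patterns in the template, e.g. an intramolecular match
#' of a bimolecular template.
#'
#' @return A `filter_strategy`.
#' @export
reactant_count_filter <- function() {
  structure(list(id = "reactant-count",
                 check = function(reaction) {
                   expected <- reaction$template$n_reactant_patterns
                   got <- length(reaction$reactants)
                   if (got != expected) {
                     list(keep = FALSE, reason = "reactant-count")
                   } else {
                     list(keep = TRUE, reason = NA_character_)
                   }
                 }),
            class = "filter_strategy")
}

#' Feasibility filter
#'
#' Wraps a reaction scoring function into a filter: reactions scoring below
#' `cutoff` are rejected.  The score is recorded in the reaction metadata by
#' the caller.
#'
#' @param score_fn Function mapping a `retro_reaction` to a probability.
#' @param cutoff Rejection threshold in `[0, 1]` (default 0.05).
#' @return A `filter_strategy`.
#' @export
feasibility_filter <- function(score_fn, cutoff = 0.05) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  structure(list(id = "feasibility", cutoff = cutoff,
                 check = function(reaction) {
                   s <- score_fn(reaction)
                   if (!is.numeric(s) || is.na(s) || s < 0 || s > 1)
                     stop("feasibility score outside [0, 1]", call. = FALSE)
                   list(keep = s >= cutoff,
                        reason = if (s >= cutoff) NA_character_
                                 else "feasibility",
                        score = s)
                 }),
            class = "filter_strategy")
}

# Run all filters; returns list(keep, reason, scores).
apply_filters <- function(reaction, filters, diag = NULL) {
  scores <- list()
  for (f in filters) {
    v <- f$check(reaction)
    if (!is.null(v$score)) scores[[f$id]] <- v$score
    if (!v$keep) {
      if (!is.null(diag))
        diag$filtered_reactions <- (diag$filtered_reactions %||% 0L) + 1L
      return(list(keep = FALSE, reason = v$reason, scores = scores))
    }
  }
  list(keep = TRUE, reason = NA_character_, scores = scores)
}
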