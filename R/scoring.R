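# Scoring of search states and synthetic routes.
#
# The default state score is a bounded linear blend of the fraction of
# starting material in stock and a depth penalty:
#
#   score = w_stock * frac + w_len * (1 - min(n, L_max) / L_max)
#
# It is 1 exactly for a solved zero-step state, 0 for a fully unsolved state
# at maximum depth, monotone in both arguments, and in [0, 1] throughout.
# Route-cost scoring follows the molecule/reaction cost model of Badowski et
# al.: a flat cost per reaction plus a flat penalty per starting material not
# found in stock.

#' Default state score
#'
#' @param frac_in_stock Fraction of the state's molecules in stock.
#' @param n_transforms Depth of the state (maximum per-molecule number of
#'   retro steps from the target).
#' @param w_stock,w_len Blend weights; must sum to 1 (defaults 0.95/0.05).
#' @param max_transforms Depth at which the length term reaches 0 (default 6).
#' @return Score in `[0, 1]`.
#' @examples
#' state_score(1, 0)                        # 1
#' state_score(0.5, 3, max_transforms = 6)  # 0.5 under default weights
#' @export
state_score <- function(frac_in_stock, n_transforms, w_stock = 0.95,
                        w_len = 0.05, max_transforms = 6L) {
  if (abs(w_stock + w_len - 1) > 1e-9)
    stop("w_stock + w_len must equal 1", call. = FALSE)
  if (frac_in_stock < 0 || frac_in_stock > 1 || n_transforms < 0 ||
      max_transforms <= 0)
    stop("invalid state score arguments", call. = FALSE)
  depth <- min(n_transforms, max_transforms) / max_transforms
  w_stock * frac_in_stock + w_len * (1 - depth)
}

#' Fraction of a route's starting materials found in stock
#'
#' @param tree A `reaction_tree`.
#' @param sources List of `stock_source` objects; if omitted, the trees' own
#'   `in_stock` flags are used.
#' @param criteria Optional `stop_criteria`.
#' @return Fraction in `[0, 1]`; a route with no molecules counts as 1.
#' @export
fraction_in_stock <- function(tree, sources = NULL, criteria = NULL) {
  leaves <- route_leaves(tree)
  if (length(leaves) == 0) return(1)
  flags <- vapply(leaves, function(l) {
    if (is.null(sources)) isTRUE(l$in_stock)
    else in_stock(canonicalize(l$smiles), sources, criteria)
  }, logical(1))
  mean(flags)
}

#' Number of reactions in a route
#'
#' @param tree A `reaction_tree`.
#' @return Reaction-step count (ordering: minimize).
#' @export
number_of_reactions <- function(tree) {
  compute_metrics(tree)$n_steps
}

#' Number of precursors in a route
#'
#' Counts leaf molecules, duplicates included per occurrence.
#'
#' @param tree A `reaction_tree`.
#' @return Leaf count.
#' @export
number_of_precursors <- function(tree) {
  length(route_leaves(tree))
}

#' Average template occurrence over a route's reactions
#'
#' Mean of the `n_examples` counts of the templates used by the route; 0 for
#' a route without reactions.
#'
#' @param tree A `reaction_tree`.
#' @return Mean example count.
#' @export
average_template_occurrence <- function(tree) {
  rxns <- route_reactions(tree)
  if (length(rxns) == 0) return(0)
  counts <- vapply(rxns, function(r) {
    v <- r$metadata$n_examples
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))
  mean(counts)
}

#' Cost parameters for the Badowski route cost
#'
#' @param reaction_cost Cost per reaction step (default 1).
#' @param unavailable_molecule_cost Penalty per starting material not in
#'   stock (default 10).
#' @return A `cost_parameters`.
#' @export
cost_parameters <- function(reaction_cost = 1, unavailable_molecule_cost = 10) {
  stopifnot(is.finite(reaction_cost), reaction_cost > 0,
            is.finite(unavailable_molecule_cost),
            unavailable_molecule_cost > 0)
  structure(list(reaction_cost = reaction_cost,
                 unavailable_molecule_cost = unavailable_molecule_cost),
            class = "cost_parameters")
}

#' Badowski-style route cost
#'
#' Sum of a flat cost per reaction and, for every leaf molecule not in stock,
#' a flat unavailability penalty.  When `use_prices = TRUE` and a leaf is in
#' a priced stock source, its minimum price substitutes the flat penalty.
#'
#' @param tree A `reaction_tree`.
#' @param params A `cost_parameters`.
#' @param sources Optional list of `stock_source`; if omitted the trees' own
#'   `in_stock` flags are used.
#' @param criteria Optional `stop_criteria`.
#' @param use_prices Substitute stock prices for in-stock leaves (default
#'   FALSE, giving in-stock leaves cost 0).
#' @return Non-negative cost (ordering: minimize).
#' @export
badowski_cost <- function(tree, params = cost_parameters(), sources = NULL,
                          criteria = NULL, use_prices = FALSE) {
  n_rxn <- number_of_reactions(tree)
  cost <- n_rxn * params$reaction_cost
  for (l in route_leaves(tree)) {
    avail <- if (is.null(sources)) isTRUE(l$in_stock)
             else in_stock(canonicalize(l$smiles), sources, criteria)
    if (!avail) {
      cost <- cost + params$unavailable_molecule_cost
    } else if (use_prices && !is.null(sources)) {
      p <- stock_price(canonicalize(l$smiles), sources)
      if (!is.na(p)) cost <- cost + p
    }
  }
  cost
}

# Default route ranking score used at extraction: the state score evaluated
# on the route (depth = longest linear sequence).
route_score <- function(tree, w_stock = 0.95, w_len = 0.05,
                        max_transforms = 6L) {
  m <- compute_metrics(tree)
  state_score(fraction_in_stock(tree), m$longest_linear_sequence,
              w_stock, w_len, max_transforms)
}

#' Select a route scorer by name
#'
#' Returns a scoring function `f(tree) -> numeric` oriented for
#' maximization (scorers whose natural ordering is "minimize", such as the
#' reaction count or the Badowski cost, are negated).  These are the scorers
#' selectable from the batch configuration.
#'
#' @param name One of `"state_score"`, `"fraction_in_stock"`,
#'   `"number_of_reactions"`, `"number_of_precursors"`,
#'   `"average_template_occurrence"`, `"badowski_cost"`.
#' @param ... Parameters forwarded to the underlying scorer
#'   (e.g. `max_transforms` for the state score, `params` for the cost).
#' @return A function of one `reaction_tree`.
#' @export
route_scorer <- function(name = c("state_score", "fraction_in_stock",
                                  "number_of_reactions",
                                  "number_of_precursors",
                                  "average_template_occurrence",
                                  "badowski_cost"), ...) {
  name <- match.arg(name)
  extra <- list(...)
  switch(name,
         state_score = function(tree)
           do.call(route_score, c(list(tree), extra)),
         fraction_in_stock = function(tree)
           do.call(fraction_in_stock, c(list(tree), extra)),
         number_of_reactions = function(tree) -number_of_reactions(tree),
         number_of_precursors = function(tree) -number_of_precursors(tree),
         average_template_occurrence = function(tree)
           average_template_occurrence(tree),
         badowski_cost = function(tree)
           -do.call(badowski_cost, c(list(tree), extra)))
}
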