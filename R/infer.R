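# Exact inference: a brute-force enumeration oracle and production variable
# elimination. Both answer P(query | evidence) for a single query node.

evidence_to_idx <- function(spec, evidence) {
  if (length(evidence) == 0L) return(list())
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    stop("evidence must be a named node -> state mapping")
  }
  bad <- setdiff(names(evidence), names(spec$nodes))
  if (length(bad) > 0L) stop("evidence on unknown node(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (v in names(evidence)) {
    i <- match(as.character(evidence[[v]]), spec$nodes[[v]])
    if (is.na(i)) {
      stop(sprintf("state '%s' is not valid for node '%s'", evidence[[v]], v))
    }
    out[[v]] <- i
  }
  out
}

#' Exact posterior of one node by variable elimination
#'
#' Computes `P(query | evidence)` exactly. Non-query, non-evidence variables
#' are summed out greedily in min-weight order with a deterministic
#' alphabetical tie-break. If the query node itself carries evidence the
#' posterior is degenerate at the evidence state.
#'
#' @param model a `bbn_model`.
#' @param evidence named character vector or list mapping nodes to observed
#'   states; may be empty.
#' @param query name of the node whose posterior is wanted.
#' @return named numeric vector over the query node's states, summing to 1.
#' @export
infer_ve <- function(model, evidence = list(), query) {
  spec <- model$spec
  stopifnot(query %in% names(spec$nodes))
  ev_idx <- evidence_to_idx(spec, evidence)
  states <- spec$nodes[[query]]
  if (query %in% names(ev_idx)) {
    post <- stats::setNames(rep(0, length(states)), states)
    post[ev_idx[[query]]] <- 1
    return(post)
  }
  res <- ve_posterior(model, ev_idx, query)
  stats::setNames(as.numeric(res$posterior), states)
}

# Internal: posterior over a set of query variables plus evidence mass.
ve_posterior <- function(model, ev_idx, query_vars) {
  cards <- node_cards(model$spec)
  fs <- reduce_by_evidence(model_factors(model), ev_idx)
  res <- ve_eliminate(fs, cards, query = query_vars)
  if (!is.finite(res$p_evidence) || res$p_evidence <= 0) {
    stop("impossible evidence: the observed states have zero probability")
  }
  list(posterior = res$table / res$p_evidence, p_evidence = res$p_evidence)
}

#' Exact posterior of one node by full enumeration
#'
#' Test oracle: sums the factored joint distribution over every configuration
#' of the free (non-evidence) variables. Limited to joint state spaces of at
#' most `10^7` configurations.
#'
#' @inheritParams infer_ve
#' @return named numeric vector over the query node's states, summing to 1.
#' @export
infer_enumeration <- function(model, evidence = list(), query) {
  spec <- model$spec
  stopifnot(query %in% names(spec$nodes))
  cards <- node_cards(spec)
  if (prod(cards) > 1e7) stop("joint state space exceeds 10^7 configurations")
  ev_idx <- evidence_to_idx(spec, evidence)
  states <- spec$nodes[[query]]
  if (query %in% names(ev_idx)) {
    post <- stats::setNames(rep(0, length(states)), states)
    post[ev_idx[[query]]] <- 1
    return(post)
  }
  free <- setdiff(names(spec$nodes), names(ev_idx))
  grid <- as.matrix(expand.grid(lapply(cards[free], seq_len)))
  colnames(grid) <- free
  full <- matrix(0L, nrow = nrow(grid), ncol = length(cards),
                 dimnames = list(NULL, names(cards)))
  full[, free] <- grid
  for (v in names(ev_idx)) full[, v] <- ev_idx[[v]]
  p <- rep(1, nrow(full))
  for (v in names(spec$nodes)) {
    idx <- full[, v] + cards[v] * (parent_config_index(full, spec, v) - 1L)
    p <- p * model$cpts[[v]][idx]
  }
  tot <- sum(p)
  if (tot <= 0) stop("impossible evidence: the observed states have zero probability")
  post <- vapply(seq_along(states), function(s) sum(p[full[, query] == s]), numeric(1))
  stats::setNames(post / tot, states)
}
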