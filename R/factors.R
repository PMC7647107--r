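# Internal factor algebra over discrete variables.
#
# A factor is a list(vars = character(), values = numeric array) where the
# array's k-th dimension indexes states of vars[k]. A factor with no variables
# is a scalar. These are the primitives behind both exact inference routines.

new_factor <- function(vars, values) {
  if (length(vars) == 0L) {
    return(list(vars = character(0), values = as.numeric(values)))
  }
  values <- as.array(values)
  if (length(dim(values)) != length(vars)) {
    stop("factor dimension/variable mismatch")
  }
  list(vars = vars, values = values)
}

factor_cards <- function(f) {
  if (length(f$vars) == 0L) return(integer(0))
  stats::setNames(dim(f$values), f$vars)
}

# Slice a factor on var = state_index, dropping that dimension.
factor_reduce <- function(f, var, state_index) {
  p <- match(var, f$vars)
  if (is.na(p)) return(f)
  d <- dim(f$values)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[p]] <- state_index
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  newdim <- d[-p]
  vars <- f$vars[-p]
  if (length(vars) == 0L) {
    return(new_factor(character(0), as.numeric(vals)))
  }
  dim(vals) <- newdim
  new_factor(vars, vals)
}

# Broadcast f onto the variable set `vars` (a superset of f$vars) with
# cardinalities `cards` (named), returning the value array in `vars` order.
factor_expand <- function(f, vars, cards) {
  if (length(f$vars) == 0L) {
    return(array(f$values, dim = cards[vars]))
  }
  extra <- setdiff(vars, f$vars)
  vals <- f$values
  cur <- f$vars
  if (length(extra) > 0L) {
    vals <- array(vals, dim = c(dim(as.array(vals)), cards[extra]))
    cur <- c(cur, extra)
  }
  aperm(array(vals, dim = cards[cur]), match(vars, cur))
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0L) {
    if (length(f2$vars) == 0L) return(new_factor(character(0), f1$values * f2$values))
    return(new_factor(f2$vars, f2$values * as.numeric(f1$values)))
  }
  if (length(f2$vars) == 0L) {
    return(new_factor(f1$vars, f1$values * as.numeric(f2$values)))
  }
  cards <- c(factor_cards(f1), factor_cards(f2))
  cards <- cards[!duplicated(names(cards))]
  vars <- names(cards)
  v1 <- factor_expand(f1, vars, cards)
  v2 <- factor_expand(f2, vars, cards)
  new_factor(vars, v1 * v2)
}

factor_product_list <- function(fs) {
  out <- fs[[1L]]
  if (length(fs) > 1L) {
    for (k in 2L:length(fs)) out <- factor_product(out, fs[[k]])
  }
  out
}

# Sum a variable out of a factor.
factor_sum_out <- function(f, var) {
  p <- match(var, f$vars)
  if (is.na(p)) return(f)
  d <- dim(f$values)
  if (length(d) == 1L) {
    return(new_factor(character(0), sum(f$values)))
  }
  perm <- c(p, seq_along(d)[-p])
  vals <- aperm(f$values, perm)
  vals <- colSums(array(vals, dim = c(d[p], prod(d[-p]))))
  dim(vals) <- d[-p]
  new_factor(f$vars[-p], vals)
}

# Restrict a list of factors by hard evidence (named integer state indices).
reduce_by_evidence <- function(factors, evidence_idx) {
  if (length(evidence_idx) == 0L) return(factors)
  lapply(factors, function(f) {
    for (v in intersect(names(evidence_idx), f$vars)) {
      f <- factor_reduce(f, v, evidence_idx[[v]])
    }
    f
  })
}

# Variable elimination over evidence-reduced factors.
#
# Eliminates every variable not in `query` using a min-weight (product of
# cardinalities of the induced clique) greedy order with alphabetical
# tie-break, then multiplies the remaining factors. Returns the unnormalized
# table over `query` (in the order given) and the evidence probability mass.
ve_eliminate <- function(factors, cards, query = character(0)) {
  factors <- Filter(function(f) TRUE, factors)
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), query)
  while (length(elim) > 0L) {
    # greedy min-weight choice, deterministic tie-break by name
    weights <- vapply(elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f) {
        if (v %in% f$vars) f$vars else character(0)
      })))
      prod(cards[nb])
    }, numeric(1))
    ord <- order(weights, elim)
    v <- elim[ord[1L]]
    hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- factor_product_list(factors[hit])
    factors <- c(factors[!hit], list(factor_sum_out(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  res <- factor_product_list(factors)
  if (length(query) > 0L) {
    cq <- cards[query]
    vals <- factor_expand(res, query, cq)
    res <- new_factor(query, array(vals, dim = cq))
  }
  list(table = res$values, p_evidence = sum(res$values))
}
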