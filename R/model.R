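#' Fitted discrete network model
#'
#' A `bbn_model` couples a [network_spec()] with one conditional probability
#' table (CPT) per node. Each CPT is stored as an array whose first dimension
#' indexes the node's states and whose remaining dimensions index the states
#' of its parents, so every column (fixed parent configuration) is a
#' probability vector.
#'
#' @name bbn_model
NULL

new_bbn_model <- function(spec, cpts, meta = list()) {
  m <- structure(list(spec = spec, cpts = cpts, meta = meta), class = "bbn_model")
  check_model(m)
  m
}

check_model <- function(model) {
  spec <- model$spec
  if (!setequal(names(model$cpts), names(spec$nodes))) {
    stop("CPTs must cover exactly the nodes of the specification")
  }
  cards <- node_cards(spec)
  for (v in names(spec$nodes)) {
    cpt <- model$cpts[[v]]
    want <- c(cards[v], cards[spec$parents[[v]]])
    if (!identical(unname(dim(as.array(cpt))), as.integer(unname(want)))) {
      stop(sprintf("CPT for '%s' has the wrong dimensions", v))
    }
    cols <- matrix(cpt, nrow = cards[v])
    s <- colSums(cols)
    if (any(cols < -1e-12) || any(abs(s - 1) > 1e-9)) {
      stop(sprintf("CPT for '%s' has a column that is not a probability vector", v))
    }
  }
  invisible(TRUE)
}

#' @export
print.bbn_model <- function(x, ...) {
  cat(sprintf("Fitted discrete network: %d nodes, %d edges\n",
              length(x$spec$nodes), nrow(x$spec$edges)))
  if (!is.null(x$meta$iterations)) {
    cat(sprintf("  learning: %d iteration(s), prior ESS %.3g, final log-likelihood %.4f\n",
                x$meta$iterations, x$meta$prior_ess %||% NA,
                utils::tail(x$meta$loglik_trace, 1)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert a categorical dataset (data frame of factors/characters, NA for
# missing) into an integer code matrix aligned with the spec's state lists.
dataset_to_codes <- function(data, spec) {
  miss <- setdiff(names(spec$nodes), names(data))
  if (length(miss) > 0L) {
    stop("dataset lacks columns for nodes: ", paste(miss, collapse = ", "))
  }
  codes <- matrix(NA_integer_, nrow = nrow(data), ncol = length(spec$nodes),
                  dimnames = list(NULL, names(spec$nodes)))
  for (v in names(spec$nodes)) {
    x <- as.character(data[[v]])
    idx <- match(x, spec$nodes[[v]])
    bad <- !is.na(x) & is.na(idx)
    if (any(bad)) {
      stop(sprintf("unseen state token(s) for node '%s': %s", v,
                   paste(unique(x[bad]), collapse = ", ")))
    }
    codes[, v] <- idx
  }
  codes
}

empty_cpt <- function(spec, v) {
  cards <- node_cards(spec)
  dims <- c(cards[v], cards[spec$parents[[v]]])
  array(0, dim = dims, dimnames = c(
    stats::setNames(list(spec$nodes[[v]]), v),
    lapply(stats::setNames(spec$parents[[v]], spec$parents[[v]]),
           function(p) spec$nodes[[p]])
  ))
}

# Linear index of each row's parent configuration for node v (NA if any
# parent missing); configurations are column-major over the parent order.
parent_config_index <- function(codes, spec, v) {
  pa <- spec$parents[[v]]
  if (length(pa) == 0L) return(rep(1L, nrow(codes)))
  cards <- node_cards(spec)[pa]
  idx <- rep(0L, nrow(codes))
  mult <- 1L
  for (k in seq_along(pa)) {
    idx <- idx + (codes[, pa[k]] - 1L) * mult
    mult <- mult * cards[k]
  }
  idx + 1L
}

# Turn a (child-state x parent-config) count array into a CPT with Dirichlet
# smoothing: cell -> (count + ess/k) / (config total + ess). Configurations
# with zero counts and zero prior fall back to the uniform distribution.
counts_to_cpt <- function(counts, prior_ess) {
  k <- dim(as.array(counts))[1L]
  m <- matrix(counts, nrow = k)
  tot <- colSums(m)
  sm <- sweep(m + prior_ess / k, 2L, tot + prior_ess, `/`)
  dead <- tot + prior_ess == 0
  if (any(dead)) sm[, dead] <- 1 / k
  array(sm, dim = dim(as.array(counts)), dimnames = dimnames(counts))
}

#' Closed-form CPT estimation from complete family observations
#'
#' Estimates each node's CPT by counting the rows in which the node and all
#' of its parents are observed, with a symmetric Dirichlet prior of total
#' pseudo-count `prior_ess` per parent configuration. With `prior_ess = 0`
#' this is maximum likelihood; unobserved parent configurations then default
#' to the uniform distribution.
#'
#' @param data data frame with one (factor or character) column per spec
#'   node; `NA` marks a missing state.
#' @param spec a [network_spec()].
#' @param prior_ess non-negative prior equivalent sample size per parent
#'   configuration (default 1, i.e. a uniform Dirichlet prior).
#' @return a `bbn_model`.
#' @export
count_estimate <- function(data, spec, prior_ess = 1) {
  stopifnot(prior_ess >= 0)
  codes <- dataset_to_codes(data, spec)
  cpts <- expected_counts(codes, spec, model = NULL)$counts
  cpts <- lapply(cpts, counts_to_cpt, prior_ess = prior_ess)
  model <- new_bbn_model(spec, cpts, meta = list(
    method = "count", iterations = 1L, prior_ess = prior_ess,
    loglik_trace = NA_real_, seed = NA_integer_))
  model$meta$loglik_trace <- model_loglik(model, codes)
  model
}

# Expected family counts. With model = NULL only complete families count
# (hard counts); with a model, families containing missing members contribute
# their exact posterior mass given each household's observed nodes.
# Returns counts (per node) and the per-household log-evidence.
expected_counts <- function(codes, spec, model = NULL) {
  cards <- node_cards(spec)
  counts <- lapply(stats::setNames(names(spec$nodes), names(spec$nodes)),
                   function(v) empty_cpt(spec, v))
  n <- nrow(codes)
  logev <- rep(NA_real_, n)

  # vectorized pass over complete families
  for (v in names(spec$nodes)) {
    fam <- c(v, spec$parents[[v]])
    ok <- rowSums(is.na(codes[, fam, drop = FALSE])) == 0L
    if (any(ok)) {
      idx <- codes[ok, v] + cards[v] * (parent_config_index(codes[ok, , drop = FALSE], spec, v) - 1L)
      tab <- tabulate(idx, nbins = length(counts[[v]]))
      counts[[v]] <- counts[[v]] + array(tab, dim = dim(as.array(counts[[v]])),
                                         dimnames = dimnames(counts[[v]]))
    }
  }
  rows_incomplete <- which(rowSums(is.na(codes)) > 0L)

  if (!is.null(model)) {
    base_factors <- model_factors(model)
    for (h in rows_incomplete) {
      ev <- codes[h, ]
      ev_idx <- ev[!is.na(ev)]
      missing_nodes <- names(ev)[is.na(ev)]
      fh <- reduce_by_evidence(base_factors, as.list(ev_idx))
      p_e <- NA_real_
      for (v in names(spec$nodes)) {
        fam <- c(v, spec$parents[[v]])
        q <- intersect(missing_nodes, fam)
        if (length(q) == 0L) next
        res <- ve_eliminate(fh, cards, query = q)
        if (!is.finite(res$p_evidence) || res$p_evidence <= 0) {
          stop(sprintf("non-finite or zero likelihood for household row %d", h))
        }
        p_e <- res$p_evidence
        post <- as.numeric(res$table) / res$p_evidence
        grid <- as.matrix(expand.grid(lapply(cards[q], seq_len)))
        fam_idx <- matrix(rep(ev[fam], each = nrow(grid)), nrow = nrow(grid),
                          dimnames = list(NULL, fam))
        fam_idx[, q] <- grid
        # linear index into the (child x parents) count array
        lin <- fam_idx[, 1L]
        mult <- cards[v]
        pa <- spec$parents[[v]]
        for (k in seq_along(pa)) {
          lin <- lin + (fam_idx[, pa[k]] - 1L) * mult
          mult <- mult * cards[pa[k]]
        }
        counts[[v]][lin] <- counts[[v]][lin] + post
      }
      logev[h] <- log(p_e)
    }
  }
  list(counts = counts, log_evidence = logev,
       rows_incomplete = rows_incomplete)
}

# CPTs as a factor list for the elimination engine.
model_factors <- function(model) {
  spec <- model$spec
  lapply(stats::setNames(names(spec$nodes), names(spec$nodes)), function(v) {
    new_factor(c(v, spec$parents[[v]]), model$cpts[[v]])
  })
}

# Observed-data log-likelihood (missing nodes marginalized out exactly).
model_loglik <- function(model, codes) {
  spec <- model$spec
  cards <- node_cards(spec)
  ll <- 0
  complete <- rowSums(is.na(codes)) == 0L
  if (any(complete)) {
    for (v in names(spec$nodes)) {
      idx <- codes[complete, v] +
        cards[v] * (parent_config_index(codes[complete, , drop = FALSE], spec, v) - 1L)
      ll <- ll + sum(log(model$cpts[[v]][idx]))
    }
  }
  if (any(!complete)) {
    base_factors <- model_factors(model)
    for (h in which(!complete)) {
      ev <- codes[h, ]
      fh <- reduce_by_evidence(base_factors, as.list(ev[!is.na(ev)]))
      p_e <- ve_eliminate(fh, cards, query = character(0))$p_evidence
      if (!is.finite(p_e) || p_e <= 0) {
        stop(sprintf("non-finite or zero likelihood for household row %d", h))
      }
      ll <- ll + log(p_e)
    }
  }
  ll
}

# Dirichlet penalty term of the MAP objective: (ess/k) * sum(log theta).
map_penalty <- function(cpts, prior_ess) {
  if (prior_ess == 0) return(0)
  sum(vapply(cpts, function(cpt) {
    k <- dim(as.array(cpt))[1L]
    (prior_ess / k) * sum(log(pmax(cpt, 1e-300)))
  }, numeric(1)))
}

#' EM estimation of CPTs under missing data
#'
#' Expectation-maximization for the network's CPTs when some node states are
#' unobserved. The E-step computes, for every household and every family
#' (node plus parents) containing a missing member, the exact posterior over
#' the missing members given the household's observed nodes (by variable
#' elimination); the M-step re-estimates every CPT from the expected counts
#' with the same Dirichlet smoothing as [count_estimate()]. With
#' `prior_ess > 0` the iteration maximizes the Dirichlet-penalized
#' log-likelihood, whose trace is checked to be non-decreasing on every run;
#' the observed-data log-likelihood trace is also recorded. On complete data
#' the algorithm reduces to [count_estimate()] after a single iteration.
#'
#' @inheritParams count_estimate
#' @param tol relative change in the objective below which iteration stops
#'   (default `1e-6`).
#' @param max_iter maximum EM iterations (default 500).
#' @param init `"uniform"` (deterministic, the default) or `"random"`
#'   (Dirichlet(1) draws controlled by `seed`).
#' @param seed integer seed used when `init = "random"`.
#' @return a `bbn_model` with `meta$loglik_trace`, `meta$objective_trace`,
#'   `meta$iterations`, `meta$prior_ess` and `meta$seed`.
#' @export
em_learn <- function(data, spec, prior_ess = 1, tol = 1e-6, max_iter = 500,
                     init = c("uniform", "random"), seed = NULL) {
  init <- match.arg(init)
  stopifnot(prior_ess >= 0, max_iter >= 1)
  codes <- dataset_to_codes(data, spec)
  if (any(rowSums(!is.na(codes)) == 0L)) {
    stop("every household must have at least one observed node")
  }

  if (!anyNA(codes)) {
    model <- count_estimate(data, spec, prior_ess = prior_ess)
    model$meta$method <- "em"
    model$meta$objective_trace <- model$meta$loglik_trace +
      map_penalty(model$cpts, prior_ess)
    return(model)
  }

  cards <- node_cards(spec)
  cpts <- lapply(stats::setNames(names(spec$nodes), names(spec$nodes)), function(v) {
    cpt <- empty_cpt(spec, v)
    k <- cards[v]
    if (init == "uniform") {
      cpt[] <- 1 / k
    } else {
      if (!is.null(seed)) set.seed(seed)
      g <- matrix(stats::rgamma(length(cpt), shape = 1), nrow = k)
      cpt[] <- sweep(g, 2L, colSums(g), `/`)
    }
    cpt
  })
  model <- new_bbn_model(spec, cpts)

  ll_trace <- numeric(0)
  obj_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ec <- expected_counts(codes, spec, model = model)
    ll <- model_loglik_from_parts(model, codes, ec)
    obj <- ll + map_penalty(model$cpts, prior_ess)
    if (length(obj_trace) > 0L) {
      prev <- utils::tail(obj_trace, 1)
      if (obj < prev - 1e-8 * (abs(prev) + 1)) {
        stop(sprintf("EM objective decreased at iteration %d (%.8f -> %.8f)",
                     iter, prev, obj))
      }
    }
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, obj)
    if (length(obj_trace) >= 2L) {
      prev <- obj_trace[length(obj_trace) - 1L]
      if (abs(obj - prev) <= tol * (abs(prev) + 1e-12)) break
    }
    if (iter >= max_iter) break
    new_cpts <- lapply(ec$counts, counts_to_cpt, prior_ess = prior_ess)
    model <- new_bbn_model(spec, new_cpts)
  }
  model$meta <- list(method = "em", iterations = iter, prior_ess = prior_ess,
                     loglik_trace = ll_trace, objective_trace = obj_trace,
                     seed = if (is.null(seed)) NA_integer_ else seed,
                     converged = iter < max_iter)
  model
}

# Log-likelihood reusing the per-household evidence masses computed during the
# E-step (incomplete rows) plus a vectorized pass over complete rows.
model_loglik_from_parts <- function(model, codes, ec) {
  spec <- model$spec
  cards <- node_cards(spec)
  ll <- 0
  complete <- rowSums(is.na(codes)) == 0L
  if (any(complete)) {
    for (v in names(spec$nodes)) {
      idx <- codes[complete, v] +
        cards[v] * (parent_config_index(codes[complete, , drop = FALSE], spec, v) - 1L)
      ll <- ll + sum(log(model$cpts[[v]][idx]))
    }
  }
  ll + sum(ec$log_evidence[ec$rows_incomplete])
}
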