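# Model interrogation: predictive delta-P inference, scenario propagation,
# CPT sensitivity under proportional co-variation, and stratified k-fold
# cross-validation with one-vs-rest ROC AUC.

#' Predictive (delta-P) inference over all non-target nodes
#'
#' For every node other than the target and every one of its states, clamps
#' that node as hard evidence (all other nodes free), recomputes the exact
#' posterior probability of the target state, and reports it as a percentage.
#' A node's delta-P is the spread (max minus min) of those updated
#' percentages, computed on unrounded values and rounded last. States that
#' are impossible under the model (zero prior mass) are reported as `NA` and
#' excluded from the spread with a warning.
#'
#' @param model a `bbn_model`.
#' @param target name of the outcome node (default `"hwt_behaviour"`).
#' @param target_state the outcome state of interest (default
#'   `"regular user"`).
#' @param digits rounding for reported percentages (default 0, integer
#'   percentages).
#' @return a `delta_p_report`: list with `baseline_pct`, `updated` (data frame
#'   node/state/p_pct), `delta` (data frame node/delta_p) and the target
#'   definition.
#' @export
delta_p <- function(model, target = "hwt_behaviour",
                    target_state = "regular user", digits = 0) {
  spec <- model$spec
  stopifnot(target %in% names(spec$nodes))
  if (!target_state %in% spec$nodes[[target]]) {
    stop(sprintf("'%s' is not a state of node '%s'", target_state, target))
  }
  baseline <- infer_ve(model, list(), target)[[target_state]] * 100
  nodes <- setdiff(names(spec$nodes), target)
  rows <- list()
  for (v in nodes) {
    for (s in spec$nodes[[v]]) {
      p <- tryCatch(
        infer_ve(model, stats::setNames(s, v), target)[[target_state]] * 100,
        error = function(e) {
          warning(sprintf("state %s=%s is impossible under the model; excluded", v, s))
          NA_real_
        })
      rows[[length(rows) + 1L]] <- data.frame(node = v, state = s, p_pct_raw = p)
    }
  }
  updated <- do.call(rbind, rows)
  updated$p_pct <- round(updated$p_pct_raw, digits)
  delta <- do.call(rbind, lapply(nodes, function(v) {
    p <- updated$p_pct_raw[updated$node == v]
    p <- p[!is.na(p)]
    data.frame(node = v,
               delta_p_raw = if (length(p)) max(p) - min(p) else NA_real_)
  }))
  delta$delta_p <- round(delta$delta_p_raw, digits)
  delta <- delta[order(-delta$delta_p_raw), ]
  rownames(delta) <- NULL
  structure(list(target = target, target_state = target_state,
                 baseline_pct = baseline,
                 baseline_pct_rounded = round(baseline, digits),
                 updated = updated, delta = delta),
            class = "delta_p_report")
}

#' @export
print.delta_p_report <- function(x, ...) {
  cat(sprintf("Predictive inference for P(%s = %s)\n", x$target, x$target_state))
  cat(sprintf("  baseline: %s%%\n", format(x$baseline_pct_rounded)))
  print(x$delta[, c("node", "delta_p")], row.names = FALSE)
  invisible(x)
}

#' Scenario propagation: outcome posterior under a clamped node distribution
#'
#' Returns the full posterior over the target node when one node is set to a
#' given state distribution while everything else is left free. A degenerate
#' distribution (probability 1 on one state) is ordinary hard evidence; a
#' general distribution yields the corresponding mixture of clamped-state
#' posteriors.
#'
#' @param model a `bbn_model`.
#' @param node the node whose distribution is set.
#' @param state_distribution named (or state-ordered) non-negative vector over
#'   the node's states, summing to 1.
#' @param target the outcome node (default `"hwt_behaviour"`).
#' @return named posterior vector over the target states.
#' @export
scenario <- function(model, node, state_distribution,
                     target = "hwt_behaviour") {
  spec <- model$spec
  stopifnot(node %in% names(spec$nodes), target %in% names(spec$nodes),
            node != target)
  states <- spec$nodes[[node]]
  d <- state_distribution
  if (!is.null(names(d))) {
    if (!setequal(names(d), states)) stop("distribution names must match the node's states")
    d <- d[states]
  }
  if (length(d) != length(states) || any(d < 0) || abs(sum(d) - 1) > 1e-9) {
    stop("state_distribution must be a probability vector over the node's states")
  }
  post <- rep(0, length(spec$nodes[[target]]))
  for (i in seq_along(states)) {
    if (d[i] == 0) next
    post <- post + d[i] * infer_ve(model, stats::setNames(states[i], node), target)
  }
  stats::setNames(post, spec$nodes[[target]])
}

# Joint P(vars, evidence) as an array over `vars` (evidence members of vars
# are represented at their clamped slice, zero elsewhere).
joint_with_evidence <- function(model, ev_idx, vars) {
  cards <- node_cards(model$spec)
  free <- setdiff(vars, names(ev_idx))
  fs <- reduce_by_evidence(model_factors(model), ev_idx)
  res <- ve_eliminate(fs, cards, query = free)
  out <- array(0, dim = cards[vars],
               dimnames = lapply(stats::setNames(vars, vars),
                                 function(v) model$spec$nodes[[v]]))
  idx <- rep(list(quote(expr = )), length(vars))
  for (v in intersect(vars, names(ev_idx))) idx[[match(v, vars)]] <- ev_idx[[v]]
  vals <- if (length(free) > 0L) {
    aperm(array(res$table, dim = cards[free]), match(intersect(vars, free), free))
  } else {
    res$p_evidence
  }
  out <- do.call(`[<-`, c(list(out), idx, list(vals)))
  out
}

#' CPT parameter sensitivity of the target-state probability
#'
#' For every CPT entry theta, computes the derivative of the evidence-free
#' probability `P(target = target_state)` with respect to theta under
#' proportional co-variation (the complementary entries of the same CPT
#' column scale by `(1 - theta)/(1 - theta0)` so the column stays
#' normalized). Because the joint probability is linear in each CPT column,
#' the derivative is obtained in closed form from two exact inference runs
#' per node (the family joint with and without the target clamped); entries
#' at the boundary of the simplex fall back to one-sided linear evaluation.
#' A node's aggregate sensitivity is the maximum absolute derivative over its
#' parameters.
#'
#' @inheritParams delta_p
#' @return a `sensitivity_report`: list with `parameters` (data frame node /
#'   state / parent_config / theta / derivative) and `nodes` (data frame node /
#'   max_abs_derivative, sorted).
#' @export
sensitivity <- function(model, target = "hwt_behaviour",
                        target_state = "regular user") {
  spec <- model$spec
  stopifnot(target %in% names(spec$nodes))
  ti <- match(target_state, spec$nodes[[target]])
  if (is.na(ti)) stop(sprintf("'%s' is not a state of node '%s'", target_state, target))
  cards <- node_cards(spec)
  params <- list()
  for (v in names(spec$nodes)) {
    fam <- c(v, spec$parents[[v]])
    Fj <- joint_with_evidence(model, stats::setNames(list(ti), target), fam)
    K <- cards[v]
    Fm <- matrix(Fj, nrow = K)          # child state x parent config
    Pm <- matrix(model$cpts[[v]], nrow = K)
    n_cfg <- ncol(Pm)
    der <- matrix(NA_real_, nrow = K, ncol = n_cfg)
    for (j in seq_len(n_cfg)) {
      p0 <- Pm[, j]
      f0 <- Fm[, j]
      if (all(p0 > 1e-12) && all(p0 < 1 - 1e-12)) {
        ck <- f0 / p0
        for (i in seq_len(K)) {
          der[i, j] <- ck[i] - sum(f0[-i]) / (1 - p0[i])
        }
      } else {
        der[, j] <- vapply(seq_len(K), function(i) {
          sensitivity_fd(model, v, i, j, target, ti, p0)
        }, numeric(1))
      }
    }
    cfg <- parent_config_labels(spec, v)
    params[[v]] <- data.frame(
      node = v,
      state = rep(spec$nodes[[v]], times = n_cfg),
      parent_config = rep(cfg, each = K),
      theta = as.numeric(Pm),
      derivative = as.numeric(der)
    )
  }
  parameters <- do.call(rbind, params)
  rownames(parameters) <- NULL
  nodes <- stats::aggregate(list(max_abs_derivative = abs(parameters$derivative)),
                            by = list(node = parameters$node), FUN = max)
  nodes <- nodes[order(-nodes$max_abs_derivative), ]
  rownames(nodes) <- NULL
  structure(list(target = target, target_state = target_state,
                 parameters = parameters, nodes = nodes),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("CPT sensitivity of P(%s = %s) under proportional co-variation\n",
              x$target, x$target_state))
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

parent_config_labels <- function(spec, v) {
  pa <- spec$parents[[v]]
  if (length(pa) == 0L) return("(root)")
  grid <- expand.grid(lapply(stats::setNames(pa, pa), function(p) spec$nodes[[p]]),
                      stringsAsFactors = FALSE)
  apply(grid, 1L, function(r) paste(paste0(pa, "=", r), collapse = ","))
}

# One-sided slope for boundary parameters: P(target_state) is linear in theta
# under proportional co-variation, so a single perturbed evaluation is exact.
# A column at a degenerate vertex redistributes mass uniformly.
sensitivity_fd <- function(model, v, i, j, target, ti, p0, h = 0.01) {
  K <- length(p0)
  t0 <- p0[i]
  t1 <- if (t0 >= 1 - 1e-12) t0 - h else t0 + h
  newcol <- numeric(K)
  newcol[i] <- t1
  rest0 <- p0[-i]
  if (sum(rest0) > 1e-12) {
    newcol[-i] <- rest0 * (1 - t1) / sum(rest0)
  } else {
    newcol[-i] <- (1 - t1) / (K - 1)
  }
  m2 <- model
  cpt <- matrix(m2$cpts[[v]], nrow = K)
  cpt[, j] <- newcol
  dim(cpt) <- dim(as.array(m2$cpts[[v]]))
  dimnames(cpt) <- dimnames(m2$cpts[[v]])
  m2$cpts[[v]] <- cpt
  p_base <- infer_ve(model, list(), target)[[ti]]
  p_new <- infer_ve(m2, list(), target)[[ti]]
  (p_new - p_base) / (t1 - t0)
}

# Rank (Mann-Whitney) AUC with ties counted half; NA when a class is empty.
auc_rank <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Stratified k-fold cross-validation of outcome prediction
#'
#' Splits households into `k` folds stratified by the observed outcome state
#' (seeded, deterministic), learns the network on each training split with
#' [em_learn()], and predicts every held-out household's outcome posterior
#' given all of its observed non-outcome nodes as evidence. Reports the
#' confusion matrix, per-class one-vs-rest AUC (rank statistic, ties counted
#' half), their unweighted macro average, and overall argmax accuracy (ties
#' broken by state order). Households with a missing outcome contribute to
#' training but are never scored.
#'
#' @param data data frame of categorical node states (`NA` = missing).
#' @param spec a [network_spec()].
#' @param outcome name of the outcome node (default `"hwt_behaviour"`).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed (default 0).
#' @param prior_ess,tol,max_iter passed to [em_learn()].
#' @return a `cv_result`: list with `folds`, `predictions` (data frame with
#'   per-state posterior columns, predicted and observed class), `confusion`,
#'   `auc` (per class), `macro_auc`, `accuracy`, `roc` (per-class TPR/FPR
#'   points).
#' @export
cross_validate <- function(data, spec, outcome = "hwt_behaviour", k = 10,
                           seed = 0, prior_ess = 1, tol = 1e-6,
                           max_iter = 500) {
  codes <- dataset_to_codes(data, spec)
  states <- spec$nodes[[outcome]]
  obs <- codes[, outcome]
  if (any(table(factor(obs, levels = seq_along(states))) < k)) {
    stop(sprintf("every outcome state needs at least %d observed rows", k))
  }
  n <- nrow(codes)

  assign_folds <- function(s) {
    rng <- local({ set.seed(s); sample.int(n) })
    folds <- integer(n)
    for (lv in c(seq_along(states), NA)) {
      idx <- if (is.na(lv)) which(is.na(obs)) else which(obs == lv)
      idx <- idx[order(match(idx, rng))]   # seeded shuffle within stratum
      if (length(idx)) folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  }
  folds <- assign_folds(seed)
  for (attempt in 1:10) {
    bad <- FALSE
    for (f in seq_len(k)) {
      tr <- obs[folds != f]
      if (all(is.na(tr))) bad <- TRUE
    }
    if (!bad) break
    warning("outcome entirely missing in a training split; refolding with a new seed")
    folds <- assign_folds(seed + attempt)
  }

  post <- matrix(NA_real_, nrow = n, ncol = length(states),
                 dimnames = list(NULL, states))
  for (f in seq_len(k)) {
    model <- em_learn(data[folds != f, , drop = FALSE], spec,
                      prior_ess = prior_ess, tol = tol, max_iter = max_iter)
    for (h in which(folds == f & !is.na(obs))) {
      ev <- codes[h, ]
      ev <- ev[!is.na(ev)]
      ev <- ev[names(ev) != outcome]
      ev_states <- vapply(names(ev), function(v) spec$nodes[[v]][ev[[v]]], character(1))
      post[h, ] <- infer_ve(model, ev_states, outcome)
    }
  }
  scored <- which(!is.na(obs) & !is.na(post[, 1L]))
  pred_class <- apply(post[scored, , drop = FALSE], 1L, which.max)
  observed <- obs[scored]
  confusion <- table(
    observed = factor(states[observed], levels = states),
    predicted = factor(states[pred_class], levels = states))
  auc <- vapply(seq_along(states), function(s) {
    auc_rank(post[scored, s], observed == s)
  }, numeric(1))
  names(auc) <- states
  roc <- lapply(stats::setNames(seq_along(states), states), function(s) {
    roc_points(post[scored, s], observed == s)
  })
  predictions <- data.frame(row = scored, post[scored, , drop = FALSE],
                            observed = states[observed],
                            predicted = states[pred_class],
                            check.names = FALSE)
  structure(list(k = k, seed = seed, folds = folds,
                 predictions = predictions, confusion = confusion,
                 auc = auc, macro_auc = mean(auc, na.rm = TRUE),
                 accuracy = mean(pred_class == observed), roc = roc),
            class = "cv_result")
}

# ROC curve points (FPR, TPR) at every distinct score threshold.
roc_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  keep <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(y)[keep] / max(sum(y), 1L))
  fpr <- c(0, cumsum(!y)[keep] / max(sum(!y), 1L))
  data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("  accuracy: %.1f%%  macro AUC: %.3f\n",
              100 * x$accuracy, x$macro_auc))
  cat("  per-class AUC:\n")
  print(round(x$auc, 3))
  cat("  confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
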