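#' Discrete network specification
#'
#' A `bbn_spec` holds the qualitative part of a discrete Bayesian belief
#' network: a set of named nodes, each with an ordered list of categorical
#' states, and a directed acyclic edge set. The default specification built by
#' [default_network_spec()] is the three-layer structure used throughout the
#' package: eight socio-economic characteristic (SEC) root nodes, five RANAS
#' psychological factor nodes (each a child of every SEC node), and a single
#' household-water-treatment (HWT) behaviour node whose parents are the five
#' RANAS nodes. SEC effects on behaviour are therefore fully mediated by the
#' psychological layer.
#'
#' @param nodes named list; one ordered character vector of states per node.
#' @param edges two-column character matrix or data frame, columns
#'   parent/child; may have zero rows.
#' @param layers optional named character vector tagging nodes with a layer
#'   label (e.g. `"sec"`, `"ranas"`, `"outcome"`); used only for validation
#'   and reporting.
#' @return object of class `bbn_spec` with elements `nodes`, `edges`,
#'   `parents`, `order` (a topological order) and `layers`.
#' @export
network_spec <- function(nodes, edges, layers = NULL) {
  if (is.null(names(nodes)) || anyDuplicated(names(nodes))) {
    stop("nodes must be a uniquely named list of state vectors")
  }
  for (nm in names(nodes)) {
    st <- nodes[[nm]]
    if (!is.character(st) || length(st) < 2L || anyDuplicated(st)) {
      stop(sprintf("node '%s' needs >= 2 distinct character states", nm))
    }
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(0), ncol = 2)
  if (ncol(edges) != 2L) stop("edges must have two columns (parent, child)")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")
  bad <- setdiff(unique(as.vector(edges)), names(nodes))
  if (length(bad) > 0L) {
    stop("edge endpoints not declared as nodes: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicated edges")
  parents <- lapply(stats::setNames(names(nodes), names(nodes)), function(v) {
    unname(edges[edges[, "child"] == v, "parent"])
  })
  ord <- topological_order(names(nodes), parents)
  spec <- structure(
    list(nodes = nodes, edges = edges, parents = parents, order = ord,
         layers = layers),
    class = "bbn_spec"
  )
  spec
}

# Kahn's algorithm; errors naming a cycle if one exists.
topological_order <- function(node_names, parents) {
  remaining <- node_names
  placed <- character(0)
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(v) {
      all(parents[[v]] %in% placed)
    }, logical(1))]
    if (length(ready) == 0L) {
      stop("edges contain a cycle through: ", paste(remaining, collapse = " -> "))
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' @export
print.bbn_spec <- function(x, ...) {
  cat(sprintf("Discrete network specification: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  for (nm in x$order) {
    pa <- x$parents[[nm]]
    cat(sprintf("  %s [%s]%s\n", nm, paste(x$nodes[[nm]], collapse = "/"),
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

node_cards <- function(spec) {
  vapply(spec$nodes, length, integer(1))
}

#' Validate a network specification
#'
#' Checks acyclicity, state-list sanity and, when layer tags are present,
#' conformance with the three-layer mediation structure (no edge from the SEC
#' layer directly into the outcome layer, no edges within a layer, no edge
#' pointing from a lower to a higher layer).
#'
#' @param spec a [network_spec()] object.
#' @return invisibly, a list with `ok` (logical) and `messages`; problems
#'   beyond what `network_spec()` already enforces are reported rather than
#'   thrown.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "bbn_spec"))
  msgs <- character(0)
  # construction already guarantees a DAG and sane state lists; re-check order
  ord <- topological_order(names(spec$nodes), spec$parents)
  if (!setequal(ord, names(spec$nodes))) msgs <- c(msgs, "topological order incomplete")
  if (!is.null(spec$layers)) {
    rank <- c(sec = 1, ranas = 2, outcome = 3)
    lr <- rank[spec$layers[names(spec$nodes)]]
    names(lr) <- names(spec$nodes)
    for (k in seq_len(nrow(spec$edges))) {
      p <- spec$edges[k, 1]; ch <- spec$edges[k, 2]
      if (!is.na(lr[p]) && !is.na(lr[ch]) && lr[ch] - lr[p] != 1) {
        msgs <- c(msgs, sprintf("edge %s -> %s violates the layer ordering", p, ch))
      }
    }
  }
  out <- list(ok = length(msgs) == 0L, messages = msgs)
  if (!out$ok) warning(paste(msgs, collapse = "; "))
  invisible(out)
}

sec_node_states <- function() {
  list(
    health_problem     = c("No", "Yes"),
    information_access = c("Difficult", "Medium", "Easy"),
    mother_education   = c("None", "Primary", "Secondary", "Higher"),
    father_education   = c("None", "Primary", "Secondary", "Higher"),
    wealth             = c("Poor", "Middle", "Rich"),
    religion           = c("Christian", "Islam"),
    accessibility      = c("Difficult", "Easy"),
    access_water       = c("Far", "Medium", "Close")
  )
}

ranas_node_names <- function() {
  c("risk", "attitude", "norm", "ability", "self_regulation")
}

#' Default three-layer network over the fourteen survey nodes
#'
#' @param sec_parents optional named list giving, per RANAS node, the subset of
#'   SEC nodes to use as parents. The default (`NULL`) connects every SEC node
#'   to every RANAS node (complete bipartite mediation structure). Pruned
#'   parent sets are used e.g. by the parameter-recovery benchmark, where the
#'   full structure is not identifiable at realistic sample sizes.
#' @return a [network_spec()] with layer tags.
#' @export
default_network_spec <- function(sec_parents = NULL) {
  sec <- sec_node_states()
  ranas <- ranas_node_names()
  nodes <- c(sec, stats::setNames(
    rep(list(c("Low", "Moderate", "High")), length(ranas)), ranas))
  nodes$hwt_behaviour <- c("non-user", "irregular user", "regular user")
  if (is.null(sec_parents)) {
    sec_parents <- stats::setNames(rep(list(names(sec)), length(ranas)), ranas)
  }
  edges <- do.call(rbind, c(
    lapply(ranas, function(r) cbind(sec_parents[[r]], r)),
    list(cbind(ranas, "hwt_behaviour"))
  ))
  layers <- c(stats::setNames(rep("sec", length(sec)), names(sec)),
              stats::setNames(rep("ranas", length(ranas)), ranas),
              hwt_behaviour = "outcome")
  network_spec(nodes, edges, layers = layers)
}

#' Read / write a network specification as YAML
#'
#' The on-disk format lists nodes (name, states, optional layer) and edges as
#' `[parent, child]` pairs; hand-written toy networks are accepted.
#'
#' @param path file path.
#' @rdname spec_io
#' @export
read_network_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  nodes <- stats::setNames(
    lapply(doc$nodes, function(n) as.character(n$states)),
    vapply(doc$nodes, `[[`, character(1), "name")
  )
  layers <- vapply(doc$nodes, function(n) {
    if (is.null(n$layer)) NA_character_ else n$layer
  }, character(1))
  names(layers) <- names(nodes)
  if (all(is.na(layers))) layers <- NULL
  edges <- do.call(rbind, lapply(doc$edges, function(e) as.character(e)))
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  network_spec(nodes, edges, layers = layers)
}

#' @param spec a [network_spec()] object.
#' @rdname spec_io
#' @export
write_network_spec <- function(spec, path) {
  doc <- list(
    nodes = lapply(names(spec$nodes), function(nm) {
      n <- list(name = nm, states = spec$nodes[[nm]])
      if (!is.null(spec$layers) && !is.na(spec$layers[nm])) n$layer <- unname(spec$layers[nm])
      n
    }),
    edges = lapply(seq_len(nrow(spec$edges)), function(k) unname(spec$edges[k, ]))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
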