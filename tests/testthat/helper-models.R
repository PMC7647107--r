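# Shared fixtures: toy and random networks built in code.

# Two-node chain A -> B with the classic textbook CPTs.
toy_chain_model <- function() {
  spec <- network_spec(list(A = c("a1", "a2"), B = c("b1", "b2")),
                       rbind(c("A", "B")))
  cpts <- list(
    A = array(c(0.5, 0.5), dim = 2, dimnames = list(A = c("a1", "a2"))),
    B = array(c(0.9, 0.1, 0.2, 0.8), dim = c(2, 2),
              dimnames = list(B = c("b1", "b2"), A = c("a1", "a2")))
  )
  hwtbbn:::new_bbn_model(spec, cpts)
}

# Random DAG model with 5-8 nodes, 2-3 states each, Dirichlet(1) CPT columns.
random_model <- function(seed, n_nodes = NULL, max_parents = 3) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(5:8, 1)
  names <- paste0("n", sprintf("%02d", seq_len(n_nodes)))
  cards <- sample(2:3, n_nodes, replace = TRUE)
  nodes <- lapply(seq_len(n_nodes), function(i) paste0("s", seq_len(cards[i])))
  names(nodes) <- names
  edges <- NULL
  for (i in seq_len(n_nodes)[-1]) {
    pool <- names[seq_len(i - 1)]
    k <- min(rbinom(1, length(pool), 0.4), max_parents)
    if (k > 0) {
      for (p in sample(pool, k)) edges <- rbind(edges, c(p, names[i]))
    }
  }
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  spec <- network_spec(nodes, edges)
  cpts <- lapply(names, function(v) {
    cpt <- hwtbbn:::empty_cpt(spec, v)
    K <- cards[match(v, names)]
    m <- matrix(rgamma(length(cpt), 1) + 0.05, nrow = K)
    cpt[] <- sweep(m, 2, colSums(m), `/`)
    cpt
  })
  names(cpts) <- names
  hwtbbn:::new_bbn_model(spec, cpts)
}

# Random evidence on a subset of nodes of a model (possibly empty).
random_evidence <- function(model, p = 0.4) {
  spec <- model$spec
  picked <- names(spec$nodes)[runif(length(spec$nodes)) < p]
  ev <- vapply(picked, function(v) sample(spec$nodes[[v]], 1), character(1))
  as.list(ev)
}

# Draw complete categorical data directly from a model (no emission layer).
sample_states <- function(model, n, seed) {
  sim <- list()
  set.seed(seed)
  spec <- model$spec
  cards <- hwtbbn:::node_cards(spec)
  codes <- matrix(NA_integer_, nrow = n, ncol = length(cards),
                  dimnames = list(NULL, names(cards)))
  for (v in spec$order) {
    cpt_m <- matrix(model$cpts[[v]], nrow = cards[v])
    cfg <- hwtbbn:::parent_config_index(codes, spec, v)
    cum <- apply(cpt_m, 2, cumsum)
    r <- runif(n)
    codes[, v] <- 1L + colSums(cum[, cfg, drop = FALSE] < rep(r, each = cards[v]))
  }
  as.data.frame(lapply(stats::setNames(colnames(codes), colnames(codes)),
                       function(v) spec$nodes[[v]][codes[, v]]),
                check.names = FALSE)
}
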