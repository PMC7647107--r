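# Delta-P inference, scenario propagation, CPT sensitivity, cross-validation.

# Three-node collider-free toy net: S -> R -> H plus a disconnected node D.
toy_mediation_model <- function() {
  spec <- network_spec(
    list(S = c("lo", "hi"), R = c("lo", "hi"), H = c("no", "yes"),
         D = c("d1", "d2")),
    rbind(c("S", "R"), c("R", "H")))
  cpts <- list(
    S = array(c(0.6, 0.4), 2, dimnames = list(S = c("lo", "hi"))),
    R = array(c(0.8, 0.2, 0.3, 0.7), c(2, 2),
              dimnames = list(R = c("lo", "hi"), S = c("lo", "hi"))),
    H = array(c(0.9, 0.1, 0.4, 0.6), c(2, 2),
              dimnames = list(H = c("no", "yes"), R = c("lo", "hi"))),
    D = array(c(0.5, 0.5), 2, dimnames = list(D = c("d1", "d2"))))
  hwtbbn:::new_bbn_model(spec, cpts)
}

test_that("delta-P equals enumeration-oracle posteriors and is 0 when d-separated", {
  m <- toy_mediation_model()
  dp <- delta_p(m, target = "H", target_state = "yes", digits = 4)
  for (k in seq_len(nrow(dp$updated))) {
    row <- dp$updated[k, ]
    oracle <- infer_enumeration(m, stats::setNames(row$state, row$node), "H")[["yes"]]
    expect_equal(row$p_pct_raw, oracle * 100, tolerance = 1e-9)
  }
  expect_equal(dp$delta$delta_p_raw[dp$delta$node == "D"], 0, tolerance = 1e-12)
  expect_equal(dp$baseline_pct,
               infer_enumeration(m, list(), "H")[["yes"]] * 100, tolerance = 1e-9)
  # mediated nodes upstream of H have positive spread
  expect_gt(dp$delta$delta_p_raw[dp$delta$node == "R"], 0)
})

test_that("scenario propagation matches hand-computed and consistency cases", {
  m <- toy_mediation_model()
  # hand Bayes: clamping R = hi gives P(H = yes) = 0.6
  sc <- scenario(m, "R", c(lo = 0, hi = 1), target = "H")
  expect_equal(unname(sc["yes"]), 0.6, tolerance = 1e-12)
  # clamping a node at its own no-evidence marginal leaves the target unchanged
  marg <- infer_ve(m, list(), "R")
  sc2 <- scenario(m, "R", marg, target = "H")
  expect_equal(sc2, infer_ve(m, list(), "H"), tolerance = 1e-12)
  expect_error(scenario(m, "R", c(lo = 0.7, hi = 0.7), target = "H"),
               "probability vector")
})

test_that("sensitivity has closed-form values on degenerate structures", {
  # single-node network: P(target state) is the parameter itself
  spec <- network_spec(list(X = c("A", "B", "C")), matrix(character(0), ncol = 2))
  cpt <- array(c(0.2, 0.3, 0.5), 3, dimnames = list(X = c("A", "B", "C")))
  m <- hwtbbn:::new_bbn_model(spec, list(X = cpt))
  sr <- sensitivity(m, target = "X", target_state = "A")
  d_own <- sr$parameters$derivative[sr$parameters$state == "A"]
  expect_equal(d_own, 1, tolerance = 1e-9)
  # parameters of a d-separated node have derivative 0
  m2 <- toy_mediation_model()
  sr2 <- sensitivity(m2, target = "H", target_state = "yes")
  expect_equal(max(abs(sr2$parameters$derivative[sr2$parameters$node == "D"])),
               0, tolerance = 1e-12)
})

test_that("analytic sensitivity matches central finite differences", {
  perturbed_p <- function(m, v, i, j, theta, target, target_state) {
    K <- length(m$spec$nodes[[v]])
    cpt <- matrix(m$cpts[[v]], nrow = K)
    p0 <- cpt[, j]
    newcol <- numeric(K)
    newcol[i] <- theta
    newcol[-i] <- p0[-i] * (1 - theta) / sum(p0[-i])
    cpt[, j] <- newcol
    dim(cpt) <- dim(as.array(m$cpts[[v]]))
    dimnames(cpt) <- dimnames(m$cpts[[v]])
    m$cpts[[v]] <- cpt
    infer_ve(m, list(), target)[[target_state]]
  }
  h <- 1e-5
  for (seed in c(2, 5, 9)) {
    m <- random_model(seed, n_nodes = 5)
    target <- utils::tail(m$spec$order, 1)
    tstate <- m$spec$nodes[[target]][1]
    sr <- sensitivity(m, target = target, target_state = tstate)
    pp <- sr$parameters
    idx <- sample(nrow(pp), min(25, nrow(pp)))
    for (k in idx) {
      v <- pp$node[k]
      K <- length(m$spec$nodes[[v]])
      pos <- (k - min(which(pp$node == v))) # 0-based within node
      i <- pos %% K + 1
      j <- pos %/% K + 1
      th <- pp$theta[k]
      fd <- (perturbed_p(m, v, i, j, th + h, target, tstate) -
             perturbed_p(m, v, i, j, th - h, target, tstate)) / (2 * h)
      expect_equal(pp$derivative[k], fd, tolerance = 1e-6)
    }
  }
})

test_that("the rank AUC reproduces the Mann-Whitney identities", {
  expect_equal(hwtbbn:::auc_rank(c(0.9, 0.8, 0.1, 0.2),
                                 c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(hwtbbn:::auc_rank(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(31)
  sc <- runif(60)
  lab <- rbinom(60, 1, 0.5) == 1
  expect_equal(hwtbbn:::auc_rank(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("cross-validation is perfect on deterministically separable data", {
  spec <- network_spec(list(A = c("a1", "a2", "a3"), Y = c("y1", "y2", "y3")),
                       rbind(c("A", "Y")))
  set.seed(17)
  a <- sample(c("a1", "a2", "a3"), 240, replace = TRUE)
  d <- data.frame(A = a, Y = sub("a", "y", a))   # outcome determined by A
  cv <- cross_validate(d, spec, outcome = "Y", k = 10, seed = 0)
  expect_equal(cv$macro_auc, 1.0)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(sum(cv$confusion), 240)
  expect_equal(unname(diag(cv$confusion)), unname(table(factor(d$Y))),
               ignore_attr = TRUE)
})

test_that("fold assignment is stratified, seeded and reproducible", {
  spec <- network_spec(list(A = c("a1", "a2"), Y = c("y1", "y2")),
                       rbind(c("A", "Y")))
  set.seed(23)
  d <- data.frame(A = sample(c("a1", "a2"), 200, TRUE),
                  Y = sample(c("y1", "y2"), 200, TRUE, prob = c(0.7, 0.3)))
  cv1 <- cross_validate(d, spec, outcome = "Y", k = 10, seed = 1)
  cv2 <- cross_validate(d, spec, outcome = "Y", k = 10, seed = 1)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$predictions, cv2$predictions)
  # strata balanced across folds within one household
  per_fold <- table(cv1$folds[d$Y == "y2"])
  expect_lte(diff(range(per_fold)), 1)
  expect_error(cross_validate(d[1:15, ], spec, outcome = "Y", k = 10),
               "at least")
})
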