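# CPT learning: closed-form counting and EM under missing data.

single_node_spec <- function(states = c("A", "B")) {
  network_spec(list(X = states), matrix(character(0), ncol = 2))
}

test_that("counting reproduces maximum-likelihood and Laplace proportions", {
  spec <- single_node_spec()
  d <- data.frame(X = rep(c("A", "B"), c(60, 40)))
  m0 <- count_estimate(d, spec, prior_ess = 0)
  expect_equal(as.numeric(m0$cpts$X), c(0.6, 0.4))
  m1 <- count_estimate(d, spec, prior_ess = 1)
  expect_equal(as.numeric(m1$cpts$X), c(60.5 / 101, 40.5 / 101))
  expect_error(count_estimate(data.frame(X = "C"), spec), "unseen state")
})

test_that("counting with zero prior recovers exact frequencies on balanced data", {
  spec <- network_spec(list(P = c("p1", "p2"), C = c("c1", "c2")),
                       rbind(c("P", "C")))
  # every parent configuration enumerated equally, child frequencies exact
  d <- data.frame(P = rep(c("p1", "p2"), each = 20),
                  C = c(rep(c("c1", "c2"), c(15, 5)), rep(c("c1", "c2"), c(4, 16))))
  m <- count_estimate(d, spec, prior_ess = 0)
  expect_equal(matrix(m$cpts$C, nrow = 2), cbind(c(0.75, 0.25), c(0.2, 0.8)))
})

test_that("EM on complete data equals smoothed counting after one iteration", {
  truth <- recovery_ground_truth()
  d <- sample_states(truth$model, n = 400, seed = 3)
  for (ess in c(0, 1)) {
    em <- em_learn(d, truth$model$spec, prior_ess = ess)
    ct <- count_estimate(d, truth$model$spec, prior_ess = ess)
    expect_equal(em$meta$iterations, 1L)
    expect_equal(em$cpts, ct$cpts, tolerance = 1e-12)
  }
})

test_that("EM marginalizes missing observations correctly (symmetric case)", {
  spec <- single_node_spec()
  d <- data.frame(X = c(rep("A", 50), rep("B", 50)))
  d2 <- rbind(d, data.frame(X = rep(NA_character_, 100)))
  expect_error(em_learn(d2, spec), "observed node")  # fully empty rows rejected
  # with a second observed node the missing-X rows are legal and uninformative
  spec2 <- network_spec(list(X = c("A", "B"), Y = c("y1", "y2")),
                        matrix(character(0), ncol = 2))
  d3 <- data.frame(X = c(rep("A", 50), rep("B", 50), rep(NA_character_, 100)),
                   Y = rep(c("y1", "y2"), 100))
  m <- em_learn(d3, spec2, prior_ess = 0)
  expect_equal(as.numeric(m$cpts$X), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("the EM objective trace is non-decreasing and converges", {
  truth <- make_ground_truth(missing_rate = 0.15)
  sim <- generate_survey(truth, n = 120, seed = 11)
  dd <- discretize_scores(build_scores(sim$survey), sim$survey)
  m <- em_learn(dd, truth$model$spec, prior_ess = 1, tol = 1e-6, max_iter = 60)
  expect_true(anyNA(dd[, names(truth$model$spec$nodes)]))
  expect_gt(m$meta$iterations, 1L)
  obj <- m$meta$objective_trace
  expect_true(all(diff(obj) >= -1e-8 * (abs(obj[-length(obj)]) + 1)))
})

test_that("learned CPTs reproduce empirical marginals on complete data", {
  truth <- recovery_ground_truth()
  d <- sample_states(truth$model, n = 600, seed = 4)
  m <- count_estimate(d, truth$model$spec, prior_ess = 0)
  for (v in c("risk", "hwt_behaviour", "mother_education")) {
    emp <- as.numeric(table(factor(d[[v]], truth$model$spec$nodes[[v]]))) / nrow(d)
    # empirical-parent-weighted sum of the learned CPT equals the marginal
    pa <- truth$model$spec$parents[[v]]
    if (length(pa) == 0) {
      got <- as.numeric(m$cpts[[v]])
    } else {
      cfg <- hwtbbn:::parent_config_index(hwtbbn:::dataset_to_codes(d, truth$model$spec),
                                          truth$model$spec, v)
      w <- tabulate(cfg, nbins = ncol(matrix(m$cpts[[v]], nrow = length(truth$model$spec$nodes[[v]])))) / nrow(d)
      got <- as.numeric(matrix(m$cpts[[v]], nrow = length(truth$model$spec$nodes[[v]])) %*% w)
    }
    expect_equal(got, emp, tolerance = 1e-9)
  }
})

test_that("EM recovers generating CPTs from ample complete state data", {
  truth <- recovery_ground_truth()
  d <- sample_states(truth$model, n = 5000, seed = 21)
  m <- em_learn(d, truth$model$spec, prior_ess = 0)
  l1 <- hwtbbn:::cpt_l1(m, truth$model)
  expect_lt(mean(l1), 0.05)
})

test_that("seeded random initialization is reproducible and converges", {
  spec2 <- network_spec(list(X = c("A", "B"), Y = c("y1", "y2")),
                        rbind(c("X", "Y")))
  set.seed(33)
  d <- data.frame(X = sample(c("A", "B"), 80, TRUE),
                  Y = sample(c("y1", "y2"), 80, TRUE))
  d$Y[sample(80, 20)] <- NA
  m1 <- em_learn(d, spec2, prior_ess = 1, init = "random", seed = 5)
  m2 <- em_learn(d, spec2, prior_ess = 1, init = "random", seed = 5)
  expect_equal(m1$cpts, m2$cpts, tolerance = 1e-12)
  expect_true(m1$meta$converged)
  obj <- m1$meta$objective_trace
  expect_true(all(diff(obj) >= -1e-8 * (abs(obj[-length(obj)]) + 1)))
})
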