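#' Run the full determinant analysis on a survey table
#'
#' Chains every stage of the analysis: index construction
#' ([build_scores()]), discretization into node states
#' ([discretize_scores()]), CPT learning ([em_learn()]), predictive
#' delta-P inference and CPT sensitivity for the "regular user" outcome,
#' stratified cross-validation, the forced-entry regression of the HWT
#' behaviour score on the sixteen RANAS sub-factor items, and chi-square
#' tests of each SEC node against the discretized behaviour.
#'
#' @param survey a `survey_table`.
#' @param spec the network structure (default [default_network_spec()]).
#' @param prior_ess,tol,max_iter,init,seed passed to [em_learn()].
#' @param cv_k,cv_seed cross-validation folds and fold seed; `cv_k = 0`
#'   skips cross-validation.
#' @param target_state outcome state of interest for delta-P and
#'   sensitivity.
#' @param digits report rounding (integer percentages by default).
#' @return an `hwt_analysis`: list with `scores`, `dataset`, `model`,
#'   `baseline` (posterior over the outcome), `delta_p`, `sensitivity`,
#'   `cv`, `regression`, `chi_square` (per SEC node).
#' @export
hwt_pipeline <- function(survey, spec = default_network_spec(),
                         prior_ess = 1, tol = 1e-6, max_iter = 500,
                         init = "uniform", seed = NULL,
                         cv_k = 10, cv_seed = 0,
                         target_state = "regular user", digits = 0) {
  stopifnot(inherits(survey, "survey_table"))
  cb <- survey$codebook
  scores <- build_scores(survey)
  dataset <- discretize_scores(scores, survey)
  model <- em_learn(dataset, spec, prior_ess = prior_ess, tol = tol,
                    max_iter = max_iter, init = init, seed = seed)
  baseline <- infer_ve(model, list(), "hwt_behaviour")
  dp <- delta_p(model, target_state = target_state, digits = digits)
  sens <- sensitivity(model, target_state = target_state)
  cv <- if (cv_k > 0) {
    cross_validate(dataset, spec, k = cv_k, seed = cv_seed,
                   prior_ess = prior_ess, tol = tol, max_iter = max_iter)
  }
  items <- cb$name[cb$role == "ranas_item"]
  reg <- ols_forced_entry(scores$data$hwt_score,
                          as.matrix(survey$data[, items]))
  chis <- lapply(stats::setNames(codebook_vars(cb, "sec"),
                                 codebook_vars(cb, "sec")), function(v) {
    tryCatch(chi_square(dataset[[v]], dataset$hwt_behaviour),
             error = function(e) NULL)
  })
  structure(list(survey = survey, scores = scores, dataset = dataset,
                 model = model, baseline = baseline, delta_p = dp,
                 sensitivity = sens, cv = cv, regression = reg,
                 chi_square = chis),
            class = "hwt_analysis")
}

#' @export
print.hwt_analysis <- function(x, ...) {
  cat("Household water treatment determinant analysis\n")
  cat(sprintf("  households: %d; EM iterations: %d\n",
              nrow(x$dataset), x$model$meta$iterations))
  cat(sprintf("  baseline P(hwt_behaviour): %s\n",
              paste(sprintf("%s %.0f%%", names(x$baseline), 100 * x$baseline),
                    collapse = ", ")))
  print(x$delta_p)
  if (!is.null(x$cv)) {
    cat(sprintf("  CV: accuracy %.1f%%, macro AUC %.3f\n",
                100 * x$cv$accuracy, x$cv$macro_auc))
  }
  invisible(x)
}

#' Reproduce the full analysis from a deposited survey workbook
#'
#' Convenience wrapper: reads a survey file (CSV or XLSX) against a
#' codebook and runs [hwt_pipeline()]. A codebook mapping the file's column
#' headers onto the instrument's variables must be supplied if the headers
#' differ from the default vocabulary.
#'
#' @param path survey file path.
#' @param codebook an `hwt_codebook`.
#' @param ... passed on to [hwt_pipeline()].
#' @return an `hwt_analysis`.
#' @export
reproduce_study <- function(path, codebook = default_codebook(), ...) {
  if (!file.exists(path)) {
    stop("survey file not found: ", path,
         " (the deposited study workbook must be supplied by the user)")
  }
  hwt_pipeline(read_survey(path, codebook), ...)
}
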