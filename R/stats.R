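# Supporting classical analyses: forced-entry multivariate OLS of the HWT
# behaviour score on the sixteen RANAS sub-factor items, and Pearson
# chi-square tests of independence between discretized variables.

#' Forced-entry multivariate linear regression
#'
#' Ordinary least squares of the outcome on all predictors entered together
#' (no selection), after listwise deletion of rows with any missing value.
#' Reports, per predictor, the unstandardized coefficient B with its
#' standard error, the standardized coefficient beta
#' (`B * sd(x) / sd(y)` on the analysis sample), the t statistic and the
#' two-sided p value, plus adjusted R-squared and the sample sizes.
#' Significance stars are rendered at 0.05 / 0.01 / 0.001.
#'
#' @param y numeric outcome vector (e.g. the HWT behaviour score).
#' @param X numeric matrix or data frame of predictors (households x items).
#' @return a `regression_result`: list with `coefficients` (data frame:
#'   term, B, SE_B, beta, t, p, stars), `intercept`, `adj_r_squared`,
#'   `r_squared`, `n_used`, `n_dropped`.
#' @export
ols_forced_entry <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(cbind(y, X))
  n_dropped <- sum(!keep)
  y0 <- y[keep]
  X0 <- X[keep, , drop = FALSE]
  n <- length(y0)
  p <- ncol(X0)
  if (n <= p + 1L) stop("too few complete rows for the number of predictors")
  qrX <- qr(cbind(1, X0))
  if (qrX$rank < p + 1L) {
    dependent <- colnames(X0)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)] - 1L)]
    stop("rank-deficient design; collinear column(s): ",
         paste(dependent, collapse = ", "))
  }
  fit <- stats::lm(y0 ~ X0)
  sm <- summary(fit)
  co <- sm$coefficients
  rownames(co) <- sub("^X0", "", rownames(co))
  sds <- apply(X0, 2L, stats::sd)
  beta <- co[-1L, 1L] * sds / stats::sd(y0)
  stars <- cut(co[-1L, 4L], breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  coefficients <- data.frame(
    term = colnames(X0), B = co[-1L, 1L], SE_B = co[-1L, 2L],
    beta = beta, t = co[-1L, 3L], p = co[-1L, 4L],
    stars = as.character(stars), row.names = NULL
  )
  structure(list(coefficients = coefficients,
                 intercept = unname(co[1L, 1L]),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 residual_se = sm$sigma,
                 n_used = n, n_dropped = n_dropped),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Forced-entry OLS: n = %d (%d dropped listwise), adjusted R^2 = %.3f\n",
              x$n_used, x$n_dropped, x$adj_r_squared))
  df <- x$coefficients
  df$B <- sprintf("%.3f", df$B)
  df$SE_B <- sprintf("%.3f", df$SE_B)
  df$beta <- sprintf("%.3f%s", x$coefficients$beta, df$stars)
  print(df[, c("term", "B", "SE_B", "beta")], row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic over the r x c contingency table of two
#' categorical vectors (pairs with a missing member dropped), without
#' continuity correction, with the p value from the upper tail of the
#' chi-square distribution on (r-1)(c-1) degrees of freedom.
#'
#' @param a,b categorical vectors (character or factor) of equal length.
#' @return a `chi_square_result`: list with `statistic`, `df`, `p_value`,
#'   `observed` and `expected` tables.
#' @export
chi_square <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have the same length")
  keep <- !is.na(a) & !is.na(b)
  tab <- table(droplevels(factor(a[keep])), droplevels(factor(b[keep])))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("both variables need at least two observed categories")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("structural zero: an expected cell count is 0")
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), observed = tab,
                 expected = ct$expected),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2(%d) = %.2f, p = %.3g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}
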