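# Index construction: first-principal-component scores for the wealth index,
# the five RANAS factors and the HWT behaviour outcome, plus quantile
# discretization into the categorical node states used by the network.

#' First principal component scores of an item matrix
#'
#' Items are z-scored and the scores are the projections onto the first
#' principal component of the standardized matrix (equivalently, the leading
#' eigenvector of the item correlation matrix — the DHS wealth-index
#' convention). The sign of the component is fixed by requiring a
#' non-negative correlation between the scores and the unweighted mean of
#' the input items, so "more of the items" always means a higher score.
#' Rows containing missing values receive a missing score (impute first with
#' [impute_items()] if desired); zero-variance items are dropped with a
#' warning.
#'
#' @param items numeric matrix, households x items.
#' @param orientation_anchor `"mean"` (default; anchor the sign to the item
#'   mean) or `"none"` (deterministic but arbitrary sign: largest-magnitude
#'   loading positive).
#' @return list with `scores` (length `nrow(items)`, `NA` for incomplete
#'   rows), `loadings` (named, per retained item), `variance_explained`
#'   (fraction in (0,1]) and `dropped` (names of zero-variance items).
#' @export
pc1_scores <- function(items, orientation_anchor = c("mean", "none")) {
  orientation_anchor <- match.arg(orientation_anchor)
  items <- as.matrix(items)
  if (is.null(colnames(items))) {
    colnames(items) <- paste0("item", seq_len(ncol(items)))
  }
  if (ncol(items) < 2L) stop("at least two items are required")
  complete <- stats::complete.cases(items)
  if (sum(complete) < 3L) stop("at least three complete rows are required")
  sds <- apply(items[complete, , drop = FALSE], 2L, stats::sd)
  dropped <- colnames(items)[sds == 0]
  if (length(dropped) == ncol(items)) stop("all items have zero variance")
  if (length(dropped) > 0L) {
    warning("dropping zero-variance item(s): ", paste(dropped, collapse = ", "))
    items <- items[, sds > 0, drop = FALSE]
  }
  x <- items[complete, , drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  v <- pc$rotation[, 1L]
  z <- scale(x, center = pc$center, scale = pc$scale)
  s <- drop(z %*% v)
  if (orientation_anchor == "mean") {
    # anchor on the standardized item mean: invariant to positive affine
    # rescaling of any item, equivariant (sign flip) under joint negation
    anchor <- rowMeans(z)
    if (stats::sd(anchor) > 0 && stats::cor(s, anchor) < 0) {
      v <- -v; s <- -s
    }
  } else if (v[which.max(abs(v))] < 0) {
    v <- -v; s <- -s
  }
  scores <- rep(NA_real_, nrow(items))
  scores[complete] <- s
  list(scores = scores, loadings = v,
       variance_explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Within-factor mean imputation of missing item responses
#'
#' For each household, if at least half of the factor's items are observed
#' the missing ones are replaced by the item's sample mean (over observed
#' responses); otherwise the whole row is flagged missing, which propagates
#' as a missing factor score and later as a missing node state for EM.
#'
#' @param items numeric matrix, households x items of one factor.
#' @return matrix of the same shape; rows with too little information are
#'   entirely `NA`.
#' @export
impute_items <- function(items) {
  items <- as.matrix(items)
  present <- rowSums(!is.na(items))
  colmeans <- colMeans(items, na.rm = TRUE)
  enough <- present >= ncol(items) / 2
  out <- items
  for (j in seq_len(ncol(items))) {
    fill <- enough & is.na(items[, j])
    out[fill, j] <- colmeans[j]
  }
  out[!enough, ] <- NA_real_
  out
}

#' Asset-based relative wealth index
#'
#' First-principal-component score of the binary household asset checklist
#' (DHS-style): households owning more of the discriminating assets score
#' higher under the positive orientation.
#'
#' @param assets numeric 0/1 matrix, households x assets.
#' @return as [pc1_scores()].
#' @export
wealth_index <- function(assets) {
  pc1_scores(impute_items(assets), orientation_anchor = "mean")
}

#' HWT behaviour score from the five outcome items
#'
#' Reverse-coded items (per the codebook, e.g. the frequency of drinking raw
#' water) are flipped onto the "more/safer treatment" orientation before
#' scoring, then the first principal component is extracted as in
#' [pc1_scores()].
#'
#' @param answers numeric matrix, households x behaviour items, with column
#'   names matching the codebook.
#' @param codebook an `hwt_codebook` declaring per-item polarity.
#' @return as [pc1_scores()].
#' @export
hwt_behaviour_score <- function(answers, codebook = default_codebook()) {
  answers <- apply_polarity(as.matrix(answers), codebook)
  pc1_scores(impute_items(answers), orientation_anchor = "mean")
}

#' Rank-based quantile discretization of a score vector
#'
#' Households are sorted by score with ties broken by id for determinism and
#' the lowest block assigned to the lowest state, following the scheme's
#' cumulative fractions (`tertile`: thirds; `forty_forty_twenty`: 40/40/20 as
#' used for the wealth index). Cut sizes are `diff(ceiling(cumsum(q) * m))`
#' over the `m` non-missing scores, so category counts are exact and
#' reproducible regardless of tied values. A fully degenerate vector (all
#' non-missing scores equal) carries no ordering information and is assigned
#' entirely to the lowest state, with a warning. Missing scores yield
#' missing states.
#'
#' @param scores numeric vector.
#' @param scheme `"tertile"` or `"forty_forty_twenty"`.
#' @param ids optional vector of unique household ids used to break ties
#'   (default: position).
#' @param labels state labels, lowest first; defaults to Low/Moderate/High
#'   for tertiles and Poor/Middle/Rich for the 40/40/20 scheme.
#' @return character vector of state labels with `cutpoints` attribute (the
#'   score at each block boundary).
#' @export
discretize <- function(scores, scheme = c("tertile", "forty_forty_twenty"),
                       ids = NULL, labels = NULL) {
  scheme <- match.arg(scheme)
  q <- switch(scheme, tertile = c(1, 1, 1) / 3,
              forty_forty_twenty = c(0.4, 0.4, 0.2))
  if (is.null(labels)) {
    labels <- switch(scheme, tertile = c("Low", "Moderate", "High"),
                     forty_forty_twenty = c("Poor", "Middle", "Rich"))
  }
  if (is.null(ids)) ids <- seq_along(scores)
  if (anyDuplicated(ids)) stop("ids must be unique")
  ok <- !is.na(scores)
  m <- sum(ok)
  if (m < 3L) stop("at least three non-missing scores are required")
  out <- rep(NA_character_, length(scores))
  if (length(unique(scores[ok])) == 1L) {
    warning("all non-missing scores are identical; assigning the lowest state")
    out[ok] <- labels[1L]
    attr(out, "cutpoints") <- rep(scores[ok][1L], 2L)
    return(out)
  }
  counts <- diff(c(0L, ceiling(cumsum(q) * m)))
  ord <- order(scores[ok], ids[ok])
  states <- rep(labels, times = counts)
  out[ok][ord] <- states
  cuts <- sort(scores[ok])[cumsum(counts)[1:2]]
  attr(out, "cutpoints") <- cuts
  out
}

#' Build the continuous score table from a survey
#'
#' Runs the whole index-construction stage: the asset wealth index, one
#' first-component score per RANAS factor (reverse-coded items flipped,
#' within-factor mean imputation) and the HWT behaviour score.
#'
#' @param survey a `survey_table`.
#' @return a `score_table`: list with `data` (data frame of household id and
#'   the seven scores) and `details` (per-index loadings, variance explained
#'   and dropped items).
#' @export
build_scores <- function(survey) {
  stopifnot(inherits(survey, "survey_table"))
  cb <- survey$codebook
  d <- survey$data
  id_col <- codebook_vars(cb, "id")[1L]
  details <- list()

  score_of <- function(cols, flip = FALSE) {
    m <- as.matrix(d[, cols, drop = FALSE])
    if (flip) m <- apply_polarity(m, cb)
    fit <- pc1_scores(impute_items(m), orientation_anchor = "mean")
    fit
  }

  out <- data.frame(row.names = seq_len(nrow(d)))
  out[[id_col]] <- d[[id_col]]
  fit <- score_of(codebook_vars(cb, "asset"))
  out$wealth_score <- fit$scores; details$wealth <- fit

  factor_cols <- list(risk = "Risk", attitude = "Attitude", norm = "Norm",
                      ability = "Ability", self_regulation = "Self-regulation")
  for (nm in names(factor_cols)) {
    fit <- score_of(ranas_items(cb, factor_cols[[nm]]), flip = TRUE)
    out[[paste0(nm, "_score")]] <- fit$scores
    details[[nm]] <- fit
  }
  fit <- score_of(codebook_vars(cb, "behaviour_item"), flip = TRUE)
  out$hwt_score <- fit$scores; details$hwt <- fit

  structure(list(data = out, details = details, id_col = id_col),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Score table: %d households, %d indices\n",
              nrow(x$data), ncol(x$data) - 1L))
  ve <- vapply(x$details, `[[`, numeric(1), "variance_explained")
  print(round(ve, 3))
  invisible(x)
}

#' Discretize scores and raw SEC answers into the network's node states
#'
#' Produces the categorical dataset over the fourteen network nodes: the
#' seven raw SEC answers carried over as-is, the wealth index cut 40/40/20
#' into Poor/Middle/Rich, the five RANAS factor scores and the HWT behaviour
#' score cut into tertiles (Low/Moderate/High and non-user/irregular
#' user/regular user respectively). Missing scores or answers become missing
#' states.
#'
#' @param scores a `score_table` from [build_scores()].
#' @param survey the `survey_table` the scores were built from.
#' @return data frame (class `discrete_dataset`) with the household id and
#'   one factor-like character column per network node; `cutpoints`
#'   attribute records the discretization boundaries.
#' @export
discretize_scores <- function(scores, survey) {
  stopifnot(inherits(scores, "score_table"), inherits(survey, "survey_table"))
  cb <- survey$codebook
  id_col <- scores$id_col
  ids <- scores$data[[id_col]]
  out <- data.frame(row.names = seq_len(nrow(scores$data)))
  out[[id_col]] <- ids
  cuts <- list()
  for (v in setdiff(codebook_vars(cb, "sec"), "wealth")) {
    out[[v]] <- survey$data[[v]]
  }
  w <- discretize(scores$data$wealth_score, "forty_forty_twenty", ids = ids)
  out$wealth <- as.character(w); cuts$wealth <- attr(w, "cutpoints")
  for (nm in c("risk", "attitude", "norm", "ability", "self_regulation")) {
    s <- discretize(scores$data[[paste0(nm, "_score")]], "tertile", ids = ids)
    out[[nm]] <- as.character(s); cuts[[nm]] <- attr(s, "cutpoints")
  }
  h <- discretize(scores$data$hwt_score, "tertile", ids = ids,
                  labels = c("non-user", "irregular user", "regular user"))
  out$hwt_behaviour <- as.character(h); cuts$hwt_behaviour <- attr(h, "cutpoints")
  attr(out, "cutpoints") <- cuts
  class(out) <- c("discrete_dataset", "data.frame")
  out
}
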