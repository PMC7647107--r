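#' Survey codebook
#'
#' The codebook declares every survey variable: its role (`id`, `sec`,
#' `asset`, `ranas_item`, `behaviour_item`), measurement scale (`likert_1_5`,
#' `binary_0_1`, `categorical` with an ordered state list, or `count`), the
#' RANAS factor owning each psychological item, and per-item polarity
#' (reverse-coded items are flipped before any scoring). Column-name mapping
#' is explicit — a survey column is used only if its header matches a
#' codebook variable name exactly.
#'
#' The shipped default codebook encodes the study instrument: eight
#' socio-economic characteristics (one of them, the wealth index, derived
#' from an eight-item asset checklist rather than asked directly), sixteen
#' RANAS sub-factor items (3 Risk, 3 Attitude, 3 Norm, 3 Ability, 4
#' Self-regulation, one of which is the binary barrier-planning item), and
#' five HWT behaviour items.
#'
#' @param path path to a codebook YAML file.
#' @return object of class `hwt_codebook`: a data frame with one row per
#'   variable plus a `states` list-column.
#' @export
read_codebook <- function(path) {
  doc <- yaml::read_yaml(path)
  vars <- doc$variables
  cb <- data.frame(
    name = vapply(vars, `[[`, character(1), "name"),
    role = vapply(vars, `[[`, character(1), "role"),
    scale = vapply(vars, function(v) v$scale %||% NA_character_, character(1)),
    factor = vapply(vars, function(v) v$factor %||% NA_character_, character(1)),
    polarity = vapply(vars, function(v) v$polarity %||% "positive", character(1)),
    derived = vapply(vars, function(v) isTRUE(v$derived), logical(1)),
    stringsAsFactors = FALSE
  )
  cb$states <- lapply(vars, function(v) {
    if (is.null(v$states)) NULL else as.character(v$states)
  })
  cb <- structure(cb, class = c("hwt_codebook", "data.frame"))
  validate_codebook(cb)
  cb
}

#' @rdname read_codebook
#' @export
default_codebook <- function() {
  read_codebook(system.file("extdata", "codebook.yaml", package = "hwtbbn",
                            mustWork = TRUE))
}

validate_codebook <- function(cb) {
  if (anyDuplicated(cb$name)) stop("codebook variable names must be unique")
  roles <- c("id", "sec", "asset", "ranas_item", "behaviour_item")
  bad <- setdiff(cb$role, roles)
  if (length(bad)) stop("unknown codebook role(s): ", paste(bad, collapse = ", "))
  ri <- cb[cb$role == "ranas_item", ]
  factors <- c("Risk", "Attitude", "Norm", "Ability", "Self-regulation")
  if (any(!ri$factor %in% factors)) {
    stop("every ranas_item must belong to one of the five RANAS factors")
  }
  want <- c(Risk = 3L, Attitude = 3L, Norm = 3L, Ability = 3L,
            `Self-regulation` = 4L)
  got <- table(factor(ri$factor, levels = factors))
  if (!all(got == want)) {
    stop("RANAS factors must own 3/3/3/3/4 sub-factor items; got ",
         paste(got, collapse = "/"))
  }
  sec <- cb[cb$role == "sec", ]
  if (nrow(sec) != 8L) stop("exactly eight SEC variables are required")
  for (k in seq_len(nrow(sec))) {
    if (is.null(sec$states[[k]]) || length(sec$states[[k]]) < 2L) {
      stop(sprintf("SEC variable '%s' needs an ordered state list", sec$name[k]))
    }
  }
  invisible(TRUE)
}

codebook_vars <- function(cb, role) cb$name[cb$role == role]

ranas_items <- function(cb, factor_name) {
  cb$name[cb$role == "ranas_item" & cb$factor == factor_name]
}

# Flip reverse-coded items onto the positive orientation.
apply_polarity <- function(mat, cb) {
  for (nm in colnames(mat)) {
    row <- cb[cb$name == nm, ]
    if (nrow(row) == 1L && row$polarity == "negative") {
      mat[, nm] <- switch(row$scale,
                          likert_1_5 = 6 - mat[, nm],
                          binary_0_1 = 1 - mat[, nm],
                          -mat[, nm])
    }
  }
  mat
}
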