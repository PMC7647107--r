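#' Read and validate a household survey table
#'
#' Reads a delimited table (CSV) or spreadsheet workbook (XLSX, first sheet
#' by default) and validates every cell against the codebook: Likert
#' responses must be integers in 1..5, binary responses 0/1, categorical
#' responses members of the declared state list, counts non-negative
#' integers. Unparseable or out-of-range cells become missing and are
#' counted in the validation report; the row count is always preserved.
#' Cells equal to one of `missing_tokens` (default: the empty cell) are
#' missing by convention and are never imputed at this layer.
#'
#' @param path file path (`.csv` or `.xlsx`).
#' @param codebook an `hwt_codebook`, e.g. [default_codebook()].
#' @param missing_tokens character vector of sentinels treated as missing.
#' @param sheet sheet to read from a workbook (default the first).
#' @return object of class `survey_table`: list with `data` (one row per
#'   household; numeric columns for Likert/binary/count variables, character
#'   for categoricals, `NA` = missing), `codebook` and `validation`
#'   (counts of missing and invalid cells, with messages).
#' @export
read_survey <- function(path, codebook = default_codebook(),
                        missing_tokens = c("", "NA"), sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading workbooks requires the 'readxl' package")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet,
                                     col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  as_survey_table(raw, codebook, missing_tokens = missing_tokens)
}

#' Coerce a raw data frame of character responses into a `survey_table`
#'
#' @param raw data frame of character (or coercible) responses with a header
#'   matching codebook variable names.
#' @inheritParams read_survey
#' @export
as_survey_table <- function(raw, codebook = default_codebook(),
                            missing_tokens = c("", "NA")) {
  cb <- codebook
  expected <- cb$name[!cb$derived]
  absent <- setdiff(expected, names(raw))
  if (length(absent) > 0L) {
    stop("survey table lacks mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  unknown <- setdiff(names(raw), cb$name)
  if (length(unknown) > 0L) {
    warning("ignoring column(s) not in the codebook: ",
            paste(unknown, collapse = ", "))
  }
  id_col <- codebook_vars(cb, "id")[1L]
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate household id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  n_missing <- 0L
  n_invalid <- 0L
  msgs <- character(0)
  out <- data.frame(row.names = seq_along(ids))
  out[[id_col]] <- ids
  for (k in which(!cb$derived & cb$role != "id")) {
    nm <- cb$name[k]
    x <- trimws(as.character(raw[[nm]]))
    x[is.na(x) | x %in% missing_tokens] <- NA_character_
    n_missing <- n_missing + sum(is.na(x))
    if (cb$scale[k] == "categorical") {
      bad <- !is.na(x) & !(x %in% cb$states[[k]])
      if (any(bad)) {
        n_invalid <- n_invalid + sum(bad)
        msgs <- c(msgs, sprintf(
          "%s: %d cell(s) outside the declared states (%s) set to missing",
          nm, sum(bad), paste(unique(x[bad]), collapse = ", ")))
        x[bad] <- NA_character_
      }
      out[[nm]] <- x
    } else {
      v <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & (is.na(v) | v != round(v) |
        switch(cb$scale[k],
               likert_1_5 = v < 1 | v > 5,
               binary_0_1 = !(v %in% c(0, 1)),
               count = v < 0,
               FALSE))
      if (any(bad)) {
        n_invalid <- n_invalid + sum(bad)
        msgs <- c(msgs, sprintf("%s: %d out-of-range cell(s) set to missing",
                                nm, sum(bad)))
        v[bad] <- NA_real_
      }
      out[[nm]] <- v
    }
  }
  if (length(msgs) > 0L) {
    warning(paste(msgs, collapse = "; "))
  }
  structure(list(data = out, codebook = cb,
                 validation = list(n_rows = nrow(out), n_missing = n_missing,
                                   n_invalid = n_invalid, messages = msgs)),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("Household survey: %d households, %d variables (%d missing cells",
              nrow(x$data), ncol(x$data) - 1L, x$validation$n_missing))
  cat(sprintf(", %d invalid cells coerced to missing)\n", x$validation$n_invalid))
  invisible(x)
}

#' Write a survey table back to CSV
#'
#' Missing values are written as empty cells, so a round trip through
#' [write_survey()] and [read_survey()] reproduces the table exactly.
#'
#' @param table a `survey_table`.
#' @param path output CSV path.
#' @export
write_survey <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Descriptive summary of a survey table
#'
#' Mirrors the usual survey reporting: per Likert/binary/count item the
#' number of non-missing responses, mean and sample standard deviation
#' (n-1 denominator); per categorical variable the state frequencies, which
#' together with the missing count sum to the number of households.
#'
#' @param table a `survey_table`.
#' @return a `survey_summary`: list with `items` (data frame) and
#'   `categoricals` (named list of frequency tables including a `<missing>`
#'   count).
#' @export
summarize_survey <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  if (nrow(table$data) == 0L) stop("empty survey table")
  cb <- table$codebook
  num_vars <- cb$name[!cb$derived & cb$scale %in%
                        c("likert_1_5", "binary_0_1", "count")]
  items <- do.call(rbind, lapply(num_vars, function(nm) {
    x <- table$data[[nm]]
    data.frame(variable = nm, factor = cb$factor[cb$name == nm],
               n = sum(!is.na(x)), missing = sum(is.na(x)),
               mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  }))
  cat_vars <- cb$name[!cb$derived & !is.na(cb$scale) & cb$scale == "categorical"]
  categoricals <- lapply(stats::setNames(cat_vars, cat_vars), function(nm) {
    x <- table$data[[nm]]
    states <- cb$states[[which(cb$name == nm)]]
    freq <- table(factor(x, levels = states))
    c(freq, `<missing>` = sum(is.na(x)))
  })
  structure(list(items = items, categoricals = categoricals,
                 n_rows = nrow(table$data)),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("Survey summary over %d households\n", x$n_rows))
  df <- x$items
  df$mean <- round(df$mean, 2)
  df$sd <- round(df$sd, 2)
  print(df, row.names = FALSE)
  for (nm in names(x$categoricals)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$categoricals[[nm]])
  }
  invisible(x)
}
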