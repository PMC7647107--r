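# Survey reading, validation, writing and descriptive summaries.

make_mini_codebook <- function() {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  writeLines(c(
    "variables:",
    "  - {name: household_id, role: id}",
    "  - {name: health_problem, role: sec, scale: categorical, states: ['No', 'Yes']}",
    "  - {name: information_access, role: sec, scale: categorical, states: [Difficult, Medium, Easy]}",
    "  - {name: mother_education, role: sec, scale: categorical, states: [None, Primary, Secondary, Higher]}",
    "  - {name: father_education, role: sec, scale: categorical, states: [None, Primary, Secondary, Higher]}",
    "  - {name: wealth, role: sec, scale: categorical, states: [Poor, Middle, Rich], derived: true}",
    "  - {name: religion, role: sec, scale: categorical, states: [Christian, Islam]}",
    "  - {name: accessibility, role: sec, scale: categorical, states: [Difficult, Easy]}",
    "  - {name: access_water, role: sec, scale: categorical, states: [Far, Medium, Close]}",
    "  - {name: r1, role: ranas_item, factor: Risk, scale: likert_1_5}",
    "  - {name: r2, role: ranas_item, factor: Risk, scale: likert_1_5}",
    "  - {name: r3, role: ranas_item, factor: Risk, scale: likert_1_5}",
    "  - {name: a1, role: ranas_item, factor: Attitude, scale: likert_1_5}",
    "  - {name: a2, role: ranas_item, factor: Attitude, scale: likert_1_5}",
    "  - {name: a3, role: ranas_item, factor: Attitude, scale: likert_1_5}",
    "  - {name: no1, role: ranas_item, factor: Norm, scale: likert_1_5}",
    "  - {name: no2, role: ranas_item, factor: Norm, scale: likert_1_5}",
    "  - {name: no3, role: ranas_item, factor: Norm, scale: likert_1_5}",
    "  - {name: ab1, role: ranas_item, factor: Ability, scale: likert_1_5}",
    "  - {name: ab2, role: ranas_item, factor: Ability, scale: likert_1_5}",
    "  - {name: ab3, role: ranas_item, factor: Ability, scale: likert_1_5}",
    "  - {name: s1, role: ranas_item, factor: Self-regulation, scale: likert_1_5}",
    "  - {name: s2, role: ranas_item, factor: Self-regulation, scale: likert_1_5}",
    "  - {name: s3, role: ranas_item, factor: Self-regulation, scale: likert_1_5}",
    "  - {name: s4, role: ranas_item, factor: Self-regulation, scale: binary_0_1}"
  ), path)
  read_codebook(path)
}

test_that("reading preserves rows and counts blank cells as missing", {
  cb <- make_mini_codebook()
  cols <- cb$name[!cb$derived]
  df <- as.data.frame(lapply(stats::setNames(cols, cols), function(x) c("1", "2", "3")))
  df$household_id <- c("H1", "H2", "H3")
  for (v in codebook_vars(cb, "sec")[codebook_vars(cb, "sec") != "wealth"]) {
    df[[v]] <- cb$states[[which(cb$name == v)]][1]
  }
  df$s4 <- c("0", "1", "0")
  df$r1[2] <- ""   # one blank Likert cell
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  sv <- read_survey(path, cb)
  expect_s3_class(sv, "survey_table")
  expect_equal(nrow(sv$data), 3)
  expect_equal(sv$validation$n_missing, 1)
  expect_true(is.na(sv$data$r1[2]))
})

test_that("out-of-range responses become missing with a warning", {
  cb <- make_mini_codebook()
  cols <- cb$name[!cb$derived]
  df <- as.data.frame(lapply(stats::setNames(cols, cols), function(x) c("2", "3")))
  df$household_id <- c("H1", "H2")
  for (v in setdiff(codebook_vars(cb, "sec"), "wealth")) {
    df[[v]] <- cb$states[[which(cb$name == v)]][1]
  }
  df$s4 <- c("1", "0")
  df$r2[1] <- "7"                  # Likert out of range
  df$religion[2] <- "Buddhist"     # undeclared state
  expect_warning(sv <- as_survey_table(df, cb), "out-of-range|states")
  expect_true(is.na(sv$data$r2[1]))
  expect_true(is.na(sv$data$religion[2]))
  expect_equal(sv$validation$n_invalid, 2)
})

test_that("schema and id problems are rejected with informative errors", {
  cb <- make_mini_codebook()
  cols <- cb$name[!cb$derived]
  df <- as.data.frame(lapply(stats::setNames(cols, cols), function(x) c("2", "3")))
  df$household_id <- c("H1", "H1")
  expect_error(as_survey_table(df[, setdiff(names(df), "r1")], cb), "r1")
  expect_error(as_survey_table(df, cb), "duplicate")
})

test_that("a generated survey round-trips through write-then-read unchanged", {
  truth <- make_ground_truth()
  sim <- generate_survey(truth, n = 202, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(sim$survey, path)
  sv2 <- read_survey(path, truth$codebook)
  expect_equal(sv2$data, sim$survey$data, ignore_attr = TRUE)
})

test_that("summaries follow survey conventions (sample SD, frequencies sum to n)", {
  cb <- make_mini_codebook()
  cols <- cb$name[!cb$derived]
  n <- 5
  df <- as.data.frame(lapply(stats::setNames(cols, cols),
                             function(x) as.character(rep(3, n))))
  df$household_id <- paste0("H", 1:n)
  for (v in setdiff(codebook_vars(cb, "sec"), "wealth")) {
    st <- cb$states[[which(cb$name == v)]]
    df[[v]] <- st[c(1, 2, 1, 2, 1)]
  }
  df$s4 <- c("0", "1", "0", "0", "1")
  df$r1 <- as.character(1:5)
  sv <- as_survey_table(df, cb)
  sm <- summarize_survey(sv)
  expect_equal(sm$items$mean[sm$items$variable == "r2"], 3)
  expect_equal(sm$items$sd[sm$items$variable == "r2"], 0)
  # sample SD convention on {1,2,3,4,5}
  expect_equal(sm$items$mean[sm$items$variable == "r1"], 3)
  expect_equal(sm$items$sd[sm$items$variable == "r1"], 1.5811, tolerance = 1e-4)
  for (v in names(sm$categoricals)) {
    expect_equal(sum(sm$categoricals[[v]]), n)
  }
  empty <- sv
  empty$data <- sv$data[0, ]
  expect_error(summarize_survey(empty), "empty")
})

test_that("the shipped codebook satisfies the instrument invariants", {
  cb <- default_codebook()
  ri <- cb[cb$role == "ranas_item", ]
  expect_equal(as.integer(sort(table(ri$factor))), c(3L, 3L, 3L, 3L, 4L))
  expect_equal(sum(cb$role == "sec"), 8)
  expect_equal(cb$states[[which(cb$name == "mother_education")]],
               c("None", "Primary", "Secondary", "Higher"))
  expect_equal(cb$states[[which(cb$name == "religion")]], c("Christian", "Islam"))
  expect_equal(cb$states[[which(cb$name == "accessibility")]], c("Difficult", "Easy"))
  expect_equal(sum(cb$role == "behaviour_item"), 5)
  expect_equal(sum(cb$role == "asset"), 8)
})
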