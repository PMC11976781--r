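test_that("month utilities parse, index and sequence correctly", {
  expect_equal(month_seq("2017-01", 3), c("2017-01", "2017-02", "2017-03"))
  expect_equal(month_seq("2019-11", 4),
               c("2019-11", "2019-12", "2020-01", "2020-02"))
  expect_equal(month_index("2020-04", "2017-01"), 39L)
  expect_error(parse_month("2020-13"), "unparseable")
  expect_error(parse_month("April 2020"), "unparseable")
})

test_that("variable config defaults follow the 1/(2n) rule", {
  n16 <- default_variable_specs()
  expect_equal(nrow(n16), 16L)
  expect_true(all(n16$min_weight == 0.03125))
  expect_equal(default_min_weight(16), 0.03125)

  two <- tiny_specs()
  expect_true(all(two$min_weight == 0.25))
})

test_that("variable config round-trips through YAML and JSON", {
  specs <- default_variable_specs()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_variable_config(specs, path)
    back <- read_variable_config(path)
    expect_equal(as.data.frame(back), as.data.frame(specs))
  }
})

test_that("invalid variable configs are rejected", {
  expect_error(
    variable_specs(c("a", "b"), "access", "desirable",
                   min_weight = c(0.6, 0.6)),
    "exceeds 1")
  expect_error(
    variable_specs("a", "access", "neutral"),
    "without a band")
  expect_error(
    variable_specs("a", "access", "desirable", neutral_lo = 10,
                   neutral_hi = 20),
    "non-neutral")
  expect_error(
    variable_specs("a", "access", "neutral", neutral_lo = 90,
                   neutral_hi = 80),
    "lo < hi")
  expect_error(variable_specs("a", "access", "upwards"), "direction")
})

test_that("panels round-trip through long-form CSV with missing mask", {
  specs <- tiny_specs()
  vals <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2))
  panel <- tiny_panel(vals, months = c("2020-01", "2020-02"),
                      specs = specs)
  expect_equal(length(panel$values), 8L)

  panel$values[1, 2, 1] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path, specs)
  expect_identical(is.na(back$values), is.na(panel$values))
  expect_equal(back$values, panel$values)
  expect_equal(back$entities, panel$entities)
  expect_equal(back$months, panel$months)
})

test_that("wide-form panels are accepted", {
  specs <- tiny_specs()
  df <- data.frame(entity = c("a", "a", "b", "b"), group = "G",
                   month = rep(c("2020-01", "2020-02"), 2),
                   v1 = 1:4, v2 = c(5, NA, 7, 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  p <- read_panel(path, specs, format = "wide")
  expect_equal(dim(p), c(2L, 2L, 2L))
  expect_true(is.na(p$values["a", "2020-02", "v2"]))
  expect_equal(p$values["b", "2020-01", "v1"], 3)
})

test_that("malformed panel files raise specific errors", {
  specs <- tiny_specs()
  base <- data.frame(entity = "a", group = "G", month = "2020-01",
                     variable = "v1", value = 1)
  write_df <- function(df) {
    path <- tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    path
  }
  expect_error(
    read_panel(write_df(transform(base, variable = "mystery")), specs),
    "unknown variable")
  expect_error(read_panel(write_df(rbind(base, base)), specs),
               "duplicate")
  expect_error(
    read_panel(write_df(transform(base, month = "Jan-2020")), specs),
    "unparseable")
  two_groups <- rbind(base,
                      data.frame(entity = "a", group = "H",
                                 month = "2020-01", variable = "v2",
                                 value = 1))
  expect_error(read_panel(write_df(two_groups), specs),
               "more than one group")
})

test_that("validation reports missing fractions and constant columns", {
  specs <- tiny_specs()
  vals <- array(rnorm(2 * 25 * 2), c(2, 25, 2))
  panel <- tiny_panel(vals, months = month_seq("2019-01", 25),
                      specs = specs)
  rep0 <- validate_panel(panel, specs)
  expect_equal(nrow(rep0$missing_cells), 0L)
  expect_equal(rep0$missing_fraction, 0)

  panel$values[cbind(c(1, 2, 1), c(1, 5, 9), c(1, 1, 2))] <- NA
  rep3 <- validate_panel(panel, specs)
  expect_equal(nrow(rep3$missing_cells), 3L)
  expect_equal(rep3$missing_fraction, 3 / 100)
  # per-variable counts sum to the total
  expect_equal(sum(table(rep3$missing_cells$variable)), 3L)

  panel$values[, , 2] <- 7
  repc <- validate_panel(panel, specs)
  expect_true("v2" %in% repc$constant_columns$variable)
  expect_false("v1" %in% repc$constant_columns$variable)
})

test_that("score tables round-trip losslessly and reject empty input", {
  Y <- micro_Y()
  panel <- as_std_panel(Y)
  tab <- score_group(panel, "G", bod_config("optimistic", "none"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(tab, path)
  back <- read_scores(path)
  expect_identical(back$score, tab$score)
  expect_identical(back$benchmark, tab$benchmark)
  expect_equal(nrow(back), 4L)
  expect_error(write_scores(tab[0, ], path), "empty")
})
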