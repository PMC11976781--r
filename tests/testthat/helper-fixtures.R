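# shared fixtures, all built in code

# the 4-entity worked micro-example: C caps the optimistic sum at 1.25,
# D forces the pessimistic sum up to 5/3
micro_Y <- function() {
  rbind(A = c(1.0, 0.5), B = c(0.5, 1.0), C = c(0.8, 0.8),
        D = c(0.6, 0.6))
}

# a tiny two-variable spec set (default min weight 1/(2*2) = 0.25)
tiny_specs <- function(direction = c("desirable", "desirable")) {
  variable_specs(name = c("v1", "v2"),
                 dimension = c("access", "productivity"),
                 direction = direction,
                 neutral_lo = ifelse(direction == "neutral", 80, NA),
                 neutral_hi = ifelse(direction == "neutral", 90, NA))
}

# panel with explicit values: one group, `ne` entities x `nm` months x
# variables taken from a 3-d array or a matrix (entities x variables,
# constant over months)
tiny_panel <- function(values, months = NULL, group = "G",
                       specs = tiny_specs()) {
  if (is.matrix(values)) {
    nm <- if (is.null(months)) 1L else length(months)
    arr <- array(NA_real_, c(nrow(values), nm, ncol(values)))
    for (m in seq_len(nm)) arr[, m, ] <- values
    values <- arr
  }
  ne <- dim(values)[1]
  if (is.null(months)) months <- month_seq("2020-01", dim(values)[2])
  ents <- data.frame(entity = sprintf("%s%02d", group, seq_len(ne)),
                     group = group, stringsAsFactors = FALSE)
  kpi_panel(values, ents, months, specs$name)
}

# standardized panel wrapper around an already-scaled matrix (values must
# lie in (0, 1]); bypasses Eq.-(11) rescaling so LP examples keep their
# hand-computed numbers
as_std_panel <- function(values, months = NULL, group = "G",
                         specs = tiny_specs()) {
  p <- tiny_panel(values, months = months, group = group, specs = specs)
  attr(p, "oriented") <- TRUE
  attr(p, "standardized") <- TRUE
  p
}

# small, fast synthetic configuration for pipeline tests
small_synth <- function(seed = 1, missing_rate = 0, n_months = 30,
                        groups = c(B = 5, E = 4)) {
  synth_config(groups = groups, n_months = n_months,
               start_month = "2019-01", shock_month = "2020-04",
               missing_rate = missing_rate, seed = seed,
               later_waves = data.frame(month = "2020-11", scale = 0.3))
}

expect_scores_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$score, b$score, tolerance = tol)
}
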