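test_that("worked micro-example reproduces hand-verified LP optima", {
  Y <- micro_Y()
  opt <- bod_config("optimistic", "none")
  pes <- bod_config("pessimistic", "none")

  expect_equal(solve_optimistic(Y, 4, opt)$score, 0.75, tolerance = 1e-9)
  expect_equal(solve_pessimistic(Y, 3, pes)$score, 4 / 3,
               tolerance = 1e-9)

  pess_all <- vapply(1:4, function(t) solve_pessimistic(Y, t, pes)$score,
                     numeric(1))
  expect_equal(pess_all, c(1, 1, 4 / 3, 1), tolerance = 1e-9)
})

test_that("score_group flags the non-dominated entities as benchmarks", {
  panel <- as_std_panel(micro_Y())
  tab <- score_group(panel, "G", bod_config("optimistic", "none"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$benchmark, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(tab$score[4], 0.75, tolerance = 1e-9)
})

test_that("single-entity groups score 1 under both orientations", {
  Y <- matrix(c(0.4, 0.9), 1, 2)
  expect_equal(solve_optimistic(Y, 1, bod_config("optimistic",
                                                 "none"))$score, 1,
               tolerance = 1e-9)
  expect_equal(solve_pessimistic(Y, 1, bod_config("pessimistic",
                                                  "none"))$score, 1,
               tolerance = 1e-9)
})

test_that("column extreme holders sit on the respective frontiers", {
  set.seed(7)
  Y <- matrix(runif(8 * 3, 0.01, 1), 8, 3)
  opt <- bod_config("optimistic", "none")
  pes <- bod_config("pessimistic", "none")
  for (j in 1:3) {
    expect_equal(solve_optimistic(Y, which.max(Y[, j]), opt)$score, 1,
                 tolerance = 1e-8)
    expect_equal(solve_pessimistic(Y, which.min(Y[, j]), pes)$score, 1,
                 tolerance = 1e-8)
  }
  all_opt <- vapply(1:8, function(t) solve_optimistic(Y, t, opt)$score,
                    numeric(1))
  all_pes <- vapply(1:8, function(t) solve_pessimistic(Y, t, pes)$score,
                    numeric(1))
  expect_true(all(all_opt <= 1 + 1e-9) && all(all_opt > 0))
  expect_true(all(all_pes >= 1 - 1e-9))
})

test_that("multipliers satisfy the active restriction and reproduce the score", {
  set.seed(11)
  Y <- matrix(runif(6 * 3, 0.01, 1), 6, 3)
  w <- rep(1 / 6, 3)
  for (orient in c("optimistic", "pessimistic")) {
    for (restr in c("multiplier_share", "pie_share")) {
      cfg <- bod_config(orient, restr, min_weights = w)
      s <- if (orient == "optimistic") solve_optimistic(Y, 2, cfg) else
        solve_pessimistic(Y, 2, cfg)
      a <- s$multipliers
      expect_true(all(a >= -1e-9))
      expect_equal(sum(a * Y[2, ]), s$score, tolerance = 1e-8)
      if (restr == "multiplier_share") {
        expect_true(all(a - w * sum(a) >= -1e-8))
      } else {
        expect_true(all(a * Y[2, ] - w * sum(a * Y[2, ]) >= -1e-8))
      }
      lhs <- as.vector(Y %*% a)
      if (orient == "optimistic") {
        expect_true(all(lhs <= 1 + 1e-8))
      } else {
        expect_true(all(lhs >= 1 - 1e-8))
      }
    }
  }
})

test_that("production solver agrees with the vertex-enumeration oracle", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(2:4, 1)
    m <- sample(3:6, 1)
    Y <- matrix(runif(m * n, 0.01, 1), m, n)
    w <- rep(runif(1, 0.01, 1 / (2 * n)), n)
    t <- sample(m, 1)
    for (orient in c("optimistic", "pessimistic")) {
      for (restr in c("none", "multiplier_share", "pie_share")) {
        cfg <- bod_config(orient, restr, min_weights = w)
        s <- if (orient == "optimistic")
          solve_optimistic(Y, t, cfg)$score
        else solve_pessimistic(Y, t, cfg)$score
        expect_equal(s, oracle_score(Y, t, cfg)$score, tolerance = 1e-6)
      }
    }
  }
})

test_that("third-party LP solver confirms unrestricted optimistic optima", {
  # pracma::linprog is an unrelated simplex implementation; small
  # instances only
  set.seed(77)
  for (rep in 1:10) {
    m <- sample(3:6, 1)
    Y <- matrix(runif(m * 2, 0.01, 1), m, 2)
    t <- sample(m, 1)
    ref <- pracma::linprog(cc = Y[t, ], A = Y, b = rep(1, m),
                           maximize = TRUE, maxiter = 200)
    mine <- solve_optimistic(Y, t, bod_config("optimistic", "none"))
    expect_equal(mine$score, ref$fval, tolerance = 1e-7)
  }
})

test_that("oracle refuses oversized instances", {
  expect_error(oracle_score(matrix(0.5, 7, 2), 1,
                            bod_config("optimistic", "none")),
               "too large")
  expect_error(oracle_score(matrix(0.5, 3, 5), 1,
                            bod_config("optimistic", "none")),
               "too large")
})

test_that("optimistic scores rise weakly with the target's own data", {
  set.seed(5)
  Y <- matrix(runif(5 * 3, 0.2, 0.9), 5, 3)
  cfg <- bod_config("optimistic", "multiplier_share",
                    min_weights = rep(0.1, 3))
  base <- solve_optimistic(Y, 2, cfg)$score
  # reference constraints fixed: only the target's objective row improves
  Y2 <- Y
  Y2[2, 1] <- Y2[2, 1] + 0.05
  res <- bodbench:::bod_score_group_cpp(Y, Y2[2, , drop = FALSE],
                                        rep(0.1, 3), 0L, 1L)
  expect_gte(res$score[1] + 1e-10, base)
})

test_that("duplicated months yield identical scores by symmetry", {
  set.seed(9)
  vals <- matrix(runif(8, 10, 90), 4, 2)
  panel <- tiny_panel(vals, months = c("2020-01", "2020-02"))
  std <- standardize_panel(panel, tiny_specs())
  tab <- score_panel(std, bod_config("optimistic", "multiplier_share"))
  s1 <- tab$score[tab$month == "2020-01"]
  s2 <- tab$score[tab$month == "2020-02"]
  expect_equal(s1[order(tab$entity[tab$month == "2020-01"])],
               s2[order(tab$entity[tab$month == "2020-02"])],
               tolerance = 1e-12)
})

test_that("identical inputs give bit-identical score tables", {
  set.seed(21)
  Y <- matrix(runif(30, 0.01, 1), 10, 3)
  specs3 <- variable_specs(c("v1", "v2", "v3"), "access", "desirable")
  panel <- as_std_panel(array(Y, c(10, 1, 3)), specs = specs3)
  cfg <- bod_config("pessimistic", "pie_share")
  t1 <- score_group(panel, "G", cfg)
  t2 <- score_group(panel, "G", cfg)
  expect_identical(t1$score, t2$score)
  expect_identical(attr(t1, "multipliers"), attr(t2, "multipliers"))
})

test_that("windowed reference sets relax the meta-frontier", {
  set.seed(27)
  vals <- array(runif(4 * 6 * 2, 10, 90), c(4, 6, 2))
  panel <- tiny_panel(vals, months = month_seq("2020-01", 6))
  std <- standardize_panel(panel, tiny_specs())
  cfg <- bod_config("optimistic", "multiplier_share")
  meta <- score_group(std, "G", cfg)
  full_window <- score_group(std, "G", cfg, window = 6)
  expect_equal(full_window$score, meta$score, tolerance = 1e-12)

  monthly <- score_group(std, "G", cfg, window = 1)
  # fewer reference constraints can only raise an optimistic score
  expect_true(all(monthly$score >= meta$score - 1e-9))
  # each per-month frontier contains at least one benchmark
  expect_true(all(tapply(monthly$benchmark, monthly$month, any)))
})

test_that("pessimistic rescaling maps the oracle scores to {0,0,1,0}", {
  panel <- as_std_panel(micro_Y())
  tab <- score_group(panel, "G", bod_config("pessimistic", "none"))
  res <- rescale_pessimistic(tab)
  expect_equal(res$rescaled_score, c(0, 0, 1, 0), tolerance = 1e-9)
  expect_equal(min(res$rescaled_score), 0)
  expect_equal(max(res$rescaled_score), 1)

  flat <- tab
  flat$score <- rep(1, 4)
  expect_error(rescale_pessimistic(flat), "degenerate")
  expect_error(rescale_pessimistic(score_group(panel, "G",
                                               bod_config("optimistic",
                                                           "none"))),
               "pessimistic")
})

test_that("weight sums above one are rejected before the solver runs", {
  expect_error(bod_config("optimistic", "multiplier_share",
                          min_weights = c(0.6, 0.6)),
               "exceeds 1")
})

test_that("scoring refuses panels with missing cells", {
  vals <- matrix(c(1, 2, NA, 4), 2, 2)
  panel <- as_std_panel(vals)
  expect_error(score_group(panel, "G", bod_config("optimistic", "none")),
               "missing")
})
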