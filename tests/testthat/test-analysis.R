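mk_table <- function(entity, month, score, group = "G") {
  data.frame(entity = entity, group = group, month = month,
             orientation = "optimistic", restriction = "multiplier_share",
             score = score, benchmark = score >= 1 - 1e-6,
             rescaled_score = NA_real_, stringsAsFactors = FALSE)
}

test_that("monthly rankings order descending with shared rank 1 on ties", {
  tab <- mk_table(c("a", "b", "c"), "2020-01", c(0.9, 1.0, 0.8))
  r <- monthly_rankings(tab)
  expect_equal(r$rank[match(c("a", "b", "c"), r$entity)], c(2L, 1L, 3L))
  expect_equal(r$entity[r$rank1], "b")

  tie <- mk_table(c("a", "b", "c"), "2020-01", c(1.0, 1.0, 0.8))
  rt <- monthly_rankings(tie)
  expect_setequal(rt$entity[rt$rank1], c("a", "b"))

  solo <- mk_table("a", c("2020-01", "2020-02"), c(0.5, 0.6))
  rs <- monthly_rankings(solo)
  expect_true(all(rs$rank == 1L) && all(rs$rank1))

  dup <- rbind(tab, tab[1, ])
  expect_error(monthly_rankings(dup), "duplicate")
})

test_that("top entities are picked by window mean with lexicographic ties", {
  tab <- mk_table(rep(c("a", "b", "c"), each = 2),
                  rep(c("2020-01", "2020-02"), 3),
                  c(0.9, 0.9, 0.95, 0.95, 0.8, 0.8))
  top <- top_entities(tab, c("2020-01", "2020-02"), 2)
  expect_equal(top$entity, c("b", "a"))
  all3 <- top_entities(tab, c("2020-01", "2020-02"), 3)
  expect_equal(nrow(all3), 3L)
  expect_error(top_entities(tab, c("2020-01", "2020-02"), 4), "exceeds")
  expect_error(top_entities(tab, c("2021-01", "2021-02"), 1), "empty")

  tie <- mk_table(rep(c("z", "y"), each = 1), "2020-01", c(0.5, 0.5))
  expect_equal(top_entities(tie, c("2020-01", "2020-01"), 1)$entity, "y")
})

test_that("benchmark frequency counts intersecting months", {
  months <- month_seq("2020-01", 4)
  tab <- mk_table(rep(c("a", "b"), each = 4), rep(months, 2),
                  c(1, 0.5, 1, 0.5, 0.9, 0.9, 0.8, 0.9))
  r <- monthly_rankings(tab)
  win <- c("2020-01", "2020-04")
  expect_equal(benchmark_frequency(r, c("a", "b"), win), 1)
  expect_equal(benchmark_frequency(r, "zzz", win), 0)
  expect_equal(benchmark_frequency(r, "b", win), 0.5)  # months 2 and 4
})

test_that("frequency table is nondecreasing in k", {
  set.seed(41)
  months <- month_seq("2020-01", 12)
  tab <- do.call(rbind, lapply(sprintf("e%02d", 1:6), function(e)
    mk_table(e, months, runif(12, 0.5, 1))))
  ranks <- monthly_rankings(tab)
  ft <- frequency_table(tab, ranks, c(months[1], months[12]), k_max = 6)
  expect_true(all(diff(ft$frequency[order(ft$k)]) >= -1e-12))
  expect_equal(ft$frequency[ft$k == 6], 1)  # exhaustive set
})

test_that("pre/post summary splits inclusively and credits ties", {
  months <- month_seq("2020-01", 6)
  tab <- rbind(mk_table("a", months, rep(0.9, 6)),
               mk_table("b", months, rep(0.8, 6)))
  ranks <- monthly_rankings(tab)
  pp <- prepost_summary(tab, ranks, "2020-03", k = 1)
  pe <- pp$per_entity
  expect_equal(pe$pre_avg, pe$post_avg)            # constant scores
  expect_equal(pe$pre_share[pe$entity == "a"], 1)  # rank-1 all pre months
  expect_equal(pe$post_share[pe$entity == "b"], 0)
  expect_equal(pp$per_group$pre_freq, 1)
  expect_error(prepost_summary(tab, ranks, "2025-01", 1), "inside")
  expect_error(prepost_summary(tab, ranks, "2020-06", 1), "inside")

  # without ties, rank-1 shares sum to one in each window
  set.seed(42)
  tabr <- do.call(rbind, lapply(c("a", "b", "c"), function(e)
    mk_table(e, months, runif(6, 0.3, 0.99))))
  ppr <- prepost_summary(tabr, monthly_rankings(tabr), "2020-03", k = 1)
  expect_equal(sum(ppr$per_entity$pre_share), 1)
  expect_equal(sum(ppr$per_entity$post_share), 1)
})

test_that("gap series have exact slopes and shift invariance", {
  months <- month_seq("2020-01", 3)
  tab <- rbind(mk_table("top", months, c(0.6, 0.7, 0.8)),
               mk_table("bot", months, c(0.5, 0.5, 0.5)))
  gs <- gap_series(tab, "top", "bot")
  expect_equal(gs$series$gap, c(0.1, 0.2, 0.3))
  expect_equal(gs$slope, 0.1, tolerance = 1e-12)

  shifted <- tab
  shifted$score <- shifted$score + 0.05
  gs2 <- gap_series(shifted, "top", "bot")
  expect_equal(gs2$series$gap, gs$series$gap, tolerance = 1e-12)
  expect_equal(gs2$slope, gs$slope, tolerance = 1e-12)

  same <- rbind(mk_table("x", months, c(0.4, 0.5, 0.6)),
                mk_table("y", months, c(0.4, 0.5, 0.6)))
  gs3 <- gap_series(same, "x", "y", split = "2020-02")
  expect_equal(gs3$series$gap, rep(0, 3))
  expect_equal(gs3$slope, 0, tolerance = 1e-12)
  expect_equal(gs3$pre_avg, 0)
  expect_equal(gs3$post_avg, 0)

  expect_error(gap_series(tab, "top", "top"), "overlap")
  expect_error(gap_series(tab, character(0), "bot"), "nonempty")
})

test_that("evolution summary produces ordered five-number lines", {
  months <- month_seq("2020-01", 2)
  solo <- mk_table("a", months, c(0.7, 0.9))
  es <- evolution_summary(solo)
  expect_equal(es$min, es$mean)
  expect_equal(es$mean, es$max)

  pair <- rbind(mk_table("a", "2020-01", 0), mk_table("b", "2020-01", 1))
  ep <- evolution_summary(pair)
  expect_equal(ep$mean, 0.5)
  expect_equal(ep$min, 0)
  expect_equal(ep$max, 1)

  five <- do.call(rbind, lapply(sprintf("e%d", 1:5), function(e)
    mk_table(e, "2020-01", 0.77)))
  ef <- evolution_summary(five)
  expect_true(all(ef[, c("min", "q1", "mean", "q3", "max")] == 0.77))

  set.seed(43)
  rnd <- do.call(rbind, lapply(sprintf("e%d", 1:9), function(e)
    mk_table(e, months, runif(2))))
  er <- evolution_summary(rnd)
  expect_true(all(er$min <= er$q1 & er$q1 <= er$q3 & er$q3 <= er$max))
})
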