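score_col <- function(table, use_rescaled = FALSE) {
  if (use_rescaled) {
    if (all(is.na(table$rescaled_score)))
      stop("table has no rescaled scores; run rescale_pessimistic() first",
           call. = FALSE)
    table$rescaled_score
  } else table$score
}

#' Monthly rankings and rank-1 benchmark sets
#'
#' Within each (group, month), entities are ranked by descending score.
#' Entities whose scores lie within `tolerance` of the month's maximum
#' share rank 1 and together form the monthly benchmark set.
#'
#' @param table a score table (typically expected optimistic scores).
#' @param tolerance tie tolerance for sharing rank 1.
#' @param use_rescaled rank on `rescaled_score` instead of `score`.
#' @return `data.frame` with columns `entity`, `group`, `month`, `score`,
#'   `rank`, `rank1`.
#' @export
monthly_rankings <- function(table, tolerance = 1e-6,
                             use_rescaled = FALSE) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (anyDuplicated(table[c("group", "month", "entity")]))
    stop("duplicate entity within a month", call. = FALSE)
  s <- score_col(table, use_rescaled)
  key <- paste(table$group, table$month)
  rk <- stats::ave(-s, key, FUN = function(z) rank(z, ties.method = "min"))
  mx <- stats::ave(s, key, FUN = max)
  out <- data.frame(entity = table$entity, group = table$group,
                    month = table$month, score = s, rank = as.integer(rk),
                    rank1 = s >= mx - tolerance, stringsAsFactors = FALSE)
  out$rank[out$rank1] <- 1L
  out[order(out$group, out$month, out$rank, out$entity), ]
}

in_window <- function(month, window) {
  month >= window[1] & month <= window[2]
}

#' Top-k entities of each group by mean score over a window
#'
#' Ties are broken deterministically by entity id (lexicographic).
#'
#' @param table a score table.
#' @param window month pair `c(first, last)`, inclusive.
#' @param k number of entities per group.
#' @param use_rescaled rank on `rescaled_score`.
#' @return `data.frame` with columns `group`, `entity`, `mean_score`, `k`
#'   rows per group.
#' @export
top_entities <- function(table, window, k, use_rescaled = FALSE) {
  window <- parse_month(window)
  stopifnot(length(window) == 2L)
  sub <- table[in_window(table$month, window), , drop = FALSE]
  if (!nrow(sub)) stop("empty window ", window[1], "..", window[2],
                       call. = FALSE)
  s <- score_col(sub, use_rescaled)
  agg <- stats::aggregate(list(mean_score = s),
                          by = list(group = sub$group, entity = sub$entity),
                          FUN = mean)
  parts <- lapply(split(agg, agg$group), function(d) {
    if (k > nrow(d))
      stop("k exceeds number of entities in group ", d$group[1],
           call. = FALSE)
    d <- d[order(-d$mean_score, d$entity), , drop = FALSE]
    d[seq_len(k), , drop = FALSE]
  })
  out <- do.call(rbind.data.frame, c(parts, make.row.names = FALSE))
  out[order(out$group, -out$mean_score, out$entity), , drop = FALSE]
}

#' Benchmark frequency of an entity set
#'
#' Fraction of window months in which the monthly rank-1 (benchmark) set
#' intersects the given entity set.  Expects rankings of a single group.
#'
#' @param ranks a [monthly_rankings()] frame for one group.
#' @param entities character vector of entity ids.
#' @param window month pair `c(first, last)`, inclusive.
#' @return a fraction in `[0, 1]`.
#' @export
benchmark_frequency <- function(ranks, entities, window) {
  window <- parse_month(window)
  if (length(unique(ranks$group)) != 1L)
    stop("benchmark_frequency expects rankings of a single group",
         call. = FALSE)
  sub <- ranks[in_window(ranks$month, window), , drop = FALSE]
  months <- unique(sub$month)
  if (!length(months)) stop("empty window", call. = FALSE)
  hit <- vapply(months, function(m) {
    any(sub$entity[sub$month == m & sub$rank1] %in% entities)
  }, logical(1))
  mean(hit)
}

#' Benchmark-frequency table over k = 1..k_max
#'
#' For each group, the top-k entities (by mean score over the window) and
#' the fraction of window months whose benchmark is among them -- the
#' sensitivity table of benchmark consistency.  Nondecreasing in k by
#' construction.
#'
#' @param table a score table.
#' @param ranks matching [monthly_rankings()].
#' @param window month pair, inclusive.
#' @param k_max largest top-set size (capped at each group's entity
#'   count).
#' @return `data.frame` with columns `k`, `group`, `frequency`.
#' @export
frequency_table <- function(table, ranks, window, k_max = 5) {
  groups <- sort(unique(table$group))
  out <- expand.grid(k = seq_len(k_max), group = groups,
                     stringsAsFactors = FALSE)
  sizes <- vapply(groups, function(g)
    length(unique(table$entity[table$group == g])), integer(1))
  out <- out[out$k <= sizes[out$group], , drop = FALSE]
  rownames(out) <- NULL
  out$frequency <- mapply(function(k, g) {
    tops <- top_entities(table[table$group == g, , drop = FALSE],
                         window, k)
    benchmark_frequency(ranks[ranks$group == g, , drop = FALSE],
                        tops$entity, window)
  }, out$k, out$group)
  out
}

#' Pre/post-shock performance summary
#'
#' Splits the horizon at `split` (the pre window runs from the first month
#' through `split` inclusive) and reports, per entity, the average score
#' and the share of months spent as rank-1 benchmark in each window; per
#' group, the top-k entity set of the pre window and its combined
#' benchmark frequency in both windows.  Ties credit every tied entity, so
#' shares can sum to more than 1 in months with shared rank 1.
#'
#' @param table a score table.
#' @param ranks matching [monthly_rankings()].
#' @param split last month of the pre window (`"YYYY-MM"`), strictly
#'   inside the horizon.
#' @param k top-set size per group.
#' @return a list with `per_entity` and `per_group` frames.
#' @export
prepost_summary <- function(table, ranks, split, k = 2) {
  split <- parse_month(split)
  months <- sort(unique(table$month))
  if (split < months[1] || split >= months[length(months)])
    stop("split must lie strictly inside the horizon", call. = FALSE)
  pre <- c(months[1], split)
  post <- c(months[which(months == split) + 1L], months[length(months)])

  win_stats <- function(win) {
    sub <- table[in_window(table$month, win), , drop = FALSE]
    rsub <- ranks[in_window(ranks$month, win), , drop = FALSE]
    nm <- length(unique(sub$month))
    avg <- stats::aggregate(list(avg = sub$score),
                            by = list(entity = sub$entity,
                                      group = sub$group), FUN = mean)
    b1 <- stats::aggregate(list(share = rsub$rank1),
                           by = list(entity = rsub$entity,
                                     group = rsub$group),
                           FUN = function(z) sum(z) / nm)
    merge(avg, b1, by = c("entity", "group"))
  }
  a <- win_stats(pre); b <- win_stats(post)
  names(a)[3:4] <- c("pre_avg", "pre_share")
  names(b)[3:4] <- c("post_avg", "post_share")
  per_entity <- merge(a, b, by = c("entity", "group"))
  per_entity <- per_entity[order(per_entity$group, -per_entity$pre_avg), ]
  rownames(per_entity) <- NULL

  groups <- sort(unique(table$group))
  per_group <- do.call(rbind.data.frame, lapply(groups, function(g) {
    tg <- table[table$group == g, , drop = FALSE]
    rg <- ranks[ranks$group == g, , drop = FALSE]
    tops <- top_entities(tg, pre, k)$entity
    data.frame(group = g, top_entities = paste(tops, collapse = ","),
               pre_freq = benchmark_frequency(rg, tops, pre),
               post_freq = benchmark_frequency(rg, tops, post),
               stringsAsFactors = FALSE)
  }))
  list(per_entity = per_entity, per_group = per_group,
       pre_window = pre, post_window = post)
}

#' Monthly gap between a top set and a bottom set
#'
#' For each month, the mean score of the designated top set minus the mean
#' score of the designated bottom set; optionally averaged over pre/post
#' windows, with the ordinary-least-squares slope of the gap on the
#' 0-based month index.
#'
#' @param table a score table of a single group.
#' @param top,bottom disjoint nonempty entity sets.
#' @param split optional last month of the pre window.
#' @param use_rescaled compute the gap on `rescaled_score`.
#' @return a list with `series` (`data.frame` month, gap), `slope` (per
#'   month), and, when `split` is given, `pre_avg` and `post_avg`.
#' @export
gap_series <- function(table, top, bottom, split = NULL,
                       use_rescaled = FALSE) {
  if (!length(top) || !length(bottom))
    stop("top and bottom sets must be nonempty", call. = FALSE)
  if (length(intersect(top, bottom)))
    stop("top and bottom sets overlap", call. = FALSE)
  s <- score_col(table, use_rescaled)
  months <- sort(unique(table$month))
  gap <- vapply(months, function(m) {
    sel <- table$month == m
    mean(s[sel & table$entity %in% top]) -
      mean(s[sel & table$entity %in% bottom])
  }, numeric(1))
  series <- data.frame(month = months, gap = as.numeric(gap))
  idx <- seq_along(months) - 1
  slope <- unname(coef(lm(gap ~ idx))[2])
  out <- list(series = series, slope = slope)
  if (!is.null(split)) {
    split <- parse_month(split)
    out$pre_avg <- mean(series$gap[series$month <= split])
    out$post_avg <- mean(series$gap[series$month > split])
  }
  out
}

#' Five-line evolution summary per month
#'
#' The per-month minimum, first quartile, mean, third quartile, and
#' maximum of scores within each group -- the five lines of a score
#' evolution chart.  Quartiles use linear interpolation (type 7).
#'
#' @param table a score table.
#' @param use_rescaled summarize `rescaled_score`.
#' @return `data.frame` with columns `group`, `month`, `min`, `q1`,
#'   `mean`, `q3`, `max`.
#' @export
evolution_summary <- function(table, use_rescaled = FALSE) {
  stopifnot(nrow(table) > 0)
  s <- score_col(table, use_rescaled)
  agg <- stats::aggregate(
    list(value = s),
    by = list(group = table$group, month = table$month),
    FUN = function(z) c(min = min(z), q1 = quantile(z, 0.25, names = FALSE),
                        mean = mean(z),
                        q3 = quantile(z, 0.75, names = FALSE), max = max(z)))
  out <- cbind(agg[c("group", "month")], as.data.frame(agg$value))
  names(out) <- c("group", "month", "min", "q1", "mean", "q3", "max")
  out[order(out$group, out$month), ]
}
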