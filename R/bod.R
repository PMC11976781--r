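BOD_ORIENTATIONS <- c("optimistic", "pessimistic")
BOD_RESTRICTIONS <- c("none", "multiplier_share", "pie_share")

#' BoD model configuration
#'
#' @param orientation `"optimistic"` (each entity gets its most favourable
#'   weights; CI in `(0, 1]`, 1 = benchmark) or `"pessimistic"` (least
#'   favourable weights; CI >= 1, 1 = on the worst-practice frontier).
#' @param restriction `"none"`, `"multiplier_share"` (each multiplier must
#'   carry at least `w_j` of the multiplier sum) or `"pie_share"` (each
#'   variable must contribute at least `w_j` of the aggregate score).
#' @param min_weights vector of minimum weights `w_j`, one per variable;
#'   their sum must not exceed 1.  Ignored when `restriction = "none"`.
#' @param benchmark_tolerance how close to 1 a score must be to flag the
#'   entity-month as a benchmark (optimistic) or anti-benchmark
#'   (pessimistic).
#' @param solver_tolerance feasibility tolerance used in invariant checks.
#' @return a list of class `"bod_config"`.
#' @export
bod_config <- function(orientation = c("optimistic", "pessimistic"),
                       restriction = c("multiplier_share", "none",
                                       "pie_share"),
                       min_weights = NULL,
                       benchmark_tolerance = 1e-6,
                       solver_tolerance = 1e-7) {
  orientation <- match.arg(orientation)
  restriction <- match.arg(restriction)
  stopifnot(benchmark_tolerance > 0, solver_tolerance > 0)
  if (restriction != "none" && !is.null(min_weights)) {
    stopifnot(all(min_weights >= 0))
    if (sum(min_weights) > 1 + 1e-12)
      stop("sum of min_weights exceeds 1; restricted model infeasible",
           call. = FALSE)
  }
  structure(list(orientation = orientation, restriction = restriction,
                 min_weights = min_weights,
                 benchmark_tolerance = benchmark_tolerance,
                 solver_tolerance = solver_tolerance),
            class = "bod_config")
}

cfg_weights <- function(cfg, n) {
  if (cfg$restriction == "none") return(rep(0, n))
  w <- cfg$min_weights
  if (is.null(w)) w <- rep(default_min_weight(n), n)
  if (length(w) == 1L) w <- rep(w, n)
  if (length(w) != n)
    stop("min_weights length ", length(w), " does not match ", n,
         " variables", call. = FALSE)
  w
}

solve_bod_matrix <- function(Y, targets, cfg) {
  stopifnot(is.matrix(Y), all(is.finite(Y)), all(Y > 0))
  w <- cfg_weights(cfg, ncol(Y))
  # exact pruning of the reference set: a row weakly dominated by another
  # contributes an implied constraint (alpha >= 0), so only the Pareto
  # frontier of the relevant orientation is kept
  keep <- pareto_filter_cpp(Y, if (cfg$orientation == "optimistic")
    1L else -1L)
  res <- bod_score_group_cpp(Y[keep, , drop = FALSE],
                             Y[targets, , drop = FALSE], w,
                             match(cfg$orientation, BOD_ORIENTATIONS) - 1L,
                             match(cfg$restriction, BOD_RESTRICTIONS) - 1L)
  if (any(res$status == 1L))
    stop("BoD program infeasible under restriction '", cfg$restriction,
         "' (check that the minimum weights sum to at most 1)",
         call. = FALSE)
  if (any(res$status != 0L))
    stop("LP solver failed (status ",
         paste(unique(res$status[res$status != 0]), collapse = ","), ")",
         call. = FALSE)
  res
}

#' Solve one BoD program
#'
#' Scores a single entity-month (a row of the group matrix) against the
#' pooled all-months reference set of its peer group.  `solve_optimistic()`
#' maximizes the weighted sum of the target's standardized values subject
#' to every entity-month scoring at most 1 under the same weights;
#' `solve_pessimistic()` minimizes it subject to every entity-month scoring
#' at least 1.  The configured weight restriction is enforced in its exact
#' linearized form.
#'
#' @param Y numeric matrix of standardized values (rows entity-months,
#'   columns variables; all entries positive, see [standardize_minmax()]).
#' @param target row index of the entity-month to score.
#' @param cfg a [bod_config()]; the orientation must match the function
#'   used.
#' @return a list with `score`, `multipliers` (the optimal `alpha`),
#'   and `benchmark` (optimistic: score within tolerance of 1) or
#'   `anti_benchmark` (pessimistic).
#' @examples
#' Y <- rbind(A = c(1, 0.5), B = c(0.5, 1), C = c(0.8, 0.8),
#'            D = c(0.6, 0.6))
#' cfg <- bod_config("optimistic", "none")
#' solve_optimistic(Y, 4, cfg)$score  # 0.75
#' @export
solve_optimistic <- function(Y, target, cfg) {
  if (cfg$orientation != "optimistic")
    stop("cfg orientation is not optimistic", call. = FALSE)
  res <- solve_bod_matrix(Y, target, cfg)
  list(score = res$score[1], multipliers = res$alpha[1, ],
       benchmark = res$score[1] >= 1 - cfg$benchmark_tolerance)
}

#' @rdname solve_optimistic
#' @export
solve_pessimistic <- function(Y, target, cfg) {
  if (cfg$orientation != "pessimistic")
    stop("cfg orientation is not pessimistic", call. = FALSE)
  res <- solve_bod_matrix(Y, target, cfg)
  list(score = res$score[1], multipliers = res$alpha[1, ],
       anti_benchmark = res$score[1] <= 1 + cfg$benchmark_tolerance)
}

#' Score every entity-month of one peer group
#'
#' Each entity-month is scored against the pooled all-months reference set
#' of the group (meta-frontier), so scores are comparable across time.
#' Deterministic given the panel and configuration.
#'
#' @param panel a standardized [kpi_panel()] (see [standardize_minmax()]).
#' @param group peer-group label.
#' @param cfg a [bod_config()].
#' @param window optional window length in months.  The default (`NULL`)
#'   pools the whole horizon into one reference set (meta-frontier).  An
#'   integer `w` partitions the horizon into consecutive blocks of `w`
#'   months and scores each entity-month against its own block only —
#'   the windowed analysis used to check for frontier shifts.
#' @return a score table: `data.frame` with columns `entity`, `group`,
#'   `month`, `orientation`, `restriction`, `score`, `benchmark`,
#'   `rescaled_score` (`NA` until [rescale_pessimistic()] is applied), and
#'   a `"multipliers"` attribute (matrix, one row per record).  For the
#'   optimistic orientation `benchmark` flags scores at 1; for the
#'   pessimistic orientation it flags the worst-practice frontier
#'   (anti-benchmarks).
#' @export
score_group <- function(panel, group, cfg, window = NULL) {
  Y <- group_matrix(panel, group)
  if (anyNA(Y))
    stop("group ", group, " contains missing cells; impute first",
         call. = FALSE)
  if (is.null(window)) {
    res <- solve_bod_matrix(Y, seq_len(nrow(Y)), cfg)
    score <- res$score
    alpha <- res$alpha
  } else {
    stopifnot(window >= 1)
    block <- (month_index(attr(Y, "month"), panel$months[1])) %/%
      as.integer(window)
    score <- numeric(nrow(Y))
    alpha <- matrix(NA_real_, nrow(Y), ncol(Y))
    for (bl in unique(block)) {
      rows <- which(block == bl)
      res <- solve_bod_matrix(Y[rows, , drop = FALSE],
                              seq_along(rows), cfg)
      score[rows] <- res$score
      alpha[rows, ] <- res$alpha
    }
  }
  near1 <- if (cfg$orientation == "optimistic")
    score >= 1 - cfg$benchmark_tolerance
  else score <= 1 + cfg$benchmark_tolerance
  out <- data.frame(
    entity = attr(Y, "entity"), group = group, month = attr(Y, "month"),
    orientation = cfg$orientation, restriction = cfg$restriction,
    score = score, benchmark = near1, rescaled_score = NA_real_,
    stringsAsFactors = FALSE
  )
  attr(out, "multipliers") <- alpha
  class(out) <- c("bod_scores", "data.frame")
  out
}

#' @rdname score_group
#' @param groups labels to score; default all groups in the panel.
#' @export
score_panel <- function(panel, cfg, groups = NULL, window = NULL) {
  if (is.null(groups)) groups <- unique(panel$entities$group)
  parts <- lapply(groups, function(g) score_group(panel, g, cfg,
                                                  window = window))
  out <- do.call(rbind.data.frame, c(parts, make.row.names = FALSE))
  attr(out, "multipliers") <- do.call(rbind, lapply(parts,
                                                    attr, "multipliers"))
  class(out) <- c("bod_scores", "data.frame")
  out
}

#' Rescale pessimistic scores to the 0-1 range
#'
#' Raw pessimistic CIs live on a `>= 1` scale measuring distance from the
#' worst-practice frontier and are not comparable with optimistic scores.
#' The linear min-max rescaling `(CI - min) / (max - min)` is applied
#' within each peer group and orientation, so 0 marks the lowest observed
#' performance and 1 the highest.
#'
#' @param table a pessimistic score table from [score_group()] /
#'   [score_panel()].
#' @return the table with `rescaled_score` filled in.
#' @export
rescale_pessimistic <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (!all(table$orientation == "pessimistic"))
    stop("rescaling applies to pessimistic score tables only",
         call. = FALSE)
  for (g in unique(table$group)) {
    sel <- table$group == g
    s <- table$score[sel]
    if (max(s) == min(s))
      stop("all pessimistic scores equal in group ", g,
           "; rescaling degenerate", call. = FALSE)
    table$rescaled_score[sel] <- (s - min(s)) / (max(s) - min(s))
  }
  table
}

#' Write or read a score table as CSV
#'
#' Round-trips losslessly at full double precision (values serialized with
#' 17 significant digits).
#'
#' @param table a score table ([score_group()]).
#' @param path CSV path.
#' @export
write_scores <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  df <- as.data.frame(table)
  for (col in c("score", "rescaled_score"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  df$rescaled_score[df$rescaled_score == "NA"] <- ""
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(entity = "character", month = "character",
                                group = "character", score = "numeric",
                                rescaled_score = "numeric",
                                benchmark = "logical"))
  class(df) <- c("bod_scores", "data.frame")
  df
}
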