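#' Brute-force BoD oracle by vertex enumeration
#'
#' Independent check of the production simplex solver: assembles the full
#' constraint system of the requested BoD program (entity rows, weight
#' restriction rows, and nonnegativity), enumerates every square subsystem
#' of size equal to the number of variables, solves it, keeps the feasible
#' vertices, and returns the best objective among them.  Valid because the
#' optimum of each BoD program is attained at a vertex: the optimistic
#' feasible region is a bounded polytope, and the pessimistic region is
#' pointed with a nonnegative objective over its recession cone.
#'
#' Intended for small instances only (at most 4 variables and 6
#' entity-months); larger instances raise an error rather than enumerate
#' millions of subsystems.
#'
#' @inheritParams solve_optimistic
#' @param tol feasibility tolerance for vertex screening.
#' @return a list with `score` and `multipliers` (an optimal vertex).
#' @examples
#' Y <- rbind(c(1, 0.5), c(0.5, 1), c(0.8, 0.8), c(0.6, 0.6))
#' oracle_score(Y, 3, bod_config("pessimistic", "none"))$score  # 4/3
#' @export
oracle_score <- function(Y, target, cfg, tol = 1e-9) {
  stopifnot(is.matrix(Y))
  n <- ncol(Y); m <- nrow(Y)
  if (n > 4L || m > 6L)
    stop("oracle instance too large (limit: 4 variables, 6 entity-months)",
         call. = FALSE)
  w <- cfg_weights(cfg, n)
  optimistic <- cfg$orientation == "optimistic"

  # rows: A %*% alpha (dir) b, dir +1 means >=, -1 means <=
  A <- Y
  b <- rep(1, m)
  dir <- rep(if (optimistic) -1 else 1, m)
  if (cfg$restriction == "multiplier_share") {
    G <- diag(n) - matrix(w, n, n)          # alpha_j >= w_j * sum(alpha)
    A <- rbind(A, G); b <- c(b, rep(0, n)); dir <- c(dir, rep(1, n))
  } else if (cfg$restriction == "pie_share") {
    yt <- Y[target, ]
    G <- diag(yt, n) - outer(w, yt)         # a_j y_tj >= w_j sum(a_i y_ti)
    A <- rbind(A, G); b <- c(b, rep(0, n)); dir <- c(dir, rep(1, n))
  }
  A <- rbind(A, diag(n)); b <- c(b, rep(0, n)); dir <- c(dir, rep(1, n))

  cc <- Y[target, ]
  best <- if (optimistic) -Inf else Inf
  bestx <- NULL
  for (idx in combn(nrow(A), n, simplify = FALSE)) {
    M <- A[idx, , drop = FALSE]
    x <- tryCatch(solve(M, b[idx]), error = function(e) NULL)
    if (is.null(x)) next
    lhs <- as.vector(A %*% x)
    if (!all(ifelse(dir > 0, lhs >= b - tol, lhs <= b + tol))) next
    obj <- sum(cc * x)
    if (if (optimistic) obj > best else obj < best) {
      best <- obj; bestx <- x
    }
  }
  if (is.null(bestx))
    stop("oracle found no feasible vertex (infeasible program)",
         call. = FALSE)
  list(score = best, multipliers = bestx)
}
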