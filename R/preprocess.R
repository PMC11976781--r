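#' Deviation from a neutral band
#'
#' A neutral KPI (inpatient bed occupancy) is best anywhere inside its band
#' -- between 80 and 90 percent by default -- and degrades linearly outside
#' it.  The deviation is 0 inside the band, `lo - value` below it and
#' `value - hi` above it; downstream the deviation is treated as an
#' undesirable quantity.
#'
#' @param value numeric vector (percent scale); `NA` passes through.
#' @param band numeric pair `c(lo, hi)` with `lo < hi`.
#' @return nonnegative deviations, same length as `value`.
#' @examples
#' neutral_deviation(c(70, 85, 95), c(80, 90))  # 10, 0, 5
#' @export
neutral_deviation <- function(value, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  pmax(band[1] - value, value - band[2], 0)
}

#' Orient all variables so that larger means better
#'
#' Desirable variables pass through unchanged; undesirable variables are
#' negated (order reversal, algebraically equivalent to the reflected
#' min-max formula applied later); neutral variables are replaced by minus
#' their band deviation, so the band maps to the maximum of the transform.
#' Missing cells are preserved.
#'
#' @param panel a [kpi_panel()] of raw values.
#' @param specs a [variable_specs()] frame covering the panel's variables.
#' @return a [kpi_panel()] of oriented values, flagged with
#'   `attr(, "oriented")`.
#' @export
align_direction <- function(panel, specs) {
  stopifnot(inherits(panel, "kpi_panel"))
  validate_specs(specs)
  if (!identical(panel$variables, specs$name))
    stop("panel variables do not match specs (name and order)",
         call. = FALSE)
  vals <- panel$values
  for (v in seq_len(nrow(specs))) {
    vals[, , v] <- switch(specs$direction[v],
      desirable = vals[, , v],
      undesirable = -vals[, , v],
      neutral = -neutral_deviation(vals[, , v],
                                   c(specs$neutral_lo[v],
                                     specs$neutral_hi[v])))
  }
  out <- kpi_panel(vals, panel$entities, panel$months, panel$variables)
  attr(out, "oriented") <- TRUE
  out
}

#' Min-max standardization to the ascending (0.01, 1] scale
#'
#' Maps each oriented value by `0.99 * (y - min) / (max - min) + 0.01`,
#' where min and max are the observed extremes of the variable within the
#' standardization scope: per peer group over all months (the default,
#' matching group-wise frontiers) or pooled over all entities.  The lower
#' bound 0.01 is deliberately nonzero so the pie-share weight restriction
#' stays well defined.  Missing cells are preserved and the bounds used are
#' recorded for reuse by the imputer.
#'
#' @param panel an oriented [kpi_panel()] (see [align_direction()]).
#' @param scope `"per_group"` or `"pooled"`.
#' @param degenerate_fill optional value in `(0, 1]` used for a constant
#'   column (`max == min`); the default is to raise an error, since
#'   silently keeping such a column would distort the weight restrictions.
#' @return a [kpi_panel()] of values in `[0.01, 1]` with a `bounds`
#'   attribute (`data.frame` of group, variable, lower, upper on the
#'   oriented scale; group is `"*"` for pooled scope).
#' @export
standardize_minmax <- function(panel, scope = c("per_group", "pooled"),
                               degenerate_fill = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(panel, "kpi_panel"))
  vals <- panel$values
  groups <- if (scope == "per_group") unique(panel$entities$group) else "*"
  bounds <- list()
  for (g in groups) {
    sel <- if (identical(g, "*")) seq_len(nrow(panel$entities)) else
      which(panel$entities$group == g)
    for (v in seq_along(panel$variables)) {
      x <- vals[sel, , v]
      obs <- x[!is.na(x)]
      if (!length(obs))
        stop("variable ", panel$variables[v], " has no observed value in ",
             "scope ", g, call. = FALSE)
      lo <- min(obs); hi <- max(obs)
      if (hi == lo) {
        if (is.null(degenerate_fill))
          stop("constant column within scope: variable ",
               panel$variables[v], ", group ", g,
               " (set degenerate_fill to override)", call. = FALSE)
        x[] <- ifelse(is.na(x), NA_real_, degenerate_fill)
      } else {
        x <- 0.99 * (x - lo) / (hi - lo) + 0.01
      }
      vals[sel, , v] <- x
      bounds[[length(bounds) + 1L]] <-
        data.frame(group = g, variable = panel$variables[v],
                   lower = lo, upper = hi)
    }
  }
  out <- kpi_panel(vals, panel$entities, panel$months, panel$variables)
  attr(out, "oriented") <- TRUE
  attr(out, "standardized") <- TRUE
  attr(out, "scope") <- scope
  attr(out, "bounds") <- do.call(rbind, bounds)
  out
}

#' Orient and standardize in one step
#'
#' Convenience composition of [align_direction()] and
#' [standardize_minmax()].
#'
#' @inheritParams align_direction
#' @inheritParams standardize_minmax
#' @return a standardized [kpi_panel()].
#' @export
standardize_panel <- function(panel, specs,
                              scope = c("per_group", "pooled"),
                              degenerate_fill = NULL) {
  standardize_minmax(align_direction(panel, specs), scope = scope,
                     degenerate_fill = degenerate_fill)
}
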