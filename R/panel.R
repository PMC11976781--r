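#' KPI panel container
#'
#' A `kpi_panel` holds an entity x month x variable array of raw KPI values
#' with `NA` marking missing cells, together with the entity-to-peer-group
#' assignment and the ordered month axis.  Entities are sorted
#' lexicographically and months chronologically; months must be contiguous
#' at monthly resolution and each entity belongs to exactly one group for
#' the whole horizon.
#'
#' @param values numeric array `c(n_entities, n_months, n_variables)`.
#' @param entities `data.frame` with columns `entity` and `group`.
#' @param months character vector of `"YYYY-MM"` months.
#' @param variables character vector of variable names.
#' @return an object of class `"kpi_panel"`.
#' @export
kpi_panel <- function(values, entities, months, variables) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  months <- parse_month(months)
  if (is.unsorted(months, strictly = TRUE))
    stop("months must be strictly increasing", call. = FALSE)
  if (length(months) > 1L) {
    idx <- month_index(months, months[1])
    if (!identical(idx, seq_along(months) - 1L))
      stop("months must be contiguous at monthly resolution", call. = FALSE)
  }
  stopifnot(is.data.frame(entities),
            all(c("entity", "group") %in% names(entities)))
  entities$entity <- as.character(entities$entity)
  entities$group <- as.character(entities$group)
  if (anyDuplicated(entities$entity))
    stop("each entity must have exactly one group", call. = FALSE)
  if (is.unsorted(entities$entity))
    stop("entities must be in lexicographic order", call. = FALSE)
  stopifnot(dim(values)[1] == nrow(entities),
            dim(values)[2] == length(months),
            dim(values)[3] == length(variables))
  dimnames(values) <- list(entities$entity, months, variables)
  structure(list(values = values, entities = entities, months = months,
                 variables = as.character(variables)),
            class = "kpi_panel")
}

#' @export
print.kpi_panel <- function(x, ...) {
  nmis <- sum(is.na(x$values))
  cat(sprintf(
    "<kpi_panel> %d entities (%d groups) x %d months x %d variables; %d missing cells (%.2f%%)\n",
    nrow(x$entities), length(unique(x$entities$group)), length(x$months),
    length(x$variables), nmis, 100 * nmis / length(x$values)))
  invisible(x)
}

#' @export
dim.kpi_panel <- function(x) dim(x$values)

#' Convert a panel to long form
#'
#' @param x a [kpi_panel()].
#' @param ... unused.
#' @return `data.frame` with columns `entity`, `group`, `month`,
#'   `variable`, `value` (missing cells as `NA`).
#' @export
as.data.frame.kpi_panel <- function(x, ...) {
  grid <- expand.grid(entity = x$entities$entity, month = x$months,
                      variable = x$variables, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$group <- x$entities$group[match(grid$entity, x$entities$entity)]
  grid$value <- as.vector(x$values)
  grid[, c("entity", "group", "month", "variable", "value")]
}

#' Read a KPI panel from CSV
#'
#' Long form (canonical) has columns `entity, group, month, variable,
#' value`; wide form has `entity, group, month` plus one column per
#' variable.  Missing cells are empty fields or `NA`.  Cells absent from a
#' long-form file are treated as missing.
#'
#' @param path CSV file path.
#' @param specs a [variable_specs()] frame; the panel's variable axis
#'   follows its order.
#' @param format `"long"` or `"wide"`.
#' @return a [kpi_panel()].
#' @export
read_panel <- function(path, specs, format = c("long", "wide")) {
  format <- match.arg(format)
  validate_specs(specs)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(entity = "character", month = "character",
                                group = "character"))
  if (format == "wide") {
    need <- c("entity", "group", "month", specs$name)
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("wide panel lacks columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    df <- cbind(
      df[rep(seq_len(nrow(df)), times = nrow(specs)),
         c("entity", "group", "month")],
      variable = rep(specs$name, each = nrow(df)),
      value = unlist(df[specs$name], use.names = FALSE)
    )
  }
  need <- c("entity", "group", "month", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(df$variable), specs$name)
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  df$month <- parse_month(df$month)
  if (anyDuplicated(df[c("entity", "month", "variable")]))
    stop("duplicate (entity, month, variable) records", call. = FALSE)
  grp <- unique(df[c("entity", "group")])
  if (anyDuplicated(grp$entity))
    stop("entity assigned to more than one group", call. = FALSE)
  grp <- grp[order(grp$entity), , drop = FALSE]
  rownames(grp) <- NULL
  months <- month_seq(min(df$month),
                      month_index(max(df$month), min(df$month)) + 1L)
  values <- array(NA_real_,
                  dim = c(nrow(grp), length(months), nrow(specs)))
  ei <- match(df$entity, grp$entity)
  mi <- match(df$month, months)
  vi <- match(df$variable, specs$name)
  values[cbind(ei, mi, vi)] <- as.numeric(df$value)
  kpi_panel(values, grp, months, specs$name)
}

#' Write a KPI panel to long-form CSV
#'
#' @inheritParams as.data.frame.kpi_panel
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_panel <- function(x, path) {
  df <- as.data.frame(x)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a KPI panel
#'
#' Reporting only; the panel is not modified.  Negative values are flagged
#' as out of range (all catalogue KPIs are nonnegative rates or ratios),
#' and a variable whose observed values are constant within a peer group is
#' flagged because min-max standardization degenerates there.
#'
#' @param panel a [kpi_panel()].
#' @param specs a [variable_specs()] frame.
#' @return a list with `missing_cells` (`data.frame` of entity, month,
#'   variable), `missing_fraction`, `out_of_range`, and `constant_columns`
#'   (`data.frame` of group, variable).
#' @export
validate_panel <- function(panel, specs) {
  stopifnot(inherits(panel, "kpi_panel"))
  if (!identical(panel$variables, specs$name))
    stop("panel variables do not match specs", call. = FALSE)
  long <- as.data.frame(panel)
  mis <- long[is.na(long$value), c("entity", "month", "variable")]
  rownames(mis) <- NULL
  neg <- long[!is.na(long$value) & long$value < 0,
              c("entity", "month", "variable", "value")]
  rownames(neg) <- NULL
  cc <- list()
  for (g in unique(panel$entities$group)) {
    sel <- panel$entities$group == g
    for (v in seq_along(panel$variables)) {
      vals <- panel$values[sel, , v]
      vals <- vals[!is.na(vals)]
      if (length(vals) && min(vals) == max(vals))
        cc[[length(cc) + 1L]] <- data.frame(group = g,
                                            variable = panel$variables[v])
    }
  }
  list(
    missing_cells = mis,
    missing_fraction = nrow(mis) / length(panel$values),
    out_of_range = neg,
    constant_columns = if (length(cc)) do.call(rbind, cc) else
      data.frame(group = character(), variable = character())
  )
}

#' Extract one peer group as an entity-month matrix
#'
#' Rows are entity-months (all months pooled, the meta-frontier reference
#' set), columns are variables.  Row order is month-major within entity
#' order, with row names `"entity|month"`.
#'
#' @param panel a [kpi_panel()].
#' @param group peer-group label.
#' @return numeric matrix with attributes `entity` and `month` giving the
#'   row coordinates.
#' @export
group_matrix <- function(panel, group) {
  sel <- which(panel$entities$group == group)
  if (!length(sel)) stop("unknown group: ", group, call. = FALSE)
  ne <- length(sel); nm <- length(panel$months)
  out <- matrix(aperm(panel$values[sel, , , drop = FALSE], c(1, 2, 3)),
                nrow = ne * nm, ncol = length(panel$variables))
  colnames(out) <- panel$variables
  ent <- rep(panel$entities$entity[sel], times = nm)
  mon <- rep(panel$months, each = ne)
  rownames(out) <- paste(ent, mon, sep = "|")
  attr(out, "entity") <- ent
  attr(out, "month") <- mon
  out
}
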