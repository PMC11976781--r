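KPI_DIMENSIONS <- c("access", "clinical_safety", "productivity",
                    "care_appropriateness")
KPI_DIRECTIONS <- c("desirable", "undesirable", "neutral")

#' Variable metadata for a KPI panel
#'
#' A variable specification records, for each KPI, the dimension it belongs
#' to, its desired direction of change (`"desirable"`: the higher the
#' better; `"undesirable"`: the lower the better; `"neutral"`: best inside
#' an interior band), the neutral band where applicable, and the minimum
#' weight `min_weight` the variable must receive under the weight-restricted
#' BoD models.  When `min_weight` is omitted it defaults to `1 / (2 * n)`
#' where `n` is the number of variables, so that with the standard 16-KPI
#' catalogue every variable is guaranteed a share of at least 0.03125.
#'
#' @param name character vector of variable names.
#' @param dimension one of `"access"`, `"clinical_safety"`,
#'   `"productivity"`, `"care_appropriateness"` (recycled).
#' @param direction one of `"desirable"`, `"undesirable"`, `"neutral"`.
#' @param neutral_lo,neutral_hi band bounds, required iff
#'   `direction == "neutral"` (percent scale; `neutral_lo < neutral_hi`).
#' @param min_weight minimum weight in `[0, 1]`; `NA` entries are filled
#'   with the `1 / (2 * n)` default.
#' @return a `data.frame` of class `"variable_spec"` with one row per
#'   variable.
#' @examples
#' variable_specs(c("on_time_rate", "occupancy"),
#'                dimension = c("access", "productivity"),
#'                direction = c("desirable", "neutral"),
#'                neutral_lo = c(NA, 80), neutral_hi = c(NA, 90))
#' @export
variable_specs <- function(name, dimension, direction,
                           neutral_lo = NA_real_, neutral_hi = NA_real_,
                           min_weight = NA_real_) {
  n <- length(name)
  if (n == 0L) stop("at least one variable is required", call. = FALSE)
  if (anyDuplicated(name)) stop("duplicate variable names", call. = FALSE)
  specs <- data.frame(
    name = as.character(name),
    dimension = rep_len(as.character(dimension), n),
    direction = rep_len(as.character(direction), n),
    neutral_lo = rep_len(as.numeric(neutral_lo), n),
    neutral_hi = rep_len(as.numeric(neutral_hi), n),
    min_weight = rep_len(as.numeric(min_weight), n),
    stringsAsFactors = FALSE
  )
  specs$min_weight[is.na(specs$min_weight)] <- default_min_weight(n)
  class(specs) <- c("variable_spec", "data.frame")
  validate_specs(specs)
}

#' @rdname variable_specs
#' @param n number of variables.
#' @export
default_min_weight <- function(n) 1 / (2 * n)

#' @rdname variable_specs
#' @param specs object to validate.
#' @export
validate_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  need <- c("name", "dimension", "direction", "neutral_lo", "neutral_hi",
            "min_weight")
  miss <- setdiff(need, names(specs))
  if (length(miss)) stop("specs lack columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(specs$dimension, KPI_DIMENSIONS)
  if (length(bad)) stop("unknown dimension(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(specs$direction, KPI_DIRECTIONS)
  if (length(bad)) stop("unknown direction(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  neutral <- specs$direction == "neutral"
  has_band <- !is.na(specs$neutral_lo) & !is.na(specs$neutral_hi)
  if (any(neutral & !has_band))
    stop("neutral variable(s) without a band: ",
         paste(specs$name[neutral & !has_band], collapse = ", "),
         call. = FALSE)
  if (any(!neutral & has_band))
    stop("band given for non-neutral variable(s): ",
         paste(specs$name[!neutral & has_band], collapse = ", "),
         call. = FALSE)
  if (any(has_band & specs$neutral_lo >= specs$neutral_hi))
    stop("neutral band must satisfy lo < hi", call. = FALSE)
  if (any(specs$min_weight < 0 | specs$min_weight > 1))
    stop("min_weight must lie in [0, 1]", call. = FALSE)
  if (sum(specs$min_weight) > 1 + 1e-12)
    stop("sum of min_weight exceeds 1 (", round(sum(specs$min_weight), 4),
         "); the weight-restricted models would be infeasible", call. = FALSE)
  invisible(specs)
}

#' Read or write variable metadata
#'
#' Variable configurations are stored as YAML or JSON (chosen by file
#' extension) with a top-level `variables` list; each element has `name`,
#' `dimension`, `direction`, and optionally `neutral_band: [lo, hi]` and
#' `min_weight`.  Omitted `min_weight` entries default to `1 / (2 * n)`
#' over the `n` variables listed.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_variable_config()` returns a [variable_specs()] frame.
#' @export
read_variable_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  vars <- raw$variables
  if (is.null(vars) || !length(vars))
    stop("config has no 'variables' entry", call. = FALSE)
  get1 <- function(v, field, default = NA) {
    x <- v[[field]]
    if (is.null(x)) default else x
  }
  band <- lapply(vars, function(v) get1(v, "neutral_band", c(NA, NA)))
  variable_specs(
    name = vapply(vars, get1, "", field = "name"),
    dimension = vapply(vars, get1, "", field = "dimension"),
    direction = vapply(vars, get1, "", field = "direction"),
    neutral_lo = vapply(band, function(b) as.numeric(b[1]), 0),
    neutral_hi = vapply(band, function(b) as.numeric(b[2]), 0),
    min_weight = vapply(vars, function(v)
      as.numeric(get1(v, "min_weight", NA_real_)), 0)
  )
}

#' @rdname read_variable_config
#' @param specs a [variable_specs()] frame.
#' @export
write_variable_config <- function(specs, path) {
  validate_specs(specs)
  vars <- lapply(seq_len(nrow(specs)), function(i) {
    v <- list(name = specs$name[i], dimension = specs$dimension[i],
              direction = specs$direction[i],
              min_weight = specs$min_weight[i])
    if (specs$direction[i] == "neutral")
      v$neutral_band <- c(specs$neutral_lo[i], specs$neutral_hi[i])
    v
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(variables = vars), path)
  } else if (ext == "json") {
    jsonlite::write_json(list(variables = vars), path, auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported config format: .", ext, call. = FALSE)
  invisible(path)
}
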