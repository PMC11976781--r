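#' End-to-end pipeline runners
#'
#' Thin orchestration over the package's functions, mirroring a
#' simulate / score / analyze workflow with files on disk.  Every output
#' directory receives a `manifest.json` recording the configuration and
#' seed, so a run is reproducible from its manifest.
#'
#' `run_simulate()` writes a synthetic panel (`panel.csv`), its variable
#' catalogue (`variables.yaml`) and the generator ground truth
#' (`truth.json`).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param cfg a [synth_config()]; its seed is overridden by `seed` when
#'   given.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(out_dir, seed = NULL, cfg = synth_config()) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_panel(cfg)
  write_panel(sim$panel, file.path(out_dir, "panel.csv"))
  write_variable_config(sim$specs, file.path(out_dir, "variables.yaml"))
  truth <- sim$truth
  truth$mask <- if (is.null(truth$mask)) NULL else which(truth$mask) - 1L
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest(out_dir, list(step = "simulate", seed = cfg$seed,
                         groups = as.list(cfg$groups),
                         n_months = cfg$n_months,
                         missing_rate = cfg$missing_rate))
  message(sprintf("simulated %d entities x %d months x 16 variables -> %s",
                  sum(cfg$groups), cfg$n_months, out_dir))
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param panel_path,variables_path inputs written by `run_simulate()` (or
#'   any panel/config in the same formats).
#' @param models list of [bod_config()]s to run; the default covers the
#'   four orientation x restriction combinations.
#' @param replicates imputation replicates K; 0 disables imputation (the
#'   panel must then be complete).
#' @export
run_score <- function(out_dir, panel_path, variables_path,
                      models = default_model_matrix(), replicates = 200,
                      seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- read_variable_config(variables_path)
  panel <- read_panel(panel_path, specs)
  has_missing <- anyNA(panel$values)
  files <- character(0)
  for (cfg in models) {
    if (has_missing && replicates > 0) {
      imp <- draw_imputations(panel, specs,
                              imputation_config(replicates = replicates,
                                                seed = seed))
      tab <- expected_scores(score_distribution(imp, cfg))
    } else {
      if (has_missing)
        stop("panel has missing cells; set replicates > 0", call. = FALSE)
      tab <- score_panel(standardize_panel(panel, specs), cfg)
    }
    if (cfg$orientation == "pessimistic") tab <- rescale_pessimistic(tab)
    f <- file.path(out_dir, sprintf("scores_%s_%s.csv", cfg$orientation,
                                    cfg$restriction))
    write_scores(tab, f)
    files <- c(files, f)
  }
  manifest(out_dir, list(step = "score", seed = seed,
                         replicates = replicates,
                         models = vapply(models, function(m)
                           paste(m$orientation, m$restriction, sep = "/"),
                           character(1))))
  message("wrote ", length(files), " score tables -> ", out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param scores_path a score CSV written by `run_score()` (expected
#'   optimistic scores drive the benchmark analysis).
#' @param split last month of the pre window.
#' @param k_max largest top-set size of the frequency table.
#' @param k top/bottom set size for the pre/post and gap reports.
#' @export
run_analyze <- function(out_dir, scores_path, split = "2020-03",
                        k_max = 5, k = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_scores(scores_path)
  months <- sort(unique(table$month))
  ranks <- monthly_rankings(table)
  pre <- c(months[1], split)
  freq <- frequency_table(table, ranks, pre, k_max = k_max)
  write.csv(freq, file.path(out_dir, "benchmark_frequency.csv"),
            row.names = FALSE)
  pp <- prepost_summary(table, ranks, split, k = k)
  write.csv(pp$per_entity, file.path(out_dir, "prepost_entities.csv"),
            row.names = FALSE)
  jsonlite::write_json(pp$per_group,
                       file.path(out_dir, "prepost_groups.json"),
                       auto_unbox = TRUE, digits = NA)
  gaps <- do.call(rbind.data.frame, lapply(sort(unique(table$group)),
    function(g) {
      tg <- table[table$group == g, , drop = FALSE]
      all_rank <- top_entities(tg, pre, length(unique(tg$entity)))
      tops <- all_rank$entity[seq_len(k)]
      bots <- utils::tail(all_rank$entity, k)
      gs <- gap_series(tg, tops, bots, split = split)
      data.frame(group = g, month = gs$series$month, gap = gs$series$gap,
                 slope = gs$slope, pre_avg = gs$pre_avg,
                 post_avg = gs$post_avg, stringsAsFactors = FALSE)
    }))
  write.csv(gaps, file.path(out_dir, "gap_series.csv"), row.names = FALSE)
  evo <- evolution_summary(table)
  write.csv(evo, file.path(out_dir, "evolution_summary.csv"),
            row.names = FALSE)
  manifest(out_dir, list(step = "analyze", split = split, k = k,
                         k_max = k_max, scores = basename(scores_path)))
  message("wrote 4 analysis reports -> ", out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @export
run_all <- function(out_dir, seed = 1L, cfg = synth_config(),
                    replicates = 200, split = "2020-03", k = 2) {
  run_simulate(file.path(out_dir, "sim"), seed = seed, cfg = cfg)
  run_score(file.path(out_dir, "scores"),
            file.path(out_dir, "sim", "panel.csv"),
            file.path(out_dir, "sim", "variables.yaml"),
            replicates = replicates, seed = seed)
  run_analyze(file.path(out_dir, "analysis"),
              file.path(out_dir, "scores",
                        "scores_optimistic_multiplier_share.csv"),
              split = split, k = k)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @export
default_model_matrix <- function() {
  list(bod_config("optimistic", "multiplier_share"),
       bod_config("optimistic", "pie_share"),
       bod_config("pessimistic", "multiplier_share"),
       bod_config("pessimistic", "pie_share"))
}

manifest <- function(out_dir, fields) {
  fields$package <- "bodbench"
  fields$version <- as.character(utils::packageVersion("bodbench"))
  fields$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
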