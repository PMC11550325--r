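sb_log <- function(level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  thr <- getOption("sellabench.log_level", "info")
  if (levels[[level]] >= levels[[thr]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Pipeline configuration
#'
#' Either `input` (a dataset file in the annotation GeoJSON dialect) or
#' `study` (a [study_config()] to simulate from) must be supplied.
#'
#' @param study A [study_config()], or `NULL` when evaluating existing data.
#' @param input Path to a dataset file, or `NULL` when simulating.
#' @param out_dir Output directory (created if needed).
#' @param colormap Heat-map palette name (pinned; see [render_heatmap()]).
#' @param report_precision Decimal places for p values in printed reports
#'   (CSV files always keep full precision).
#' @param seed Integer seed; overrides `study$seed` when both are given.
#' @param heatmaps Render the per-subgroup agreement heat maps (can be
#'   disabled for speed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, input = NULL, out_dir,
                            colormap = "viridis", report_precision = 3L,
                            seed = NULL, heatmaps = TRUE) {
  if (is.null(study) && is.null(input))
    stop("pipeline_config: supply either a study config or an input path")
  stopifnot(report_precision >= 1L)
  if (!is.null(seed) && !is.null(study)) study$seed <- as.integer(seed)
  structure(list(study = study, input = input, out_dir = out_dir,
                 colormap = colormap,
                 report_precision = as.integer(report_precision),
                 seed = if (!is.null(seed)) as.integer(seed)
                        else if (!is.null(study)) study$seed else NULL,
                 heatmaps = isTRUE(heatmaps)),
            class = "pipeline_config")
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

export_metrics_csv <- function(metrics, changes, path) {
  out <- metrics
  out$fp_pct <- 100 * out$fp_frac
  out$fn_pct <- 100 * out$fn_frac
  key <- paste(out$annotator_id, out$image_id, sep = "\r")
  ckey <- paste(changes$annotator_id, changes$image_id, sep = "\r")
  i <- match(key, ckey)
  out$changed <- changes$annotation_changed[i]
  out$outcome <- changes$dice_outcome[i]
  out <- out[, c("annotator_id", "group", "image_id", "round", "dice",
                 "fp_pct", "fn_pct", "centroid_hit", "changed", "outcome")]
  write_csv_file(out, path)
}

render_all_heatmaps <- function(dataset, out_dir, colormap) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- vapply(dataset$annotators, `[[`, "", "group")
  files <- character(0)
  for (f in dataset$frames) {
    gt <- dataset$ground_truth[[f$image_id]]
    ai <- dataset$ai_prediction[[f$image_id]]
    for (g in intersect(GROUPS, unique(groups))) {
      members <- names(groups)[groups == g]
      for (rnd in c("PRE", "POST")) {
        anns <- Filter(Negate(is.null), lapply(members, function(a)
          get_annotation(dataset, a, f$image_id, rnd)))
        if (!length(anns)) next
        masks <- lapply(anns, rasterize, frame = f)
        amap <- agreement_map(masks, f$image_id, rnd, g)
        amap$n_annotators <- length(members)  # normalize by subgroup size
        path <- file.path(out_dir, sprintf("%s_%s_%s.png", g, f$image_id, rnd))
        render_heatmap(amap, gt, ai, path, colormap = colormap)
        files <- c(files, path)
      }
    }
  }
  files
}

#' Run the full simulate / evaluate / report pipeline
#'
#' Loads (or simulates) a study dataset, scores every annotation against
#' ground truth, writes the per-annotation metrics CSV, the four summary
#' tables, the per-subgroup agreement heat maps, and a manifest recording the
#' configuration, seed and package versions. Two runs with an identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  if (!is.null(config$input)) {
    sb_log("info", "loading dataset from %s", config$input)
    dataset <- load_dataset(config$input)
  } else {
    sb_log("info", "simulating study (seed %d)", config$study$seed)
    dataset <- generate_study(config$study)
    write_dataset(dataset, out("dataset.geojson"))
  }
  if (nrow(dataset$completeness))
    sb_log("warn", "%d missing round entries excluded from paired analyses",
           nrow(dataset$completeness))

  sb_log("info", "evaluating %d annotations", length(dataset$annotations))
  ev <- evaluate_dataset(dataset)
  files <- c(
    metrics = export_metrics_csv(ev$metrics, ev$changes, out("metrics.csv")),
    ai_metrics = write_csv_file(ev$ai_metrics, out("ai_metrics.csv")))

  tabs <- summarize_study(ev$metrics, ev$changes)
  for (nm in names(tabs))
    files[[nm]] <- write_csv_file(tabs[[nm]], out(paste0(nm, ".csv")))

  heatmap_files <- character(0)
  if (config$heatmaps) {
    sb_log("info", "rendering agreement heat maps")
    heatmap_files <- render_all_heatmaps(dataset, out("heatmaps"),
                                         config$colormap)
  }

  manifest <- list(
    package = "sellabench",
    version = as.character(utils::packageVersion("sellabench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    colormap = config$colormap,
    report_precision = config$report_precision,
    input = config$input,
    study = if (!is.null(config$study)) unclass_deep(config$study),
    outputs = c(unname(files), heatmap_files),
    n_annotations = length(dataset$annotations),
    n_missing_pairs = nrow(dataset$completeness))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Summarize tables at report precision
#'
#' Formats a summary table for printed reports, rounding p values to the
#' configured number of decimals while leaving the CSV outputs untouched.
#'
#' @param tab A data frame with a `p_value` column.
#' @param digits Decimal places.
#' @return The data frame with `p_value` rounded.
#' @export
format_report <- function(tab, digits = 3L) {
  if ("p_value" %in% names(tab)) tab$p_value <- round(tab$p_value, digits)
  tab
}

cli_fail <- function(category, e) {
  message(sprintf("error [%s]: %s", category, conditionMessage(e)))
  1L
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (config to dataset file), `evaluate` (dataset to
#' metrics CSVs), `report` (dataset to tables and heat maps) and `run` (all
#' three). Flags: `--config PATH` (pipeline/study configuration as JSON),
#' `--input PATH` (dataset file, for evaluate/report), `--seed INT`
#' (overrides the config seed), `--out DIR`, `--log-level LEVEL`,
#' `--no-heatmaps`. Returns 0 on success and a nonzero status with a
#' categorized error message otherwise.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   [commandArgs()]).
#' @return Integer exit status, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--log-level", type = "character", default = "info",
                          dest = "log_level"),
    optparse::make_option("--no-heatmaps", action = "store_true",
                          default = FALSE, dest = "no_heatmaps"))
  parser <- optparse::OptionParser(
    usage = "%prog [simulate|evaluate|report|run] [options]",
    option_list = spec)
  parsed <- tryCatch(
    optparse::parse_args(parser, args = args, positional_arguments = 1L),
    error = function(e) e)
  if (inherits(parsed, "error")) return(invisible(cli_fail("usage", parsed)))
  cmd <- parsed$args
  opt <- parsed$options
  old <- options(sellabench.log_level = opt$log_level)
  on.exit(options(old), add = TRUE)

  read_study <- function() {
    if (is.null(opt$config)) stop("--config is required for this subcommand")
    cfg <- jsonlite::read_json(opt$config)
    groups <- if (!is.null(cfg$groups)) {
      lapply(cfg$groups, function(g)
        list(n = g$n, profile = do.call(annotator_profile, g$profile)))
    } else NULL
    study_config(
      n_images = cfg$n_images %||% 6L,
      frame_width = cfg$frame_width %||% 720L,
      frame_height = cfg$frame_height %||% 576L,
      groups = groups,
      ai_target_dice = cfg$ai_target_dice %||% 0.85,
      ai_tolerance = cfg$ai_tolerance %||% 0.02,
      seed = opt$seed %||% cfg$seed)
  }

  status <- tryCatch({
    switch(cmd,
      simulate = {
        ds <- generate_study(read_study())
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_dataset(ds, file.path(opt$out, "dataset.geojson"))
        sb_log("info", "wrote %s", file.path(opt$out, "dataset.geojson"))
      },
      evaluate = {
        if (is.null(opt$input)) stop("--input is required for evaluate")
        ds <- load_dataset(opt$input)
        ev <- evaluate_dataset(ds)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        export_metrics_csv(ev$metrics, ev$changes,
                           file.path(opt$out, "metrics.csv"))
        write_csv_file(ev$ai_metrics, file.path(opt$out, "ai_metrics.csv"))
      },
      report = {
        if (is.null(opt$input)) stop("--input is required for report")
        cfg <- pipeline_config(input = opt$input, out_dir = opt$out,
                               heatmaps = !opt$no_heatmaps)
        run_pipeline(cfg)
      },
      run = {
        cfg <- pipeline_config(study = read_study(), out_dir = opt$out,
                               seed = opt$seed, heatmaps = !opt$no_heatmaps)
        run_pipeline(cfg)
      },
      stop("unknown subcommand: ", cmd))
    0L
  },
  error = function(e) cli_fail("pipeline", e))
  invisible(status)
}
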