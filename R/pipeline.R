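config_schema <- function() list(
  input = list(stack = NULL, times = NULL, reference_points = NULL),
  output = list(dir = "."),
  grid = list(bounds = NULL, n_arenas = 50L, layout = NULL,
              exclude_arenas = integer(), exclude_windows = NULL),
  detection = list(min_area = 300, method = "otsu", threshold = NULL,
                   polarity = "dark_objects", min_contrast = 20),
  vitality = list(move_threshold = 7, quiescent_h = 4, confirm_m = 2,
                  occupancy_window_h = 10, compensate_shifts = TRUE,
                  agree_frac = 0.5, min_shift = 3),
  qc = list(auto = FALSE, n_sd = 5),
  survival = list(lethality_at = numeric(), group = "all"),
  simulate = list(n_arenas = 50L, arena_px = c(126L, 456L), frames = 72L,
                  frame_interval = 1,
                  occupancy_probs = c(0.388, 0.505, 0.092, 0.012, 0.003),
                  survival_dist = list(name = "exponential", mean = 40),
                  movement_px = c(12, 2), worm_area_px = 1000,
                  fade_after_death = 0, debris_rate = 0.1,
                  bubble_rate = 0.01, global_shift_events = NULL,
                  noise_sd = 2, background_level = 200, worm_level = 60),
  seed = 1L)

#' Validate a run configuration
#'
#' Reads a YAML run configuration (or takes an equivalent nested list),
#' fills in every documented default, and rejects unknown keys so typos
#' cannot silently disable a setting. Parameter ranges are checked and all
#' problems are reported together.
#'
#' @param config path to a YAML file, YAML text, or a nested list.
#' @return the validated configuration (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (is.null(config)) config <- list()
  stop_if(!is.list(config), "config must be a YAML mapping")
  schema <- config_schema()
  errors <- character()

  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key: ", unknown))
  for (sec in intersect(names(config), names(schema))) {
    if (!is.list(schema[[sec]])) next
    bad <- setdiff(names(config[[sec]]), names(schema[[sec]]))
    if (length(bad))
      errors <- c(errors, paste0("unknown key: ", sec, ".", bad))
  }
  merged <- modifyList(schema, config[intersect(names(config), names(schema))],
                       keep.null = TRUE)
  # normalise containers so configs round-trip through YAML unchanged
  merged$grid$exclude_arenas <- as.integer(unlist(merged$grid$exclude_arenas))
  merged$survival$lethality_at <-
    as.numeric(unlist(merged$survival$lethality_at))

  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  v <- merged$vitality
  chk(is_number(v$move_threshold) && v$move_threshold >= 0,
      "vitality.move_threshold must be >= 0")
  chk(is_number(v$quiescent_h) && v$quiescent_h > 0,
      "vitality.quiescent_h must be > 0")
  chk(is_count(v$confirm_m) && v$confirm_m >= 1,
      "vitality.confirm_m must be a count >= 1")
  chk(is_number(v$occupancy_window_h) && v$occupancy_window_h > 0,
      "vitality.occupancy_window_h must be > 0")
  chk(is_number(v$agree_frac) && v$agree_frac > 0 && v$agree_frac < 1,
      "vitality.agree_frac must lie in (0, 1)")
  chk(is_number(v$min_shift) && v$min_shift >= 0,
      "vitality.min_shift must be >= 0")
  d <- merged$detection
  chk(is_number(d$min_area) && d$min_area >= 0,
      "detection.min_area must be >= 0")
  chk(is_number(d$min_contrast) && d$min_contrast >= 0,
      "detection.min_contrast must be >= 0")
  chk(d$method %in% c("otsu", "fixed"),
      "detection.method must be otsu or fixed")
  chk(d$polarity %in% c("dark_objects", "light_objects"),
      "detection.polarity must be dark_objects or light_objects")
  chk(is_count(merged$seed), "seed must be a non-negative integer")

  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  structure(merged, class = "run_config")
}

sim_config_from_run <- function(config) {
  do.call(sim_config, c(config$simulate, list(seed = config$seed)))
}

#' Run the full image-to-survival pipeline
#'
#' Orchestrates load, align, segment, detect, vitality, and survival from
#' one validated configuration: reads the stack, applies the rigid
#' alignment when reference points are supplied, builds the arena grid,
#' scores every arena, and writes the documented outputs plus a manifest
#' with checksums. Numeric output formatting is fixed (times to 0.1 h,
#' fractions to 3 decimals), so re-running an identical configuration on
#' identical inputs reproduces identical files.
#'
#' Outputs in `config$output$dir`: `moving_counts.tsv`, `death_calls.csv`,
#' `survival_curve.csv`, `survival_summary.json`, `yield.txt`,
#' `manifest.json`, and `run.log`.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stop_if(is.null(config$input$stack), "input.stack is required")
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output$dir, "run.log")
  cat("", file = logf)
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                                ..., "\n", sep = "", file = logf,
                                append = TRUE)

  log_line("stage load: ", config$input$stack)
  series <- load_frame_series(config$input$stack, times = config$input$times)

  if (!is.null(config$input$reference_points)) {
    log_line("stage align: ", config$input$reference_points)
    rp <- read.csv(config$input$reference_points)
    tr <- estimate_rigid_transform(rp[, c("src_row", "src_col")],
                                   rp[, c("dst_row", "dst_col")])
    log_line(sprintf("  rotation %.6f rad, translation (%.2f, %.2f), rms %.3f",
                     tr$rotation, tr$translation[1], tr$translation[2],
                     attr(tr, "rms")))
    series$frames <- lapply(series$frames, apply_transform, t = tr)
  }

  g <- config$grid
  bounds <- g$bounds %||% c(1, 1, dim(series$frames[[1]]))
  windows <- if (!is.null(g$exclude_windows) && is.character(g$exclude_windows))
    read.csv(g$exclude_windows) else g$exclude_windows
  spec <- grid_spec(bounds, n_arenas = g$n_arenas, layout = g$layout,
                    exclude_arenas = unlist(g$exclude_arenas),
                    exclude_windows = windows)
  regions <- build_grid(spec)
  log_line("stage segment: ", spec$n_arenas, " arenas")

  excl <- exclusion_mask(spec, series$times)
  if (isTRUE(config$qc$auto))
    excl <- excl | qc_flag_frames(series, regions, n_sd = config$qc$n_sd)

  log_line("stage detect/vitality")
  res <- score_stack(
    series, regions,
    min_area = config$detection$min_area, method = config$detection$method,
    threshold = config$detection$threshold,
    polarity = config$detection$polarity,
    min_contrast = config$detection$min_contrast, exclude = excl,
    move_threshold = config$vitality$move_threshold,
    quiescent_h = config$vitality$quiescent_h,
    confirm_m = config$vitality$confirm_m,
    occupancy_window_h = config$vitality$occupancy_window_h,
    compensate_shifts = config$vitality$compensate_shifts,
    agree_frac = config$vitality$agree_frac,
    min_shift = config$vitality$min_shift)

  for (i in which(res$calls$status %in% c("excluded", "empty"))) {
    reason <- if (res$calls$flags[i] != "") res$calls$flags[i]
              else if (identical(res$calls$occupancy[i], "4+")) "occupancy 4+"
              else "no resident objects"
    log_line("excluded arena ", res$calls$arena[i], ": ", reason)
  }

  paths <- c(
    moving_counts = file.path(config$output$dir, "moving_counts.tsv"),
    death_calls = file.path(config$output$dir, "death_calls.csv"),
    survival_curve = file.path(config$output$dir, "survival_curve.csv"),
    survival_summary = file.path(config$output$dir, "survival_summary.json"),
    yield = file.path(config$output$dir, "yield.txt"))
  write_moving_counts(res, paths["moving_counts"])
  write_death_calls(res$calls, paths["death_calls"])

  scored <- sum(res$calls$status %in% c("dead", "censored"))
  if (scored > 0 && any(res$calls$status == "dead")) {
    sdat <- calls_to_surv_data(res$calls, group = config$survival$group)
    write_survival_outputs(sdat,
                           lethality_at = unlist(config$survival$lethality_at),
                           curve_file = paths["survival_curve"],
                           summary_file = paths["survival_summary"])
  } else {
    paths <- paths[setdiff(names(paths), c("survival_curve",
                                           "survival_summary"))]
    log_line("survival outputs skipped: no death events")
  }

  yield <- compute_yield(res$calls, capacity = spec$n_arenas)
  cat(sprintf("yield: %.1f%% (%d/%d arenas scored)\n", yield, scored,
              spec$n_arenas), file = paths["yield"])
  log_line(sprintf("yield %.1f%%", yield))

  manifest <- list(
    package = "vitalscan",
    version = as.character(utils::packageVersion("vitalscan")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = unclass(config),
    inputs = as.list(tools::md5sum(Filter(file.exists, unlist(
      config$input[c("stack", "times", "reference_points")])))),
    counts = list(
      arenas = spec$n_arenas, frames = length(series$frames),
      scored = scored,
      dead = sum(res$calls$status == "dead"),
      censored = sum(res$calls$status == "censored"),
      excluded = sum(res$calls$status == "excluded"),
      empty = sum(res$calls$status == "empty"),
      yield_percent = round(yield, 1),
      global_shifts_flagged = sum(res$shift_flags)),
    outputs = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest,
                       file.path(config$output$dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log_line("done")
  invisible(manifest)
}

#' Write survival outputs for a dataset
#'
#' Writes the Kaplan-Meier curve table as CSV (`time`, `n_risk`,
#' `n_event`, `survival`) and the summary as JSON.
#'
#' @param data a [surv_data()].
#' @param lethality_at times (hours) for percent-dead reporting.
#' @param curve_file,summary_file output paths (NULL skips either).
#' @return invisibly, the [summarize_survival()] result.
#' @export
write_survival_outputs <- function(data, lethality_at = numeric(),
                                   curve_file = NULL, summary_file = NULL) {
  km <- km_curve(data)
  smry <- summarize_survival(data, lethality_at = lethality_at %||% numeric())
  if (!is.null(curve_file)) {
    out <- data.frame(time = sprintf("%.1f", km$curve$time),
                      n_risk = km$curve$n_risk, n_event = km$curve$n_event,
                      survival = sprintf("%.3f", km$curve$survival))
    write.csv(out, curve_file, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_file))
    jsonlite::write_json(unclass(smry), summary_file, auto_unbox = TRUE,
                         digits = 8, dataframe = "columns")
  invisible(smry)
}
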