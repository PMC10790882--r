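## coerce/validate the gaze stream dialect; derives az/el from gx,gy,gz
## when only the vector form is present
as_gaze_stream <- function(x) {
  stopifnot(is.data.frame(x))
  if (!"az_deg" %in% names(x)) {
    if (all(c("gx", "gy", "gz") %in% names(x))) {
      ae <- vector_to_azel(x$gx, x$gy, x$gz,
                           if ("valid" %in% names(x)) x$valid else TRUE)
      x$az_deg <- ae$az_deg
      x$el_deg <- ae$el_deg
      x$valid <- ae$valid
    } else {
      stop("gaze stream needs an 'az_deg' column or 'gx','gy','gz' columns")
    }
  }
  if (!"time_s" %in% names(x)) stop("gaze stream needs a 'time_s' column")
  if (!"valid" %in% names(x)) x$valid <- TRUE
  x$valid <- !is.na(x$valid) & x$valid & is.finite(x$az_deg)
  x
}

as_drive_stream <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("time_s", "dist_m", "lane_offset_cm", "brake", "speed_kmh")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("driving stream missing column(s): ",
                         paste(miss, collapse = ", "))
  x$brake <- as.logical(x$brake)
  x
}

read_numeric_checked <- function(df, cols, path) {
  for (cl in cols) {
    if (!cl %in% names(df)) next
    v <- df[[cl]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop("non-numeric value in column '", cl, "' of ", path,
             " at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      df[[cl]] <- num
    }
  }
  df
}

#' Read a gaze stream CSV
#'
#' Columns are matched by name, so column order is free. Required: `time_s`
#' plus either `az_deg` or the vector triple `gx`,`gy`,`gz` (converted via
#' [vector_to_azel()]). Optional: `el_deg`, `valid`, `head_az_deg`, `aoi`,
#' `source`, `excluded`.
#'
#' @param path CSV file path.
#' @return A gaze stream `data.frame`.
#' @export
read_gaze <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df))
    stop("missing required column 'time_s' in ", path)
  if (!"az_deg" %in% names(df) && !all(c("gx", "gy", "gz") %in% names(df)))
    stop("missing required column 'az_deg' (or 'gx','gy','gz') in ", path)
  df <- read_numeric_checked(df, c("time_s", "az_deg", "el_deg",
                                   "head_az_deg", "gx", "gy", "gz"), path)
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  if ("excluded" %in% names(df)) df$excluded <- as.logical(df$excluded)
  as_gaze_stream(df)
}

#' Write a gaze stream CSV
#' @param gaze Gaze stream `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(gaze, path) {
  utils::write.csv(gaze, path, row.names = FALSE)
  invisible(path)
}

#' Read a driving stream CSV
#'
#' Required columns: `time_s`, `dist_m`, `lane_offset_cm`, `brake`,
#' `speed_kmh`.
#'
#' @param path CSV file path.
#' @return A driving stream `data.frame`.
#' @export
read_drive <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- read_numeric_checked(df, c("time_s", "dist_m", "lane_offset_cm",
                                   "speed_kmh"), path)
  as_drive_stream(df)
}

#' Write a driving stream CSV
#' @param drive Driving stream `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drive <- function(drive, path) {
  utils::write.csv(drive, path, row.names = FALSE)
  invisible(path)
}

#' Default project configuration
#'
#' Every threshold defaults to the study value where one exists (2 degrees /
#' 120 ms / 30 deg/s fixation rule, 90 deg/s saccade rule, 10 Hz filter,
#' 10 degree central band, 5 degree saccade endpoint rule, 30 and 45 degree
#' scan criteria, 100 m brake search, 41.76 m fallback, 60 Hz gaze and
#' 240 Hz driving rates). The remainder (buffer length, bypass threshold,
#' fade width, lane boundary) are declared package defaults.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    version = "1",
    rig = list(panel_px_w = 3400, panel_px_h = 2720, panel_half_angle = 30),
    mask = list(side = "left", fade_width_deg = 4,
                mask_color = c(128, 128, 128), update_rate_hz = 60),
    buffer = list(window_len = 3, bypass_threshold_deg = 10,
                  hold_on_invalid = TRUE),
    filter = list(cutoff_hz = 10, order = 2, sample_rate_hz = 60,
                  zero_phase = TRUE),
    thresholds = list(fix_dispersion_deg = 2, fix_min_dur_s = 0.120,
                      fix_max_speed_deg_s = 30, sacc_min_speed_deg_s = 90,
                      central_deg = 10, sacc_endpoint_min_deg = 5,
                      first_scan_deg = 30, large_scan_deg = 45,
                      brake_search_dist_m = 100, fallback_dist_m = 41.76,
                      drive_rate_hz = 240),
    lane = list(boundary_cm = 85),
    excluded_aois = c("blink", "mirror", "media", "other"),
    units = list(lane_offset = "cm", lane_var = "cm2", angle = "deg"))
}

#' Validate a configuration list
#'
#' Rejects physically impossible thresholds (e.g. a filter cutoff at or
#' above Nyquist) before any computation.
#'
#' @param config Configuration list as from [default_config()] or
#'   [read_config()].
#' @return The config, invisibly; errors on invalid settings.
#' @export
validate_config <- function(config) {
  need <- c("rig", "mask", "buffer", "filter", "thresholds", "lane")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing section(s): ", paste(miss, collapse = ", "))
  filter_config(config$filter$cutoff_hz, config$filter$order,
                config$filter$sample_rate_hz, config$filter$zero_phase)
  th <- config$thresholds
  if (th$fix_dispersion_deg <= 0 || th$fix_min_dur_s <= 0 ||
      th$fix_max_speed_deg_s <= 0 || th$sacc_min_speed_deg_s <= 0)
    stop("event thresholds must be positive")
  if (th$fix_max_speed_deg_s >= th$sacc_min_speed_deg_s)
    stop("fixation velocity bound must lie below the saccade threshold")
  if (th$fallback_dist_m <= 0 || th$brake_search_dist_m <= th$fallback_dist_m)
    stop("brake search distance must exceed the fallback distance")
  if (!config$mask$side %in% c("left", "right"))
    stop("mask side must be 'left' or 'right'")
  if (config$buffer$window_len < 1 || config$buffer$bypass_threshold_deg <= 0)
    stop("invalid buffer policy")
  if (config$lane$boundary_cm <= 0) stop("lane boundary must be positive")
  invisible(config)
}

#' Read a YAML configuration file
#'
#' Missing keys fall back to [default_config()]; the merged configuration is
#' validated before being returned.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a synthetic study to a directory
#'
#' One gaze and one driving CSV per scenario plus `manifest.csv` and
#' `manifest.json` of all planted quantities.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$scenarios)) {
    write_gaze(study$scenarios[[id]]$gaze,
               file.path(dir, paste0(id, "_gaze.csv")))
    write_drive(study$scenarios[[id]]$drive,
                file.path(dir, paste0(id, "_drive.csv")))
  }
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir Study directory.
#' @return A list with `scenarios` (gaze + drive per scenario) and
#'   `manifest`.
#' @export
read_study <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  scenarios <- lapply(manifest$scenario, function(id)
    list(gaze = read_gaze(file.path(dir, paste0(id, "_gaze.csv"))),
         drive = read_drive(file.path(dir, paste0(id, "_drive.csv")))))
  names(scenarios) <- manifest$scenario
  list(scenarios = scenarios, manifest = manifest)
}

#' Run the full processing pipeline over a study
#'
#' Stage order: preprocessing, event detection, scenario metrics, EAB
#' classification. Writes per-scenario metrics, aggregate summaries, EAB
#' tables and a run log (config hash, seed, package version) when `out_dir`
#' is given. A stage failure aborts with the scenario id.
#'
#' @param study A `synthetic_study`, or a list with `scenarios` and
#'   `manifest` as returned by [read_study()].
#' @param config Configuration list.
#' @param out_dir Optional output directory.
#' @param eab_metrics Metric columns to classify with the EAB analysis.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return A list: `metrics` (per-scenario `data.frame`), `aggregate`,
#'   `eab` (one [eab_table()] per requested metric), `buffer`
#'   ([buffer_table()] on mean lane position).
#' @export
run_pipeline <- function(study, config = default_config(), out_dir = NULL,
                         eab_metrics = c("lane_mean_cm", "gaze_mean",
                                         "phase_duration_s"),
                         seed = NA) {
  validate_config(config)
  manifest <- study$manifest
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$scenario[i]
    sc <- study$scenarios[[id]]
    rows[[i]] <- tryCatch(
      scenario_metrics(sc$gaze, sc$drive,
                       subject = manifest$subject[i],
                       condition = manifest$condition[i],
                       intersection = manifest$intersection[i],
                       config = config),
      error = function(e) stop("metrics stage failed for scenario '", id,
                               "': ", conditionMessage(e)))
  }
  metrics <- do.call(rbind, rows)
  agg <- aggregate_metrics(metrics)
  eab <- lapply(eab_metrics, function(m) eab_table(metrics, m))
  names(eab) <- eab_metrics
  buf <- buffer_table(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "scenario_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(agg$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(first_scan_30 = agg$first_scan_30,
           first_scan_45 = agg$first_scan_45,
           missing_scans = agg$missing_scans,
           lane_crossings = agg$lane_crossings,
           buffer = buf,
           eab_counts = lapply(eab, `[[`, "counts")),
      file.path(out_dir, "summaries.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "config_used.yaml")
    yaml::write_yaml(config, cfg_path)
    log <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                seed = seed,
                n_scenarios = nrow(metrics),
                package_version = as.character(utils::packageVersion("hemigaze")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE)
  }
  list(metrics = metrics, aggregate = agg, eab = eab, buffer = buf)
}
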