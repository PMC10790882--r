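#' Segment an intersection approach into its deceleration phase
#'
#' The analysis window runs from the first brake activation found within the
#' search distance of the intersection to the moment the zebra crossing
#' (distance zero) is reached. If the brake is never pressed inside the
#' search distance, the window starts at the fallback distance instead,
#' which corresponds to a typical deceleration onset 3 s before an
#' intersection at the urban speed limit.
#'
#' @param drive Driving stream `data.frame` with `time_s`, `dist_m`
#'   (distance to the intersection, non-increasing to 0), `brake` (logical),
#'   and `speed_kmh`.
#' @param search_dist_m Brake search distance, metres.
#' @param fallback_dist_m Fallback window start, metres.
#' @return A list of class `scenario_window`: `t_start`, `t_end`, `trigger`
#'   (`"brake"` or `"fallback"`), and `brake_dist_m` (distance at first
#'   braking, `NA` for fallback).
#' @export
segment_deceleration <- function(drive, search_dist_m = 100,
                                 fallback_dist_m = 41.76) {
  drive <- as_drive_stream(drive)
  i_end <- which(drive$dist_m <= 0)[1]
  if (is.na(i_end)) stop("approach never reaches the intersection (dist 0)")
  hit <- which(drive$brake & drive$dist_m <= search_dist_m &
                 drive$dist_m > 0)[1]
  if (!is.na(hit) && drive$time_s[hit] < drive$time_s[i_end]) {
    w <- list(t_start = drive$time_s[hit], t_end = drive$time_s[i_end],
              trigger = "brake", brake_dist_m = drive$dist_m[hit])
  } else {
    j <- which(drive$dist_m <= fallback_dist_m)[1]
    if (is.na(j)) stop("approach never reaches the fallback distance (",
                       fallback_dist_m, " m)")
    w <- list(t_start = drive$time_s[j], t_end = drive$time_s[i_end],
              trigger = "fallback", brake_dist_m = NA_real_)
  }
  structure(w, class = "scenario_window")
}

## subset a stream to the closed window [t_start, t_end]
clip_window <- function(stream, window) {
  stream[stream$time_s >= window$t_start & stream$time_s <= window$t_end, ,
         drop = FALSE]
}

#' Lateral lane-keeping metrics over a window
#'
#' @param drive Driving stream already clipped to the analysis window.
#' @param boundary_cm Unsigned lane-offset magnitude beyond which the vehicle
#'   is counted as crossing a lane boundary. Default 85 cm =
#'   (3.5 m lane - 1.8 m vehicle) / 2.
#' @return A list: `lane_mean_cm`, `lane_var` (sample variance, cm^2),
#'   `lane_crossings` (entries into the out-of-lane region, counted on
#'   upward crossings of the boundary only).
#' @export
lane_metrics <- function(drive, boundary_cm = 85) {
  x <- drive$lane_offset_cm
  stopifnot(length(x) >= 1L)
  outside <- abs(x) > boundary_cm
  entries <- sum(outside[-1] & !outside[-length(outside)]) +
    as.integer(outside[1])
  list(lane_mean_cm = mean(x),
       lane_var = if (length(x) > 1L) stats::var(x) else 0,
       lane_crossings = entries)
}

#' Side of the first large peripheral scan
#'
#' @param gaze Preprocessed gaze stream clipped to the window.
#' @param threshold_deg Minimum gaze eccentricity, degrees (30 or 45).
#' @return `"left"`, `"right"`, or `"none"`.
#' @export
first_peripheral_scan <- function(gaze, threshold_deg = 30) {
  az <- usable_az(gaze)
  i <- which(abs(az) >= threshold_deg)[1]
  if (is.na(i)) "none" else if (az[i] < 0) "left" else "right"
}

## azimuths that enter gaze statistics: unexcluded, filtered where available
usable_az <- function(gaze) {
  az <- az_column(gaze)
  excl <- if ("excluded" %in% names(gaze)) gaze$excluded else rep(FALSE, length(az))
  az[!excl & is.finite(az)]
}

#' Missing large scans toward each periphery
#'
#' A side is flagged missing when the gaze never reaches the criterion
#' eccentricity toward it during the window — the eccentricity needed to
#' perceive approaching same-speed hazards.
#'
#' @param gaze Preprocessed gaze stream clipped to the window.
#' @param threshold_deg Criterion eccentricity, degrees.
#' @return `list(left =, right =)` logicals.
#' @export
missing_large_scans <- function(gaze, threshold_deg = 45) {
  az <- usable_az(gaze)
  list(left = !any(az <= -threshold_deg), right = !any(az >= threshold_deg))
}

#' Summary statistics of horizontal gaze position
#'
#' @param gaze Preprocessed gaze stream clipped to the window.
#' @return `list(gaze_var, gaze_mean, gaze_min, gaze_max)` (sample variance,
#'   n-1 denominator); all `NA` with fewer than 2 usable samples.
#' @export
gaze_summary <- function(gaze) {
  az <- usable_az(gaze)
  if (length(az) < 2L)
    return(list(gaze_var = NA_real_, gaze_mean = NA_real_,
                gaze_min = NA_real_, gaze_max = NA_real_))
  list(gaze_var = stats::var(az), gaze_mean = mean(az),
       gaze_min = min(az), gaze_max = max(az))
}

#' Hemispace fixation counts and durations
#'
#' Fixations beyond the central band (mean azimuth below -5 or above +5
#' degrees for the default 10 degree band) are assigned to the left or right
#' hemispace; central fixations count toward neither.
#'
#' @param fixations Output of [detect_fixations()].
#' @param central_deg Width of the excluded central band, degrees.
#' @return `list(fix_n_left, fix_n_right, fix_dur_left, fix_dur_right)`;
#'   mean durations are `NA` for an absent side.
#' @export
hemispace_fixations <- function(fixations, central_deg = 10) {
  half <- central_deg / 2
  l <- fixations$mean_az_deg < -half
  r <- fixations$mean_az_deg > half
  list(fix_n_left = sum(l), fix_n_right = sum(r),
       fix_dur_left = if (any(l)) mean(fixations$duration_s[l]) else NA_real_,
       fix_dur_right = if (any(r)) mean(fixations$duration_s[r]) else NA_real_)
}

#' Mean amplitude of peripheral saccades per direction
#'
#' A saccade counts toward a side when it moves in that direction and its
#' endpoint lies more than the eccentricity threshold into that hemifield;
#' a leftward saccade ending near the midline counts toward neither side.
#'
#' @param saccades Output of [detect_saccades()].
#' @param endpoint_min_deg Minimum endpoint eccentricity, degrees.
#' @return `list(sacc_amp_left, sacc_amp_right)` mean amplitudes (degrees),
#'   `NA` for an empty class.
#' @export
directional_saccades <- function(saccades, endpoint_min_deg = 5) {
  l <- saccades$direction == "left" &
    saccades$endpoint_az_deg < -endpoint_min_deg
  r <- saccades$direction == "right" &
    saccades$endpoint_az_deg > endpoint_min_deg
  list(sacc_amp_left = if (any(l)) mean(saccades$amplitude_deg[l]) else NA_real_,
       sacc_amp_right = if (any(r)) mean(saccades$amplitude_deg[r]) else NA_real_)
}

#' Compute all scenario metrics for one intersection approach
#'
#' Runs preprocessing on the gaze stream, segments the deceleration phase on
#' the driving stream, clips both streams to the closed window (gaze at
#' 60 Hz and driving at 240 Hz are aligned by timestamp), detects events,
#' and assembles the full per-scenario metric record.
#'
#' @param gaze Raw gaze stream for the approach.
#' @param drive Driving stream for the approach.
#' @param subject,condition,intersection Scenario identifiers (`condition`
#'   in NV/LHH/RHH, `intersection` in SCI/LTI/RTI).
#' @param config A [default_config()]-style configuration list.
#' @return One-row `data.frame` of class `scenario_metrics`.
#' @export
scenario_metrics <- function(gaze, drive, subject = NA, condition = NA,
                             intersection = NA, config = default_config()) {
  th <- config$thresholds
  g <- preprocess_gaze(gaze, excluded_aois = config$excluded_aois,
                       cfg = filter_config(config$filter$cutoff_hz,
                                           config$filter$order,
                                           config$filter$sample_rate_hz,
                                           config$filter$zero_phase))
  w <- segment_deceleration(drive, th$brake_search_dist_m, th$fallback_dist_m)
  dw <- clip_window(drive, w)
  gw <- clip_window(g, w)
  fx <- detect_fixations(gw, th$fix_dispersion_deg, th$fix_min_dur_s,
                         th$fix_max_speed_deg_s, th$central_deg)
  sc <- detect_saccades(gw, th$sacc_min_speed_deg_s)
  lane <- lane_metrics(dw, config$lane$boundary_cm)
  gs <- gaze_summary(gw)
  hs <- hemispace_fixations(fx, th$central_deg)
  ds <- directional_saccades(sc, th$sacc_endpoint_min_deg)
  ms <- missing_large_scans(gw, th$large_scan_deg)
  res <- data.frame(
    subject = subject, condition = condition, intersection = intersection,
    trigger = w$trigger, brake_dist_m = w$brake_dist_m,
    phase_duration_s = w$t_end - w$t_start,
    lane_mean_cm = lane$lane_mean_cm, lane_var = lane$lane_var,
    lane_crossings = lane$lane_crossings,
    first_scan_30 = first_peripheral_scan(gw, th$first_scan_deg),
    first_scan_45 = first_peripheral_scan(gw, th$large_scan_deg),
    missing_scan_left = ms$left, missing_scan_right = ms$right,
    gaze_var = gs$gaze_var, gaze_mean = gs$gaze_mean,
    gaze_min = gs$gaze_min, gaze_max = gs$gaze_max,
    n_fixations = nrow(fx), n_saccades = nrow(sc),
    fix_n_left = hs$fix_n_left, fix_n_right = hs$fix_n_right,
    fix_dur_left = hs$fix_dur_left, fix_dur_right = hs$fix_dur_right,
    sacc_amp_left = ds$sacc_amp_left, sacc_amp_right = ds$sacc_amp_right,
    stringsAsFactors = FALSE)
  class(res) <- c("scenario_metrics", class(res))
  res
}

#' Count as a percentage, rounded half-up to two decimals
#'
#' @param k,K Numerator and denominator counts, `0 <= k <= K`.
#' @return `100 * k / K` rounded half-up to two decimals; `NA` when `K` is 0.
#' @export
percentage <- function(k, K) {
  if (any(K == 0, na.rm = TRUE)) {
    out <- rep(NA_real_, max(length(k), length(K)))
    ok <- K != 0
    out[ok] <- percentage(rep_len(k, length(out))[ok],
                          rep_len(K, length(out))[ok])
    return(out)
  }
  stopifnot(all(k >= 0), all(k <= K))
  floor(100 * k / K * 100 + 0.5 + sqrt(.Machine$double.eps)) / 100
}

#' Aggregate scenario metrics to condition-level summaries
#'
#' @param records `data.frame` of rows from [scenario_metrics()].
#' @return A list: `summary` (mean/SD of each numeric metric per condition x
#'   intersection, long format), `first_scan_30`/`first_scan_45` (side counts
#'   per condition with percentages), `missing_scans` (per-condition and
#'   pooled counts with percentages), `lane_crossings` (scenarios with at
#'   least one crossing, per condition).
#' @export
aggregate_metrics <- function(records) {
  stopifnot(nrow(records) > 0)
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      c("subject"))
  key <- interaction(records$condition, records$intersection, drop = TRUE)
  summ <- do.call(rbind, lapply(levels(key), function(kk) {
    sub <- records[key == kk, , drop = FALSE]
    do.call(rbind, lapply(num_cols, function(cl) {
      x <- sub[[cl]]
      data.frame(condition = sub$condition[1], intersection = sub$intersection[1],
                 metric = cl, mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE),
                 n = sum(is.finite(x)), stringsAsFactors = FALSE)
    }))
  }))
  side_table <- function(col) {
    tab <- table(records$condition, records[[col]])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("condition", "side", "k")
    Kc <- table(records$condition)
    df$K <- as.integer(Kc[df$condition])
    df$pct <- percentage(df$k, df$K)
    df
  }
  miss_table <- local({
    K <- nrow(records)
    per <- do.call(rbind, lapply(split(records, records$condition), function(s)
      data.frame(condition = s$condition[1],
                 missing_left = sum(s$missing_scan_left),
                 missing_right = sum(s$missing_scan_right),
                 K = nrow(s), stringsAsFactors = FALSE)))
    pooled <- data.frame(condition = "all",
                         missing_left = sum(records$missing_scan_left),
                         missing_right = sum(records$missing_scan_right),
                         K = K, stringsAsFactors = FALSE)
    out <- rbind(per, pooled)
    out$pct_left <- percentage(out$missing_left, out$K)
    out$pct_right <- percentage(out$missing_right, out$K)
    rownames(out) <- NULL
    out
  })
  cross <- do.call(rbind, lapply(split(records, records$condition), function(s)
    data.frame(condition = s$condition[1],
               scenarios_with_crossing = sum(s$lane_crossings > 0),
               total_crossings = sum(s$lane_crossings),
               K = nrow(s), stringsAsFactors = FALSE)))
  rownames(cross) <- NULL
  list(summary = summ,
       first_scan_30 = side_table("first_scan_30"),
       first_scan_45 = side_table("first_scan_45"),
       missing_scans = miss_table,
       lane_crossings = cross)
}
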