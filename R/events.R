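## sampling period estimate; robust to occasional gaps
sample_period <- function(time_s) {
  if (length(time_s) < 2L) return(NA_real_)
  stats::median(diff(time_s))
}

#' Angular speed of the horizontal gaze signal
#'
#' Central differences on the (filtered) azimuth, one-sided at the ends;
#' returns absolute angular speed in degrees per second.
#'
#' @param time_s Sample times, strictly increasing, seconds.
#' @param az_deg Azimuth samples, degrees.
#' @return Numeric vector of |angular speed|, same length as the input.
#' @export
gaze_velocity <- function(time_s, az_deg) {
  n <- length(time_s)
  stopifnot(n >= 3L, length(az_deg) == n)
  if (any(diff(time_s) <= 0)) stop("duplicate or non-increasing timestamps")
  v <- numeric(n)
  v[1] <- (az_deg[2] - az_deg[1]) / (time_s[2] - time_s[1])
  v[n] <- (az_deg[n] - az_deg[n - 1]) / (time_s[n] - time_s[n - 1])
  i <- 2:(n - 1)
  v[i] <- (az_deg[i + 1] - az_deg[i - 1]) / (time_s[i + 1] - time_s[i - 1])
  abs(v)
}

## maximal runs of unexcluded samples, as a list of index vectors
unexcluded_runs <- function(excluded, min_len = 1L) {
  r <- rle(!excluded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  mapply(function(s, e) s:e, starts[keep], ends[keep], SIMPLIFY = FALSE)
}

az_column <- function(gaze) {
  if ("az_filt" %in% names(gaze)) gaze$az_filt else gaze$az_deg
}

hemifield_of <- function(mean_az, central_deg = 10) {
  half <- central_deg / 2
  ifelse(mean_az < -half, "left", ifelse(mean_az > half, "right", "central"))
}

#' Detect fixations by dispersion and velocity thresholds
#'
#' A fixation is a maximal stretch of gaze in which the horizontal position
#' stays within the dispersion threshold over at least the minimum duration
#' and sample speed never reaches the velocity bound (I-DT-style detector
#' with a conjunctive velocity check). A window seeds at the smallest run of
#' samples whose covered time reaches `min_dur_s` (each sample covers one
#' frame period, so duration = t_end - t_start + period) and extends
#' rightward while both conditions hold. Excluded samples terminate events.
#'
#' @param gaze Preprocessed gaze stream (`time_s`, `az_filt`/`az_deg`,
#'   optional `excluded`).
#' @param dispersion_deg Maximum within-event horizontal position range.
#' @param min_dur_s Minimum fixation duration, seconds.
#' @param max_speed_deg_s Sample speeds must stay strictly below this bound.
#' @param central_deg Width of the central band used for hemifield labels.
#' @return `data.frame(t_start, t_end, duration_s, mean_az_deg, hemifield)`.
#' @export
detect_fixations <- function(gaze, dispersion_deg = 2, min_dur_s = 0.120,
                             max_speed_deg_s = 30, central_deg = 10) {
  gaze <- as_gaze_stream(gaze)
  az_all <- az_column(gaze)
  excl <- if ("excluded" %in% names(gaze)) gaze$excluded else rep(FALSE, nrow(gaze))
  out <- list()
  for (idx in unexcluded_runs(excl, min_len = 3L)) {
    t <- gaze$time_s[idx]
    az <- az_all[idx]
    dt <- sample_period(t)
    v <- gaze_velocity(t, az)
    n <- length(t)
    i <- 1L
    while (i <= n) {
      # seed: smallest j with covered time >= min_dur_s
      j <- i
      while (j <= n && (t[j] - t[i] + dt) < min_dur_s - 1e-9) j <- j + 1L
      if (j > n) break
      w <- az[i:j]
      if ((max(w) - min(w)) <= dispersion_deg && all(v[i:j] < max_speed_deg_s)) {
        lo <- min(w); hi <- max(w)
        while (j < n) {
          nlo <- min(lo, az[j + 1L]); nhi <- max(hi, az[j + 1L])
          if ((nhi - nlo) > dispersion_deg || v[j + 1L] >= max_speed_deg_s) break
          j <- j + 1L; lo <- nlo; hi <- nhi
        }
        m <- mean(az[i:j])
        out[[length(out) + 1L]] <- data.frame(
          t_start = t[i], t_end = t[j], duration_s = t[j] - t[i] + dt,
          mean_az_deg = m, hemifield = hemifield_of(m, central_deg))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0), mean_az_deg = numeric(0),
                      hemifield = character(0)))
  do.call(rbind, out)
}

#' Detect saccades by a velocity threshold
#'
#' Saccades are maximal runs of samples whose angular speed reaches the
#' minimum rotation velocity. Amplitude is the absolute horizontal
#' displacement between the first and last sample of the run; direction is
#' the sign of that displacement and `endpoint_az_deg` the azimuth at the
#' run's last sample. Excluded samples break runs.
#'
#' @param gaze Preprocessed gaze stream.
#' @param min_speed_deg_s Velocity threshold, degrees per second.
#' @return `data.frame(t_start, t_end, amplitude_deg, direction,
#'   endpoint_az_deg, peak_speed_deg_s)`.
#' @export
detect_saccades <- function(gaze, min_speed_deg_s = 90) {
  gaze <- as_gaze_stream(gaze)
  az_all <- az_column(gaze)
  excl <- if ("excluded" %in% names(gaze)) gaze$excluded else rep(FALSE, nrow(gaze))
  out <- list()
  for (idx in unexcluded_runs(excl, min_len = 3L)) {
    t <- gaze$time_s[idx]
    az <- az_all[idx]
    v <- gaze_velocity(t, az)
    fast <- v >= min_speed_deg_s
    r <- rle(fast)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      d <- az[b] - az[a]
      out[[length(out) + 1L]] <- data.frame(
        t_start = t[a], t_end = t[b], amplitude_deg = abs(d),
        direction = if (d < 0) "left" else "right",
        endpoint_az_deg = az[b], peak_speed_deg_s = max(v[a:b]))
    }
  }
  if (!length(out))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      amplitude_deg = numeric(0), direction = character(0),
                      endpoint_az_deg = numeric(0),
                      peak_speed_deg_s = numeric(0)))
  do.call(rbind, out)
}
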