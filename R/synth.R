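#' Per-condition scanning profile for the synthetic study
#'
#' Defaults emulate the direction of the reported condition effects: longer
#' fixations and smaller saccadic amplitudes under left-sided loss (LHH),
#' a rightward mean-gaze bias under right-sided loss (RHH), and reduced
#' probabilities of large (>= 45 degree) peripheral scans under LHH on both
#' sides. Magnitudes are plausible free parameters of the generator, not
#' reproduction targets.
#'
#' @param condition `"NV"`, `"LHH"` or `"RHH"` (selects the defaults), or
#'   any label when all parameters are given explicitly.
#' @param fix_dur_mean,fix_dur_sd Mean and SD of fixation duration, seconds.
#' @param sacc_amp_mean,sacc_amp_sd Mean and SD of saccade amplitude, deg.
#' @param gaze_bias_deg Mean horizontal gaze eccentricity, degrees
#'   (negative = left).
#' @param p_large_scan_left,p_large_scan_right Probability that a scenario
#'   contains a >= 45 degree scan toward that side.
#' @param blink_rate_per_min Blink events per minute (blink suppression
#'   under high visual demand keeps this below resting rates).
#' @param dropout_rate Fraction of samples with tracker signal loss.
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(condition = c("NV", "LHH", "RHH"),
                              fix_dur_mean = NULL, fix_dur_sd = NULL,
                              sacc_amp_mean = NULL, sacc_amp_sd = NULL,
                              gaze_bias_deg = NULL,
                              p_large_scan_left = NULL,
                              p_large_scan_right = NULL,
                              blink_rate_per_min = 6,
                              dropout_rate = 0.02) {
  condition <- match.arg(condition)
  def <- switch(condition,
    NV  = list(fd = 0.26, fs = 0.10, am = 30, as = 10, bias = -2.5,
               pl = 0.89, pr = 0.75),
    LHH = list(fd = 0.33, fs = 0.15, am = 20, as = 10, bias = -1.9,
               pl = 0.68, pr = 0.57),
    RHH = list(fd = 0.31, fs = 0.12, am = 28, as = 12, bias = 3.4,
               pl = 0.84, pr = 0.70))
  p <- list(condition = condition,
            fix_dur_mean = fix_dur_mean %||% def$fd,
            fix_dur_sd = fix_dur_sd %||% def$fs,
            sacc_amp_mean = sacc_amp_mean %||% def$am,
            sacc_amp_sd = sacc_amp_sd %||% def$as,
            gaze_bias_deg = gaze_bias_deg %||% def$bias,
            p_large_scan_left = p_large_scan_left %||% def$pl,
            p_large_scan_right = p_large_scan_right %||% def$pr,
            blink_rate_per_min = blink_rate_per_min,
            dropout_rate = dropout_rate)
  stopifnot(p$fix_dur_mean > 0.12, p$fix_dur_sd >= 0,
            p$sacc_amp_mean > 0, p$sacc_amp_sd >= 0,
            p$p_large_scan_left >= 0, p$p_large_scan_left <= 1,
            p$p_large_scan_right >= 0, p$p_large_scan_right <= 1,
            p$dropout_rate >= 0, p$dropout_rate < 1)
  structure(p, class = "condition_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default condition profiles for the synthetic study
#' @return Named list of [condition_profile()] objects for NV, LHH, RHH.
#' @export
default_profiles <- function() {
  list(NV = condition_profile("NV"), LHH = condition_profile("LHH"),
       RHH = condition_profile("RHH"))
}

#' Driving-trace profile for the synthetic study
#'
#' @param approach_speed_kmh Cruise speed before braking (urban limit).
#' @param brake_onset_dist_m Distance at which braking starts; `NA` for an
#'   approach with no brake activation.
#' @param lane_offset_mean_cm Mean lane offset (negative = left of centre).
#' @param lane_ar1_phi,lane_noise_sd_cm AR(1) parameters of the lane-offset
#'   process at the driving sample rate.
#' @param crossing_boundary_cm Lane-crossing boundary.
#' @param start_dist_m Distance at which the approach trace begins.
#' @param end_speed_kmh Residual speed when reaching the zebra crossing.
#' @param cross_traffic_period_s Period of crossing traffic at the
#'   intersection (scene parameter, carried for completeness).
#' @return An object of class `drive_profile`.
#' @export
drive_profile <- function(approach_speed_kmh = 50, brake_onset_dist_m = 60,
                          lane_offset_mean_cm = -17, lane_ar1_phi = 0.999,
                          lane_noise_sd_cm = 0.9, crossing_boundary_cm = 85,
                          start_dist_m = 150, end_speed_kmh = 7,
                          cross_traffic_period_s = 9) {
  stopifnot(approach_speed_kmh > 0, abs(lane_ar1_phi) < 1,
            is.na(brake_onset_dist_m) || brake_onset_dist_m <= start_dist_m)
  structure(list(approach_speed_kmh = approach_speed_kmh,
                 brake_onset_dist_m = brake_onset_dist_m,
                 lane_offset_mean_cm = lane_offset_mean_cm,
                 lane_ar1_phi = lane_ar1_phi,
                 lane_noise_sd_cm = lane_noise_sd_cm,
                 crossing_boundary_cm = crossing_boundary_cm,
                 start_dist_m = start_dist_m,
                 end_speed_kmh = end_speed_kmh,
                 cross_traffic_period_s = cross_traffic_period_s),
            class = "drive_profile")
}

## location parameter for a normal truncated to [lo, hi] so that the
## truncated mean equals the requested arithmetic mean
trunc_norm_location <- function(target, s, lo = 5, hi = 75) {
  if (s == 0) return(max(lo, min(hi, target)))
  tmean <- function(mu) {
    al <- (lo - mu) / s; be <- (hi - mu) / s
    mu + s * (stats::dnorm(al) - stats::dnorm(be)) /
      (stats::pnorm(be) - stats::pnorm(al))
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 c(target - 4 * s, target + s), extendInt = "yes")$root
}

## number of samples (inclusive of both endpoint samples) spanned by a
## constant-velocity saccade of amplitude a at rate_hz. Transit velocity is
## held near 600 deg/s -- close to the representable limit at 60 Hz -- so
## that the 10 Hz analysis filter, not the generator kinematics, determines
## the detector's velocity profile, and the implied speed stays far above
## twice the 90 deg/s detection threshold
saccade_n_samples <- function(a, rate_hz = 60) {
  dt <- 1 / rate_hz
  pmax(2L, as.integer(round(a / (600 * dt))) + 1L)
}

## shifted-lognormal fixation duration with arithmetic mean m and sd s
rfixdur <- function(n, m, s, shift = 0.15) {
  mu_arith <- m - shift
  stopifnot(mu_arith > 0)
  if (s == 0) return(rep(m, n))
  sig2 <- log(1 + s^2 / mu_arith^2)
  shift + stats::rlnorm(n, log(mu_arith) - sig2 / 2, sqrt(sig2))
}

## snap fixation positions out of the guard band around the 30 deg
## first-scan criterion so plateau noise cannot straddle it
snap_guard <- function(pos, lo = 27.5, hi = 32.5) {
  a <- abs(pos)
  in_band <- a > lo & a < hi
  a[in_band] <- ifelse(a[in_band] < (lo + hi) / 2, lo, hi)
  ifelse(pos < 0, -a, a)
}

#' Generate a synthetic gaze scanpath with planted events
#'
#' Builds an alternating fixation/saccade trajectory: fixation durations are
#' shifted-lognormal at the profile mean/SD; fixation positions follow a
#' mean-reverting walk around the profile's gaze bias with saccade
#' amplitudes drawn from the profile's amplitude distribution, confined to
#' +/-40 degrees except for scheduled peripheral excursions beyond 50
#' degrees that realise the profile's large-scan probabilities. Saccades are
#' constant-velocity ramps laid out on the sample grid with main-sequence
#' durations (about 25 ms + 2.5 ms per degree, capped so transit velocity
#' stays well above twice the 90 deg/s detection threshold); endpoint
#' samples sit exactly on the flanking fixation positions so planted
#' durations and amplitudes are sample-exact. Gaussian position noise,
#' blinks and tracker dropouts
#' are injected at the profile rates; the head-gaze channel is a 2 Hz
#' low-passed copy of the eye signal. Identical seeds give identical output.
#'
#' @param profile A [condition_profile()].
#' @param duration_s Stream duration, seconds (>= 1).
#' @param seed Integer seed for all randomness in this stream.
#' @param rate_hz Sampling rate.
#' @param noise_sd_deg SD of per-sample position noise, degrees.
#' @param n_fixations If given, generate exactly this many fixations and
#'   derive the duration instead.
#' @return A list: `gaze` (stream `data.frame`), `events` (planted fixation
#'   and saccade list), `profile`.
#' @export
generate_scanpath <- function(profile, duration_s = 10, seed = 1,
                              rate_hz = 60, noise_sd_deg = 0.3,
                              n_fixations = NULL) {
  stopifnot(inherits(profile, "condition_profile"),
            duration_s >= 1 || !is.null(n_fixations))
  set.seed(as.integer(seed))
  bias <- profile$gaze_bias_deg

  ## saccade amplitudes: normal truncated to [5, 75] degrees with the
  ## location adjusted so the truncated mean equals the profile mean
  amp_mu <- trunc_norm_location(profile$sacc_amp_mean, profile$sacc_amp_sd)
  draw_amp <- function() {
    if (profile$sacc_amp_sd == 0) return(amp_mu)
    repeat {
      a <- stats::rnorm(1, amp_mu, profile$sacc_amp_sd)
      if (a >= 5 && a <= 75) return(a)
    }
  }

  ## --- plan the fixation sequence -------------------------------------
  want_left <- stats::runif(1) < profile$p_large_scan_left
  want_right <- stats::runif(1) < profile$p_large_scan_right
  # excursions launch in the later part of the stream (approach phase)
  exc_times <- c(if (want_left) stats::runif(1, 0.45, 0.75) else NULL,
                 if (want_right) stats::runif(1, 0.75, 0.95) else NULL)
  exc_sides <- c(if (want_left) -1 else NULL, if (want_right) 1 else NULL)
  horizon <- if (!is.null(n_fixations)) Inf else duration_s

  box_c <- max(-4, min(4, bias))   # box centre (biases beyond +/-4 clamped)
  box_h <- 36                      # box half-width, keeps |pos| <= 40
  pos <- snap_guard(max(box_c - box_h,
                        min(box_c + box_h, bias + stats::rnorm(1, 0, 8))))
  fix_pos <- pos
  fix_dur <- rfixdur(1, profile$fix_dur_mean, profile$fix_dur_sd)
  t_cum <- fix_dur
  mode <- "central"; exc_done <- 0L; exc_target <- NA_real_
  while ((is.null(n_fixations) && t_cum < horizon) ||
         (!is.null(n_fixations) && length(fix_pos) < n_fixations)) {
    frac <- if (is.finite(horizon)) t_cum / horizon else 1
    if (mode == "central" && exc_done < length(exc_times) &&
        is.null(n_fixations) && frac >= exc_times[exc_done + 1L]) {
      mode <- "excursion"
      exc_target <- exc_sides[exc_done + 1L] * stats::runif(1, 52, 78)
    }
    a <- draw_amp()
    if (mode == "excursion") {
      dir <- sign(exc_target - pos)
      new <- pos + dir * a
      if (abs(new) >= abs(exc_target)) new <- exc_target   # arrived (cap)
      pos <- new
      if (abs(pos) >= 50) {                                # excursion done
        mode <- "return"; exc_done <- exc_done + 1L
      }
    } else if (mode == "return") {
      dir <- sign(box_c - pos)
      new <- pos + dir * a
      if (abs(new - box_c) <= box_h) { pos <- snap_guard(new); mode <- "central" }
      else pos <- new
    } else {
      ## reflecting walk in a box centred on the gaze bias: the symmetric
      ## box keeps the stationary mean at the bias itself
      target <- box_c + stats::rnorm(1, 0, 12)
      dir <- if (target >= pos) 1 else -1
      new <- pos + dir * a
      if (abs(new - box_c) > box_h) new <- pos - dir * a
      if (abs(new - box_c) > box_h)
        new <- pos - sign(pos - box_c) * min(a, box_h + abs(pos - box_c))
      pos <- snap_guard(new)
    }
    fix_pos <- c(fix_pos, pos)
    d <- rfixdur(1, profile$fix_dur_mean, profile$fix_dur_sd)
    fix_dur <- c(fix_dur, d)
    t_cum <- t_cum + d + 0.05            # rough saccade allowance
    if (length(fix_pos) > 5000) break
  }

  ## --- lay out the sample grid ----------------------------------------
  ## fixations occupy whole frame periods; each transition is a
  ## constant-velocity ramp whose first and last samples sit exactly on the
  ## flanking fixation positions, so planted durations and amplitudes are
  ## recoverable sample-exactly by the threshold detector
  dt <- 1 / rate_hz
  nf <- length(fix_pos)
  az <- numeric(0)
  ev <- list()
  i_cur <- 0L
  for (k in seq_len(nf)) {
    n1 <- max(8L, as.integer(round(fix_dur[k] / dt)))
    ev[[length(ev) + 1L]] <- data.frame(
      type = "fixation", t_start = i_cur * dt,
      t_end = (i_cur + n1 - 1L) * dt, duration_s = n1 * dt,
      position_deg = fix_pos[k], amplitude_deg = NA_real_)
    az <- c(az, rep(fix_pos[k], n1))
    i_cur <- i_cur + n1
    if (k < nf) {
      amp <- abs(fix_pos[k + 1] - fix_pos[k])
      ns <- saccade_n_samples(amp, rate_hz)
      ramp <- fix_pos[k] + (fix_pos[k + 1] - fix_pos[k]) *
        (0:(ns - 1L)) / (ns - 1L)
      ev[[length(ev) + 1L]] <- data.frame(
        type = "saccade", t_start = i_cur * dt,
        t_end = (i_cur + ns - 1L) * dt, duration_s = ns * dt,
        position_deg = fix_pos[k + 1], amplitude_deg = amp)
      az <- c(az, ramp)
      i_cur <- i_cur + ns
    }
  }
  events <- do.call(rbind, ev)
  if (is.null(n_fixations)) {
    n <- as.integer(round(duration_s / dt))
    if (length(az) >= n) az <- az[1:n]
    else az <- c(az, rep(az[length(az)], n - length(az)))
  }
  n <- length(az)
  time_s <- (0:(n - 1L)) * dt
  total <- n * dt
  if (noise_sd_deg > 0) az <- az + stats::rnorm(n, 0, noise_sd_deg)

  ## blinks: short held-eyelid episodes labelled in the AOI channel
  aoi <- rep("front", n)
  n_blinks <- stats::rpois(1, profile$blink_rate_per_min * total / 60)
  if (n_blinks > 0) {
    bstart <- sort(stats::runif(n_blinks, 0, total - 0.2))
    for (b in bstart) {
      idx <- which(time_s >= b & time_s < b + 0.15)
      if (length(idx)) {
        aoi[idx] <- "blink"
        az[idx] <- az[idx[1]]            # lid closed: signal frozen
      }
    }
  }

  ## dropouts: short invalid runs at the profile rate
  valid <- rep(TRUE, n)
  n_runs <- round(profile$dropout_rate * n / 3)
  if (n_runs > 0) {
    rs <- sample.int(n, n_runs)
    for (r in rs) valid[r:min(n, r + sample(1:4, 1))] <- FALSE
  }

  ## head channel: the eye azimuth plus a slowly drifting error (AR(1),
  ## 2 degree stationary SD, ~1 s correlation time) -- less accurate but
  ## more stable than the eye signal, as a head-pose-derived direction is
  phi_h <- exp(-dt)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, 2)
  innov <- stats::rnorm(n, 0, 2 * sqrt(1 - phi_h^2))
  for (i in seq_len(n - 1L)) e[i + 1L] <- phi_h * e[i] + innov[i + 1L]
  head_az <- az + e
  gaze <- data.frame(time_s = time_s, az_deg = ifelse(valid, az, NA_real_),
                     el_deg = 0, valid = valid, head_az_deg = head_az,
                     aoi = aoi, stringsAsFactors = FALSE)
  list(gaze = gaze, events = events, profile = profile)
}

#' Generate a synthetic driving trace with planted window truth
#'
#' Speed holds at the approach speed, then decelerates uniformly from the
#' brake-onset distance so that the residual speed is reached at the zebra
#' crossing; distance integrates speed down to zero. Lane offset follows an
#' AR(1) process around the profile mean.
#'
#' @param profile A [drive_profile()].
#' @param seed Integer seed.
#' @param rate_hz Driving sample rate.
#' @return A list: `drive` (stream `data.frame`) and `truth`
#'   (`t_start`, `t_end`, `trigger`, `brake_dist_m`).
#' @export
generate_drive <- function(profile = drive_profile(), seed = 1,
                           rate_hz = 240) {
  stopifnot(inherits(profile, "drive_profile"))
  set.seed(as.integer(seed))
  dt <- 1 / rate_hz
  v0 <- profile$approach_speed_kmh / 3.6
  ve <- profile$end_speed_kmh / 3.6
  onset <- profile$brake_onset_dist_m
  n_max <- ceiling(profile$start_dist_m / ve / dt) + 10L
  tt <- dd <- vv <- numeric(n_max)
  bb <- logical(n_max)
  dist <- profile$start_dist_m
  v <- v0
  braking <- FALSE
  t <- 0
  i <- 0L
  while (dist > 0 && i < n_max - 1L) {
    if (!is.na(onset) && !braking && dist <= onset) braking <- TRUE
    i <- i + 1L
    tt[i] <- t; dd[i] <- dist; vv[i] <- v; bb[i] <- braking
    if (braking) {
      a <- (v0^2 - ve^2) / (2 * onset)
      v <- max(ve, v - a * dt)
    }
    dist <- dist - v * dt
    t <- t + dt
  }
  i <- i + 1L
  tt[i] <- t; dd[i] <- max(0, dist); vv[i] <- v; bb[i] <- braking
  n <- i
  tt <- tt[1:n]; dd <- dd[1:n]; vv <- vv[1:n]; bb <- bb[1:n]
  lane <- numeric(n)
  lane[1] <- profile$lane_offset_mean_cm +
    stats::rnorm(1, 0, profile$lane_noise_sd_cm /
                   sqrt(max(1e-12, 1 - profile$lane_ar1_phi^2)))
  if (profile$lane_noise_sd_cm == 0 && profile$lane_ar1_phi == 0)
    lane[1] <- profile$lane_offset_mean_cm
  eps <- stats::rnorm(n, 0, profile$lane_noise_sd_cm)
  for (i in 2:n)
    lane[i] <- profile$lane_offset_mean_cm +
      profile$lane_ar1_phi * (lane[i - 1] - profile$lane_offset_mean_cm) +
      eps[i]
  drive <- data.frame(time_s = tt, dist_m = dd, lane_offset_cm = lane,
                      brake = bb, speed_kmh = vv * 3.6)
  i_brake <- which(bb & dd <= 100 & dd > 0)[1]
  if (!is.na(i_brake)) {
    truth <- list(t_start = tt[i_brake], t_end = tt[n], trigger = "brake",
                  brake_dist_m = dd[i_brake])
  } else {
    j <- which(dd <= 41.76)[1]
    truth <- list(t_start = tt[j], t_end = tt[n], trigger = "fallback",
                  brake_dist_m = NA_real_)
  }
  list(drive = drive, truth = truth)
}

## inline (generator-side) categorical truths over the window, computed
## directly from the raw generated samples
window_truths <- function(gaze, drive, truth, boundary_cm) {
  inwin <- function(t) t >= truth$t_start & t <= truth$t_end
  g <- gaze[inwin(gaze$time_s), , drop = FALSE]
  usable <- !(g$aoi %in% c("blink", "mirror", "media", "other")) &
    is.finite(g$az_deg)
  az <- g$az_deg[usable]
  first_side <- function(thr) {
    i <- which(abs(az) >= thr)[1]
    if (is.na(i)) "none" else if (az[i] < 0) "left" else "right"
  }
  x <- drive$lane_offset_cm[inwin(drive$time_s)]
  outside <- abs(x) > boundary_cm
  list(first_scan_30 = first_side(30), first_scan_45 = first_side(45),
       missing_scan_left = !any(az <= -45),
       missing_scan_right = !any(az >= 45),
       lane_crossings = sum(outside[-1] & !outside[-length(outside)]) +
         as.integer(outside[1]))
}

#' Generate a complete synthetic study
#'
#' Emulates the study layout: `n_subjects` x three vision conditions
#' (NV, LHH, RHH) x three intersection maneuvers (SCI, LTI, RTI), one gaze
#' and one driving stream per scenario, with a manifest of all planted
#' quantities. Subject/scenario seeds are derived deterministically from
#' `master_seed`. Straight-crossing approaches under normal vision have a
#' small chance of no brake activation, mirroring such cases in real
#' approaches; all other scenarios brake within the search distance.
#'
#' @param n_subjects Number of subjects.
#' @param profiles Named list of [condition_profile()]s for NV, LHH, RHH.
#' @param dprofile Base [drive_profile()].
#' @param master_seed Master seed (kept below 2^31 internally).
#' @param noise_sd_deg Gaze position noise SD, degrees.
#' @return A list of class `synthetic_study`: `scenarios` (named list with
#'   `gaze`, `drive`, `events` per scenario) and `manifest` (`data.frame`
#'   of ids, seeds, window truth, categorical truths and profile
#'   parameters).
#' @export
generate_study <- function(n_subjects = 15, profiles = default_profiles(),
                           dprofile = drive_profile(), master_seed = 42,
                           noise_sd_deg = 0.3) {
  stopifnot(all(c("NV", "LHH", "RHH") %in% names(profiles)))
  conditions <- c("NV", "LHH", "RHH")
  intersections <- c("SCI", "LTI", "RTI")
  scenarios <- list()
  rows <- list()
  counter <- 0L
  set.seed(as.integer(master_seed) %% 2147483647L)
  subj_lane <- stats::rnorm(n_subjects, 0, 18)
  cond_lane <- c(NV = 0, LHH = 10, RHH = 1)
  for (s in seq_len(n_subjects)) for (cond in conditions)
    for (itype in intersections) {
      counter <- counter + 1L
      seed_sc <- (as.integer(master_seed) + 7919L * counter) %% 2147483647L
      set.seed(seed_sc)
      no_brake <- cond == "NV" && itype == "SCI" && stats::runif(1) < 0.1
      onset <- if (no_brake) NA_real_ else
        min(95, max(15, stats::rnorm(1, 60, 18)))
      dp <- dprofile
      dp$brake_onset_dist_m <- onset
      dp$lane_offset_mean_cm <- dprofile$lane_offset_mean_cm +
        subj_lane[s] + cond_lane[[cond]]
      dr <- generate_drive(dp, seed = seed_sc)
      dur <- max(dr$drive$time_s) + 1 / 240
      sp <- generate_scanpath(profiles[[cond]], duration_s = dur,
                              seed = seed_sc + 1L,
                              noise_sd_deg = noise_sd_deg)
      tr <- window_truths(sp$gaze, dr$drive, dr$truth,
                          dprofile$crossing_boundary_cm)
      id <- sprintf("S%02d_%s_%s", s, cond, itype)
      scenarios[[id]] <- list(gaze = sp$gaze, drive = dr$drive,
                              events = sp$events)
      rows[[counter]] <- data.frame(
        scenario = id, subject = s, condition = cond, intersection = itype,
        seed = seed_sc, t_start = dr$truth$t_start, t_end = dr$truth$t_end,
        trigger = dr$truth$trigger, brake_dist_m = dr$truth$brake_dist_m,
        first_scan_30 = tr$first_scan_30, first_scan_45 = tr$first_scan_45,
        missing_scan_left = tr$missing_scan_left,
        missing_scan_right = tr$missing_scan_right,
        lane_crossings = tr$lane_crossings,
        fix_dur_mean = profiles[[cond]]$fix_dur_mean,
        sacc_amp_mean = profiles[[cond]]$sacc_amp_mean,
        gaze_bias_deg = profiles[[cond]]$gaze_bias_deg,
        stringsAsFactors = FALSE)
    }
  structure(list(scenarios = scenarios, manifest = do.call(rbind, rows),
                 master_seed = master_seed),
            class = "synthetic_study")
}
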