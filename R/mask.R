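#' Three-panel rig geometry
#'
#' Describes a panoramic display of three flat panels, each tangent to a
#' circle centred on the eye point and subtending 60 degrees of azimuth, so
#' that together they tile the frontal 180 degree field of view. The vertical
#' half-angle of a panel follows from the pixel aspect ratio of the flat
#' tangent panel: `atan((H/W) * tan(panel_half_angle))`.
#'
#' @param panel_px_w,panel_px_h Panel resolution in pixels.
#' @param panel_half_angle Half of the azimuth range a panel subtends, degrees.
#' @param panel_center_azimuths Azimuths of the three panel centres, degrees.
#' @return An object of class `rig_geometry`.
#' @export
rig_geometry <- function(panel_px_w = 3400, panel_px_h = 2720,
                         panel_half_angle = 30,
                         panel_center_azimuths = c(-60, 0, 60)) {
  stopifnot(length(panel_center_azimuths) == 3L,
            panel_px_w > 0, panel_px_h > 0, panel_half_angle > 0)
  structure(list(
    panel_count = 3L,
    panel_px_w = panel_px_w,
    panel_px_h = panel_px_h,
    panel_half_angle = panel_half_angle,
    panel_center_azimuths = sort(panel_center_azimuths),
    vertical_half_angle =
      atan((panel_px_h / panel_px_w) * tan(panel_half_angle * pi / 180)) * 180 / pi
  ), class = "rig_geometry")
}

#' Hemianopic mask specification
#'
#' @param side Which hemifield is occluded, `"left"` or `"right"`.
#' @param fade_width_deg Width of the semitransparent linear fade between the
#'   fully masked and fully visible field, degrees of visual angle.
#' @param mask_color RGB triple of the occluding mask (default mid-gray,
#'   approximating road/building luminance).
#' @param update_rate_hz Nominal mask update rate.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(side = c("left", "right"), fade_width_deg = 4,
                      mask_color = c(128L, 128L, 128L), update_rate_hz = 60) {
  side <- match.arg(side)
  stopifnot(fade_width_deg >= 0, fade_width_deg < 180,
            length(mask_color) == 3L)
  structure(list(side = side, fade_width_deg = fade_width_deg,
                 mask_color = mask_color, update_rate_hz = update_rate_hz),
            class = "mask_spec")
}

#' Anchor smoothing policy
#'
#' A moving-window average stabilises the mask anchor against tracker noise;
#' the window is bypassed (and reset) for large gaze movements so that big
#' saccades relocate the mask within one frame, and the last valid anchor is
#' held on signal loss.
#'
#' @param window_len Moving-average window length in samples.
#' @param bypass_threshold_deg Gaze movement, degrees, above which the buffer
#'   is bypassed.
#' @param hold_on_invalid Hold the last output while the signal is invalid
#'   (always `TRUE`; kept explicit for the config file).
#' @return An object of class `buffer_policy`.
#' @export
buffer_policy <- function(window_len = 3L, bypass_threshold_deg = 10,
                          hold_on_invalid = TRUE) {
  stopifnot(window_len >= 1L, bypass_threshold_deg > 0, isTRUE(hold_on_invalid))
  structure(list(window_len = as.integer(window_len),
                 bypass_threshold_deg = bypass_threshold_deg,
                 hold_on_invalid = TRUE),
            class = "buffer_policy")
}

#' Convert gaze direction vectors to azimuth and elevation
#'
#' The gaze direction is a unit vector from the virtual eye position with
#' z pointing straight ahead, x rightward and y upward. Azimuth is the signed
#' horizontal angle (`atan2(x, z)`, negative = left); elevation is the angle
#' above the horizontal plane (`asin(y)`).
#'
#' @param x,y,z Components of the gaze direction vector(s).
#' @param valid Optional logical; vectors flagged invalid, or with a norm far
#'   from 1, yield an invalid result rather than an error (downstream
#'   hold-last handling applies).
#' @return `data.frame(az_deg, el_deg, valid)`.
#' @export
vector_to_azel <- function(x, y, z, valid = TRUE) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  valid <- rep_len(valid, n)
  norm <- sqrt(x^2 + y^2 + z^2)
  ok <- valid & is.finite(norm) & abs(norm - 1) < 1e-3 & norm > 0
  az <- el <- rep(NA_real_, n)
  az[ok] <- atan2(x[ok], z[ok]) * 180 / pi
  el[ok] <- asin(pmin(1, pmax(-1, y[ok] / norm[ok]))) * 180 / pi
  data.frame(az_deg = az, el_deg = el, valid = ok)
}

#' Convert azimuth/elevation back to a unit gaze vector
#'
#' Inverse of [vector_to_azel()]; used for round-trip checks.
#'
#' @param az_deg,el_deg Angles in degrees.
#' @return `data.frame(x, y, z)` unit vectors.
#' @export
azel_to_vector <- function(az_deg, el_deg) {
  az <- az_deg * pi / 180
  el <- el_deg * pi / 180
  data.frame(x = cos(el) * sin(az), y = sin(el), z = cos(el) * cos(az))
}

#' Map an azimuth/elevation to a panel pixel anchor
#'
#' Panels claim half-open azimuth sectors `[-90, -30)`, `[-30, 30)` and
#' `[30, 90]` (the right panel owns +30 exactly; +90 is included so the full
#' frontal field is covered). Within a panel the flat-tangent projection
#' gives
#' `px_x = W/2 * (1 + tan(az - center) / tan(half_angle))` and
#' `px_y = H/2 * (1 - tan(el) / tan(vertical_half_angle))`
#' with the pixel origin at the top-left corner, x rightward, y downward.
#' Coordinates are fractional; rounding is left to output formatting.
#'
#' @param az_deg,el_deg Gaze angles in degrees. Azimuths outside +/-90 are
#'   clamped to the nearest field edge and flagged.
#' @param rig A [rig_geometry()].
#' @return `data.frame(panel, px_x, px_y, clamped)` with `panel` in 0:2.
#' @export
azel_to_panel_pixel <- function(az_deg, el_deg = 0, rig = rig_geometry()) {
  n <- max(length(az_deg), length(el_deg))
  az <- rep_len(az_deg, n); el <- rep_len(el_deg, n)
  clamped <- az < -90 | az > 90
  az <- pmin(90, pmax(-90, az))
  panel <- ifelse(az < -rig$panel_half_angle, 0L,
                  ifelse(az < rig$panel_half_angle, 1L, 2L))
  center <- rig$panel_center_azimuths[panel + 1L]
  half <- rig$panel_half_angle * pi / 180
  px_x <- rig$panel_px_w / 2 * (1 + tan((az - center) * pi / 180) / tan(half))
  vhalf <- rig$vertical_half_angle * pi / 180
  el_c <- pmin(rig$vertical_half_angle, pmax(-rig$vertical_half_angle, el))
  px_y <- rig$panel_px_h / 2 * (1 - tan(el_c * pi / 180) / tan(vhalf))
  data.frame(panel = panel, px_x = px_x, px_y = px_y, clamped = clamped)
}

#' Recover azimuth/elevation from a panel pixel position
#'
#' Inverse of [azel_to_panel_pixel()]; used for the round-trip property.
#'
#' @param panel Panel index in 0:2.
#' @param px_x,px_y Pixel coordinates.
#' @param rig A [rig_geometry()].
#' @return `data.frame(az_deg, el_deg)`.
#' @export
panel_pixel_to_azel <- function(panel, px_x, px_y, rig = rig_geometry()) {
  center <- rig$panel_center_azimuths[panel + 1L]
  half <- rig$panel_half_angle * pi / 180
  az <- center + atan((2 * px_x / rig$panel_px_w - 1) * tan(half)) * 180 / pi
  vhalf <- rig$vertical_half_angle * pi / 180
  el <- atan((1 - 2 * px_y / rig$panel_px_h) * tan(vhalf)) * 180 / pi
  data.frame(az_deg = az, el_deg = el)
}

#' Smooth a whole azimuth series into anchor outputs
#'
#' Stateful replay of the anchor update rule over a full sample series:
#' moving-window averaging, bypass-with-reset for large movements, and
#' hold-last on invalid samples. [smooth_anchor()] returns the final element
#' of this replay.
#'
#' @param az Azimuth samples, degrees (oldest first).
#' @param valid Logical validity flags (recycled).
#' @param policy A [buffer_policy()].
#' @return A list: `az` (anchor azimuths), `held` (logical), `lag`
#'   (samples since the last unheld anchor).
#' @export
smooth_anchor_series <- function(az, valid = TRUE, policy = buffer_policy()) {
  n <- length(az)
  valid <- rep_len(valid, n) & is.finite(az)
  out <- numeric(n)
  held <- logical(n)
  lag <- integer(n)
  if (!any(valid)) {
    warning("all gaze samples invalid; anchor held at rig center")
    return(list(az = rep(0, n), held = rep(TRUE, n), lag = seq_len(n)))
  }
  window <- numeric(0)
  prev <- NA_real_
  for (i in seq_len(n)) {
    if (!valid[i]) {
      if (is.na(prev)) {                  # leading invalid run: rig center
        out[i] <- 0
      } else {
        out[i] <- prev
      }
      held[i] <- TRUE
      lag[i] <- if (i > 1L) lag[i - 1L] + 1L else 1L
    } else if (!is.na(prev) && abs(az[i] - prev) > policy$bypass_threshold_deg) {
      window <- az[i]                     # bypass: jump and reset the buffer
      out[i] <- az[i]
    } else {
      window <- c(window, az[i])
      if (length(window) > policy$window_len)
        window <- window[(length(window) - policy$window_len + 1L):length(window)]
      out[i] <- mean(window)
    }
    if (valid[i]) prev <- out[i]
  }
  list(az = out, held = held, lag = lag)
}

#' Smooth a gaze-azimuth history into a mask anchor azimuth
#'
#' Output is the mean of the last `window_len` valid azimuths, except that a
#' movement larger than the bypass threshold (relative to the previous output)
#' passes through unsmoothed and resets the window, and an invalid newest
#' sample holds the last valid output.
#'
#' @param az Azimuth history, degrees (oldest first).
#' @param valid Logical validity flags (recycled).
#' @param policy A [buffer_policy()].
#' @return A list with `az` (anchor azimuth for the newest sample) and `held`.
#' @export
smooth_anchor <- function(az, valid = TRUE, policy = buffer_policy()) {
  stopifnot(length(az) >= 1L)
  s <- smooth_anchor_series(az, valid, policy)
  n <- length(az)
  list(az = s$az[n], held = s$held[n])
}

#' Mask opacity at an azimuth
#'
#' For a left-sided mask anchored at `anchor_az`, opacity is 1 at and beyond
#' `anchor - fade/2`, 0 at and beyond `anchor + fade/2`, and linear in
#' between; mirror-symmetric for a right-sided mask. A zero fade width gives a
#' hard edge at the anchor.
#'
#' @param az_deg Query azimuth(s), degrees.
#' @param anchor_az Anchor azimuth, degrees.
#' @param spec A [mask_spec()].
#' @return Opacity alpha in `[0, 1]`.
#' @export
opacity_at <- function(az_deg, anchor_az, spec = mask_spec("left")) {
  f <- spec$fade_width_deg
  lo <- anchor_az - f / 2
  hi <- anchor_az + f / 2
  if (spec$side == "left") {
    a <- ifelse(az_deg <= lo, 1, ifelse(az_deg >= hi, 0, (hi - az_deg) / f))
  } else {
    a <- ifelse(az_deg >= hi, 1, ifelse(az_deg <= lo, 0, (az_deg - lo) / f))
  }
  pmin(1, pmax(0, a))
}

#' Fraction of the frontal field occluded by the mask
#'
#' Exact mean of [opacity_at()] over an azimuth interval, by piecewise-linear
#' integration. With the ramp fully inside the field this equals the hard-edge
#' value, e.g. `(anchor + 90) / 180` for a left mask over `[-90, 90]`.
#'
#' @param anchor_az Anchor azimuth, degrees.
#' @param spec A [mask_spec()].
#' @param field Two-element azimuth interval, degrees.
#' @return Occluded fraction in `[0, 1]`.
#' @export
occluded_fraction <- function(anchor_az, spec = mask_spec("left"),
                              field = c(-90, 90)) {
  stopifnot(length(field) == 2L, field[1] < field[2])
  f <- spec$fade_width_deg
  lo <- anchor_az - f / 2
  hi <- anchor_az + f / 2
  a <- field[1]; b <- field[2]
  # integral of the left-mask profile over [a, b]
  full <- max(0, min(b, lo) - a)                       # alpha = 1 region
  rl <- max(a, lo); rr <- min(b, hi)                   # ramp overlap
  ramp <- 0
  if (f > 0 && rr > rl) {
    # left-mask ramp alpha(az) = (hi - az)/f, integral over [rl, rr]
    ramp <- ((hi - rl)^2 - (hi - rr)^2) / (2 * f)
  }
  frac_left <- (full + ramp) / (b - a)
  if (spec$side == "left") frac_left
  else {
    # mirror: right mask at anchor over [a,b] == left mask at -anchor over [-b,-a]
    occluded_fraction(-anchor_az, mask_spec("left", f), c(-b, -a))
  }
}

#' Replay the gaze-contingent mask over a logged gaze stream
#'
#' Runs the 60 Hz anchor update loop offline: validity handling with
#' hold-last, moving-window smoothing with large-movement bypass, and mapping
#' of the smoothed anchor to a panel pixel position. One record is produced
#' per input sample; `lag_samples` counts samples since the last unheld
#' anchor.
#'
#' @param gaze A gaze stream `data.frame` with `time_s`, `az_deg` (or
#'   `gx`,`gy`,`gz`), optional `el_deg` and `valid`.
#' @param rig A [rig_geometry()].
#' @param spec A [mask_spec()].
#' @param policy A [buffer_policy()].
#' @return `data.frame(time_s, anchor_az_deg, panel, px_x, px_y, held,
#'   lag_samples)`.
#' @export
replay_mask <- function(gaze, rig = rig_geometry(), spec = mask_spec("left"),
                        policy = buffer_policy()) {
  gaze <- as_gaze_stream(gaze)
  bad <- which(diff(gaze$time_s) <= 0)
  if (length(bad))
    stop("gaze log timestamps not strictly increasing at row ", bad[1] + 1L)
  s <- smooth_anchor_series(gaze$az_deg, gaze$valid, policy)
  el <- if ("el_deg" %in% names(gaze)) ifelse(is.finite(gaze$el_deg), gaze$el_deg, 0) else 0
  px <- azel_to_panel_pixel(s$az, el, rig)
  data.frame(time_s = gaze$time_s, anchor_az_deg = s$az,
             panel = px$panel, px_x = px$px_x, px_y = px$px_y,
             held = s$held, lag_samples = s$lag)
}
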