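#' Low-pass filter configuration
#'
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param order Butterworth order of a single pass.
#' @param sample_rate_hz Nominal sampling rate, Hz.
#' @param zero_phase Apply forward-backward (zero-phase) filtering; offline
#'   analysis tolerates non-causal filtering, and one-way lag would bias
#'   fixation onsets.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(cutoff_hz = 10, order = 2, sample_rate_hz = 60,
                          zero_phase = TRUE) {
  if (cutoff_hz >= sample_rate_hz / 2)
    stop("filter cutoff (", cutoff_hz, " Hz) must be below the Nyquist rate (",
         sample_rate_hz / 2, " Hz)")
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 sample_rate_hz = sample_rate_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_config")
}

#' Substitute head-pose gaze direction where the eye signal is invalid
#'
#' Invalid eye samples take the less accurate but more stable head-derived
#' azimuth (`head_az_deg`); samples that are invalid and also lack a head
#' value carry the last usable azimuth forward and are marked `held`.
#'
#' @param gaze A gaze stream `data.frame` (see [read_gaze()]).
#' @return The stream with every sample carrying a usable `az_deg` and a
#'   `source` column in `eye`/`head`/`held`; the number of head substitutions
#'   is attached as attribute `n_head` (and carried-forward holds as
#'   `n_held`).
#' @export
merge_head_fallback <- function(gaze) {
  gaze <- as_gaze_stream(gaze)
  n <- nrow(gaze)
  src <- rep("eye", n)
  az <- gaze$az_deg
  head_az <- if ("head_az_deg" %in% names(gaze)) gaze$head_az_deg else rep(NA_real_, n)
  invalid <- !gaze$valid | !is.finite(az)
  use_head <- invalid & is.finite(head_az)
  az[use_head] <- head_az[use_head]
  src[use_head] <- "head"
  hold <- invalid & !is.finite(head_az)
  if (any(hold)) {
    warning(sum(hold), " invalid sample(s) without head fallback; ",
            "carrying last azimuth forward")
    for (i in which(hold)) {
      az[i] <- if (i > 1L && is.finite(az[i - 1L])) az[i - 1L] else 0
      src[i] <- "held"
    }
  }
  gaze$az_deg <- az
  gaze$source <- src
  attr(gaze, "n_head") <- sum(use_head)
  attr(gaze, "n_held") <- sum(hold)
  gaze
}

#' Flag gaze samples in excluded areas of interest
#'
#' Blinks and gazes to non-driving-related regions (mirrors, media system,
#' other) are excluded from event detection and all gaze statistics. Flagged
#' samples are not removed: they still advance time, so exclusion gaps are
#' never closed or interpolated over.
#'
#' @param gaze A gaze stream `data.frame`.
#' @param excluded_aois Character vector of AOI labels to exclude.
#' @return The stream with a logical `excluded` column.
#' @export
exclude_regions <- function(gaze,
                            excluded_aois = c("blink", "mirror", "media", "other")) {
  gaze <- as_gaze_stream(gaze)
  if (!"aoi" %in% names(gaze) || all(is.na(gaze$aoi))) {
    warning("no AOI labels present; nothing excluded")
    gaze$excluded <- FALSE
    return(gaze)
  }
  gaze$excluded <- !is.na(gaze$aoi) & gaze$aoi %in% excluded_aois
  gaze
}

## forward-backward filtering with odd-reflection end padding, so segments
## that start or end away from zero see no artificial edge step
filtfilt_refl <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 12L)
  xp <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1L):(pad + n)]
}

## analytic magnitude response of the implemented digital Butterworth
## (bilinear transform); squared when applied forward-backward
butter_gain <- function(f_hz, cfg) {
  r <- tan(pi * f_hz / cfg$sample_rate_hz) /
    tan(pi * cfg$cutoff_hz / cfg$sample_rate_hz)
  g <- 1 / sqrt(1 + r^(2 * cfg$order))
  if (cfg$zero_phase) g^2 else g
}

#' Low-pass filter the horizontal gaze signal
#'
#' Applies a digital Butterworth low-pass (default order 2, 10 Hz cutoff at
#' 60 Hz sampling, zero-phase via forward-backward application) to `az_deg`,
#' writing the result to `az_filt`. Filtering runs separately over each
#' maximal run of unexcluded samples; runs shorter than 5 samples pass
#' through unfiltered, and excluded samples keep their raw azimuth.
#'
#' @param gaze A gaze stream `data.frame`, ideally after
#'   [merge_head_fallback()] and [exclude_regions()].
#' @param cfg A [filter_config()].
#' @return The stream with an `az_filt` column.
#' @export
lowpass <- function(gaze, cfg = filter_config()) {
  gaze <- as_gaze_stream(gaze)
  stopifnot(inherits(cfg, "filter_config"))
  excl <- if ("excluded" %in% names(gaze)) gaze$excluded else rep(FALSE, nrow(gaze))
  bf <- signal::butter(cfg$order, cfg$cutoff_hz / (cfg$sample_rate_hz / 2))
  az <- gaze$az_deg
  out <- az
  r <- rle(!excl)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < 5L) next
    idx <- starts[k]:ends[k]
    out[idx] <- if (cfg$zero_phase) filtfilt_refl(bf, az[idx])
                else as.numeric(signal::filter(bf, az[idx]))
  }
  gaze$az_filt <- out
  gaze
}

#' Run the full gaze preprocessing pipeline
#'
#' Fixed stage order: head-pose fallback, then AOI exclusion, then low-pass
#' filtering (filter segments are broken by exclusion gaps rather than
#' interpolated, which would fabricate gaze positions inside blinks).
#'
#' @param gaze Raw gaze stream.
#' @param excluded_aois Labels passed to [exclude_regions()].
#' @param cfg A [filter_config()].
#' @return Preprocessed stream with `source`, `excluded` and `az_filt`.
#' @export
preprocess_gaze <- function(gaze,
                            excluded_aois = c("blink", "mirror", "media", "other"),
                            cfg = filter_config()) {
  g <- merge_head_fallback(gaze)
  g <- exclude_regions(g, excluded_aois)
  lowpass(g, cfg)
}
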