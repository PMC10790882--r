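# Independent brute-force oracles and trace builders shared across tests.

# Exhaustive window-scan fixation oracle: for each start index, grow the
# window sample by sample, recomputing dispersion and speeds from scratch,
# and emit the maximal admissible window whose covered time reaches the
# minimum duration. Independent of the package's incremental detector.
oracle_fixations <- function(time_s, az, disp = 2, min_dur = 0.120,
                             vmax = 30) {
  n <- length(az)
  dt <- stats::median(diff(time_s))
  v <- numeric(n)
  v[1] <- abs((az[2] - az[1]) / (time_s[2] - time_s[1]))
  v[n] <- abs((az[n] - az[n - 1]) / (time_s[n] - time_s[n - 1]))
  for (k in 2:(n - 1))
    v[k] <- abs((az[k + 1] - az[k - 1]) / (time_s[k + 1] - time_s[k - 1]))
  out <- list()
  i <- 1L
  while (i <= n) {
    j_max <- i - 1L
    for (j in i:n) {
      w <- az[i:j]
      if ((max(w) - min(w)) > disp || any(v[i:j] >= vmax)) break
      j_max <- j
    }
    if (j_max >= i && (time_s[j_max] - time_s[i] + dt) >= min_dur - 1e-9) {
      out[[length(out) + 1L]] <- c(i = i, j = j_max)
      i <- j_max + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
}

# Run-length saccade oracle on the same speed series.
oracle_saccades <- function(time_s, az, vmin = 90) {
  n <- length(az)
  v <- numeric(n)
  v[1] <- abs((az[2] - az[1]) / (time_s[2] - time_s[1]))
  v[n] <- abs((az[n] - az[n - 1]) / (time_s[n] - time_s[n - 1]))
  for (k in 2:(n - 1))
    v[k] <- abs((az[k + 1] - az[k - 1]) / (time_s[k + 1] - time_s[k - 1]))
  fast <- v >= vmin
  out <- list()
  k <- 1L
  while (k <= n) {
    if (fast[k]) {
      j <- k
      while (j < n && fast[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(i = k, j = j,
                                   amp = abs(az[j] - az[k]))
      k <- j + 1L
    } else k <- k + 1L
  }
  if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("i", "j", "amp")))
}

# Type-7 quantile by hand (sort + linear interpolation of order statistics),
# independent of stats::quantile.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Plateau-and-ramp trace builder used by event tests: positions held for
# dur_s each, joined by linear transitions of trans_s seconds.
make_trace <- function(positions, dur_s, trans_s = 0.05, rate = 60,
                       noise = 0, aoi = "front") {
  dt <- 1 / rate
  az <- numeric(0)
  for (k in seq_along(positions)) {
    az <- c(az, rep(positions[k], round(dur_s[min(k, length(dur_s))] / dt)))
    if (k < length(positions)) {
      ns <- max(2, round(trans_s / dt))
      az <- c(az, positions[k] + (positions[k + 1] - positions[k]) *
                (1:(ns - 1)) / ns)
    }
  }
  if (noise > 0) az <- az + stats::rnorm(length(az), 0, noise)
  data.frame(time_s = (seq_along(az) - 1) * dt, az_deg = az,
             valid = TRUE, aoi = aoi, stringsAsFactors = FALSE)
}

# Random plateau/transition trace for oracle-equivalence checks.
random_trace <- function(n_plateaus = 6, rate = 60) {
  pos <- runif(n_plateaus, -60, 60)
  dur <- runif(n_plateaus, 0.05, 0.6)
  make_trace(pos, dur, trans_s = runif(1, 0.02, 0.12), rate = rate,
             noise = runif(1, 0, 0.5))
}
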