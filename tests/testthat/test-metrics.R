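drive_df <- function(dist, lane = 0, brake = FALSE, rate = 240) {
  n <- length(dist)
  data.frame(time_s = (0:(n - 1)) / rate, dist_m = dist,
             lane_offset_cm = rep_len(lane, n),
             brake = rep_len(brake, n), speed_kmh = 50)
}

# simple linear approach: 150 m to 0 at constant 13.9 m/s, 240 Hz
approach <- function(brake_from_dist = NA, release_at = NA) {
  v <- 50 / 3.6
  dist <- seq(150, 0, by = -v / 240)
  brake <- if (is.na(brake_from_dist)) rep(FALSE, length(dist))
           else dist <= brake_from_dist
  if (!is.na(release_at)) brake <- brake & dist > release_at
  drive_df(dist, brake = brake)
}

test_that("the deceleration phase starts at braking or the fallback distance", {
  d <- approach(brake_from_dist = 80)
  w <- segment_deceleration(d)
  expect_equal(w$trigger, "brake")
  expect_equal(w$brake_dist_m, 80, tolerance = 0.1)
  expect_equal(w$t_end, d$time_s[which(d$dist_m <= 0)[1]])
  # no braking at all: fallback at 41.76 m
  w2 <- segment_deceleration(approach())
  expect_equal(w2$trigger, "fallback")
  d3 <- approach()
  expect_equal(d3$dist_m[d3$time_s == w2$t_start] <= 41.76, TRUE)
  # brake only beyond 100 m, released before the search zone: fallback
  w3 <- segment_deceleration(approach(brake_from_dist = 130,
                                      release_at = 105))
  expect_equal(w3$trigger, "fallback")
  # approach that never reaches the intersection errors
  expect_error(segment_deceleration(drive_df(seq(150, 60, length.out = 100))),
               "never reaches")
})

test_that("lane metrics give mean, variance and upward boundary crossings", {
  d <- drive_df(rep(10, 100), lane = -17)
  lm_ <- lane_metrics(d)
  expect_equal(lm_$lane_mean_cm, -17)
  expect_equal(lm_$lane_var, 0)
  expect_equal(lm_$lane_crossings, 0)
  # sinusoid of amplitude 100 about 0: one crossing per side per period
  t <- seq(0, 3 - 1e-9, by = 1 / 240)
  d2 <- drive_df(rep(10, length(t)), lane = 100 * sin(2 * pi * t))
  expect_equal(lane_metrics(d2, boundary_cm = 85)$lane_crossings, 6)
  # translation shifts the mean, not the variance
  d3 <- d2; d3$lane_offset_cm <- d2$lane_offset_cm + 30
  expect_equal(lane_metrics(d3)$lane_mean_cm,
               lane_metrics(d2)$lane_mean_cm + 30)
  expect_equal(lane_metrics(d3)$lane_var, lane_metrics(d2)$lane_var)
})

test_that("first peripheral scan side and missing large scans follow the thresholds", {
  g <- data.frame(time_s = (0:299) / 60,
                  az_deg = c(rep(0, 50), rep(-35, 50), rep(0, 50),
                             rep(50, 50), rep(0, 100)))
  expect_equal(first_peripheral_scan(g, 30), "left")
  expect_equal(first_peripheral_scan(g, 45), "right")
  g2 <- data.frame(time_s = (0:99) / 60, az_deg = rep(c(-25, 25), 50))
  expect_equal(first_peripheral_scan(g2, 30), "none")
  ms <- missing_large_scans(g)
  expect_false(ms$right)
  expect_true(ms$left)
  g3 <- data.frame(time_s = (0:99) / 60,
                   az_deg = seq(-55, 50, length.out = 100))
  expect_equal(missing_large_scans(g3), list(left = FALSE, right = FALSE))
  g4 <- data.frame(time_s = (0:99) / 60,
                   az_deg = seq(-50, 30, length.out = 100))
  expect_equal(missing_large_scans(g4), list(left = FALSE, right = TRUE))
})

test_that("gaze summaries are sample statistics over usable samples", {
  g <- data.frame(time_s = (0:9) / 60, az_deg = rep(5, 10))
  s <- gaze_summary(g)
  expect_equal(s, list(gaze_var = 0, gaze_mean = 5, gaze_min = 5,
                       gaze_max = 5))
  g2 <- data.frame(time_s = (0:2) / 60, az_deg = c(-10, 0, 10))
  s2 <- gaze_summary(g2)
  expect_equal(s2$gaze_var, 100)    # n-1 denominator
  expect_equal(s2$gaze_mean, 0)
  # negation negates and swaps the extremes, variance unchanged
  g3 <- g2; g3$az_deg <- -g3$az_deg
  s3 <- gaze_summary(g3)
  expect_equal(s3$gaze_min, -s2$gaze_max)
  expect_equal(s3$gaze_max, -s2$gaze_min)
  expect_equal(s3$gaze_var, s2$gaze_var)
  # fewer than two usable samples gives a missing result
  expect_true(is.na(gaze_summary(g2[1, ])$gaze_mean))
})

test_that("hemispace fixation counts exclude the central band", {
  fx <- data.frame(mean_az_deg = c(-20, -8, 3, 12),
                   duration_s = c(0.3, 0.2, 0.25, 0.4))
  h <- hemispace_fixations(fx)
  expect_equal(h$fix_n_left, 2)
  expect_equal(h$fix_n_right, 1)
  expect_equal(h$fix_dur_left, 0.25)
  expect_equal(h$fix_dur_right, 0.4)
  h2 <- hemispace_fixations(data.frame(mean_az_deg = c(-4, 0, 5),
                                       duration_s = rep(0.2, 3)))
  expect_equal(h2$fix_n_left + h2$fix_n_right, 0)
  expect_true(is.na(h2$fix_dur_left))
})

test_that("directional saccade means apply the endpoint eccentricity rule", {
  sc <- data.frame(direction = "right", endpoint_az_deg = 20,
                   amplitude_deg = 20)
  d <- directional_saccades(sc)
  expect_equal(d$sacc_amp_right, 20)
  expect_true(is.na(d$sacc_amp_left))
  # leftward saccade ending at +2 counts toward neither side
  sc2 <- data.frame(direction = "left", endpoint_az_deg = 2,
                    amplitude_deg = 8)
  d2 <- directional_saccades(sc2)
  expect_true(is.na(d2$sacc_amp_left) && is.na(d2$sacc_amp_right))
  # mixed batch equals a filter-then-average oracle
  set.seed(8)
  sc3 <- data.frame(direction = sample(c("left", "right"), 100, TRUE),
                    endpoint_az_deg = runif(100, -60, 60),
                    amplitude_deg = runif(100, 1, 40))
  d3 <- directional_saccades(sc3)
  keep_l <- sc3$direction == "left" & sc3$endpoint_az_deg < -5
  expect_equal(d3$sacc_amp_left, mean(sc3$amplitude_deg[keep_l]))
})

test_that("percentages are rounded half-up to two decimals", {
  expect_equal(percentage(25, 84), 29.76)
  expect_equal(percentage(19, 84), 22.62)
  expect_equal(percentage(26, 132), 19.70)
  expect_equal(percentage(0, 42), 0)
  expect_equal(percentage(1, 800), 0.13)   # exact .5 rounds up
  expect_true(is.na(percentage(3, 0)))
  # scale-free
  set.seed(2)
  k <- sample(0:50, 20, TRUE); K <- k + sample(1:50, 20, TRUE)
  expect_equal(percentage(2 * k, 2 * K), percentage(k, K))
})

test_that("aggregation reproduces planted per-scenario counts", {
  recs <- expand.grid(subject = 1:4, condition = c("NV", "LHH", "RHH"),
                      intersection = c("SCI", "LTI", "RTI"),
                      stringsAsFactors = FALSE)
  set.seed(4)
  recs$lane_mean_cm <- rnorm(nrow(recs), -17, 10)
  recs$lane_crossings <- rpois(nrow(recs), 0.1)
  recs$first_scan_30 <- sample(c("left", "right", "none"), nrow(recs), TRUE)
  recs$first_scan_45 <- recs$first_scan_30
  recs$missing_scan_left <- runif(nrow(recs)) < 0.2
  recs$missing_scan_right <- runif(nrow(recs)) < 0.3
  a <- aggregate_metrics(recs)
  ml <- a$missing_scans
  expect_equal(ml$missing_left[ml$condition == "all"],
               sum(recs$missing_scan_left))
  expect_equal(ml$pct_left[ml$condition == "all"],
               percentage(sum(recs$missing_scan_left), nrow(recs)))
  fs <- a$first_scan_30
  for (cond in c("NV", "LHH", "RHH")) {
    sub <- recs[recs$condition == cond, ]
    for (sd_ in unique(sub$first_scan_30))
      expect_equal(fs$k[fs$condition == cond & fs$side == sd_],
                   sum(sub$first_scan_30 == sd_))
  }
  lc <- a$lane_crossings
  expect_equal(sum(lc$total_crossings), sum(recs$lane_crossings))
})
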