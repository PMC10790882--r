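test_that("gaze vectors convert to azimuth/elevation and back", {
  expect_equal(unlist(vector_to_azel(0, 0, 1)[1, 1:2]),
               c(az_deg = 0, el_deg = 0))
  expect_equal(vector_to_azel(sin(pi / 6), 0, cos(pi / 6))$az_deg, 30,
               tolerance = 1e-9)
  r <- vector_to_azel(0.25, 0.25, 0.9354)
  expect_equal(r$az_deg, atan2(0.25, 0.9354) * 180 / pi, tolerance = 1e-4)
  expect_equal(r$el_deg, asin(0.25 / sqrt(0.25^2 + 0.25^2 + 0.9354^2)) *
                 180 / pi, tolerance = 1e-4)
  # inverse recovers the vector
  set.seed(1)
  az <- runif(200, -179, 179); el <- runif(200, -80, 80)
  v <- azel_to_vector(az, el)
  back <- vector_to_azel(v$x, v$y, v$z)
  expect_lt(max(abs(back$az_deg - az)), 1e-6)
  expect_lt(max(abs(back$el_deg - el)), 1e-6)
  # invalid input is flagged, not an error
  bad <- vector_to_azel(0, 0, 0)
  expect_false(bad$valid)
  expect_true(is.na(bad$az_deg))
})

test_that("azimuths map to the correct panel and pixel", {
  rig <- rig_geometry()
  p <- azel_to_panel_pixel(0, 0, rig)
  expect_equal(p$panel, 1L)
  expect_equal(p$px_x, 1700)
  expect_equal(p$px_y, 1360)
  # sector boundary: the right panel owns +30 exactly
  p30 <- azel_to_panel_pixel(30, 0, rig)
  expect_equal(p30$panel, 2L)
  expect_equal(p30$px_x, 0, tolerance = 1e-9)
  p15 <- azel_to_panel_pixel(15, 0, rig)
  expect_equal(p15$panel, 1L)
  expect_equal(p15$px_x, 1700 * (1 + tan(15 * pi / 180) / tan(30 * pi / 180)),
               tolerance = 1e-9)
  expect_equal(round(p15$px_x), 2489)
  # clamping outside the frontal field
  pc <- azel_to_panel_pixel(95, 0, rig)
  expect_true(pc$clamped)
  expect_equal(pc$panel, 2L)
})

test_that("sector tiling covers the field once and pixel round-trip is tight", {
  rig <- rig_geometry()
  set.seed(42)
  az <- runif(10000, -90, 90 - 1e-9)
  el <- runif(10000, -20, 20)
  p <- azel_to_panel_pixel(az, el, rig)
  # exactly one panel claims each azimuth and pixels stay on-panel
  expect_true(all(p$panel %in% 0:2))
  expect_true(all(p$px_x >= 0 & p$px_x <= rig$panel_px_w))
  expect_true(all(p$px_y >= 0 & p$px_y <= rig$panel_px_h))
  sector <- findInterval(az, c(-90, -30, 30, 90.000001)) - 1L
  expect_identical(p$panel, as.integer(sector))
  back <- panel_pixel_to_azel(p$panel, p$px_x, p$px_y, rig)
  p2 <- azel_to_panel_pixel(back$az_deg, back$el_deg, rig)
  expect_lt(max(abs(p2$px_x - p$px_x)), 0.5)
  expect_lt(max(abs(p2$px_y - p$px_y)), 0.5)
})

test_that("anchor smoothing averages, bypasses large steps, and holds on loss", {
  pol <- buffer_policy(window_len = 3, bypass_threshold_deg = 10)
  expect_equal(smooth_anchor(rep(5, 6), policy = pol)$az, 5)
  expect_equal(smooth_anchor(c(0, 3, 6), policy = pol)$az, 3)
  # a 40 degree step passes through unsmoothed on its first sample
  s <- smooth_anchor_series(c(0, 0, 0, 40, 40), TRUE, pol)
  expect_equal(s$az[4], 40)
  expect_equal(s$az[5], 40)  # window reset: no snap-back
  # a step within the threshold is fully tracked within window_len samples
  s2 <- smooth_anchor_series(c(rep(0, 5), rep(8, 5)), TRUE, pol)
  expect_equal(s2$az[5 + 3], 8)
  # invalid newest sample holds the last output
  s3 <- smooth_anchor_series(c(1, 1, 1, NA, NA, 1), c(TRUE, TRUE, TRUE,
                                                      FALSE, FALSE, TRUE), pol)
  expect_equal(s3$az[4], 1)
  expect_true(s3$held[4] && s3$held[5])
  expect_equal(s3$lag[4:6], c(1L, 2L, 0L))
  expect_warning(smooth_anchor_series(c(NA, NA), FALSE, pol), "invalid")
})

test_that("mask opacity ramps linearly and occluded fraction integrates it", {
  hard <- mask_spec("left", fade_width_deg = 0)
  expect_equal(opacity_at(-10, 0, hard), 1)
  expect_equal(opacity_at(10, 0, hard), 0)
  expect_equal(opacity_at(0, 0, mask_spec("left", 4)), 0.5)
  expect_equal(opacity_at(22.5, 20, mask_spec("right", 10)), 0.75)
  # monotone across the boundary
  az <- seq(-30, 30, by = 0.25)
  a <- opacity_at(az, 0, mask_spec("left", 7))
  expect_true(all(diff(a) <= 0))
  a_r <- opacity_at(az, 0, mask_spec("right", 7))
  expect_true(all(diff(a_r) >= 0))

  expect_equal(occluded_fraction(0, hard), 0.5)
  expect_equal(occluded_fraction(45, mask_spec("left", 12)), 0.75)
  expect_equal(occluded_fraction(-30, mask_spec("right", 10)), 2 / 3,
               tolerance = 1e-12)
})

test_that("occluded fraction agrees with numeric integration of opacity", {
  set.seed(7)
  grid <- seq(-90, 90, by = 0.01)
  for (k in 1:20) {
    spec <- mask_spec(sample(c("left", "right"), 1), runif(1, 0, 30))
    anchor <- runif(1, -80, 80)
    expect_equal(occluded_fraction(anchor, spec),
                 mean(opacity_at(grid, anchor, spec)),
                 tolerance = 1e-3)
  }
})

test_that("mask replay is deterministic, holds through dropouts, and tracks steps", {
  dt <- 1 / 60
  g <- data.frame(time_s = (0:59) * dt, az_deg = 12, el_deg = 0, valid = TRUE)
  r <- replay_mask(g)
  expect_equal(nrow(r), 60)
  expect_true(all(!r$held))
  expect_equal(length(unique(round(r$px_x, 9))), 1)
  expect_identical(r, replay_mask(g))
  # 5-sample dropout holds the anchor
  g2 <- g
  g2$valid[20:24] <- FALSE
  r2 <- replay_mask(g2)
  expect_true(all(r2$held[20:24]))
  expect_equal(unique(r2$anchor_az_deg[20:24]), r2$anchor_az_deg[19])
  expect_equal(r2$lag_samples[20:24], 1:5)
  # a scripted 30 degree step relocates the anchor in one sample (bypass)
  g3 <- g
  g3$az_deg <- c(rep(0, 30), rep(30, 30))
  r3 <- replay_mask(g3)
  expect_equal(r3$anchor_az_deg[31], 30)
  # non-monotone timestamps are rejected with the offending index
  g4 <- g
  g4$time_s[10] <- g4$time_s[8]
  expect_error(replay_mask(g4), "row 10")
})
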