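test_that("scanpath generation is deterministic in the seed", {
  p <- condition_profile("NV")
  a <- generate_scanpath(p, duration_s = 5, seed = 33)
  b <- generate_scanpath(p, duration_s = 5, seed = 33)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$events, b$events)
  c_ <- generate_scanpath(p, duration_s = 5, seed = 34)
  expect_false(identical(a$gaze$az_deg, c_$gaze$az_deg))
})

test_that("planted noise-free events are recovered exactly by the detector", {
  p <- condition_profile("NV", blink_rate_per_min = 0, dropout_rate = 0)
  sp <- generate_scanpath(p, seed = 5, noise_sd_deg = 0, n_fixations = 3)
  g <- preprocess_gaze(sp$gaze)
  fx <- detect_fixations(g)
  sc <- detect_saccades(g)
  expect_equal(nrow(fx), 3)
  expect_equal(nrow(sc), 2)
  planted <- sp$events[sp$events$type == "fixation", ]
  expect_equal(fx$mean_az_deg, planted$position_deg, tolerance = 0.05)
  expect_equal(sc$amplitude_deg,
               sp$events$amplitude_deg[sp$events$type == "saccade"],
               tolerance = 0.6)
})

test_that("an infeasible profile is rejected", {
  expect_error(condition_profile("NV", fix_dur_mean = 0.10), "fix_dur_mean")
})

test_that("generated drives plant the deceleration window truth", {
  dr <- generate_drive(drive_profile(brake_onset_dist_m = 80), seed = 3)
  w <- segment_deceleration(dr$drive)
  expect_equal(w$trigger, "brake")
  expect_equal(w$t_start, dr$truth$t_start)
  expect_equal(w$t_end, dr$truth$t_end)
  expect_equal(w$brake_dist_m, 80, tolerance = 0.1)
  # no braking: fallback at 41.76 m
  dr2 <- generate_drive(drive_profile(brake_onset_dist_m = NA), seed = 3)
  w2 <- segment_deceleration(dr2$drive)
  expect_equal(w2$trigger, "fallback")
  expect_equal(w2$t_start, dr2$truth$t_start)
  # deterministic lane keeping: zero variance
  dr3 <- generate_drive(drive_profile(lane_ar1_phi = 0, lane_noise_sd_cm = 0),
                        seed = 1)
  expect_equal(stats::var(dr3$drive$lane_offset_cm), 0)
  # speed ramps down to the residual speed at the crossing
  expect_lt(dr$drive$speed_kmh[nrow(dr$drive)], 10)
  expect_equal(dr$drive$speed_kmh[1], 50)
})

test_that("a study has the full scenario grid and a manifest", {
  st <- generate_study(n_subjects = 2, master_seed = 7)
  expect_equal(length(st$scenarios), 2 * 3 * 3)
  expect_equal(nrow(st$manifest), 18)
  expect_setequal(unique(st$manifest$condition), c("NV", "LHH", "RHH"))
  expect_setequal(unique(st$manifest$intersection), c("SCI", "LTI", "RTI"))
  expect_true(all(st$manifest$seed < 2^31))
  # different master seeds give different data with identical schema
  st2 <- generate_study(n_subjects = 2, master_seed = 8)
  expect_identical(names(st2$manifest), names(st$manifest))
  expect_false(identical(st$scenarios[[1]]$gaze$az_deg,
                         st2$scenarios[[1]]$gaze$az_deg))
  # reproducible
  st3 <- generate_study(n_subjects = 2, master_seed = 7)
  expect_identical(st$manifest, st3$manifest)
})

test_that("study files round-trip losslessly through the readers", {
  st <- generate_study(n_subjects = 1, master_seed = 11)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  rt <- read_study(dir)
  expect_identical(rt$manifest$scenario, st$manifest$scenario)
  id <- st$manifest$scenario[1]
  expect_equal(rt$scenarios[[id]]$gaze$az_deg,
               st$scenarios[[id]]$gaze$az_deg, tolerance = 1e-12)
  expect_equal(rt$scenarios[[id]]$drive$lane_offset_cm,
               st$scenarios[[id]]$drive$lane_offset_cm, tolerance = 1e-12)
})

test_that("pipeline metrics recover the planted categorical truths", {
  # noise-free study: first-scan sides, missing scans and lane crossings
  # must match the manifest exactly
  profs <- lapply(default_profiles(), function(p) {
    p$blink_rate_per_min <- 0; p$dropout_rate <- 0; p
  })
  st <- generate_study(n_subjects = 3, profiles = profs, master_seed = 19,
                       noise_sd_deg = 0)
  res <- run_pipeline(st)
  m <- merge(res$metrics, st$manifest,
             by = c("subject", "condition", "intersection"),
             suffixes = c("", "_truth"))
  expect_equal(nrow(m), 27)
  expect_identical(m$trigger, m$trigger_truth)
  expect_identical(m$first_scan_30, m$first_scan_30_truth)
  expect_identical(m$first_scan_45, m$first_scan_45_truth)
  expect_identical(m$missing_scan_left, m$missing_scan_left_truth)
  expect_identical(m$missing_scan_right, m$missing_scan_right_truth)
  expect_identical(m$lane_crossings, m$lane_crossings_truth)
  # phase duration equals the planted window length
  expect_equal(m$phase_duration_s, m$t_end - m$t_start, tolerance = 1e-9)
})
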