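test_that("subject generation is deterministic and respects the variation config", {
  expect_identical(generate_subject(5), generate_subject(5))
  none <- subject_variation(corner_sd = 0, eye_vector_sd = 0, gain_rsd = 0,
                            quad_sd = 0, rot_gain_rsd = 0)
  a <- generate_subject(1, none); b <- generate_subject(2, none)
  expect_equal(a$base_pupil, b$base_pupil)
  expect_equal(a$base_corner, b$base_corner)
  expect_equal(a$gain_x, b$gain_x)
  # default config: anatomical spread across subjects dwarfs measurement noise
  pupils <- t(sapply(1:50, function(s) generate_subject(s)$base_pupil))
  expect_gt(min(apply(pupils, 2, sd)), 10 * subject_variation()$noise_sd)
})

test_that("the forward model decomposes into head, gaze and noise terms", {
  quiet <- subject_variation(noise_sd = 0)
  p <- generate_subject(3, quiet)
  # all perturbations off: bases are returned
  o <- forward_observe(p, c(0, 0))
  expect_equal(c(o$pupil_x, o$pupil_y), p$base_pupil)
  expect_equal(c(o$corner_m, o$corner_n), p$base_corner)
  # rot_gain = 0: head translation is perfectly common-mode
  p0 <- generate_subject(3, subject_variation(noise_sd = 0, rot_gain = 0,
                                              rot_gain_rsd = 0))
  a <- forward_observe(p0, c(120, -60), head_offset = c(15, -9))
  b <- forward_observe(p0, c(120, -60), head_offset = c(-40, 22))
  expect_equal(c(a$pupil_x - a$corner_m, a$pupil_y - a$corner_n),
               c(b$pupil_x - b$corner_m, b$pupil_y - b$corner_n),
               tolerance = 1e-12)
  # quad = 0: pupil displacement is linear in the target
  lin <- generate_subject(3, subject_variation(noise_sd = 0, quad_mean = 0,
                                               quad_sd = 0))
  base <- forward_observe(lin, c(0, 0))
  d1 <- forward_observe(lin, c(100, 50))
  d2 <- forward_observe(lin, c(200, 100))
  expect_equal(2 * (d1$pupil_x - base$pupil_x), d2$pupil_x - base$pupil_x,
               tolerance = 1e-9)
  expect_equal(2 * (d1$pupil_y - base$pupil_y), d2$pupil_y - base$pupil_y,
               tolerance = 1e-9)
})

test_that("head motion is a clamped random walk, absent when the step is zero", {
  still <- generate_subject(4, subject_variation(head_step_sd = 0))
  sim <- simulate_session(still, script_grid_4x7(), seed = 9)
  expect_true(all(sim$head_track == 0))

  wild <- generate_subject(4, subject_variation(head_step_sd = 50,
                                                head_limit = 120))
  long_script <- script_grid_4x7()[rep(1:28, length.out = 10000), ]
  sim2 <- simulate_session(wild, long_script, seed = 10)
  expect_lte(max(abs(sim2$head_track)), 120)
  expect_gt(max(abs(sim2$head_track)), 100)  # the clamp is actually exercised

  s1 <- simulate_session(still, script_grid_4x7(), seed = 11)
  s2 <- simulate_session(still, script_grid_4x7(), seed = 11)
  expect_identical(s1$observations, s2$observations)
})

test_that("scripts have the documented shapes", {
  cal <- script_calibration_9pt()
  expect_equal(nrow(cal), 9)
  expect_equal(as.numeric(cal[1, ]), c(0, 0))  # centre first
  expect_equal(nrow(unique(cal)), 9)
  grid <- script_grid_4x7()
  expect_equal(nrow(grid), 28)
  expect_equal(length(unique(grid$tx)), 7)
  expect_equal(length(unique(grid$ty)), 4)
  lens <- sapply(1:30, function(s) nrow(script_free_play(s)))
  expect_true(all(lens >= 40 & lens <= 107))
  fp <- script_free_play(3)
  expect_true(all(paste(fp$tx, fp$ty) %in% paste(grid$tx, grid$ty)))
})

test_that("cohorts expose calibration and full-trial segments per subject", {
  one <- generate_cohort(1, seed = 5)
  expect_gte(nrow(one[[1]]$observations), 9 + 40)
  cal_targets <- one[[1]]$observations[1:9, c("tx", "ty")]
  expect_equal(as.matrix(cal_targets), as.matrix(script_calibration_9pt()),
               ignore_attr = TRUE)

  cohort <- generate_cohort(12, seed = 6, free_play_length = 40)
  bases <- t(sapply(cohort, function(s) s$profile$base_pupil))
  expect_equal(nrow(unique(bases)), 12)
})

test_that("a noiseless still subject with quad = 0 is exactly learnable in every space", {
  profile <- exact_profile(8)
  grid <- script_grid_4x7()
  train <- simulate_session(profile, grid[seq(1, 27, 2), ], seed = 12)
  test_s <- simulate_session(profile, grid[seq(2, 28, 2), ], seed = 13)
  for (space in space_kinds()) {
    origin <- capture_origin(train$observations[1, ])
    fit <- gaze_fit(make_feature(train$observations, space, origin),
                    train$observations[, c("tx", "ty")], space = space)
    g <- predict(fit, make_feature(test_s$observations, space, origin))
    err <- sqrt((g[, 1] - test_s$observations$tx)^2 +
                (g[, 2] - test_s$observations$ty)^2)
    expect_lt(max(err), 1e-3)
  }
})

test_that("subjects are disjoint globally but overlap in local-relative space", {
  cohort <- generate_cohort(8, seed = 14, free_play_length = 40)
  dg <- feature_dispersion(cohort, "global_absolute")
  dl <- feature_dispersion(cohort, "local_relative")
  expect_gt(dg$between / dl$between, 5)
  # globally the clouds separate (between exceeds within); locally they sit
  # on top of each other
  expect_gt(dg$between, dg$within)
  expect_lt(dl$between, 0.3 * dl$within)
})

test_that("ignoring the head components hurts under head motion", {
  v <- subject_variation(noise_sd = 0, head_step_sd = 8)
  profile <- generate_subject(15, v)
  grid <- script_grid_4x7()
  train <- simulate_session(profile, grid[c(1:28, 1:10), ], seed = 16)
  test_s <- simulate_session(profile, grid[c(15:28, 1:14), ], seed = 17)
  origin <- capture_origin(train$observations[1, ])
  err_for <- function(strip_head) {
    tr <- make_feature(train$observations, "local_relative", origin)
    te <- make_feature(test_s$observations, "local_relative", origin)
    if (strip_head) { tr$e3 <- tr$e4 <- te$e3 <- te$e4 <- 0 }
    fit <- gaze_fit(tr, train$observations[, c("tx", "ty")])
    g <- predict(fit, te)
    mean(sqrt((g[, 1] - test_s$observations$tx)^2 +
              (g[, 2] - test_s$observations$ty)^2))
  }
  expect_gt(err_for(TRUE), err_for(FALSE))
})
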