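test_that("prior models enforce their sample and target invariants", {
  feat <- rand_features(8, seed = 1)
  set.seed(2)
  tgt <- cbind(rnorm(8, 0, 100), rnorm(8, 0, 100))
  expect_s3_class(prior_model(feat, tgt), "gaze_prior")
  expect_error(prior_model(feat[1:7, ], tgt[1:7, ]), "at least 8")
  expect_error(prior_model(feat, matrix(5, 8, 2)), "distinct targets")
  expect_error(prior_model(feat, tgt, base_weight = 0), "positive")
})

test_that("a centre start plants the zero-feature/centre-target pair", {
  prior <- small_prior("local_relative")
  obs <- observations(40, -20, 10, 5)
  ses <- start_session_center(prior, obs)
  expect_equal(as.numeric(ses$current[1, c("e1", "e2", "e3", "e4")]),
               c(0, 0, 0, 0))
  expect_equal(as.numeric(ses$current[1, c("tx", "ty")]), c(0, 0))
  # the heavily weighted centre sample pins the origin feature near (0, 0)
  expect_lt(sqrt(sum(estimate_gaze(ses, obs)^2)), 1)
  # weight contract
  expect_error(start_session_center(prior, obs, current_weight = 0.5),
               "at least")
})

test_that("estimation composes feature construction, design row and coefficients", {
  prior <- small_prior("local_relative")
  first <- observations(10, 10, 2, 2)
  ses <- start_session_center(prior, first)
  obs <- observations(18, 6, 3, 1)
  manual_feat <- make_feature(obs, ses$space, ses$origin)
  manual <- as.numeric(design_row(manual_feat) %*% coef(ses$model))
  expect_equal(as.numeric(estimate_gaze(ses, obs)), manual, tolerance = 1e-12)
  # deterministic
  expect_identical(estimate_gaze(ses, obs), estimate_gaze(ses, obs))
})

test_that("session models always equal a from-scratch refit of prior plus current", {
  prior <- small_prior("local_relative")
  profile <- exact_profile(3)
  script <- script_grid_4x7()[1:12, ]
  sim <- simulate_session(profile, script, seed = 4)
  ses <- start_session_center(prior, sim$observations[1, ])
  for (i in 2:12) {
    ses <- update_session(ses, sim$observations[i, ],
                          c(sim$observations$tx[i], sim$observations$ty[i]))
  }
  s <- rbind(ses$prior$samples, ses$current)
  scratch <- gaze_fit(s[, c("e1", "e2", "e3", "e4")], s[, c("tx", "ty")],
                      weights = s$weight, space = ses$space)
  expect_lt(max(abs(coef(scratch) - coef(ses$model))), 1e-9)
})

test_that("repeating an update is equivalent to one sample at sqrt(2) weight", {
  prior <- small_prior("local_relative")
  first <- observations(0, 0, 0, 0)
  obs <- observations(12, 8, 1, -1)
  ses0 <- start_session_center(prior, first)
  twice <- update_session(update_session(ses0, obs, c(100, 40)),
                          obs, c(100, 40))
  s <- rbind(ses0$prior$samples, ses0$current)
  feat <- make_feature(obs, ses0$space, ses0$origin)
  extra <- data.frame(feat, tx = 100, ty = 40,
                      weight = sqrt(2) * ses0$current_weight,
                      provenance = "current")
  s2 <- rbind(s, extra)
  oracle <- gaze_fit(s2[, c("e1", "e2", "e3", "e4")], s2[, c("tx", "ty")],
                     weights = s2$weight, space = ses0$space)
  expect_lt(max(abs(coef(twice$model) - coef(oracle))), 1e-9)
  expect_equal(nrow(twice$current), 3)  # both stored
})

test_that("static sessions never change after initialization", {
  prior <- small_prior("local_relative")
  ses <- start_session_center(prior, observations(0, 0, 0, 0),
                              adaptive = FALSE)
  before <- coef(ses$model)
  for (i in 1:5) {
    ses <- update_session(ses, observations(i, i, 0, 0), c(50 * i, 0))
  }
  expect_identical(coef(ses$model), before)
  expect_equal(nrow(ses$current), 1)
})

test_that("adapting on the current subject beats the prior alone", {
  prior <- small_prior("local_relative", seed = 21)
  profile <- exact_profile(99)
  # first fixation must be on the screen centre (centre-start contract)
  train_script <- rbind(script_calibration_9pt()[1, ],
                        script_grid_4x7()[seq(1, 27, 2), ])
  train <- simulate_session(profile, train_script, seed = 5)
  heldout <- simulate_session(profile, script_grid_4x7()[seq(2, 28, 2), ],
                              seed = 6)
  ses <- start_session_center(prior, train$observations[1, ])
  static_err <- adaptive_err <- NULL
  eval_err <- function(ses) {
    g <- estimate_gaze(ses, heldout$observations)
    mean(sqrt((g[, 1] - heldout$observations$tx)^2 +
              (g[, 2] - heldout$observations$ty)^2))
  }
  static_err <- eval_err(ses)
  for (i in 2:nrow(train$observations)) {
    ses <- update_session(ses, train$observations[i, ],
                          c(train$observations$tx[i],
                            train$observations$ty[i]))
  }
  adaptive_err <- eval_err(ses)
  expect_lt(adaptive_err, static_err)
  expect_lt(adaptive_err, 5)  # personalised model is near-exact, screen px
})

test_that("an arbitrary start at the centre matches the centre start", {
  prior <- small_prior("local_relative", seed = 31)
  # prior whose intercept is re-anchored at zero so f(0) = t_c exactly
  s <- prior$samples
  fit0 <- gaze_fit(s[, c("e1", "e2", "e3", "e4")], s[, c("tx", "ty")],
                   weights = s$weight, space = prior$space)
  shift <- coef(fit0)["1", ]
  s$tx <- s$tx - shift["x"]; s$ty <- s$ty - shift["y"]
  prior0 <- prior_model(s[, c("e1", "e2", "e3", "e4")],
                        s[, c("tx", "ty")], space = prior$space,
                        provenance = s$provenance)
  obs <- observations(25, -10, 4, 2)
  ses_c <- start_session_center(prior0, obs)
  ses_a <- start_session_arbitrary(prior0, obs, c(0, 0))
  expect_equal(c(ses_a$origin$x0, ses_a$origin$y0),
               c(ses_c$origin$x0, ses_c$origin$y0), tolerance = 1e-6)
  probe <- observations(30, -5, 4, 2)
  expect_equal(estimate_gaze(ses_a, probe), estimate_gaze(ses_c, probe),
               tolerance = 1e-5)
})

test_that("arbitrary starts recover a forward-constructed origin", {
  prior <- small_prior("local_relative", seed = 41)
  s <- prior$samples
  fit <- gaze_fit(s[, c("e1", "e2", "e3", "e4")], s[, c("tx", "ty")],
                  weights = s$weight, space = prior$space)
  set.seed(42)
  x <- 20; y <- -15; m <- 3; n <- 1
  true_origin <- c(x, y) - runif(2, -50, 50)
  t_a <- as.numeric(design_row(c(c(x, y) - true_origin, 0, 0)) %*% coef(fit))
  obs <- observations(x, y, m, n)
  ses <- start_session_arbitrary(prior, obs, t_a)
  expect_equal(c(ses$origin$x0, ses$origin$y0), true_origin,
               tolerance = 1e-6)
  expect_equal(c(ses$origin$m0, ses$origin$n0), c(m, n))
  # both the reconstructed-centre and the measured samples were added
  expect_equal(nrow(ses$current), 2)
  expect_equal(as.numeric(ses$current[1, c("tx", "ty")]), c(0, 0))
  expect_equal(as.numeric(ses$current[2, c("tx", "ty")]), t_a)
})

test_that("unreachable arbitrary targets surface an error and no session", {
  prior <- small_prior("local_relative", seed = 51)
  expect_error(start_session_arbitrary(prior, observations(0, 0, 0, 0),
                                       c(1e6, 0)),
               "no admissible root")
  expect_error(start_session_arbitrary(small_prior("corner_relative"),
                                       observations(0, 0, 0, 0), c(0, 0)),
               "local")
})

test_that("elevated current weight lowers held-out error versus equal weight", {
  errs <- sapply(1:10, function(seed) {
    cohort <- generate_cohort(5, seed = 600 + seed, free_play_length = 1)
    prior <- prior_from_sessions(cohort[1:4], "local_relative")
    profile <- cohort[[5]]$profile
    grid <- script_grid_4x7()
    train <- simulate_session(profile, grid[c(1:20, 1:8), ],
                              seed = 700 + seed)
    test_s <- simulate_session(profile, grid[21:28, ], seed = 800 + seed)
    one <- sapply(c(100, 1), function(w) {
      ses <- start_session_center(prior, train$observations[1, ],
                                  current_weight = w)
      for (i in 2:nrow(train$observations)) {
        ses <- update_session(ses, train$observations[i, ],
                              c(train$observations$tx[i],
                                train$observations$ty[i]))
      }
      g <- estimate_gaze(ses, test_s$observations)
      mean(sqrt((g[, 1] - test_s$observations$tx)^2 +
                (g[, 2] - test_s$observations$ty)^2))
    })
    one  # c(err at ratio 100, err at ratio 1)
  })
  expect_lt(median(errs[1, ]), median(errs[2, ]))
})

test_that("prior bundles survive a JSON round trip", {
  prior <- small_prior("corner_relative", seed = 61)
  path <- withr::local_tempfile(fileext = ".json")
  write_prior(prior, path)
  back <- read_prior(path)
  expect_equal(back$space, prior$space)
  expect_equal(back$base_weight, prior$base_weight)
  expect_equal(as.matrix(back$samples[, 1:7]),
               as.matrix(prior$samples[, 1:7]), tolerance = 1e-12,
               ignore_attr = TRUE)
})
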