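# Synthetic subjects and sessions.
#
# The simulator stands in for human recordings: each subject has anatomical
# base positions for pupil and eye corner (which differ across subjects far
# more than measurement noise within a subject), an oculomotor gain mapping
# screen-target offsets to pupil displacement, a mild quadratic optical
# distortion, and a small coupling of head translation into the pupil-corner
# vector. Head position follows a bounded random walk, emulating the small
# translations a restrained subject still produces.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Default cross-subject variation of the simulator
#'
#' Spreads (standard deviations unless noted) of the subject-profile
#' parameters: `corner_sd` — camera/head placement of the eye corner across
#' subjects, pixels; `eye_vector_sd` — anatomical pupil-to-corner offset,
#' pixels; `gain`, `gain_rsd` — mean oculomotor gain (pupil px per screen px)
#' and its relative spread; `quad_mean`, `quad_sd` — quadratic distortion
#' (pixels^-1): a systematic component shared by all subjects (one camera
#' rig, one perspective/optics geometry) plus a per-subject spread;
#' `rot_gain`, `rot_gain_rsd` — mean head-to-pupil coupling and
#' relative spread; `noise_sd` — within-subject measurement noise, px;
#' `head_step_sd` — head random-walk step, px per fixation; `head_limit` —
#' maximum head excursion, px (120 px = 30 mm at the default 4 px/mm);
#' `cubic` — optional cubic misspecification term, default 0.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of variation parameters.
#' @export
subject_variation <- function(...) {
  cfg <- list(corner_sd = 70, eye_vector = c(-25, 5), eye_vector_sd = 8,
              gain = 0.09, gain_rsd = 0.10,
              quad_mean = 3e-5, quad_sd = 1e-5,
              rot_gain = 0.05, rot_gain_rsd = 0.2,
              noise_sd = 0.5, head_step_sd = 3, head_limit = 120,
              px_per_mm = 4, cubic = 0)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Draw a synthetic subject profile
#'
#' Deterministic given the seed. With all spreads set to zero every subject
#' shares the same base positions and gains.
#'
#' @param seed Integer seed.
#' @param variation A [subject_variation()] list.
#' @param subject_id Identifier stored in generated observations.
#' @return An object of class `subject_profile`.
#' @export
generate_subject <- function(seed, variation = subject_variation(),
                             subject_id = sprintf("s%d", seed)) {
  v <- variation
  with_seed(seed, {
    base_corner <- stats::rnorm(2, 0, v$corner_sd)
    eye_vec <- v$eye_vector + stats::rnorm(2, 0, v$eye_vector_sd)
    base_pupil <- base_corner + eye_vec
    gains <- v$gain * exp(stats::rnorm(2, 0, v$gain_rsd))
    quad <- v$quad_mean + stats::rnorm(2, 0, v$quad_sd)
    rot <- v$rot_gain * exp(stats::rnorm(1, 0, v$rot_gain_rsd))
    structure(list(subject_id = subject_id,
                   base_pupil = base_pupil, base_corner = base_corner,
                   gain_x = gains[1], gain_y = gains[2],
                   quad_x = quad[1], quad_y = quad[2],
                   rot_gain = rot,
                   noise_sd = v$noise_sd, head_step_sd = v$head_step_sd,
                   head_limit = v$head_limit, cubic = v$cubic,
                   seed = seed),
              class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject %s: pupil base (%.1f, %.1f), corner base (%.1f, %.1f), gain (%.3f, %.3f)\n",
    x$subject_id, x$base_pupil[1], x$base_pupil[2],
    x$base_corner[1], x$base_corner[2], x$gain_x, x$gain_y))
  invisible(x)
}

#' Forward-generate one observation
#'
#' The eye corner moves with the head; the pupil moves with the head, plus a
#' gaze-dependent displacement (linear gain in the target offset plus a mild
#' quadratic distortion), plus a small head-coupling term `rot_gain` that
#' leaks head translation into the pupil-corner vector (the counter-rotation
#' of the eye when the head shifts while fixating). With `rot_gain = 0` and
#' no noise, head translation is perfectly common-mode: the pupil-corner
#' vector depends on the target alone.
#'
#' @param profile A `subject_profile`.
#' @param target Screen point `(tx, ty)` being fixated.
#' @param head_offset Head translation `(hx, hy)`, video px.
#' @param fixation_index,timestamp Bookkeeping fields for the observation.
#' @return A one-row observation `data.frame`.
#' @export
forward_observe <- function(profile, target, head_offset = c(0, 0),
                            fixation_index = 0L,
                            timestamp = as.numeric(fixation_index)) {
  tx <- target[1]; ty <- target[2]
  h <- as.numeric(head_offset)
  corner <- profile$base_corner + h + stats::rnorm(2, 0, profile$noise_sd)
  gaze_disp <- c(profile$gain_x * tx + profile$quad_x * (tx^2 + tx * ty) +
                   profile$cubic * tx^3,
                 profile$gain_y * ty + profile$quad_y * (ty^2 + tx * ty) +
                   profile$cubic * ty^3)
  pupil <- profile$base_pupil + h + gaze_disp + profile$rot_gain * h +
    stats::rnorm(2, 0, profile$noise_sd)
  observations(pupil_x = pupil[1], pupil_y = pupil[2],
               corner_m = corner[1], corner_n = corner[2],
               tx = tx, ty = ty,
               subject_id = profile$subject_id,
               fixation_index = fixation_index,
               timestamp = timestamp)
}

#' Target scripts
#'
#' `script_calibration_9pt()` is the classic 9-point pattern on a 3x3 grid,
#' centre first. `script_grid_4x7()` enumerates the 4-row by 7-column
#' interaction grid, targets at cell centres. `script_free_play()` is a
#' seeded random walk over the 4x7 grid cells (moves to a random neighbouring
#' cell each step), with length drawn uniformly from 40-107 fixations — the
#' range of free-use session lengths the simulator emulates.
#'
#' @param screen A [screen_geometry()].
#' @param margin Fraction of the half-extent kept clear at the border of the
#'   9-point pattern.
#' @return A `data.frame` of targets `(tx, ty)` with a `kind` attribute.
#' @export
script_calibration_9pt <- function(screen = screen_geometry(),
                                   margin = 0.30) {
  hx <- screen$width_px / 2 * (1 - margin)
  hy <- screen$height_px / 2 * (1 - margin)
  pts <- expand.grid(tx = c(-hx, 0, hx), ty = c(-hy, 0, hy))
  pts <- pts[order(pts$tx != 0 | pts$ty != 0), ]  # centre first
  rownames(pts) <- NULL
  attr(pts, "kind") <- "calibration_9pt"
  pts
}

grid_4x7_centres <- function(screen) {
  cols <- (seq_len(7) - 4) / 7 * screen$width_px
  rows <- (seq_len(4) - 2.5) / 4 * screen$height_px
  expand.grid(tx = cols, ty = rows)
}

#' @rdname script_calibration_9pt
#' @export
script_grid_4x7 <- function(screen = screen_geometry()) {
  pts <- grid_4x7_centres(screen)
  rownames(pts) <- NULL
  attr(pts, "kind") <- "familiarization_grid"
  pts
}

#' @rdname script_calibration_9pt
#' @param seed Integer seed for the walk and the length draw.
#' @param length Number of fixations; drawn uniformly from `[40, 107]` when
#'   `NULL`.
#' @export
script_free_play <- function(seed, length = NULL,
                             screen = screen_geometry()) {
  with_seed(seed, {
    if (is.null(length)) length <- sample(40:107, 1)
    if (length < 1) stop("free-play length must be >= 1")
    centres <- grid_4x7_centres(screen)
    pos <- c(sample(7, 1), sample(4, 1))  # (col, row)
    idx <- integer(length)
    for (i in seq_len(length)) {
      idx[i] <- (pos[2] - 1) * 7 + pos[1]
      step <- c(sample(-1:1, 1), sample(-1:1, 1))
      pos <- pmin(pmax(pos + step, c(1, 1)), c(7, 4))
    }
    pts <- centres[idx, ]
    rownames(pts) <- NULL
    attr(pts, "kind") <- "free_play"
    pts
  })
}

#' Simulate a recorded session
#'
#' Plays a target script through a subject's forward model under a clamped
#' head random walk (per-coordinate steps of sd `head_step_sd`, excursion
#' clamped to `head_limit`), producing one observation per scripted target.
#' Byte-identical output for identical (profile, script, seed).
#'
#' @param profile A `subject_profile`.
#' @param script Target table `(tx, ty)` (e.g. from the script generators).
#' @param seed Integer seed for head motion and measurement noise.
#' @return A `simulated_session`: observations (with targets attached), the
#'   profile, and the per-fixation head track.
#' @export
simulate_session <- function(profile, script, seed) {
  n <- nrow(script)
  with_seed(seed, {
    head <- matrix(0, n, 2)
    if (n > 1) {
      for (i in 2:n) {
        step <- stats::rnorm(2, 0, profile$head_step_sd)
        head[i, ] <- pmin(pmax(head[i - 1, ] + step, -profile$head_limit),
                          profile$head_limit)
      }
    }
    obs <- vector("list", n)
    for (i in seq_len(n)) {
      obs[[i]] <- forward_observe(profile,
                                  c(script$tx[i], script$ty[i]),
                                  head[i, ],
                                  fixation_index = i - 1L,
                                  timestamp = 2 * (i - 1))
    }
    structure(list(observations = do.call(rbind, obs),
                   profile = profile,
                   head_track = head,
                   script_kind = attr(script, "kind")),
              class = "simulated_session")
  })
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("Simulated session: subject %s, %d fixations (%s)\n",
              x$profile$subject_id, nrow(x$observations),
              x$script_kind %||% "custom"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a cohort of simulated subjects and sessions
#'
#' Each subject gets one session consisting of a 9-point calibration segment
#' (centre target first, matching the convention that the session origin
#' corresponds to a screen-centre fixation) followed by a free-play segment
#' over the 4x7 grid, so both "calibration pattern samples" (the first 9
#' fixations) and "full trial samples" (all fixations) can be extracted.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master seed; subject profiles and sessions derive their own
#'   seeds from it.
#' @param variation A [subject_variation()].
#' @param screen A [screen_geometry()].
#' @param free_play_length Fixed free-play length, or `NULL` to draw from
#'   `[40, 107]` per subject.
#' @return List of `simulated_session`, one per subject.
#' @export
generate_cohort <- function(n_subjects, seed = 1,
                            variation = subject_variation(),
                            screen = screen_geometry(),
                            free_play_length = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    sub_seed <- (seed * 1000L + i) %% 2147483647L
    profile <- generate_subject(sub_seed, variation,
                                subject_id = sprintf("s%02d", i))
    script <- rbind(script_calibration_9pt(screen),
                    script_free_play(sub_seed + 1L,
                                     length = free_play_length,
                                     screen = screen))
    attr(script, "kind") <- "calibration_9pt+free_play"
    simulate_session(profile, script, sub_seed + 2L)
  })
}
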