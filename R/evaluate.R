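# Experiment harness: session replay, prior-size sweep, arbitrary-initial-
# target experiment, cross-subject feature-dispersion diagnostic, and small
# summary utilities.

#' Linear-interpolation percentile
#'
#' Order-statistic percentile with linear interpolation between adjacent
#' ranks (`stats::quantile` type 7).
#'
#' @param errors Non-empty numeric vector.
#' @param q Percentile in `[0, 100]`.
#' @return The percentile value.
#' @export
percentile <- function(errors, q = 95) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("percentile of an empty sequence")
  stats::quantile(errors, q / 100, type = 7, names = FALSE)
}

#' Rank-sum comparison of two error distributions
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test, reported alongside the
#' sample medians.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `statistic` (U), `p.value`, `median_a`, `median_b`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       median_a = stats::median(a), median_b = stats::median(b))
}

#' Replay a recorded session through the gaze pipeline
#'
#' Initializes a session from the first fixation via
#' [start_session_center()] (the first scripted target is the screen
#' centre), then walks the remaining fixations in order: for each, the gaze
#' is estimated and scored against the known target BEFORE the adaptive
#' update absorbs the (feature, target) pair, so the adaptive model is never
#' graded on a sample it has already seen. Errors are fractions of screen
#' width, measured to the target centre by default (`target_radius = 0`); a
#' positive radius reproduces the boundary-distance metric of live
#' interaction.
#'
#' @param prior A `gaze_prior`.
#' @param session A `simulated_session` (or any list with an `observations`
#'   table carrying targets).
#' @param space Coordinate space to run in (defaults to the prior's).
#' @param mode `"adaptive"` (model refitted after every scored fixation) or
#'   `"static"` (model frozen after initialization).
#' @param current_weight Weight of current-user samples.
#' @param screen A [screen_geometry()].
#' @param target_radius Visual radius used in the error metric, screen px.
#' @return A `data.frame` (class `error_series`): per-fixation errors with
#'   `fixation_index`, `half` (`"first"`/`"second"`), `subject_id`, `space`,
#'   `mode`.
#' @export
run_session_replay <- function(prior, session, space = prior$space,
                               mode = c("adaptive", "static"),
                               current_weight = 100 * prior$base_weight,
                               screen = screen_geometry(),
                               target_radius = 0) {
  mode <- match.arg(mode)
  space <- match_space(space)
  if (space != prior$space) stop("prior was built in a different space")
  obs <- session$observations
  if (!all(is.finite(obs$tx) & is.finite(obs$ty))) {
    stop("replay needs a target for every fixation")
  }
  ses <- start_session_center(prior, obs[1L, ],
                              current_weight = current_weight,
                              screen = screen,
                              adaptive = (mode == "adaptive"))
  n <- nrow(obs)
  if (n < 2L) stop("session too short to replay")
  err <- numeric(n - 1L)
  for (i in 2:n) {
    g <- estimate_gaze(ses, obs[i, ])
    tgt <- c(obs$tx[i], obs$ty[i])
    d <- sqrt(sum((as.numeric(g) - tgt)^2))
    err[i - 1L] <- max(0, d - target_radius) / screen$width_px
    ses <- update_session(ses, obs[i, ], tgt)
  }
  half_split <- ceiling((n - 1L) / 2)
  out <- data.frame(
    fixation_index = obs$fixation_index[-1L],
    error = err,
    half = ifelse(seq_len(n - 1L) <= half_split, "first", "second"),
    subject_id = obs$subject_id[1L],
    space = space, mode = mode,
    stringsAsFactors = FALSE)
  class(out) <- c("error_series", "data.frame")
  out
}

#' Prior-size sweep experiment
#'
#' For each prior size `n`, draws `n_draws` random subject subsets, builds a
#' prior from their full-trial samples, replays every held-out subject's
#' session (static and/or adaptive, in each requested space), and records the
#' 95th-percentile error of the first and second halves per held-out subject.
#'
#' @param cohort List of `simulated_session` (>= 3 subjects).
#' @param spaces Coordinate spaces to evaluate.
#' @param modes Subset of `c("static", "adaptive")`.
#' @param n_values Prior sizes to test (each `< length(cohort)`).
#' @param n_draws Random subject subsets per size.
#' @param seed Seed governing the subset draws.
#' @param q Percentile recorded (default 95).
#' @param ... Passed to [run_session_replay()].
#' @return A `data.frame` (class `sweep_result`) with columns `n_prior`,
#'   `space`, `mode`, `half`, `draw`, `subject_id`, `p95`.
#' @export
prior_sweep <- function(cohort, spaces = "local_relative",
                        modes = c("static", "adaptive"),
                        n_values = seq_len(length(cohort) - 1L),
                        n_draws = 20, seed = 1, q = 95, ...) {
  N <- length(cohort)
  if (N < 3L) stop("prior sweep needs at least 3 subjects")
  if (any(n_values >= N) || any(n_values < 1L)) {
    stop("prior sizes must lie in 1 .. cohort size - 1")
  }
  rows <- list()
  for (n in n_values) {
    draws <- with_seed(seed + n, {
      lapply(seq_len(n_draws), function(d) sample(N, n))
    })
    for (d in seq_along(draws)) {
      idx <- draws[[d]]
      held_out <- setdiff(seq_len(N), idx)
      for (space in spaces) {
        prior <- prior_from_sessions(cohort[idx], space)
        for (mode in modes) {
          for (h in held_out) {
            series <- run_session_replay(prior, cohort[[h]], space = space,
                                         mode = mode, ...)
            for (half in c("first", "second")) {
              rows[[length(rows) + 1L]] <- data.frame(
                n_prior = n, space = space, mode = mode, half = half,
                draw = d, subject_id = cohort[[h]]$profile$subject_id,
                p95 = percentile(series$error[series$half == half], q),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
plot.sweep_result <- function(x, space = x$space[1], mode = x$mode[1],
                              half = "first", ...) {
  sub <- x[x$space == space & x$mode == mode & x$half == half, ]
  graphics::boxplot(p95 ~ n_prior, data = sub,
                    xlab = "subjects in prior model",
                    ylab = "95th-percentile error (fraction of width)",
                    main = sprintf("%s, %s, %s half", space, mode, half), ...)
  invisible(x)
}

#' Arbitrary-initial-target experiment
#'
#' Slides windows of `sequence_length` targets along each session (each
#' window starting one target later than the previous), replays every window
#' as a fresh session initialized on the window's FIRST target via
#' [start_session_arbitrary()], and records the error at each within-sequence
#' position. With `init = "center"` the same windows are replayed with the
#' measured screen-centre fixation (the session's fixation 0) used for
#' initialization instead of the reconstructed one, giving the paired
#' baseline for the arbitrary-vs-centre comparison.
#'
#' @param cohort List of `simulated_session`.
#' @param sequence_length Window length in targets.
#' @param space Local coordinate space to run in.
#' @param init `"arbitrary"` (reconstructed origin from the window's first
#'   target) or `"center"` (measured centre fixation as origin).
#' @param max_windows Cap on windows per session (`Inf` for all).
#' @param current_weight,screen As in [run_session_replay()].
#' @return `data.frame` with `subject_id`, `window`, `position` (1 =
#'   initialization target), `error` (fraction of screen width; position 1 is
#'   the post-initialization residual on the initial target).
#' @export
arbitrary_target_experiment <- function(cohort, sequence_length = 8,
                                        space = "local_relative",
                                        init = c("arbitrary", "center"),
                                        max_windows = Inf,
                                        current_weight = 100,
                                        screen = screen_geometry()) {
  init <- match.arg(init)
  rows <- list()
  for (s in seq_along(cohort)) {
    session <- cohort[[s]]
    obs <- session$observations
    T_ <- nrow(obs)
    if (T_ < sequence_length + 1L) {
      warning(sprintf("session %s too short for %d-target windows; skipped",
                      session$profile$subject_id, sequence_length))
      next
    }
    # windows run over fixations 2..T (post-centre), starting one later each
    starts <- seq(2L, T_ - sequence_length + 1L)
    if (is.finite(max_windows)) starts <- utils::head(starts, max_windows)
    prior <- prior_from_sessions(cohort[-s], space)
    for (w in seq_along(starts)) {
      i0 <- starts[w]
      win <- i0:(i0 + sequence_length - 1L)
      first <- obs[win[1L], ]
      t_a <- c(first$tx, first$ty)
      ses <- if (init == "arbitrary") {
        try(start_session_arbitrary(prior, first, t_a,
                                    current_weight = current_weight,
                                    screen = screen), silent = TRUE)
      } else {
        s0 <- start_session_center(prior, obs[1L, ],
                                   current_weight = current_weight,
                                   screen = screen)
        update_session(s0, first, t_a)
      }
      if (inherits(ses, "try-error")) {
        warning(sprintf("window %d of %s: %s", w,
                        session$profile$subject_id, as.character(ses)))
        next
      }
      for (p in seq_along(win)) {
        i <- win[p]
        g <- as.numeric(estimate_gaze(ses, obs[i, ]))
        tgt <- c(obs$tx[i], obs$ty[i])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = session$profile$subject_id, window = w, position = p,
          error = sqrt(sum((g - tgt)^2)) / screen$width_px,
          init = init, stringsAsFactors = FALSE)
        if (p > 1L) ses <- update_session(ses, obs[i, ], tgt)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cross-subject feature-dispersion diagnostic
#'
#' Quantifies how far apart different subjects' eye features sit in a given
#' coordinate space: `between` is the RMS distance of per-subject feature
#' centroids (gaze components e1, e2) from the grand centroid, `within` the
#' RMS distance of each subject's features from their own centroid. Local
#' referencing should collapse `between` while leaving `within` (the actual
#' gaze signal) intact.
#'
#' @param cohort List of `simulated_session` (>= 2 subjects).
#' @param space Coordinate space to measure in.
#' @param use `"calibration"` restricts to the shared 9-point segment so all
#'   subjects are compared on identical targets (differing free-play coverage
#'   would otherwise masquerade as subject structure); `"all"` uses every
#'   fixation.
#' @return List with `between`, `within`, `ratio` (= between/within) and the
#'   per-subject centroid table.
#' @export
feature_dispersion <- function(cohort, space,
                               use = c("calibration", "all")) {
  use <- match.arg(use)
  if (length(cohort) < 2L) {
    stop("between-subject dispersion needs at least 2 subjects")
  }
  space <- match_space(space)
  cents <- list(); within <- numeric(0)
  for (ses in cohort) {
    obs <- ses$observations
    if (use == "calibration") obs <- obs[seq_len(min(9L, nrow(obs))), ]
    origin <- capture_origin(obs[1L, ])
    f <- make_feature(obs, space, origin)
    ctr <- colMeans(f[, c("e1", "e2")])
    cents[[length(cents) + 1L]] <- ctr
    within <- c(within, mean(sqrt((f$e1 - ctr[1])^2 + (f$e2 - ctr[2])^2)))
  }
  cmat <- do.call(rbind, cents)
  grand <- colMeans(cmat)
  between <- sqrt(mean((cmat[, 1] - grand[1])^2 + (cmat[, 2] - grand[2])^2))
  list(between = between, within = mean(within),
       ratio = between / mean(within),
       centroids = data.frame(subject = seq_len(nrow(cmat)),
                              e1 = cmat[, 1], e2 = cmat[, 2]))
}
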