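# Session lifecycle: prior-model construction, instant initialization from a
# single fixation (screen-centre or arbitrary target), live estimation, and
# adaptive refitting with elevated weight on the current user's samples.

#' Build a prior model from pooled multi-subject fixation samples
#'
#' A prior model replaces per-session calibration: it is simply a training set
#' of (eye feature, target) pairs collected beforehand from other subjects,
#' all expressed in one coordinate space, each carrying a common base weight.
#'
#' @param features Feature table (columns `e1..e4`), one space.
#' @param targets Matrix/data.frame of screen targets `(tx, ty)`.
#' @param space Coordinate space; defaults to the feature table's attribute.
#' @param base_weight Positive weight applied to every prior sample.
#' @param provenance Subject identifier per sample (recycled).
#' @return An object of class `gaze_prior`.
#' @export
prior_model <- function(features, targets, space = NULL, base_weight = 1,
                        provenance = "prior") {
  if (is.null(space)) space <- attr(features, "space")
  space <- match_space(space)
  T_ <- as.matrix(as.data.frame(targets)[, 1:2])
  samples <- data.frame(features[, c("e1", "e2", "e3", "e4")],
                        tx = T_[, 1], ty = T_[, 2],
                        weight = base_weight,
                        provenance = as.character(provenance),
                        stringsAsFactors = FALSE)
  if (base_weight <= 0) stop("base_weight must be positive")
  if (nrow(samples) < 8L) {
    stop("a prior model needs at least 8 fixation samples")
  }
  if (nrow(unique(samples[, c("tx", "ty")])) < 2L) {
    stop("a prior model needs samples spanning at least 2 distinct targets")
  }
  structure(list(samples = samples, space = space, base_weight = base_weight),
            class = "gaze_prior")
}

#' @export
print.gaze_prior <- function(x, ...) {
  cat(sprintf(
    "Gaze prior (%s space): %d samples from %d subject(s), base weight %g\n",
    x$space, nrow(x$samples), length(unique(x$samples$provenance)),
    x$base_weight))
  invisible(x)
}

#' Build a prior model from recorded sessions
#'
#' Converts each contributing session into the chosen coordinate space using
#' that subject's OWN first fixation as the origin (the convention under
#' which corner/local features from different subjects become comparable),
#' keeps the fixations with known targets, and pools them.
#'
#' @param sessions A list of sessions; each must have an `observations` table
#'   (as from [simulate_session()] or [read_session_log()]).
#' @param space Coordinate space for the pooled features.
#' @param base_weight Weight for every prior sample.
#' @param use Which fixations to keep: all of them (`"full_trial"`) or only
#'   the 9-point calibration segment (`"calibration"`, the first 9).
#' @return A `gaze_prior`.
#' @export
prior_from_sessions <- function(sessions, space, base_weight = 1,
                                use = c("full_trial", "calibration")) {
  use <- match.arg(use)
  space <- match_space(space)
  feats <- list(); tgts <- list(); prov <- list()
  for (ses in sessions) {
    obs <- ses$observations
    if (use == "calibration") obs <- obs[seq_len(min(9L, nrow(obs))), ]
    obs <- obs[is.finite(obs$tx) & is.finite(obs$ty), ]
    if (nrow(obs) == 0L) next
    origin <- capture_origin(obs[1L, ])
    feats[[length(feats) + 1L]] <- make_feature(obs, space, origin)
    tgts[[length(tgts) + 1L]] <- cbind(obs$tx, obs$ty)
    prov[[length(prov) + 1L]] <- obs$subject_id
  }
  if (length(feats) == 0L) stop("no fixations with known targets")
  prior_model(do.call(rbind, feats), do.call(rbind, tgts), space = space,
              base_weight = base_weight,
              provenance = unlist(prov))
}

session_samples <- function(session) {
  rbind(session$prior$samples, session$current)
}

refit_session <- function(session) {
  s <- session_samples(session)
  session$model <- gaze_fit(s[, c("e1", "e2", "e3", "e4")],
                            s[, c("tx", "ty")],
                            weights = s$weight,
                            space = session$space)
  session
}

new_session <- function(prior, origin, current, current_weight, screen,
                        adaptive) {
  if (current_weight < prior$base_weight) {
    stop("current_weight must be at least the prior's base weight")
  }
  session <- structure(
    list(space = prior$space, origin = origin, prior = prior,
         current = current, current_weight = current_weight,
         model = NULL, screen = screen, adaptive = adaptive),
    class = "gaze_session")
  refit_session(session)
}

current_sample <- function(feature, target, weight, session = NULL) {
  data.frame(feature[, c("e1", "e2", "e3", "e4")],
             tx = target[1], ty = target[2],
             weight = weight, provenance = "current",
             stringsAsFactors = FALSE)
}

#' Start a session from a screen-centre fixation
#'
#' The session origin is captured from the first fixation, recorded while the
#' user looks at a target at the screen centre; the pair (feature of that
#' fixation, centre target (0, 0)) is added with the elevated current-user
#' weight and the model is refitted. Under local spaces the first feature is
#' the zero vector by construction, so the convention "zero feature maps to
#' the screen centre" is planted into the model immediately.
#'
#' @param prior A `gaze_prior`.
#' @param first_obs The session's first fixation (one row).
#' @param current_weight Weight for current-user samples; defaults to 100x the
#'   prior base weight ("much larger", so incoming data rapidly dominates).
#' @param screen A [screen_geometry()].
#' @param adaptive If `FALSE`, [update_session()] becomes a no-op and the
#'   model stays static after initialization.
#' @return A `gaze_session`.
#' @export
start_session_center <- function(prior, first_obs,
                                 current_weight = 100 * prior$base_weight,
                                 screen = screen_geometry(),
                                 adaptive = TRUE) {
  if (!inherits(prior, "gaze_prior")) stop("prior must be a gaze_prior")
  origin <- capture_origin(first_obs)
  feat <- make_feature(first_obs, prior$space, origin)
  new_session(prior, origin,
              current_sample(feat, c(0, 0), current_weight),
              current_weight, screen, adaptive)
}

#' Start a session from an arbitrary initial target
#'
#' When the first fixation is on a known but arbitrary target `t_a` rather
#' than the screen centre, the centre-gaze pupil position `(x0, y0)` is
#' reconstructed by inverting the prior model
#' ([reconstruct_center_feature()]); the origin is built from the
#' reconstruction and the measured corner position, and BOTH the
#' reconstructed sample (zero feature, centre target) and the measured sample
#' (feature of the fixation, `t_a`) are added before refitting. Only local
#' spaces are supported: in corner/global spaces the first two feature
#' components are fully measured, leaving nothing to reconstruct.
#'
#' @inheritParams start_session_center
#' @param obs The session's first fixation (one row), on target `t_a`.
#' @param t_a Screen point `(tx, ty)` of the arbitrary initial target.
#' @param window_px Admissible-root window for the inverse solve, video px.
#' @return A `gaze_session`; errors (no admissible root, degenerate prior)
#'   propagate without creating a session, so callers may fall back to a
#'   centre-target start.
#' @export
start_session_arbitrary <- function(prior, obs, t_a,
                                    current_weight = 100 * prior$base_weight,
                                    screen = screen_geometry(),
                                    adaptive = TRUE,
                                    window_px = 200) {
  if (!inherits(prior, "gaze_prior")) stop("prior must be a gaze_prior")
  if (!prior$space %in% c("local_absolute", "local_relative")) {
    stop("arbitrary-target start requires a local coordinate space")
  }
  s <- prior$samples
  prior_fit <- gaze_fit(s[, c("e1", "e2", "e3", "e4")], s[, c("tx", "ty")],
                        weights = s$weight, space = prior$space)
  rec <- reconstruct_center_feature(prior_fit, obs, t_a, window_px = window_px)
  origin <- structure(list(x0 = rec$x0, y0 = rec$y0,
                           m0 = rec$m0, n0 = rec$n0),
                      class = "gaze_origin")
  # reconstructed fixation (x0, y0, m0, n0) has the zero feature under this
  # origin and is paired with the screen centre
  e0 <- feature_vector(0, 0, 0, 0, prior$space)
  e1 <- make_feature(obs, prior$space, origin)
  current <- rbind(current_sample(e0, c(0, 0), current_weight),
                   current_sample(e1, as.numeric(t_a), current_weight))
  new_session(prior, origin, current, current_weight, screen, adaptive)
}

#' Estimate the gaze point for a new fixation
#'
#' @param session A `gaze_session`.
#' @param obs Observation rows.
#' @return Matrix with columns `tx, ty`, one row per observation.
#' @export
estimate_gaze <- function(session, obs) {
  feat <- make_feature(obs, session$space, session$origin)
  predict(session$model, feat)
}

#' Add a confirmed fixation and refit the model
#'
#' Appends the (feature, target) pair with the elevated current-user weight
#' and recalculates the weighted least-squares model, as on every accepted
#' sample of the adaptive loop. In static sessions (`adaptive = FALSE`) the
#' call is a no-op and the model never changes.
#'
#' @param session A `gaze_session`.
#' @param obs The confirmed fixation (one row).
#' @param target The screen point `(tx, ty)` the fixation was directed at.
#' @return The updated `gaze_session`.
#' @export
update_session <- function(session, obs, target) {
  if (!session$adaptive) return(session)
  validate_observations(obs)
  target <- as.numeric(target)
  if (length(target) != 2L || !all(is.finite(target))) {
    stop("target must be a finite screen point (tx, ty)")
  }
  feat <- make_feature(obs, session$space, session$origin)
  session$current <- rbind(session$current,
                           current_sample(feat, target,
                                          session$current_weight))
  refit_session(session)
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf(
    "Gaze session (%s space, %s): prior %d samples, current %d, weight ratio %g:%g\n",
    x$space, if (x$adaptive) "adaptive" else "static",
    nrow(x$prior$samples), nrow(x$current),
    x$current_weight, x$prior$base_weight))
  print(x$origin)
  invisible(x)
}

#' Save and load a prior model bundle
#'
#' The bundle is a JSON file holding the space tag, all samples with their
#' weights, and per-sample provenance identifiers.
#'
#' @param prior A `gaze_prior`.
#' @param path File path.
#' @return `write_prior()`: `path` invisibly; `read_prior()`: a `gaze_prior`.
#' @export
write_prior <- function(prior, path) {
  jsonlite::write_json(
    list(space = prior$space, base_weight = prior$base_weight,
         samples = prior$samples),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  payload <- jsonlite::fromJSON(path)
  samples <- payload$samples
  structure(list(samples = samples, space = match_space(payload$space),
                 base_weight = payload$base_weight),
            class = "gaze_prior")
}
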