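# Coordinate spaces and eye-feature construction.
#
# Raw measurements are pupil-centre (x, y) and eye-corner (m, n) positions in
# video-image pixels with origin at the image centre. Six feature
# representations differ in the origin the components are referenced to:
# a shared global origin, the session's first eye-corner position, or local
# origins at the first recorded pupil AND corner positions.

#' Enumerate the supported coordinate spaces
#'
#' The six eye-feature representations, named by the origin choice
#' (`global`, `corner`, `local`) crossed with whether the pupil component is
#' taken absolutely or relative to the eye corner.
#'
#' @return Character vector of the six space names.
#' @export
space_kinds <- function() {
  c("global_absolute", "global_relative",
    "corner_absolute", "corner_relative",
    "local_absolute", "local_relative")
}

match_space <- function(space) {
  match.arg(space, space_kinds())
}

#' Does a coordinate space need a per-session origin?
#'
#' Corner and local spaces reference features to the session's first recorded
#' eye-corner (and, for local spaces, pupil) position; global spaces do not.
#'
#' @param space One of [space_kinds()].
#' @return `TRUE` for `corner_*` and `local_*` spaces, `FALSE` for `global_*`.
#' @export
requires_origin <- function(space) {
  space <- match_space(space)
  !startsWith(space, "global")
}

#' Build a set of fixation observations
#'
#' Assembles per-fixation pupil/corner measurements (and, when known, the
#' on-screen target each fixation was directed at) into the observation table
#' the rest of the package consumes. Coordinates are continuous (sub-pixel)
#' video-image pixels with origin at the image centre; targets are screen
#' pixels with origin at the screen centre.
#'
#' @param pupil_x,pupil_y Pupil-centre coordinates, video pixels.
#' @param corner_m,corner_n Eye-corner coordinates, video pixels.
#' @param tx,ty Optional target coordinates, screen pixels (`NA` when the
#'   fixated point is unknown).
#' @param subject_id Subject identifier (recycled).
#' @param fixation_index Ordinal index within the session, starting at 0.
#' @param timestamp Seconds from session start.
#' @return A `data.frame` with one row per fixation.
#' @export
observations <- function(pupil_x, pupil_y, corner_m, corner_n,
                         tx = NA_real_, ty = NA_real_,
                         subject_id = "s1",
                         fixation_index = seq_along(pupil_x) - 1L,
                         timestamp = as.numeric(fixation_index)) {
  obs <- data.frame(
    subject_id = as.character(subject_id),
    fixation_index = as.integer(fixation_index),
    timestamp = as.numeric(timestamp),
    pupil_x = as.numeric(pupil_x),
    pupil_y = as.numeric(pupil_y),
    corner_m = as.numeric(corner_m),
    corner_n = as.numeric(corner_n),
    tx = as.numeric(tx),
    ty = as.numeric(ty),
    stringsAsFactors = FALSE
  )
  validate_observations(obs)
  obs
}

validate_observations <- function(obs) {
  needed <- c("pupil_x", "pupil_y", "corner_m", "corner_n")
  missing <- setdiff(needed, names(obs))
  if (length(missing) > 0L) {
    stop("observations lack required columns: ", paste(missing, collapse = ", "))
  }
  coords <- as.matrix(obs[needed])
  if (!all(is.finite(coords))) {
    stop("pupil/corner coordinates must all be finite")
  }
  if ("fixation_index" %in% names(obs) && any(obs$fixation_index < 0L)) {
    stop("fixation_index must be >= 0")
  }
  invisible(obs)
}

#' Capture a session origin from the first fixation
#'
#' The origin of the corner and local coordinate spaces is determined from the
#' first measured gaze fixation of the session: its pupil position becomes
#' (x0, y0) and its corner position (m0, n0). The origin is set exactly once;
#' passing an already-captured origin via `existing` is rejected.
#'
#' @param obs A one-row observation (the session's first fixation).
#' @param existing An origin already captured for this session, if any;
#'   supplying one is an error (origins are immutable).
#' @return An object of class `gaze_origin` with fields `x0, y0, m0, n0`.
#' @export
capture_origin <- function(obs, existing = NULL) {
  if (!is.null(existing)) {
    stop("session origin already captured; origins are immutable")
  }
  validate_observations(obs)
  if (nrow(obs) != 1L) stop("origin is captured from exactly one fixation")
  origin <- list(x0 = obs$pupil_x, y0 = obs$pupil_y,
                 m0 = obs$corner_m, n0 = obs$corner_n)
  class(origin) <- "gaze_origin"
  origin
}

#' @export
print.gaze_origin <- function(x, ...) {
  cat(sprintf("Session origin: pupil (%.2f, %.2f), corner (%.2f, %.2f) px\n",
              x$x0, x$y0, x$m0, x$n0))
  invisible(x)
}

#' Construct eye-feature vectors in a chosen coordinate space
#'
#' Maps raw pupil/corner measurements to the 4-component eye feature
#' (e1, e2, e3, e4) of the requested space. e1, e2 carry the gaze-direction
#' signal (pupil pose), e3, e4 the head-related signal (corner pose). In
#' `local_relative` space, e1 = (x - x0) - (m - m0) and
#' e2 = (y - y0) - (n - n0): the change of the pupil-to-corner vector since
#' the session start, with head translation cancelled by construction.
#'
#' @param obs Observation table (any number of rows).
#' @param space One of [space_kinds()].
#' @param origin A `gaze_origin`; required for corner/local spaces, ignored
#'   for global spaces.
#' @return A `data.frame` with columns `e1..e4` and attribute `"space"`.
#' @export
make_feature <- function(obs, space, origin = NULL) {
  space <- match_space(space)
  validate_observations(obs)
  if (requires_origin(space) && is.null(origin)) {
    stop(sprintf("space '%s' requires a session origin", space))
  }
  x <- obs$pupil_x; y <- obs$pupil_y
  m <- obs$corner_m; n <- obs$corner_n
  f <- switch(space,
    global_absolute = cbind(x, y, m, n),
    global_relative = cbind(x - m, y - n, m, n),
    corner_absolute = cbind(x - origin$m0, y - origin$n0,
                            m - origin$m0, n - origin$n0),
    corner_relative = cbind(x - m, y - n,
                            m - origin$m0, n - origin$n0),
    local_absolute = cbind(x - origin$x0, y - origin$y0,
                           m - origin$m0, n - origin$n0),
    local_relative = cbind((x - origin$x0) - (m - origin$m0),
                           (y - origin$y0) - (n - origin$n0),
                           m - origin$m0, n - origin$n0)
  )
  feat <- as.data.frame(f)
  names(feat) <- c("e1", "e2", "e3", "e4")
  attr(feat, "space") <- space
  feat
}

#' @rdname make_feature
#' @details `feature_vector()` builds a feature table directly from numeric
#'   components, for features not derived from raw observations (e.g. the
#'   zero feature of the origin fixation).
#' @param e1,e2,e3,e4 Feature components, pixels.
#' @export
feature_vector <- function(e1, e2, e3, e4, space) {
  space <- match_space(space)
  feat <- data.frame(e1 = as.numeric(e1), e2 = as.numeric(e2),
                     e3 = as.numeric(e3), e4 = as.numeric(e4))
  if (!all(is.finite(as.matrix(feat)))) stop("feature components must be finite")
  attr(feat, "space") <- space
  feat
}
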