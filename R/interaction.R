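# Dwell-time target selection and the boundary-distance gaze-error metric.
#
# An interactive target has an invisible bounding collider (capture region)
# and a visible object inside it. While the estimated gaze stays within the
# collider the visual object shrinks; once the accumulated dwell time exceeds
# a threshold the target's event fires and the fixation is confirmed.

#' Screen and viewing geometry
#'
#' @param width_px,height_px Display region, screen pixels.
#' @param physical_width Physical width of the display region, millimetres.
#' @param viewing_distance Eye-to-screen distance, millimetres.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 800, height_px = 372,
                            physical_width = 176, viewing_distance = 310) {
  vals <- c(width_px, height_px, physical_width, viewing_distance)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("screen geometry values must be positive and finite")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 physical_width = physical_width,
                 viewing_distance = viewing_distance),
            class = "screen_geometry")
}

#' Define an interactive gaze target
#'
#' A circular target: the visible object of radius `visual_radius` sits inside
#' a larger bounding collider of radius `collider_radius` that captures gaze
#' overlap. The collider never changes size; only the visual object shrinks
#' during dwell.
#'
#' @param center Screen point `(tx, ty)`.
#' @param visual_radius Radius of the visible object, screen px; defaults to
#'   10% of the screen width (targets sized at 8-12% of screen width).
#' @param collider_radius Radius of the bounding collider, screen px; must be
#'   at least `visual_radius`, default 1.25x.
#' @param event_id Identifier attached to trigger records.
#' @param screen A [screen_geometry()] used for the default radius.
#' @return An object of class `interactive_target`.
#' @export
interactive_target <- function(center, visual_radius = 0.10 * screen$width_px,
                               collider_radius = 1.25 * visual_radius,
                               event_id = "target",
                               screen = screen_geometry()) {
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center))) {
    stop("center must be a screen point (tx, ty)")
  }
  if (visual_radius <= 0) stop("visual_radius must be positive")
  if (collider_radius < visual_radius) {
    stop("collider must contain the visual object")
  }
  structure(list(center = center, visual_radius = visual_radius,
                 collider_radius = collider_radius,
                 event_id = as.character(event_id)),
            class = "interactive_target")
}

#' Fresh dwell state
#'
#' @return A `dwell_state`: not engaged, zero elapsed dwell, unshrunk visual
#'   object (`shrink_fraction` 1).
#' @export
dwell_state <- function() {
  structure(list(engaged = FALSE, dwell_elapsed = 0, shrink_fraction = 1),
            class = "dwell_state")
}

#' Advance the dwell timer by one frame
#'
#' If the gaze point lies inside the target's collider, dwell time
#' accumulates and the visual object shrinks linearly from full size toward
#' half size as the threshold is approached; the collider radius never
#' changes. When accumulated dwell reaches the threshold (1.8 s by default) a
#' trigger record is emitted — carrying the event id and the trigger time —
#' and the state resets. If the gaze leaves the collider the state resets
#' fully: dwell restarts from zero on re-entry.
#'
#' @param state A `dwell_state`.
#' @param gaze Estimated gaze point `(tx, ty)`, screen px.
#' @param target An [interactive_target()].
#' @param dt Frame duration, seconds (> 0).
#' @param threshold Dwell threshold, seconds.
#' @param time Current session time, seconds (recorded on triggers).
#' @return List with elements `state` (new `dwell_state`) and `trigger`
#'   (a trigger record, or `NULL`).
#' @export
step_dwell <- function(state, gaze, target, dt, threshold = 1.8, time = NA) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  gaze <- as.numeric(gaze)
  d <- sqrt(sum((gaze - target$center)^2))
  if (d > target$collider_radius) {
    return(list(state = dwell_state(), trigger = NULL))
  }
  elapsed <- state$dwell_elapsed + dt
  if (elapsed >= threshold) {
    trigger <- list(event_id = target$event_id,
                    target = target$center,
                    gaze = gaze,
                    trigger_time = time,
                    dwell = elapsed)
    return(list(state = dwell_state(), trigger = trigger))
  }
  new_state <- structure(
    list(engaged = TRUE, dwell_elapsed = elapsed,
         shrink_fraction = 1 - 0.5 * elapsed / threshold),
    class = "dwell_state")
  list(state = new_state, trigger = NULL)
}

#' Boundary-distance gaze error
#'
#' The error of a gaze estimate with respect to a target is its distance to
#' the visible object's boundary, divided by the screen width in pixels: zero
#' anywhere on or inside the visual disc (the gaze may legitimately rest
#' anywhere within the visible target), and `(d - R) / width` outside it,
#' where `d` is the distance to the target centre and `R` the visual radius.
#'
#' @param gaze Gaze point(s): numeric `(tx, ty)` or a 2-column matrix.
#' @param target An [interactive_target()], or a bare screen point (treated
#'   as a point target of radius `0`).
#' @param screen A [screen_geometry()].
#' @return Gaze error(s) as a fraction of screen width.
#' @export
gaze_error <- function(gaze, target, screen = screen_geometry()) {
  if (screen$width_px <= 0) stop("screen width must be positive")
  if (inherits(target, "interactive_target")) {
    center <- target$center
    radius <- target$visual_radius
  } else {
    center <- as.numeric(target)
    radius <- 0
  }
  g <- if (is.null(dim(gaze))) matrix(as.numeric(gaze), ncol = 2) else gaze
  d <- sqrt((g[, 1] - center[1])^2 + (g[, 2] - center[2])^2)
  pmax(0, d - radius) / screen$width_px
}

#' Convert a fractional gaze error to visual degrees
#'
#' Maps an error expressed as a fraction of the screen width to the visual
#' angle it subtends at the viewing distance:
#' `atan(fraction * physical_width / viewing_distance)` in degrees.
#'
#' @param fraction Error as a fraction of screen width.
#' @param screen A [screen_geometry()] with positive physical width and
#'   viewing distance.
#' @return Visual angle, degrees.
#' @export
error_to_degrees <- function(fraction, screen = screen_geometry()) {
  if (screen$physical_width <= 0 || screen$viewing_distance <= 0) {
    stop("physical width and viewing distance must be positive")
  }
  atan(fraction * screen$physical_width / screen$viewing_distance) * 180 / pi
}
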