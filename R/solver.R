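# Inverse-model bootstrap: recover the pupil position that corresponds to the
# screen centre when a session begins on an arbitrary target.
#
# With the head components pinned at their initial values (m = m0, n = n0),
# the first two feature components of a local-space observation are
# (x - x0, y - y0). If the user is fixating an arbitrary target t_a, the
# prior model f must satisfy f(x - x0, y - y0, 0, 0) = t_a, a 2-unknown
# quadratic system whose root gives (x0, y0) = (x, y) - f^{-1}(t_a).

#' Reconstruct the screen-centre pupil position from an arbitrary target
#'
#' Numerically inverts the prior gaze model on its first two (gaze-direction)
#' feature components, solving `f(dx, dy, 0, 0) = t_a` for `(dx, dy)` with a
#' damped least-squares (Levenberg-Marquardt) iteration, multi-started from
#' the window centre and the four window-quadrant midpoints, to termination
#' tolerance 1e-8. Because the model is quadratic there may be several roots:
#' only roots inside the `window_px` x `window_px` rectangle centred at the
#' measured pupil position are physically admissible (the eye region spans
#' only a fraction of the camera image), and among those the one nearest the
#' measured pupil position is returned.
#'
#' @param model A fitted `gaze_model` (the prior).
#' @param obs One-row observation measured while the user fixates `t_a`.
#' @param t_a The known arbitrary target, screen pixels `(tx, ty)`.
#' @param window_px Side of the admissible square window, video pixels.
#' @param tol Residual tolerance (screen px) for accepting a root.
#' @return List with `x0, y0` (reconstructed centre-gaze pupil position),
#'   `m0, n0` (measured corner), `delta` (= `f^{-1}(t_a)`), and `residual`.
#' @export
reconstruct_center_feature <- function(model, obs, t_a, window_px = 200,
                                       tol = 1e-8) {
  validate_observations(obs)
  if (nrow(obs) != 1L) stop("reconstruction uses exactly one fixation")
  t_a <- as.numeric(t_a)
  if (length(t_a) != 2L || !all(is.finite(t_a))) {
    stop("t_a must be a finite screen point (tx, ty)")
  }
  cc <- model$coefficients
  # sensitivity of f to (e1, e2) at the origin: the linear terms
  J0 <- rbind(cc[c("e1", "e2"), "x"], cc[c("e1", "e2"), "y"])
  if (rcond_2x2(J0) < 1e-10) {
    stop("prior model is degenerate: near-zero gaze-direction sensitivity")
  }

  resid_fun <- function(d) {
    v <- c(1, d[1], d[2], d[1] * d[2], d[1]^2, d[2]^2, 0, 0)
    as.numeric(v %*% cc) - t_a
  }
  jac_fun <- function(d) {
    dv1 <- c(0, 1, 0, d[2], 2 * d[1], 0, 0, 0)
    dv2 <- c(0, 0, 1, d[1], 0, 2 * d[2], 0, 0)
    # J[i, j] = d f_i / d d_j
    cbind(as.numeric(dv1 %*% cc), as.numeric(dv2 %*% cc))
  }
  # Newton polish: LM stops at its relative tolerance; a few Newton steps
  # drive the residual to the absolute 1e-8 contract
  polish <- function(d) {
    for (it in 1:30) {
      r <- resid_fun(d)
      if (sqrt(sum(r^2)) <= tol) break
      step <- tryCatch(solve(jac_fun(d), r), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      d <- d - step
    }
    d
  }
  half <- window_px / 2
  q <- half / 2
  starts <- list(c(0, 0), c(q, q), c(-q, q), c(q, -q), c(-q, -q))

  roots <- list()
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = tol^2, ptol = 1e-12,
                                           maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    d <- polish(as.numeric(fit$par))
    r <- sqrt(sum(resid_fun(d)^2))
    if (r <= tol && all(abs(d) <= half)) {
      roots[[length(roots) + 1L]] <- list(d = d, r = r)
    }
  }
  if (length(roots) == 0L) {
    stop(sprintf(
      "no admissible root: f(dx, dy, 0, 0) = (%.1f, %.1f) has no solution in the %g x %g px window",
      t_a[1], t_a[2], window_px, window_px))
  }
  # deduplicate (keys rounded, values kept at full precision) and take the
  # root nearest the measured pupil position, i.e. the smallest |delta|
  dmat <- do.call(rbind, lapply(roots, `[[`, "d"))
  dmat <- dmat[!duplicated(round(dmat, 4)), , drop = FALSE]
  best <- dmat[which.min(rowSums(dmat^2)), ]
  list(x0 = obs$pupil_x - best[1],
       y0 = obs$pupil_y - best[2],
       m0 = obs$corner_m,
       n0 = obs$corner_n,
       delta = best,
       residual = sqrt(sum(resid_fun(best)^2)))
}

rcond_2x2 <- function(J) {
  sv <- svd(J)$d
  if (max(sv) == 0) return(0)
  min(sv) / max(sv)
}
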