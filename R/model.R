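# Quadratic polynomial gaze mapping, fitted by weighted least squares.
#
# A gaze point g = (gx, gy) on the screen is modelled per axis as the dot
# product of a fixed design expansion of the eye feature e = (e1,e2,e3,e4),
#   v = (1, e1, e2, e1*e2, e1^2, e2^2, e3, e4),
# with coefficient vectors c_x = (a0..a7), c_y = (b0..b7). The gaze-direction
# components enter up to quadratic order; the head components enter linearly.

design_terms <- c("1", "e1", "e2", "e1:e2", "e1^2", "e2^2", "e3", "e4")

#' Design-matrix expansion of eye features
#'
#' Expands each feature row into the 8-term design vector
#' `(1, e1, e2, e1*e2, e1^2, e2^2, e3, e4)`.
#'
#' @param features A feature table (columns `e1..e4`) or numeric vector of
#'   length 4.
#' @return Numeric matrix with one row per feature and 8 named columns.
#' @export
design_row <- function(features) {
  if (is.numeric(features) && is.null(dim(features))) {
    features <- as.data.frame(as.list(stats::setNames(features,
                                                      c("e1", "e2", "e3", "e4"))))
  }
  f <- as.matrix(features[, c("e1", "e2", "e3", "e4")])
  if (!all(is.finite(f))) stop("features must be finite")
  v <- cbind(1, f[, 1], f[, 2], f[, 1] * f[, 2], f[, 1]^2, f[, 2]^2,
             f[, 3], f[, 4])
  colnames(v) <- design_terms
  v
}

#' Fit the quadratic gaze model by weighted least squares
#'
#' Estimates the coefficients `c = (c_x, c_y)` minimising the weighted
#' residual `||W (V c - T)||^2` per screen axis, where `V` stacks the design
#' rows of the training features, `T` the target coordinates and
#' `W = diag(w)` the per-sample weights. With equal weights this is ordinary
#' least squares. The x and y axes share `V` and `W` and are solved
#' separately. Rank-deficient systems return the minimum-norm least-squares
#' solution (via the SVD pseudoinverse), so a model is well defined from the
#' very first sample of a session. No conditioning/centring of `V` is applied
#' before solving; an optional ridge penalty (default 0) is available for
#' ill-conditioned priors.
#'
#' @param features Feature table (columns `e1..e4`), all in one space.
#' @param targets Two-column matrix or data.frame of screen points `(tx, ty)`,
#'   screen pixels with origin at the screen centre.
#' @param weights Positive per-sample weights; default all 1. Weights enter
#'   the objective squared, i.e. a sample of weight `w` contributes `w^2`
#'   times its squared residual.
#' @param space Coordinate space of the features (recorded in the model; taken
#'   from the feature table's `"space"` attribute when absent).
#' @param ridge Optional ridge penalty added to the weighted normal matrix.
#' @return An object of class `gaze_model`: coefficient matrix (8 terms by 2
#'   axes), fitted values, residuals, rank, and fit metadata.
#' @examples
#' feat <- feature_vector(rnorm(20), rnorm(20), rnorm(20), rnorm(20),
#'                        space = "local_relative")
#' tgt <- cbind(tx = rnorm(20, sd = 100), ty = rnorm(20, sd = 50))
#' fit <- gaze_fit(feat, tgt)
#' coef(fit)
#' @export
gaze_fit <- function(features, targets, weights = NULL, space = NULL,
                     ridge = 0) {
  if (is.null(space)) space <- attr(features, "space")
  if (is.null(space)) space <- "local_relative"
  space <- match_space(space)
  if (nrow(as.data.frame(features)) == 0L) stop("training set is empty")
  V <- design_row(features)
  T_ <- as.matrix(as.data.frame(targets)[, 1:2])
  colnames(T_) <- c("tx", "ty")
  M <- nrow(V)
  if (nrow(T_) != M) stop("features and targets differ in length")
  if (!all(is.finite(T_))) stop("targets must be finite")
  if (is.null(weights)) weights <- rep(1, M)
  weights <- as.numeric(weights)
  if (length(weights) != M) stop("weights must match the number of samples")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }

  Vw <- V * weights
  Tw <- T_ * weights
  if (ridge > 0) {
    A <- crossprod(Vw) + diag(ridge, ncol(V))
    cc <- solve(A, crossprod(Vw, Tw))
    rank <- ncol(V)
  } else {
    sv <- svd(Vw)
    tol <- max(dim(Vw)) * .Machine$double.eps * max(sv$d, 0)
    pos <- sv$d > tol
    rank <- sum(pos)
    if (rank == 0L) stop("design matrix is identically zero")
    cc <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], Tw) / sv$d[pos])
  }
  dimnames(cc) <- list(design_terms, c("x", "y"))
  fitted <- V %*% cc
  colnames(fitted) <- c("tx", "ty")
  structure(
    list(coefficients = cc,
         space = space,
         n = M,
         rank = rank,
         ridge = ridge,
         weights = weights,
         fitted.values = fitted,
         residuals = T_ - fitted,
         targets = T_),
    class = "gaze_model"
  )
}

#' @export
coef.gaze_model <- function(object, ...) object$coefficients

#' Predict screen gaze points from eye features
#'
#' @param object A fitted `gaze_model`.
#' @param newdata Feature table (columns `e1..e4`); defaults to the training
#'   features' fitted values when omitted.
#' @param ... Unused.
#' @return Matrix with columns `tx, ty` (screen pixels, centred origin).
#' @export
predict.gaze_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  V <- design_row(newdata)
  out <- V %*% object$coefficients
  colnames(out) <- c("tx", "ty")
  out
}

#' @export
residuals.gaze_model <- function(object, ...) object$residuals

#' @export
fitted.gaze_model <- function(object, ...) object$fitted.values

#' @export
print.gaze_model <- function(x, digits = 4, ...) {
  cat(sprintf("Quadratic gaze model (%s space), %d samples, rank %d\n",
              x$space, x$n, x$rank))
  print(round(t(x$coefficients), digits))
  invisible(x)
}

#' @export
summary.gaze_model <- function(object, ...) {
  res <- object$residuals
  w <- object$weights
  rms <- sqrt(colMeans(res^2))
  wrms <- sqrt(colSums((res * w)^2) / sum(w^2))
  err <- sqrt(rowSums(res^2))
  out <- list(model = object,
              rms = rms,
              weighted_rms = wrms,
              radial_error = summary(err),
              weight_range = range(w))
  class(out) <- "summary.gaze_model"
  out
}

#' @export
print.summary.gaze_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Residual RMS (px): x %.3f, y %.3f; weighted: x %.3f, y %.3f\n",
              x$rms[1], x$rms[2], x$weighted_rms[1], x$weighted_rms[2]))
  cat(sprintf("Sample weights in [%g, %g]\n",
              x$weight_range[1], x$weight_range[2]))
  cat("Radial training error (px):\n")
  print(x$radial_error)
  invisible(x)
}

#' @export
plot.gaze_model <- function(x, ...) {
  t_ <- x$targets
  f <- x$fitted.values
  graphics::plot(t_[, 1], t_[, 2], pch = 3, col = "grey40",
                 xlab = "tx (px)", ylab = "ty (px)",
                 main = sprintf("Gaze model fit (%s)", x$space), ...)
  graphics::points(f[, 1], f[, 2], pch = 1, col = "firebrick")
  graphics::segments(t_[, 1], t_[, 2], f[, 1], f[, 2], col = "grey70")
  graphics::legend("topright", pch = c(3, 1), col = c("grey40", "firebrick"),
                   legend = c("target", "fitted"), bty = "n")
  invisible(x)
}

#' Serialize a gaze model to and from JSON
#'
#' Coefficients are stored in fixed order (`a0..a7`, `b0..b7`) together with
#' the space tag and fit metadata (sample count, weight range, rank).
#'
#' @param model A `gaze_model`.
#' @param path File path; when `NULL`, `gaze_model_to_json()` returns the JSON
#'   string.
#' @return `gaze_model_to_json()`: the path (or JSON string) invisibly;
#'   `gaze_model_from_json()`: a `gaze_model` usable for prediction.
#' @export
gaze_model_to_json <- function(model, path = NULL) {
  payload <- list(
    space = model$space,
    cx = as.numeric(model$coefficients[, "x"]),
    cy = as.numeric(model$coefficients[, "y"]),
    terms = design_terms,
    n_samples = model$n,
    rank = model$rank,
    weight_range = range(model$weights)
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gaze_model_to_json
#' @param json A path to, or string of, JSON written by `gaze_model_to_json()`.
#' @export
gaze_model_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  cc <- cbind(x = as.numeric(payload$cx), y = as.numeric(payload$cy))
  rownames(cc) <- design_terms
  structure(
    list(coefficients = cc, space = match_space(payload$space),
         n = payload$n_samples, rank = payload$rank, ridge = 0,
         weights = numeric(0),
         fitted.values = NULL, residuals = NULL, targets = NULL),
    class = "gaze_model"
  )
}
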