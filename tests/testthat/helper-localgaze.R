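# Shared fixtures and independent oracles for the test suite.

# random feature table in general position
rand_features <- function(n, seed, space = "local_relative", scale = 20) {
  withr_seed(seed)
  feature_vector(rnorm(n, 0, scale), rnorm(n, 0, scale),
                 rnorm(n, 0, scale / 2), rnorm(n, 0, scale / 2),
                 space = space)
}

withr_seed <- function(seed) set.seed(seed)

# random coefficient matrix (8 terms x 2 axes) at screen-plausible magnitudes
rand_coefs <- function(seed) {
  set.seed(seed)
  cc <- cbind(x = c(rnorm(1, 0, 20), rnorm(1, 11, 1), rnorm(1, 0, 0.5),
                    rnorm(1, 0, 0.01), rnorm(1, 0, 0.05), rnorm(1, 0, 0.05),
                    rnorm(2, 0, 0.5)),
              y = c(rnorm(1, 0, 20), rnorm(1, 0, 0.5), rnorm(1, 11, 1),
                    rnorm(1, 0, 0.01), rnorm(1, 0, 0.05), rnorm(1, 0, 0.05),
                    rnorm(2, 0, 0.5)))
  rownames(cc) <- c("1", "e1", "e2", "e1:e2", "e1^2", "e2^2", "e3", "e4")
  cc
}

# gaze model object around explicit coefficients (prediction only)
model_from_coefs <- function(cc, space = "local_relative") {
  structure(list(coefficients = cc, space = space, n = 0, rank = 8,
                 ridge = 0, weights = numeric(0)),
            class = "gaze_model")
}

# independent weighted-least-squares oracle: literal normal equations
# c = (V' W' W V)^{-1} V' W' W T with W = diag(w)
wls_oracle <- function(features, targets, weights) {
  V <- design_row(features)
  T_ <- as.matrix(as.data.frame(targets)[, 1:2])
  W2 <- diag(weights^2, nrow = length(weights))
  solve(t(V) %*% W2 %*% V, t(V) %*% W2 %*% T_)
}

# independent term-by-term prediction oracle
predict_oracle <- function(cc, feat) {
  f <- as.numeric(feat[1, c("e1", "e2", "e3", "e4")])
  v <- c(1, f[1], f[2], f[1] * f[2], f[1]^2, f[2]^2, f[3], f[4])
  c(sum(v * cc[, "x"]), sum(v * cc[, "y"]))
}

# grid-search-plus-polish oracle for the inverse-model solve:
# coarse grid over the window, 0.1 px refinement around candidate minima,
# Nelder-Mead/BFGS polish, nearest-to-origin admissible root returned.
grid_inverse_oracle <- function(cc, t_a, window_px = 200) {
  half <- window_px / 2
  res2 <- function(dx, dy) {
    gx <- cc["1", "x"] + cc["e1", "x"] * dx + cc["e2", "x"] * dy +
      cc["e1:e2", "x"] * dx * dy + cc["e1^2", "x"] * dx^2 +
      cc["e2^2", "x"] * dy^2
    gy <- cc["1", "y"] + cc["e1", "y"] * dx + cc["e2", "y"] * dy +
      cc["e1:e2", "y"] * dx * dy + cc["e1^2", "y"] * dx^2 +
      cc["e2^2", "y"] * dy^2
    (gx - t_a[1])^2 + (gy - t_a[2])^2
  }
  coarse <- seq(-half, half, by = 2)
  R <- outer(coarse, coarse, res2)
  # candidate basins: the best coarse cells, deduplicated by separation
  ord <- order(R)[1:40]
  cand <- cbind(coarse[(ord - 1) %% length(coarse) + 1],
                coarse[(ord - 1) %/% length(coarse) + 1])
  roots <- list()
  for (k in seq_len(nrow(cand))) {
    cx <- cand[k, 1]; cy <- cand[k, 2]
    if (length(roots) > 0 &&
        any(vapply(roots, function(r) sum((r - c(cx, cy))^2) < 16,
                   logical(1)))) next
    fx <- seq(max(-half, cx - 2), min(half, cx + 2), by = 0.1)
    fy <- seq(max(-half, cy - 2), min(half, cy + 2), by = 0.1)
    Rf <- outer(fx, fy, res2)
    i <- which.min(Rf)
    start <- c(fx[(i - 1) %% length(fx) + 1], fy[(i - 1) %/% length(fx) + 1])
    pol <- stats::optim(start, function(p) res2(p[1], p[2]),
                        method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    if (pol$value < 1e-12 && all(abs(pol$par) <= half)) {
      roots[[length(roots) + 1L]] <- pol$par
    }
  }
  if (length(roots) == 0L) return(NULL)
  rmat <- do.call(rbind, roots)
  rmat[which.min(rowSums(rmat^2)), ]
}

# noiseless, motionless subject whose forward map is exactly within the
# quadratic model family (quad = 0)
exact_profile <- function(seed = 1) {
  generate_subject(seed, subject_variation(noise_sd = 0, head_step_sd = 0,
                                           quad_mean = 0, quad_sd = 0,
                                           rot_gain = 0))
}

# small deterministic multi-subject prior in a given space
small_prior <- function(space = "local_relative", n_subjects = 5, seed = 11,
                        ...) {
  cohort <- generate_cohort(n_subjects, seed = seed,
                            variation = subject_variation(...),
                            free_play_length = 30)
  prior_from_sessions(cohort, space)
}
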