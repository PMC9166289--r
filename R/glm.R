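#' Raised-cosine temporal basis
#'
#' `n` evenly spaced raised-cosine bumps over `span` seconds (relative to
#' the event), evaluated on the frame-lag grid; the half-width equals the
#' center spacing so adjacent bases overlap halfway, and each basis is
#' normalized to unit sum over the lag grid.
#'
#' @param n Number of bases.
#' @param span Numeric length-2, start and end of the support in seconds
#'   (negative = before the event).
#' @param frame_rate Frames per second of the target clock.
#' @return A `raised_cosine` list: `kernel` (lags x n matrix), `lags`
#'   (frame offsets), `centers` (seconds).
#' @export
raised_cosine_basis <- function(n, span, frame_rate) {
  stopifnot(n >= 1, length(span) == 2, span[2] > span[1])
  centers <- seq(span[1], span[2], length.out = n)
  width <- if (n > 1) diff(centers)[1] else diff(span) / 2
  lag_lo <- floor((span[1] - width) * frame_rate)
  lag_hi <- ceiling((span[2] + width) * frame_rate)
  lags <- lag_lo:lag_hi
  tsec <- lags / frame_rate
  kernel <- sapply(centers, function(c0) {
    v <- 0.5 * (1 + cos(pi * (tsec - c0) / width))
    v[abs(tsec - c0) >= width] <- 0
    v / sum(v)
  })
  structure(list(kernel = kernel, lags = lags, centers = centers,
                 width = width, frame_rate = frame_rate),
            class = "raised_cosine")
}

# cross-correlate signal with each basis column:
# out[t, k] = sum_l kernel[l, k] * s[t - lag_l]
convolve_basis <- function(s, basis) {
  n <- length(s)
  out <- matrix(0, n, ncol(basis$kernel))
  for (k in seq_len(ncol(basis$kernel))) {
    kk <- basis$kernel[, k]
    nz <- which(kk != 0)
    acc <- numeric(n)
    for (j in nz) {
      lag <- basis$lags[j]
      src <- seq_len(n) - lag
      ok <- src >= 1 & src <= n
      acc[ok] <- acc[ok] + kk[j] * s[src[ok]]
    }
    out[, k] <- acc
  }
  out
}

#' Spatial raised-cosine basis
#'
#' A `nx` x `ny` grid of separable raised-cosine bumps tiling the arena
#' (half-width equal to the center spacing along each axis; peak value 1).
#' These are the position predictors of the encoding model and double as
#' place-field proxies for chance-level estimation.
#'
#' @param nx,ny Bumps along x and y (default 10 x 10 = 100 bases).
#' @param extent Arena extent.
#' @return A `spatial_basis` list with `centers` tibble and `eval(x, y)`
#'   returning an n x (nx*ny) matrix.
#' @export
spatial_basis <- function(nx = 10, ny = 10, extent = c(1, 1)) {
  cxs <- (seq_len(nx) - 0.5) / nx * extent[1]
  cys <- (seq_len(ny) - 0.5) / ny * extent[2]
  wx <- extent[1] / nx; wy <- extent[2] / ny
  centers <- tidyr::expand_grid(cy = cys, cx = cxs)[, c("cx", "cy")]
  bump <- function(d, w) {
    v <- 0.5 * (1 + cos(pi * d / w))
    v[abs(d) >= w] <- 0
    v
  }
  evalf <- function(x, y) {
    fx <- outer(x, centers$cx, function(a, b) bump(a - b, wx))
    fy <- outer(y, centers$cy, function(a, b) bump(a - b, wy))
    fx * fy
  }
  structure(list(nx = nx, ny = ny, extent = extent, centers = centers,
                 wx = wx, wy = wy, eval = evalf),
            class = "spatial_basis")
}

#' Evaluate the spatial basis on a bin grid
#'
#' @param basis A [spatial_basis()].
#' @param spec A [bin_spec()].
#' @return Bins x n_basis matrix of basis values at bin centers.
#' @export
spatial_basis_maps <- function(basis, spec) {
  bc <- bin_centers(spec)
  basis$eval(bc$x, bc$y)
}

#' Basis specification of the encoding model
#'
#' Default counts and spans: trial onset 6 bases over +-2 s, trial offset
#' 6 over +-2 s, object velocity 6 per direction channel (8 channels) over
#' +-2 s, joystick velocity likewise, object position 100 spatial bases
#' (10 x 10), reward onset 9 bases over -2 to +4 s; 217 predictors in
#' total.
#'
#' @param frame_rate Imaging frame rate (Hz).
#' @param extent Arena extent for the spatial basis.
#' @param n_onset,n_offset,n_velocity,n_reward,n_space_x,n_space_y Basis
#'   counts per variable.
#' @return A `basis_spec` list with realized bases and the predictor-group
#'   layout (`groups`: tibble of group, column range).
#' @export
basis_spec <- function(frame_rate = 5.67, extent = c(10, 10),
                       n_onset = 6, n_offset = 6, n_velocity = 6,
                       n_reward = 9, n_space_x = 10, n_space_y = 10) {
  b_on <- raised_cosine_basis(n_onset, c(-2, 2), frame_rate)
  b_off <- raised_cosine_basis(n_offset, c(-2, 2), frame_rate)
  b_vel <- raised_cosine_basis(n_velocity, c(-2, 2), frame_rate)
  b_rew <- raised_cosine_basis(n_reward, c(-2, 4), frame_rate)
  b_sp <- spatial_basis(n_space_x, n_space_y, extent)
  counts <- c(trial_onset = n_onset, trial_offset = n_offset,
              object_velocity = 8 * n_velocity,
              joystick_velocity = 8 * n_velocity,
              object_position = n_space_x * n_space_y,
              reward = n_reward)
  ends <- cumsum(counts)
  groups <- tibble(group = names(counts), n = as.integer(counts),
                   first = as.integer(ends - counts + 1),
                   last = as.integer(ends))
  structure(list(frame_rate = frame_rate, onset = b_on, offset = b_off,
                 velocity = b_vel, reward = b_rew, space = b_sp,
                 groups = groups, n_predictors = as.integer(sum(counts))),
            class = "basis_spec")
}

#' Build the basis-expanded design matrix
#'
#' Temporal task variables (trial onset/offset flags, the 8 direction
#' channels of object and joystick velocity, reward onset flags) are
#' convolved with their raised-cosine bases; the object position is
#' expanded onto the spatial bases evaluated at the frame's coordinates.
#' All columns are z-scored (constant columns left at zero); column order
#' follows `basis$groups`.
#'
#' @param vars Frame-rate task variables: a list or tibble with fields
#'   `trial_onset`, `trial_offset`, `reward_onset` (0/1 flags),
#'   `object_velocity`, `joystick_velocity` (frames x 8 magnitude
#'   matrices), `x`, `y` (object position per frame). See
#'   [frame_variables()].
#' @param basis A [basis_spec()].
#' @return A `design_matrix`: list with `X` (frames x 217 at defaults),
#'   `center`, `scale`, `groups`, `basis`.
#' @export
build_design_matrix <- function(vars, basis = basis_spec()) {
  n <- length(vars$trial_onset)
  need <- c("trial_onset", "trial_offset", "reward_onset",
            "object_velocity", "joystick_velocity", "x", "y")
  for (f in need) if (is.null(vars[[f]])) abort(paste0("input error: missing variable ", f))
  lens <- c(length(vars$trial_offset), length(vars$reward_onset),
            nrow(vars$object_velocity), nrow(vars$joystick_velocity),
            length(vars$x), length(vars$y))
  if (any(lens != n)) abort("input error: task-variable lengths differ")
  vel_block <- function(V, b) {
    do.call(cbind, lapply(seq_len(ncol(V)), function(d) convolve_basis(V[, d], b)))
  }
  X <- cbind(
    convolve_basis(vars$trial_onset, basis$onset),
    convolve_basis(vars$trial_offset, basis$offset),
    vel_block(vars$object_velocity, basis$velocity),
    vel_block(vars$joystick_velocity, basis$velocity),
    basis$space$eval(vars$x, vars$y),
    convolve_basis(vars$reward_onset, basis$reward)
  )
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xz <- sweep(X, 2, ctr, "-")
  nz <- scl > 0
  Xz[, nz] <- sweep(Xz[, nz, drop = FALSE], 2, scl[nz], "/")
  Xz[, !nz] <- 0
  structure(list(X = Xz, center = ctr, scale = scl, groups = basis$groups,
                 basis = basis, n_frames = n),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix: %d frames x %d predictors (%s)>\n",
              x$n_frames, ncol(x$X), paste(x$groups$group, collapse = ", ")))
  invisible(x)
}

#' Poisson deviance pseudo-explained variance
#'
#' `1 - D(yhat) / D(ybar)`, where `D` is the Poisson deviance from the
#' saturated model: `D(mu) = 2 * sum(y * log(y / mu) - (y - mu))` with
#' `y log y = 0` at `y = 0`. Equals 1 when predictions reproduce the data
#' exactly and 0 for the mean-only model.
#'
#' @param y Observed non-negative counts.
#' @param y_hat Model predictions (positive rates).
#' @param y_null Null prediction; defaults to `mean(y)`.
#' @return Scalar pseudo-explained variance (NA when the null deviance is
#'   0, i.e. constant `y`).
#' @export
pseudo_ev <- function(y, y_hat, y_null = mean(y)) {
  stopifnot(length(y_hat) %in% c(1, length(y)))
  d_hat <- poisson_deviance(y, y_hat)
  d_null <- poisson_deviance(y, y_null)
  if (d_null == 0) return(NA_real_)
  1 - d_hat / d_null
}

poisson_deviance <- function(y, mu) {
  if (length(mu) == 1) mu <- rep(mu, length(y))
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Fit the Poisson elastic-net encoding model for one unit
#'
#' Splits the frames into a contiguous 70/30 train/test block (respecting
#' temporal autocorrelation), fits a Poisson GLM with elastic-net penalty
#' (mixing `alpha = 0.9`) over a path of up to 100 lambda values with
#' 5-fold cross-validation on contiguous folds of the training block,
#' selects the lambda minimizing mean CV deviance, refits on the full
#' training block, and reports pseudo-explained variance on the held-out
#' test block.
#'
#' @param design A [build_design_matrix()] result.
#' @param y Non-negative activity counts, one per frame.
#' @param train_frac Fraction of frames in the (leading) training block.
#' @param alpha Elastic-net mixing (0.9 = mostly lasso).
#' @param nlambda Length of the regularization path.
#' @param seed Integer seed (fold structure is deterministic; the seed
#'   guards any RNG used internally by the solver).
#' @return An `rl_glm_fit`: coefficients at the chosen lambda, chosen
#'   `lambda`, `pseudo_ev` (held-out), train/test index ranges, the
#'   cross-validation record and the design metadata.
#' @export
fit_encoding_model <- function(design, y, train_frac = 0.7, alpha = 0.9,
                               nlambda = 100, seed = 1L) {
  X <- design$X
  n <- nrow(X)
  if (length(y) != n) abort("input error: y length does not match design")
  if (any(y < 0)) abort("input error: y must be non-negative")
  n_train <- floor(train_frac * n)
  idx_train <- seq_len(n_train)
  idx_test <- (n_train + 1):n
  fit0 <- structure(list(
    beta = rep(0, ncol(X)), intercept = log(max(mean(y[idx_train]), 1e-12)),
    lambda = NA_real_, pseudo_ev = 0, alpha = alpha,
    idx_train = range(idx_train), idx_test = range(idx_test),
    cv = NULL, design_groups = design$groups, center = design$center,
    scale = design$scale, basis = design$basis, null_fit = TRUE,
    y_mean_train = mean(y[idx_train])
  ), class = "rl_glm_fit")
  if (all(y[idx_train] == 0) || sd(y[idx_train]) == 0) {
    warn("degenerate activity (constant on the training block): returning null fit")
    return(fit0)
  }
  set.seed(seed)
  foldid <- as.integer(cut(idx_train, 5, labels = FALSE)) # contiguous folds
  cv <- glmnet::cv.glmnet(X[idx_train, ], y[idx_train], family = "poisson",
                          alpha = alpha, nlambda = nlambda, foldid = foldid,
                          standardize = FALSE, type.measure = "deviance")
  lam <- cv$lambda.min
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))
  mu_test <- as.numeric(stats::predict(cv$glmnet.fit, X[idx_test, ], s = lam,
                                       type = "response"))
  pev <- pseudo_ev(y[idx_test], mu_test, mean(y[idx_train]))
  structure(list(
    beta = co[-1], intercept = co[1], lambda = lam, pseudo_ev = pev,
    alpha = alpha, idx_train = range(idx_train), idx_test = range(idx_test),
    cv = tibble(lambda = cv$lambda, cv_deviance = cv$cvm, cv_sd = cv$cvsd),
    design_groups = design$groups, center = design$center,
    scale = design$scale, basis = design$basis, null_fit = FALSE,
    y_mean_train = mean(y[idx_train])
  ), class = "rl_glm_fit")
}

#' @export
print.rl_glm_fit <- function(x, ...) {
  cat(sprintf("<rl_glm_fit: %d predictors, lambda %.4g, held-out pseudo-E.V. %.3f%s>\n",
              length(x$beta), x$lambda, x$pseudo_ev,
              if (x$null_fit) " (null fit)" else ""))
  invisible(x)
}

#' @export
tidy.rl_glm_fit <- function(x, ...) {
  g <- x$design_groups
  group <- character(length(x$beta))
  for (i in seq_len(nrow(g))) group[g$first[i]:g$last[i]] <- g$group[i]
  tibble(term = seq_along(x$beta), group = group, estimate = x$beta)
}

#' @export
glance.rl_glm_fit <- function(x, ...) {
  tibble(lambda = x$lambda, alpha = x$alpha, pseudo_ev = x$pseudo_ev,
         n_nonzero = sum(x$beta != 0), null_fit = x$null_fit)
}

# predict on (already z-scored) design rows
predict_fit <- function(fit, X) {
  as.numeric(exp(fit$intercept + X %*% fit$beta))
}

# refit at a fixed lambda on the training block; returns held-out pseudo-EV
refit_ev <- function(X, y, idx_train, idx_test, alpha, lambda) {
  f <- glmnet::glmnet(X[idx_train, ], y[idx_train], family = "poisson",
                      alpha = alpha, lambda = lambda, standardize = FALSE)
  mu <- as.numeric(stats::predict(f, X[idx_test, ], s = lambda,
                                  type = "response"))
  pseudo_ev(y[idx_test], mu, mean(y[idx_train]))
}

block_permute <- function(n, block, perm_blocks = NULL) {
  nb <- ceiling(n / block)
  if (is.null(perm_blocks)) perm_blocks <- sample.int(nb)
  idx <- unlist(lapply(perm_blocks, function(b) {
    ((b - 1) * block + 1):min(b * block, n)
  }))
  idx[idx <= n]
}

#' Task-related classification of a fitted unit
#'
#' Builds a null distribution of held-out pseudo-explained variance by
#' permuting the order of 2-s blocks of the design-matrix rows (block
#' length `ceiling(block_s * frame_rate)` frames, so within-block predictor
#' structure is preserved) and refitting at the chosen lambda. The unit is
#' task-related when its observed pseudo-E.V. is positive and exceeds the
#' null at `p < p_thresh`.
#'
#' @param fit An `rl_glm_fit`.
#' @param design The [build_design_matrix()] used for the fit.
#' @param y The unit's activity.
#' @param n_shuffles Number of block permutations (default 1000).
#' @param block_s Shuffle block length in seconds.
#' @param p_thresh Significance threshold (default 0.001).
#' @param seed Integer seed.
#' @return List: `task_related`, `p`, `pseudo_ev`, `null_ev` vector.
#' @export
classify_task_related <- function(fit, design, y, n_shuffles = 1000,
                                  block_s = 2, p_thresh = 0.001, seed = 1L) {
  if (fit$null_fit)
    return(list(task_related = FALSE, p = NA_real_, pseudo_ev = fit$pseudo_ev,
                null_ev = numeric(0)))
  X <- design$X
  n <- nrow(X)
  block <- ceiling(block_s * design$basis$frame_rate)
  idx_train <- fit$idx_train[1]:fit$idx_train[2]
  idx_test <- fit$idx_test[1]:fit$idx_test[2]
  set.seed(seed)
  null_ev <- vapply(seq_len(n_shuffles), function(s) {
    Xs <- X[block_permute(n, block), , drop = FALSE]
    refit_ev(Xs, y, idx_train, idx_test, fit$alpha, fit$lambda)
  }, numeric(1))
  p <- perm_p(fit$pseudo_ev, null_ev)
  list(task_related = fit$pseudo_ev > 0 && p < p_thresh, p = p,
       pseudo_ev = fit$pseudo_ev, null_ev = null_ev)
}

#' Contribution of one task variable
#'
#' Refits the model without the variable's predictor group (same pipeline,
#' fresh lambda search) and measures the drop in held-out pseudo-explained
#' variance. The drop's null distribution comes from refits of the full
#' model with the group's columns block-shuffled in time.
#'
#' @param fit An `rl_glm_fit` of the full model.
#' @param design The design matrix used for the fit.
#' @param y The unit's activity.
#' @param group One of the six task-variable group names (see
#'   `design$groups`).
#' @param n_shuffles Number of block shuffles for the null.
#' @param block_s Shuffle block length in seconds.
#' @param seed Integer seed.
#' @return List: `group`, `delta_ev` (full minus partial), `p`,
#'   `partial_ev`, `null_delta`.
#' @export
variable_contribution <- function(fit, design, y, group, n_shuffles = 100,
                                  block_s = 2, seed = 1L) {
  g <- design$groups
  if (!group %in% g$group) abort(sprintf("input error: unknown group '%s'", group))
  cols <- with(g[g$group == group, ], first:last)
  X <- design$X
  n <- nrow(X)
  idx_train <- fit$idx_train[1]:fit$idx_train[2]
  idx_test <- fit$idx_test[1]:fit$idx_test[2]
  # partial model: full pipeline without the group
  part_design <- design
  part_design$X <- X[, -cols, drop = FALSE]
  part_design$groups <- g[g$group != group, ]
  part_fit <- fit_encoding_model(part_design, y, seed = seed)
  delta <- fit$pseudo_ev - part_fit$pseudo_ev
  block <- ceiling(block_s * design$basis$frame_rate)
  set.seed(seed)
  null_delta <- vapply(seq_len(n_shuffles), function(s) {
    Xs <- X
    Xs[, cols] <- X[block_permute(n, block), cols, drop = FALSE]
    refit_ev(Xs, y, idx_train, idx_test, fit$alpha, fit$lambda) -
      part_fit$pseudo_ev
  }, numeric(1))
  p <- perm_p(delta, null_delta)
  list(group = group, delta_ev = delta, p = p,
       partial_ev = part_fit$pseudo_ev, null_delta = null_delta)
}

#' Contributions of all task variables with FDR control
#'
#' Runs [variable_contribution()] for every predictor group and
#' Benjamini-Hochberg adjusts the p-values across the six variables.
#'
#' @inheritParams variable_contribution
#' @param q BH false-discovery level.
#' @return Tibble: `group`, `delta_ev`, `p`, `p_adj`, `significant`.
#' @export
variable_contributions <- function(fit, design, y, n_shuffles = 100,
                                   block_s = 2, seed = 1L, q = 0.05) {
  res <- purrr::map_dfr(design$groups$group, function(gr) {
    v <- variable_contribution(fit, design, y, gr, n_shuffles, block_s, seed)
    tibble(group = gr, delta_ev = v$delta_ev, p = v$p,
           partial_ev = v$partial_ev)
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < q
  res
}

#' Model-derived response profile of one task variable
#'
#' Exponentiates the variable's weighted basis contribution over its
#' natural domain, with the other variables marginalized out (their
#' multiplicative factors drop when profiles are compared within a
#' variable). For `object_position` the profile is a spatial map; for the
#' velocity groups it is a direction x lag surface; for the event groups a
#' lag curve. A variable with all-zero weights yields a flat profile of 1.
#'
#' @param fit An `rl_glm_fit`.
#' @param group Predictor-group name.
#' @param grid For the position profile, a [bin_spec()] on which to
#'   evaluate (default 10 x 10 over the basis extent).
#' @return For position: an `rl_tuning_map`. Otherwise a tibble
#'   (`direction` when applicable, `lag_s`, `value`).
#' @export
response_profile <- function(fit, group, grid = NULL) {
  g <- fit$design_groups
  if (!group %in% g$group) abort(sprintf("input error: unknown group '%s'", group))
  cols <- with(g[g$group == group, ], first:last)
  beta <- fit$beta[cols]
  ctr <- fit$center[cols]; scl <- fit$scale[cols]
  w <- ifelse(scl > 0, beta / scl, 0) # weights on the raw basis scale
  basis <- fit$basis
  if (group == "object_position") {
    if (is.null(grid)) grid <- bin_spec(basis$space$nx, basis$space$ny,
                                        basis$space$extent)
    B <- spatial_basis_maps(basis$space, grid)
    eta <- drop(B %*% w)
    return(new_map(exp(eta), grid, "tuning",
                   extra = list(group = group, profile = TRUE)))
  }
  b <- switch(group, trial_onset = basis$onset, trial_offset = basis$offset,
              reward = basis$reward, basis$velocity)
  lag_s <- b$lags / basis$frame_rate
  if (group %in% c("object_velocity", "joystick_velocity")) {
    nB <- ncol(b$kernel)
    purrr::map_dfr(1:8, function(d) {
      wd <- w[((d - 1) * nB + 1):(d * nB)]
      tibble(direction = (d - 1) * 45, lag_s = lag_s,
             value = exp(drop(b$kernel %*% wd)))
    })
  } else {
    tibble(lag_s = lag_s, value = exp(drop(b$kernel %*% w)))
  }
}
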