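test_that("default basis specification yields 217 predictors; counts follow the closed form", {
  bs <- basis_spec()
  expect_equal(bs$n_predictors, 217L)
  expect_equal(bs$groups$n, c(6L, 6L, 48L, 48L, 100L, 9L))
  # property over randomized specs
  set.seed(4)
  for (k in 1:5) {
    no <- sample(3:8, 1); nv <- sample(3:8, 1); nr <- sample(4:10, 1)
    nx <- sample(4:12, 1); ny <- sample(4:12, 1)
    b <- basis_spec(n_onset = no, n_offset = no, n_velocity = nv,
                    n_reward = nr, n_space_x = nx, n_space_y = ny)
    expect_equal(b$n_predictors, no + no + 8 * nv + 8 * nv + nx * ny + nr)
  }
})

test_that("design matrix convolves impulses into the basis shapes and z-scores columns", {
  bs <- basis_spec(frame_rate = 5.67)
  n <- 300
  vars <- list(
    trial_onset = c(rep(0, 150), 1, rep(0, n - 151)),
    trial_offset = rep(0, n), reward_onset = rep(0, n),
    object_velocity = matrix(0, n, 8), joystick_velocity = matrix(0, n, 8),
    x = rep(5, n), y = rep(5, n)
  )
  dm <- build_design_matrix(vars, bs)
  expect_equal(ncol(dm$X), 217L)
  # onset columns: de-z-scored values must reproduce the kernel around the impulse
  for (k in 1:6) {
    col <- dm$X[, k] * dm$scale[k] + dm$center[k]
    kern <- bs$onset$kernel[, k]
    lags <- bs$onset$lags
    idx <- 151 + lags
    ok <- idx >= 1 & idx <= n
    expect_equal(col[idx[ok]], kern[ok], tolerance = 1e-12)
    expect_true(all(abs(col[-idx[ok]]) < 1e-12))
  }
  # z-scored non-constant columns have mean 0 / sd 1; constant columns are zero
  nzcols <- which(dm$scale > 0)
  expect_true(all(abs(colMeans(dm$X[, nzcols])) < 1e-10))
  expect_true(all(abs(apply(dm$X[, nzcols, drop = FALSE], 2, sd) - 1) < 1e-10))
  zcols <- which(dm$scale == 0)
  expect_true(all(dm$X[, zcols] == 0))
  # all-zero inputs give an all-zero pre-z-score matrix
  vars0 <- vars; vars0$trial_onset <- rep(0, n)
  dm0 <- build_design_matrix(vars0, bs)
  velcols <- with(bs$groups[3:4, ], c(first[1]:last[1], first[2]:last[2]))
  expect_true(all(dm0$scale[c(1:12, velcols)] == 0))
  vars_bad <- vars; vars_bad$x <- vars$x[-1]
  expect_error(build_design_matrix(vars_bad, bs), "input error")
})

test_that("pseudo-explained variance hits its limits and matches a hand deviance", {
  y <- c(1, 2, 3)
  expect_equal(pseudo_ev(y, y), 1)
  expect_equal(pseudo_ev(y, rep(mean(y), 3)), 0)
  yhat <- c(1.5, 2, 2.5)
  dev <- function(y, mu) 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  expect_equal(pseudo_ev(y, yhat), 1 - dev(y, yhat) / dev(y, rep(2, 3)),
               tolerance = 1e-12)
})

test_that("pseudo-EV on zero-containing counts matches the deviance oracle and is <= 1", {
  dev <- function(y, mu) 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  y0 <- c(0, 1, 4)
  mu <- c(0.5, 1.5, 4.5)
  expect_equal(pseudo_ev(y0, mu), 1 - dev(y0, mu) / dev(y0, rep(mean(y0), 3)),
               tolerance = 1e-12)
  set.seed(2)
  for (k in 1:200) {
    y <- rpois(20, 2)
    mu <- runif(20, 0.1, 5)
    if (sd(y) == 0) next
    expect_lte(pseudo_ev(y, mu), 1)
  }
  expect_true(is.na(pseudo_ev(rep(2, 4), rep(2, 4))))
})

test_that("the encoding model recovers planted sparse coefficients and rejects noise", {
  set.seed(14)
  n <- 5000
  bs <- basis_spec()
  # synthetic design: smooth AR(1) columns to mimic convolved predictors
  p <- 217
  X <- matrix(0, n, p)
  for (j in seq_len(p)) X[, j] <- as.numeric(arima.sim(list(ar = 0.8), n))
  X <- scale(X)
  groups <- bs$groups
  true_cols <- c(2, 60, 130, 160, 210)  # one per several groups
  beta <- rep(0, p); beta[true_cols] <- c(0.4, -0.3, 0.35, 0.3, -0.4)
  eta <- -1 + X %*% beta
  y <- rpois(n, exp(eta))
  dm <- list(X = X, center = attr(X, "scaled:center"),
             scale = attr(X, "scaled:scale"), groups = groups, basis = bs,
             n_frames = n)
  class(dm) <- "design_matrix"
  fit <- fit_encoding_model(dm, y, seed = 3)
  expect_gt(fit$pseudo_ev, 0)
  # support recovery: >= 90% of truly nonzero coefficients have nonzero estimates
  expect_gte(mean(fit$beta[true_cols] != 0), 0.9)
  # y independent of X: held-out pseudo-EV ~ 0
  y_ind <- rpois(n, exp(-1))
  fit0 <- fit_encoding_model(dm, y_ind, seed = 3)
  expect_lt(abs(fit0$pseudo_ev), 0.02)
  # determinism of the chosen lambda and weights
  fit2 <- fit_encoding_model(dm, y, seed = 3)
  expect_identical(fit$lambda, fit2$lambda)
  expect_identical(fit$beta, fit2$beta)
  # degenerate response -> null fit with warning
  expect_warning(fnull <- fit_encoding_model(dm, rep(0, n)), "degenerate")
  expect_equal(fnull$pseudo_ev, 0)
})

test_that("block shuffling preserves within-block structure and calibrates task-relatedness", {
  set.seed(8)
  n <- 660
  block <- 11
  idx <- rlrep:::block_permute(n, block)
  expect_equal(sort(idx), 1:n)
  # within-block neighbor pairs survive the permutation
  pairs_kept <- sum(diff(idx) == 1)
  expect_gte(pairs_kept, (block - 1) * (n %/% block) - block)
  # planted-signal unit is flagged, a null unit is not (reduced shuffles)
  bs <- basis_spec()
  p <- 217
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X)
  dm <- list(X = X, center = attr(X, "scaled:center"),
             scale = attr(X, "scaled:scale"), groups = bs$groups, basis = bs,
             n_frames = n)
  class(dm) <- "design_matrix"
  beta <- rep(0, p); beta[c(10, 120)] <- 0.8
  y <- rpois(n, exp(-0.5 + X %*% beta))
  fit <- fit_encoding_model(dm, y, seed = 2)
  ctr <- classify_task_related(fit, dm, y, n_shuffles = 60, p_thresh = 0.02,
                               seed = 4)
  expect_true(ctr$task_related)
  y0 <- rpois(n, exp(-0.5))
  fit0 <- fit_encoding_model(dm, y0, seed = 2)
  ctr0 <- classify_task_related(fit0, dm, y0, n_shuffles = 60, p_thresh = 0.02,
                                seed = 4)
  expect_false(ctr0$task_related)
})

test_that("variable contributions isolate the driving group; removing zero-weight groups is free", {
  set.seed(21)
  n <- 2000
  bs <- basis_spec()
  X <- scale(matrix(rnorm(n * 217), n, 217))
  dm <- list(X = X, center = attr(X, "scaled:center"),
             scale = attr(X, "scaled:scale"), groups = bs$groups, basis = bs,
             n_frames = n)
  class(dm) <- "design_matrix"
  # unit driven by position columns only
  pos_cols <- with(bs$groups[bs$groups$group == "object_position", ],
                   first:last)
  beta <- rep(0, 217); beta[pos_cols[c(12, 45, 77)]] <- 0.7
  y <- rpois(n, exp(-0.5 + X %*% beta))
  fit <- fit_encoding_model(dm, y, seed = 5)
  vc <- variable_contributions(fit, dm, y, n_shuffles = 150, seed = 6)
  expect_true(vc$significant[vc$group == "object_position"])
  expect_gt(vc$delta_ev[vc$group == "object_position"],
            max(vc$delta_ev[vc$group != "object_position"]))
  # removing a zero-weight group changes almost nothing
  expect_lt(abs(vc$delta_ev[vc$group == "reward"]), 0.02)
  expect_error(variable_contribution(fit, dm, y, "nonexistent"), "input error")
})

test_that("response profiles recover planted place fields and stay flat at zero weights", {
  ses <- gen_trajectory(session_spec(n_trials = 120, policy = "random",
                                     behavior_rate = 200, seed = 9))
  fv <- frame_variables(ses)
  dm <- build_design_matrix(fv, basis_spec())
  us <- unit_spec(n_place = 2, n_border = 0, n_velocity = 0, n_value = 0,
                  n_policy = 0, n_mixed = 0, n_null = 0, baseline_rate = 1,
                  snr = 5, seed = 3)
  un <- gen_units(us, ses)
  act <- render_activity(un, ses, seed = 4)
  bc <- rlrep:::bin_centers(bin_spec(10, 10, c(10, 10)))
  for (i in 1:2) {
    fit <- fit_encoding_model(dm, act[, i], seed = 5)
    rp <- response_profile(fit, "object_position")
    ctr <- un$units$params[[i]]$center
    pk <- which.max(rp$values)
    expect_lte(abs(bc$x[pk] - ctr[1]), 1.51)
    expect_lte(abs(bc$y[pk] - ctr[2]), 1.51)
    expect_true(all(rp$values > 0))
  }
  # zero-weight group: flat profile of 1
  fit1 <- fit_encoding_model(dm, act[, 1], seed = 5)
  fit1$beta[with(fit1$design_groups[fit1$design_groups$group == "reward", ],
                 first:last)] <- 0
  prof <- response_profile(fit1, "reward")
  expect_true(all(prof$value == 1))
})
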