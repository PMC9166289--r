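base_arena <- arena_spec("base")

test_that("state-value map equals gamma^(T-t) on scripted trajectories, zone bins 1", {
  # straight 3-step approach to the zone: values 0.99^3, 0.99^2, 0.99^1
  traj <- make_traj(list(list(
    xy = rbind(c(0.05, 0.05), c(0.15, 0.15), c(0.25, 0.25), c(0.35, 0.35)),
    hit = TRUE)), arena = base_arena)
  vm <- state_value_map(traj, gamma = 0.99, bins = bin_spec(10, 10, c(1, 1)))
  b <- rlrep:::bin_index(c(0.05, 0.15, 0.25), c(0.05, 0.15, 0.25), vm$spec)
  expect_equal(vm$values[b], c(0.99^3, 0.99^2, 0.99), tolerance = 1e-12)
  expect_equal(vm$values[b[1]], 0.970299, tolerance = 1e-6)
  # reward-zone bins forced to 1
  bz <- rlrep:::bin_index(0.5, 0.5, vm$spec)
  expect_equal(vm$values[bz], 1)
  # unvisited bins are missing, not zero
  expect_true(is.na(vm$values[rlrep:::bin_index(0.95, 0.05, vm$spec)]))
  # miss trials contribute 0
  traj2 <- make_traj(list(
    list(xy = rbind(c(0.05, 0.05), c(0.35, 0.35)), hit = TRUE),
    list(xy = rbind(c(0.95, 0.95), c(0.85, 0.95)), hit = FALSE)),
    arena = base_arena)
  vm2 <- state_value_map(traj2, gamma = 0.99, bins = bin_spec(10, 10, c(1, 1)))
  expect_equal(vm2$values[rlrep:::bin_index(0.95, 0.95, vm2$spec)], 0)
  expect_error(state_value_map(traj, gamma = 1.2), "input error")
})

test_that("policy map resultants follow hand vector sums and rotate equivariantly", {
  # all movements due east
  traj <- make_traj(list(list(
    xy = cbind(seq(0.05, 0.65, by = 0.1), 0.45), hit = FALSE)))
  pm <- policy_map(traj, bins = bin_spec(10, 10, c(1, 1)))
  vis <- which(is.finite(pm$values) & pm$values > 0)
  expect_true(all(abs(pm$angle[vis]) < 1e-9))
  # one bin with vectors (1,0)+(0,1) scaled into the arena
  traj2 <- make_traj(list(
    list(xy = rbind(c(0.05, 0.05), c(0.15, 0.05)), hit = FALSE),
    list(xy = rbind(c(0.05, 0.05), c(0.05, 0.15)), hit = FALSE)))
  pm2 <- policy_map(traj2, bins = bin_spec(10, 10, c(1, 1)))
  b <- rlrep:::bin_index(0.05, 0.05, pm2$spec)
  expect_equal(pm2$angle[b], pi / 4, tolerance = 1e-9)
  expect_equal(pm2$values[b], sqrt(0.1^2 + 0.1^2), tolerance = 1e-12)
  # 90-degree rotation of all trajectories rotates the resultants
  rot <- function(traj) {
    out <- traj
    out$x <- 1 - traj$y; out$y <- traj$x
    attr(out, "extent") <- c(1, 1)
    out
  }
  pm2r <- policy_map(rot(traj2), bins = bin_spec(10, 10, c(1, 1)))
  br <- rlrep:::bin_index(1 - 0.05, 0.05, pm2r$spec)
  expect_equal(pm2r$angle[br], pi / 4 + pi / 2, tolerance = 1e-9)
  expect_equal(pm2r$values[br], pm2$values[b], tolerance = 1e-12)
  # empty trajectory: empty map, not an error
  e <- policy_map(make_traj(list()), bins = bin_spec(5, 5, c(1, 1)))
  expect_true(all(is.na(e$values)))
})

test_that("diverse density matches the naive triple-loop oracle and its closed forms", {
  set.seed(21)
  trials <- lapply(1:5, function(i) {
    n <- sample(3:7, 1)
    list(xy = cbind(runif(n), runif(n)), hit = i <= 2)
  })
  traj <- make_traj(trials)
  bins <- bin_spec(6, 6, c(1, 1))
  dd <- diverse_density(traj, bins)
  expect_equal(dd$values, dd_oracle(traj, bins), tolerance = 1e-10)
  expect_equal(dd$m, 2)
  expect_equal(dd$n_miss, 3)
  # single-point successful trial at one-cell distance: p(x|T+) = e^-1
  cell <- 1 / 6
  traj1 <- make_traj(list(
    list(xy = rbind(c(cell / 2 + cell, cell / 2)), hit = TRUE),
    list(xy = rbind(c(5.5 * cell, 5.5 * cell)), hit = FALSE)))
  dd1 <- diverse_density(traj1, bins)
  # at the first bin center the hit point sits exactly one cell away
  b1 <- 1L
  miss_term <- log1p(-min(exp(-((5.5 - 0.5)^2 + (5.5 - 0.5)^2)), 1 - 1e-15))
  expect_equal(dd1$values[b1], log(exp(-1)) + miss_term, tolerance = 1e-9)
  # duplication of a successful trial enters only through the m-fold product
  traj_dup <- make_traj(list(trials[[1]], trials[[1]],
                             trials[[3]], trials[[4]], trials[[5]]))
  dd_dup <- diverse_density(traj_dup, bins)
  expect_equal(dd_dup$values, dd_oracle(traj_dup, bins), tolerance = 1e-10)
  # errors without both outcomes
  all_hit <- make_traj(list(list(xy = cbind(runif(3), runif(3)), hit = TRUE)))
  expect_error(diverse_density(all_hit, bins), "input error")
})

test_that("log DD correlation behaves at identity, negation, and matches the textbook formula", {
  set.seed(5)
  bins <- bin_spec(8, 8, c(1, 1))
  mk <- function(seed) {
    set.seed(seed)
    trials <- lapply(1:4, function(i)
      list(xy = cbind(runif(5), runif(5)), hit = i <= 2))
    diverse_density(make_traj(trials), bins)
  }
  a <- mk(1); b <- mk(2)
  expect_equal(dd_correlation(a, a), 1)
  neg <- a; neg$values <- -a$values
  expect_equal(dd_correlation(a, neg), -1)
  r <- dd_correlation(a, b)
  ok <- is.finite(a$values) & is.finite(b$values)
  x <- a$values[ok]; y <- b$values[ok]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  const <- a; const$values <- rep(1, length(a$values))
  expect_true(is.na(dd_correlation(a, const)))
})

test_that("efficiency ratio is 1 on straight paths and (a+b)/c on L-shaped ones", {
  straight <- make_traj(list(list(
    xy = cbind(seq(0.05, 0.29, length.out = 9), 0.5), hit = TRUE)),
    arena = base_arena)
  er <- efficiency_ratio(straight)
  expect_equal(er$ratio, 0.24 / (0.3 - 0.05), tolerance = 1e-9)
  # L-shaped: legs 0.25 (east) then 0.2 (north) ending at zone edge
  lshape <- make_traj(list(list(
    xy = rbind(cbind(seq(0.05, 0.3, length.out = 6), 0.1),
               cbind(0.3, seq(0.15, 0.3, length.out = 3))), hit = TRUE)),
    arena = base_arena)
  erl <- efficiency_ratio(lshape)
  zone <- base_arena$reward_zones[[1]]$rect
  straight_d <- rlrep:::rect_distance(0.05, 0.1, zone)
  expect_equal(erl$ratio, (0.25 + 0.2) / straight_d, tolerance = 1e-9)
  # start inside the zone: trial skipped
  inzone <- make_traj(list(list(xy = rbind(c(0.5, 0.5), c(0.52, 0.5)),
                                hit = TRUE)), arena = base_arena)
  expect_equal(nrow(efficiency_ratio(inzone)), 0)
})

test_that("shuffled trajectories resample the observed movement pool with edge clamping", {
  # degenerate pool: single eastward movement -> straight eastward path
  traj <- make_traj(list(list(
    xy = cbind(seq(0.2, 0.5, by = 0.05), 0.5), hit = FALSE)),
    arena = base_arena)
  sh <- shuffle_trajectories(traj, seed = 1)
  expect_equal(diff(sh$x[order(sh$t)]), rep(0.05, 6), tolerance = 1e-12)
  expect_true(all(sh$y == 0.5))
  # same seed identical, different seed differs (rich pool)
  set.seed(2)
  rich <- make_traj(list(list(
    xy = cbind(cumsum(c(0.5, runif(20, -0.04, 0.04))),
               cumsum(c(0.5, runif(20, -0.04, 0.04)))), hit = FALSE)),
    arena = base_arena)
  s1 <- shuffle_trajectories(rich, seed = 3)
  s2 <- shuffle_trajectories(rich, seed = 3)
  s3 <- shuffle_trajectories(rich, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1$x, s3$x))
  expect_true(all(s1$x >= 0 & s1$x <= 1))
})

test_that("random-walk trajectories are less efficient than guided ones", {
  ses_g <- gen_trajectory(session_spec(n_trials = 15, behavior_rate = 200,
                                       seed = 31))
  ses_r <- gen_trajectory(session_spec(n_trials = 15, policy = "random",
                                       behavior_rate = 200, seed = 32))
  eg <- efficiency_ratio(ses_g$trajectory, sample_every = 10)
  er <- efficiency_ratio(ses_r$trajectory, sample_every = 10)
  expect_lt(median(eg$ratio), 2)
  expect_gt(median(er$ratio), 2 * median(eg$ratio))
  # shuffles of the same movements rarely end at the reward zone
  sh <- shuffle_trajectories(ses_g$trajectory, seed = 5)
  ends_in_zone <- function(traj) {
    ts <- traj |> dplyr::group_by(trial) |>
      dplyr::slice_max(t, n = 1) |> dplyr::ungroup()
    mean(ts$x >= 3 & ts$x < 7 & ts$y >= 3 & ts$y < 7)
  }
  expect_lt(ends_in_zone(sh), ends_in_zone(ses_g$trajectory))
})
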