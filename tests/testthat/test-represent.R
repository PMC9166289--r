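test_that("spatial coherence separates smooth, noisy and checkerboard maps and is scale-free", {
  spec <- bin_spec(10, 10, c(1, 1))
  bc <- rlrep:::bin_centers(spec)
  ramp <- bc$x + bc$y
  expect_gt(spatial_coherence(ramp, spec), 0.95)
  set.seed(1)
  noise <- rnorm(100)
  expect_lt(abs(spatial_coherence(noise, spec)), 0.25)
  checker <- (-1)^(bc$ix + bc$iy)
  expect_lt(spatial_coherence(checker, spec), 0)
  # invariant under positive scaling
  expect_equal(spatial_coherence(3.7 * ramp, spec),
               spatial_coherence(ramp, spec), tolerance = 1e-12)
  # constant map defined as 0
  expect_equal(spatial_coherence(rep(2, 100), spec), 0)
})

test_that("border index hits its closed-form extremes and is scale-free", {
  spec <- bin_spec(10, 10, c(1, 1))
  bc <- rlrep:::bin_centers(spec)
  # field = full left border: coverage 1, distance 0 -> index 1
  left <- as.numeric(bc$ix == 1) * 10
  expect_equal(border_index(left, spec), 1)
  # central 2x2 blob: coverage 0 -> index -1
  blob <- as.numeric(bc$ix %in% 5:6 & bc$iy %in% 5:6) * 10
  expect_equal(border_index(blob, spec), -1)
  # half of the bottom border plus one central bin: hand-computed value
  half <- as.numeric((bc$iy == 1 & bc$ix <= 5) | (bc$ix == 5 & bc$iy == 5)) * 10
  cover <- 5 / 10
  d <- mean(c(rep(0, 5), 4 * 0.1)) # border bins at 0; central bin 4 cells in
  expect_equal(border_index(half, spec), (cover - d) / (cover + d),
               tolerance = 1e-12)
  expect_equal(border_index(2.2 * half, spec), border_index(half, spec))
  # empty field (constant map) -> missing
  expect_true(is.na(border_index(rep(1, 100), spec)))
})

test_that("velocity test requires both direction tuning and speed modulation", {
  set.seed(7)
  n <- 2000
  ang <- runif(n, -pi, pi)
  speed <- runif(n, 0.5, 5)
  dx <- speed * cos(ang); dy <- speed * sin(ang)
  x <- runif(n, 0, 1); y <- runif(n, 0, 1)
  tuned <- pmax(speed * cos(ang), 0) + rnorm(n, 0, 0.1)       # speed x direction
  dironly <- pmax(cos(ang), 0) * 2 + rnorm(n, 0, 0.1)          # direction, speed-flat
  flat <- rep(1, n) + rnorm(n, 0, 0.1)                         # untuned
  smp <- rlrep:::new_unit_samples(cbind(tuned, dironly, flat), x, y,
                                  bin_spec(10, 10, c(1, 1)), dx, dy)
  vt <- velocity_test(smp)
  expect_true(vt$velocity_tuned[1])
  expect_equal(unname(vt$preferred_direction[1]), 0)
  expect_false(vt$velocity_tuned[2])   # fails the speed-correlation stage
  expect_lt(vt$p_direction[2], 0.05)   # but is direction tuned
  expect_false(vt$velocity_tuned[3])
})

test_that("map classification finds perfect correlates at the permutation floor", {
  set.seed(3)
  spec <- bin_spec(8, 8, c(1, 1))
  bc <- rlrep:::bin_centers(spec)
  ref_fun <- function(x, y) exp(-((x - 0.5)^2 + (y - 0.5)^2) / 0.05)
  n <- 4000
  x <- runif(n); y <- runif(n)
  act <- cbind(ref_fun(x, y),                 # perfect correlate
               runif(n))                      # pure noise
  traj_bins <- rlrep:::bin_index(x, y, spec)
  smp <- rlrep:::new_unit_samples(act, x, y, spec, dx = rep(0.01, n),
                                  dy = rep(0, n))
  ref <- rlrep:::new_map(ref_fun(bc$x, bc$y), spec, "value")
  cl <- classify_by_map(smp, ref, n_shuffles = 200, seed = 5)
  expect_equal(cl$p[1], 1 / 201)
  expect_true(cl$classified[1])
  expect_false(cl$classified[2])
  # constant unit excluded with a reason code
  smp2 <- rlrep:::new_unit_samples(cbind(act, 0), x, y, spec,
                                   dx = rep(0.01, n), dy = rep(0, n))
  cl2 <- classify_by_map(smp2, ref, n_shuffles = 50, seed = 5)
  expect_equal(cl2$excluded[3], "constant_tuning")
  expect_true(is.na(cl2$p[3]))
})

test_that("contrast index is antisymmetric with its closed-form values", {
  expect_equal(contrast_index(0.2, 0.2, "two_reward")$value, 0)
  expect_equal(contrast_index(0.3, 0.1, "open_loop")$value, 0.5)
  expect_equal(contrast_index(0.4, 0, "subgoal")$value, 1)
  expect_true(is.na(contrast_index(0, 0, "two_reward")$value))
  for (a in c(0.1, 0.25, 0.6)) for (b in c(0, 0.3)) {
    if (a + b == 0) next
    expect_equal(contrast_index(a, b, "subgoal")$value,
                 -contrast_index(b, a, "subgoal")$value)
  }
})

test_that("quadrant enrichment reads peak locations with row-major tie-breaks", {
  spec <- bin_spec(10, 10, c(1, 1))
  nb <- 100
  mk_unit <- function(bin) { v <- rep(0, nb); v[bin] <- 1; v }
  # peaks placed deterministically: 2 bottom-left, 1 top-right
  maps <- cbind(mk_unit(rlrep:::bin_index(0.2, 0.2, spec)),
                mk_unit(rlrep:::bin_index(0.3, 0.4, spec)),
                mk_unit(rlrep:::bin_index(0.8, 0.9, spec)))
  tun <- structure(list(maps = maps, counts = rep(1, nb), spec = spec,
                        active = rep(TRUE, 3), source = "activity"),
                   class = "rl_tuning_set")
  qe <- quadrant_enrichment(tun, "bottom_left")
  expect_equal(qe$fraction, 2 / 3)
  expect_equal(unname(qe$table$fraction[qe$table$quadrant == "top_right"]), 1 / 3)
  expect_equal(sum(qe$table$fraction), 1)
  # near-uniform planted peaks: each quadrant ~ 0.25
  set.seed(9)
  mapsu <- sapply(1:400, function(i) mk_unit(sample(nb, 1)))
  tunu <- structure(list(maps = mapsu, counts = rep(1, nb), spec = spec,
                         active = rep(TRUE, 400), source = "activity"),
                    class = "rl_tuning_set")
  qeu <- quadrant_enrichment(tunu, "bottom_right")
  expect_lt(abs(qeu$fraction - 0.25), 0.07)
})

test_that("active fraction and retention cross-tabulation behave on constructed stages", {
  spec <- bin_spec(5, 5, c(1, 1))
  maps <- cbind(rep(0, 25), runif(25), runif(25))
  tun <- structure(list(maps = maps, counts = rep(1, 25), spec = spec,
                        active = c(FALSE, TRUE, TRUE), source = "probe"),
                   class = "rl_tuning_set")
  expect_equal(active_fraction(tun), 2 / 3)
  s1 <- tibble::tibble(unit = 1:6, category = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       active = TRUE)
  # stage 2 silences exactly the non-category units
  s2 <- tibble::tibble(unit = 1:6, category = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       active = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ret <- retention_analysis(s1, s2)
  expect_equal(ret$frac_active2[ret$category1], 1)
  expect_equal(ret$frac_active2[!ret$category1], 0)
  # identity stages: full retention
  ret0 <- retention_analysis(s1, s1)
  expect_true(all(ret0$frac_active2 == 1))
  expect_error(retention_analysis(s1, s2[1:3, ]), "input error")
})

test_that("region scoring ranks worst-to-best with shared mean ranks on ties", {
  m <- tibble::tibble(region = c("A", "B", "C"),
                      v1 = c(3, 1, 2), v2 = c(5, 5, 1), v3 = c(10, 2, 4))
  sc <- score_regions(m)
  # A dominates v1 and v3 and ties for best on v2
  expect_equal(sc$score[sc$region == "A"], mean(c(3, 2.5, 3)))
  expect_equal(sc$score[sc$region == "B"], mean(c(1, 2.5, 1)))
  # direction flips reverse the ranking
  sc2 <- score_regions(m, higher_better = c(v1 = FALSE, v2 = FALSE, v3 = FALSE))
  expect_equal(sc2$score[sc2$region == "B"], mean(c(3, 1.5, 3)))
  # missing cells drop the variable for all regions
  m$v2[2] <- NA
  sc3 <- score_regions(m)
  expect_equal(sc3$n_variables[1], 2)
  expect_error(score_regions(m[1, ]), "input error")
})

test_that("probe tuning is deterministic, batch-invariant, and flags dead units", {
  cfg <- hyper_config(shared = TRUE, n_layers = 2, width = 16)
  m <- build_network(cfg, seed = 5)
  # kill one unit's incoming weights: flat zero map, inactive
  m$trunks$shared[[1]]$W[, 3] <- 0
  m$trunks$shared[[1]]$b[3] <- 0
  t1 <- probe_space_tuning(m, n_states = 4000, seed = 9, batch = 1000)
  t2 <- probe_space_tuning(m, n_states = 4000, seed = 9, batch = 4000)
  expect_equal(t1$maps, t2$maps, tolerance = 1e-12)
  expect_false(t1$active[3])
  expect_true(all(t1$maps[is.finite(t1$maps[, 3]), 3] == 0))
  # hand-constructed monotone unit: rectified(x - 0.5)
  m$trunks$shared[[1]]$W[, 1] <- c(1, 0, 0, 0)
  m$trunks$shared[[1]]$b[1] <- -0.5
  t3 <- probe_space_tuning(m, n_states = 20000, seed = 9)
  map1 <- t3$maps[, 1]
  expect_gt(spatial_coherence(map1, t3$spec), 0.9)
  bc <- rlrep:::bin_centers(t3$spec)
  expect_gt(cor(map1[is.finite(map1)], bc$x[is.finite(map1)]), 0.85)
})

test_that("chance fraction is ~0 for a constant-free reference built from one basis", {
  spec <- bin_spec(10, 10, c(1, 1))
  sb <- spatial_basis(5, 5, c(1, 1))
  B <- spatial_basis_maps(sb, spec)
  # reference equal to one of the basis maps: that basis is always classified
  ref <- rlrep:::new_map(B[, 7], spec, "value")
  cf <- chance_fraction(ref, B, n_rounds = 20, n_shuffles = 1000, seed = 3)
  expect_gte(cf$chance_fraction, 1 / ncol(B))
  # observed fraction above every surrogate round -> small p
  expect_lt(cf$p_value(1.0), 0.05)
})
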