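#' State-value map from trajectories
#'
#' For each visited spatial bin, the empirical state value is the mean over
#' visits of `R_T * gamma^(T - t)`, where `T` is the trial end, `t` the
#' visit time and `R_T` the trial's terminal reward (1 on ordinary hits;
#' 1.25 / 0.125 for the high / low side of the two-reward task when
#' `reward_scale` maps terminal rewards; 0 on misses). Bins inside a reward
#' zone are set to 1. Unvisited bins are `NA`, never 0.
#'
#' @param traj Trajectory tibble (see [rollout()]).
#' @param gamma Discount factor per time bin, in (0, 1).
#' @param bins A [bin_spec()]; defaults to 20 x 20 over the trajectory's
#'   arena extent.
#' @param reward_scale Optional function mapping the terminal reward of a
#'   trial to the scale of its discounted contribution; the default maps
#'   positive terminal rewards of the base task to 1 and the two-reward
#'   task's 1 / 0.1 rewards to 1.25 / 0.125.
#' @return An `rl_value_map`.
#' @export
state_value_map <- function(traj, gamma = 0.95, bins = NULL,
                            reward_scale = NULL) {
  if (gamma <= 0 || gamma >= 1) abort("input error: gamma must be in (0, 1)")
  ext <- traj_extent(traj)
  if (is.null(bins)) bins <- bin_spec(20, 20, ext)
  if (is.null(reward_scale))
    reward_scale <- function(r) ifelse(r >= 1, 1, ifelse(r > 0, 1.25 * r, 0))
  ts <- trial_summary(traj)
  d <- dplyr::left_join(traj, ts[, c("trial", "T", "terminal_reward")], by = "trial")
  w <- reward_scale(d$terminal_reward) * gamma^(d$T - d$t)
  b <- bin_index(d$x, d$y, bins)
  sums <- rowsum(w, b)
  counts <- rowsum(rep(1, length(b)), b)
  values <- rep(NA_real_, n_bins(bins))
  values[as.integer(rownames(sums))] <- sums / counts
  cnt <- rep(0, n_bins(bins))
  cnt[as.integer(rownames(counts))] <- counts
  arena <- attr(traj, "arena")
  if (!is.null(arena)) {
    bc <- bin_centers(bins)
    for (z in arena$reward_zones) {
      inz <- in_rect(bc$x, bc$y, z$rect)
      values[inz] <- 1
    }
  }
  new_map(values, bins, "value", counts = cnt, extra = list(gamma = gamma))
}

#' Occupancy map (state-visit frequency)
#'
#' @param traj Trajectory tibble.
#' @param bins A [bin_spec()].
#' @return An `rl_occupancy_map` of visit fractions (NA for unvisited bins).
#' @export
occupancy_map <- function(traj, bins = NULL) {
  ext <- traj_extent(traj)
  if (is.null(bins)) bins <- bin_spec(20, 20, ext)
  b <- bin_index(traj$x, traj$y, bins)
  counts <- tabulate(b, n_bins(bins))
  values <- counts / sum(counts)
  values[counts == 0] <- NA_real_
  new_map(values, bins, "occupancy", counts = counts)
}

#' Policy map: per-bin resultant movement vector
#'
#' For each spatial bin, the vectorial sum of all movement vectors whose
#' origin falls in the bin, reported as a preferred direction (radians) and
#' resultant magnitude. Movement vectors are successive displacements over
#' `window` rows of the trajectory (1 step for agents; for 10-ms mouse-like
#' data use `window = 10` for the conventional 100-ms vectors).
#'
#' @param traj Trajectory tibble.
#' @param bins A [bin_spec()].
#' @param window Displacement window in rows.
#' @return An `rl_policy_map`; `values` holds resultant magnitudes,
#'   with fields `angle` (preferred direction) and `ux`, `uy` (unit
#'   vectors for display). Empty bins are `NA`.
#' @export
policy_map <- function(traj, bins = NULL, window = 1L) {
  ext <- traj_extent(traj)
  if (is.null(bins)) bins <- bin_spec(20, 20, ext)
  nb <- n_bins(bins)
  if (nrow(traj) == 0) {
    return(new_map(rep(NA_real_, nb), bins, "policy",
                   extra = list(angle = rep(NA_real_, nb),
                                ux = rep(NA_real_, nb), uy = rep(NA_real_, nb))))
  }
  mv <- traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(dx = dplyr::lead(.data$x, window) - .data$x,
                  dy = dplyr::lead(.data$y, window) - .data$y) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx))
  b <- bin_index(mv$x, mv$y, bins)
  sx <- rowsum(mv$dx, b); sy <- rowsum(mv$dy, b)
  vx <- rep(NA_real_, nb); vy <- rep(NA_real_, nb)
  idx <- as.integer(rownames(sx))
  vx[idx] <- sx; vy[idx] <- sy
  mag <- sqrt(vx^2 + vy^2)
  ang <- atan2(vy, vx)
  new_map(mag, bins, "policy",
          extra = list(angle = ang,
                       ux = ifelse(mag > 0, vx / mag, 0),
                       uy = ifelse(mag > 0, vy / mag, 0)))
}

#' Diverse-density subgoal map
#'
#' Scores each spatial bin by how densely successful trajectories pass near
#' it and unsuccessful trajectories avoid it. Bin-center-to-point distances
#' `d` are measured in units of the spatial bin size (the convention of the
#' original diverse-density subgoal-discovery work), so the Gaussian kernel
#' `p = exp(-d^2)` reaches one to two bins regardless of arena size and the
#' score discriminates local structure such as bottlenecks. Per-point
#' proximities give per-trial joint probabilities:
#' `p(x | T+) = 1 - prod(1 - p)` over a successful trial's points and
#' `p(x | T-) = prod(1 - p)` over an unsuccessful trial's; the diverse
#' density is the product over trials, returned on the log scale (products
#' are accumulated as sums of logs to avoid underflow).
#'
#' @param traj Trajectory tibble with at least one hit and one miss trial.
#' @param bins A [bin_spec()] (20 x 20 default).
#' @return An `rl_dd_map` of log diverse density, with fields `m`
#'   (successful trials) and `n_miss`.
#' @export
diverse_density <- function(traj, bins = NULL) {
  ext <- traj_extent(traj)
  if (is.null(bins)) bins <- bin_spec(20, 20, ext)
  ts <- trial_summary(traj)
  if (sum(ts$hit) == 0 || sum(!ts$hit) == 0)
    abort("input error: diverse density needs at least one successful and one unsuccessful trial")
  scale <- mean(c(bins$extent[1] / bins$nx, bins$extent[2] / bins$ny))
  bc <- bin_centers(bins)
  cx <- bc$x / scale; cy <- bc$y / scale
  logdd <- rep(0, n_bins(bins))
  for (tr in ts$trial) {
    pts <- traj[traj$trial == tr, ]
    px <- pts$x / scale; py <- pts$y / scale
    # nb x q matrix of squared distances
    d2 <- outer(cx, px, "-")^2 + outer(cy, py, "-")^2
    p <- pmin(exp(-d2), 1 - 1e-15)
    log1mp <- log1p(-p)                  # log(1 - p_ij) <= 0
    s <- rowSums(log1mp)                 # log prod(1 - p)
    if (ts$hit[ts$trial == tr]) {
      logdd <- logdd + log(pmax(-expm1(s), 1e-300)) # log(1 - prod(1-p))
    } else {
      logdd <- logdd + s
    }
  }
  new_map(logdd, bins, "dd",
          extra = list(m = sum(ts$hit), n_miss = sum(!ts$hit),
                       occupancy = tabulate(bin_index(traj$x, traj$y, bins),
                                            n_bins(bins))))
}

#' Correlation of log diverse density between sessions
#'
#' Pearson correlation over spatial bins of log DD between a session's map
#' and a reference (typically the last session's); used to track how a
#' subgoal stabilizes with learning.
#'
#' @param dd_a,dd_ref `rl_dd_map`s on identical bin specs.
#' @return Pearson r (NA when either map is constant).
#' @export
dd_correlation <- function(dd_a, dd_ref) {
  if (!same_bins(dd_a$spec, dd_ref$spec))
    abort("input error: bin specs differ")
  cor_finite(dd_a$values, dd_ref$values)
}

#' Per-trial trajectory efficiency ratio
#'
#' Path length (positions subsampled every `sample_every` rows, the coarser
#' sampling used for distance-traveled metrics) divided by the
#' straight-line distance from the trial's start to the nearest point of
#' the reward zone. Trials starting inside a zone are skipped.
#'
#' @param traj Trajectory tibble; needs an `arena` attribute (set by
#'   [rollout()] and [gen_trajectory()]) or an explicit `zone`.
#' @param sample_every Subsampling stride (rows) for the path length.
#' @param zone Optional reward-zone rectangle overriding the arena's first
#'   zone.
#' @return Tibble: `trial`, `path_length`, `straight`, `ratio`.
#' @export
efficiency_ratio <- function(traj, sample_every = 1L, zone = NULL) {
  arena <- attr(traj, "arena")
  if (is.null(zone)) {
    if (is.null(arena)) abort("input error: no arena attribute and no zone given")
    zone <- arena$reward_zones[[1]]$rect
  }
  traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      path_length = {
        k <- seq(1, dplyr::n(), by = sample_every)
        if (!k[length(k)] == dplyr::n()) k <- c(k, dplyr::n())
        sum(sqrt(diff(.data$x[k])^2 + diff(.data$y[k])^2))
      },
      straight = rect_distance(.data$x[1], .data$y[1], zone),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$straight > 0) |>
    dplyr::mutate(ratio = .data$path_length / .data$straight)
}

#' Discover a subgoal from trajectories by diverse density
#'
#' Computes the log diverse-density map and returns an intrinsic-reward
#' zone centered on its maximum over *candidate* bins: bins actually
#' visited by the trajectories and farther than `exclude_margin` from any
#' extrinsic reward zone (an intrinsic reward at the goal itself would be
#' redundant, so the goal funnel is excluded as in the subgoal-discovery
#' literature). In the two-room task the candidate maximum falls at the
#' bottleneck door region traversed by successful trajectories.
#'
#' @param traj Trajectory tibble with hits and misses.
#' @param arena The [arena_spec()] the trajectories come from (for reward
#'   zones and extent).
#' @param bins A [bin_spec()]; default 0.1-unit bins over the arena.
#' @param exclude_margin Distance (arena units) around reward zones
#'   excluded from the candidate set.
#' @param size Size of the returned subgoal rectangle (default 2 x 2 bins).
#' @return List: `zone` (rectangle), `dd` (the `rl_dd_map`), `peak_bin`.
#' @export
discover_subgoal <- function(traj, arena, bins = NULL, exclude_margin = 0.8,
                             size = NULL) {
  if (is.null(bins))
    bins <- bin_spec(round(arena$extent[1] / 0.1), round(arena$extent[2] / 0.1),
                     arena$extent)
  dd <- diverse_density(traj, bins)
  bc <- bin_centers(bins)
  v <- dd$values
  v[dd$occupancy == 0] <- NA
  for (z in arena$reward_zones)
    v[rect_distance(bc$x, bc$y, z$rect) < exclude_margin] <- NA
  if (all(!is.finite(v)))
    abort("input error: no candidate bins outside the reward-zone margin")
  masked <- new_map(v, bins, "dd")
  zone <- map_peak_rect(masked, size = size)
  # nudge the zone off walls (the peak bin itself is visitable, but the
  # surrounding rectangle may straddle a wall band)
  for (w in arena$walls) {
    if (!rects_overlap(zone, w)) next
    peak_x <- bc$x[which.max(ifelse(is.finite(v), v, -Inf))]
    wd <- zone[["x1"]] - zone[["x0"]]
    x0 <- if (peak_x >= w[["x1"]] - 1e-9 ||
              (peak_x > (w[["x0"]] + w[["x1"]]) / 2)) w[["x1"]]
          else w[["x0"]] - wd
    x0 <- min(max(x0, 0), arena$extent[1] - wd)
    zone <- rect(x0, x0 + wd, zone[["y0"]], zone[["y1"]])
  }
  list(zone = zone, dd = dd,
       peak_bin = which.max(ifelse(is.finite(v), v, -Inf)))
}

#' Shuffled trajectories from a pool of observed movements
#'
#' Builds surrogate trials by cumulatively summing movement vectors drawn
#' at random from the pool of observed per-step movements, starting from
#' each real trial's start point and clamping at the arena edges. Movements
#' recorded at the arena edges are excluded from the pool to avoid clipping
#' effects. Each surrogate trial has the same number of steps as its real
#' counterpart.
#'
#' @param traj Real trajectory tibble providing movement pool and starts.
#' @param seed Integer seed.
#' @param edge_tol Distance from an edge within which a movement's origin
#'   or endpoint disqualifies it from the pool.
#' @return A trajectory tibble of the same shape (action column `NA`).
#' @export
shuffle_trajectories <- function(traj, seed = 1L, edge_tol = 1e-9) {
  ext <- traj_extent(traj)
  mv <- traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(dx = dplyr::lead(.data$x) - .data$x,
                  dy = dplyr::lead(.data$y) - .data$y,
                  x1 = dplyr::lead(.data$x), y1 = dplyr::lead(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx))
  at_edge <- function(x, y)
    x <= edge_tol | y <= edge_tol | x >= ext[1] - edge_tol | y >= ext[2] - edge_tol
  pool <- mv[!at_edge(mv$x, mv$y) & !at_edge(mv$x1, mv$y1), c("dx", "dy")]
  if (nrow(pool) == 0) abort("input error: empty movement pool")
  set.seed(seed)
  ts <- trial_summary(traj)
  rows <- lapply(seq_len(nrow(ts)), function(i) {
    n <- ts$T[i]
    j <- sample.int(nrow(pool), n, replace = TRUE)
    x <- numeric(n); y <- numeric(n)
    cx <- ts$x0[i]; cy <- ts$y0[i]
    for (k in seq_len(n)) { # clamp at each step, as on the rig
      cx <- min(max(cx + pool$dx[j[k]], 0), ext[1])
      cy <- min(max(cy + pool$dy[j[k]], 0), ext[2])
      x[k] <- cx; y[k] <- cy
    }
    tibble(trial = ts$trial[i], t = 0:n,
           x = c(ts$x0[i], x), y = c(ts$y0[i], y),
           action = NA_integer_, reward = 0,
           terminal = c(rep(FALSE, n), TRUE))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "extent") <- ext
  attr(out, "arena") <- attr(traj, "arena")
  out
}
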