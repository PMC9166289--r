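#' Discrete movement-action specification
#'
#' The action space of the object-manipulation task: one "no movement"
#' action plus every combination of 8 movement directions (45 degree bins)
#' and 8 per-step speeds, for 65 actions in total. Per-direction speed
#' multipliers reproduce the movement anisotropy of the joystick rig
#' (movement is easiest along the top-left / bottom-right diagonal).
#'
#' @param speeds Strictly positive per-step displacement magnitudes
#'   (arena units per step). Default: 8 evenly spaced values in
#'   `[0.02, 0.15]`, so a straight crossing of the unit arena takes roughly
#'   7-50 steps under the 300-step trial cap and expert discounted returns
#'   approach 1 -- the regime in which advantage signals are large enough
#'   for the policy gradient to compete with the entropy bonus.
#' @param directions Movement angles in degrees (0 = +x, counterclockwise).
#' @param direction_weights Per-direction speed multipliers, in the order of
#'   `directions`.
#' @return An `action_spec` with the action table (`none` is action 1).
#' @export
action_spec <- function(speeds = seq(0.02, 0.15, length.out = 8),
                        directions = seq(0, 315, by = 45),
                        direction_weights = c(0.6, 0.2, 0.6, 1.0,
                                              0.6, 0.2, 0.6, 1.0)) {
  stopifnot(all(speeds > 0), length(directions) == length(direction_weights))
  nd <- length(directions); ns <- length(speeds)
  d <- rep(seq_len(nd), each = ns)
  k <- rep(seq_len(ns), times = nd)
  ang <- directions[d] * pi / 180
  mag <- speeds[k] * direction_weights[d]
  table <- tibble(
    action = seq_len(1 + nd * ns),
    direction = c(NA, directions[d]),
    speed = c(0, speeds[k]),
    dx = c(0, mag * cos(ang)),
    dy = c(0, mag * sin(ang))
  )
  structure(list(speeds = speeds, directions = directions,
                 direction_weights = direction_weights,
                 none_action = 1L, n_actions = nrow(table), table = table),
            class = "action_spec")
}

#' Arena specification for the task and its variants
#'
#' @param variant One of `"base"` (1 x 1 arena, central 0.4 x 0.4 reward
#'   zone, reward 1), `"two_reward"` (reward zone split in half: right side
#'   reward 1, left side 0.1), `"two_room"` (2 x 4 arena, vertical divider
#'   with a 0.2 x 0.4 door at its middle, 0.4 x 0.4 reward zone in the
#'   bottom-right corner of the right room) or `"subgoal"` (base arena plus
#'   a 0.2 x 0.2 intrinsic-reward zone collectable once per trial).
#' @param max_steps Trial cap in steps (default 300; 1500 for the larger
#'   two-room arena).
#' @param subgoal_corner For the subgoal variant, `"bottom_right"` or
#'   `"top_left"`: which movement-bias-favoured corner holds the intrinsic
#'   reward.
#' @param subgoal_reward Intrinsic reward paid on first entry of the
#'   subgoal zone.
#' @return An `arena_spec` list: `extent`, `reward_zones` (list of
#'   `list(rect, reward)`), `walls` (list of rectangles), optional
#'   `subgoal_zone`, `door` (two-room only) and `max_steps`.
#' @export
arena_spec <- function(variant = c("base", "two_reward", "two_room", "subgoal"),
                       max_steps = NULL,
                       subgoal_corner = c("bottom_right", "top_left"),
                       subgoal_reward = 1) {
  variant <- match.arg(variant)
  if (is.null(max_steps)) max_steps <- if (variant == "two_room") 1500L else 300L
  subgoal_corner <- match.arg(subgoal_corner)
  walls <- list(); subgoal_zone <- NULL; door <- NULL
  start_region <- NULL
  if (variant == "base" || variant == "subgoal") {
    extent <- c(1, 1)
    zones <- list(list(rect = rect(0.3, 0.7, 0.3, 0.7), reward = 1))
    if (variant == "subgoal") {
      r <- if (subgoal_corner == "bottom_right") rect(0.7, 0.9, 0.1, 0.3)
           else rect(0.1, 0.3, 0.7, 0.9)
      subgoal_zone <- list(rect = r, reward = subgoal_reward, once = TRUE)
    }
  } else if (variant == "two_reward") {
    extent <- c(1, 1)
    zones <- list(list(rect = rect(0.5, 0.7, 0.3, 0.7), reward = 1),
                  list(rect = rect(0.3, 0.5, 0.3, 0.7), reward = 0.1))
  } else { # two_room
    extent <- c(2, 4)
    zones <- list(list(rect = rect(1.6, 2.0, 0.0, 0.4), reward = 1))
    door <- rect(0.9, 1.1, 1.8, 2.2)
    walls <- list(rect(0.9, 1.1, 0.0, 1.8), rect(0.9, 1.1, 2.2, 4.0))
    start_region <- rect(0, 0.9, 0, 4) # left room
  }
  spec <- structure(list(variant = variant, extent = extent,
                         reward_zones = zones, walls = walls,
                         subgoal_zone = subgoal_zone, door = door,
                         start_region = start_region,
                         max_steps = as.integer(max_steps)),
                    class = "arena_spec")
  validate_arena(spec)
  spec
}

validate_arena <- function(spec) {
  ext <- rect(0, spec$extent[1], 0, spec$extent[2])
  all_rects <- c(lapply(spec$reward_zones, `[[`, "rect"), spec$walls,
                 if (!is.null(spec$subgoal_zone)) list(spec$subgoal_zone$rect))
  for (r in all_rects) {
    if (r[["x0"]] < 0 || r[["y0"]] < 0 ||
        r[["x1"]] > ext[["x1"]] || r[["y1"]] > ext[["y1"]])
      abort("arena configuration error: zone or wall outside the extent")
  }
  for (z in spec$reward_zones) for (w in spec$walls)
    if (rects_overlap(z$rect, w)) abort("arena configuration error: zone overlaps a wall")
  if (!is.null(spec$subgoal_zone)) {
    for (z in spec$reward_zones)
      if (rects_overlap(spec$subgoal_zone$rect, z$rect))
        abort("arena configuration error: subgoal zone overlaps a reward zone")
    for (w in spec$walls)
      if (rects_overlap(spec$subgoal_zone$rect, w))
        abort("arena configuration error: subgoal zone overlaps a wall")
  }
  if (length(spec$reward_zones) >= 2) {
    for (i in seq_along(spec$reward_zones)[-1]) for (j in seq_len(i - 1))
      if (rects_overlap(spec$reward_zones[[i]]$rect, spec$reward_zones[[j]]$rect))
        abort("arena configuration error: overlapping reward zones")
  }
  invisible(spec)
}

#' Create a task environment
#'
#' Builds a mutable environment object exposing [env_reset()] and
#' [env_step()]. Reset places the agent uniformly at random outside all
#' reward zones (left room only in the two-room variant).
#'
#' @param variant Task variant; see [arena_spec()].
#' @param arena An [arena_spec()]; defaults to the named variant's spec.
#' @param actions An [action_spec()].
#' @param ... Passed to [arena_spec()] when `arena` is not supplied.
#' @return An `rl_env` object.
#' @export
make_env <- function(variant = c("base", "two_reward", "two_room", "subgoal"),
                     arena = NULL, actions = action_spec(), ...) {
  variant <- match.arg(variant)
  if (is.null(arena)) arena <- arena_spec(variant, ...)
  if (!identical(arena$variant, variant))
    abort("arena spec variant does not match `variant`")
  if (variant == "subgoal" && is.null(arena$subgoal_zone))
    abort("configuration error: subgoal variant requires a subgoal_zone")
  validate_arena(arena)
  e <- new.env(parent = emptyenv())
  e$arena <- arena
  e$actions <- actions
  e$pos <- c(NA_real_, NA_real_)
  e$vel <- c(0, 0)
  e$steps <- 0L
  e$subgoal_collected <- FALSE
  e$terminal <- TRUE
  e$open_loop <- NULL
  class(e) <- "rl_env"
  e
}

#' @export
print.rl_env <- function(x, ...) {
  cat(sprintf("<rl_env: %s, %d actions, extent %g x %g%s>\n", x$arena$variant,
              x$actions$n_actions, x$arena$extent[1], x$arena$extent[2],
              if (!is.null(x$open_loop)) ", open-loop" else ""))
  invisible(x)
}

#' Reset an environment to a fresh trial
#'
#' @param env An `rl_env`.
#' @return The 4-dimensional observation `(x, y, vx, vy)`; velocity is the
#'   previous step's displacement and starts at zero.
#' @export
env_reset <- function(env) {
  a <- env$arena
  region <- a$start_region %||% rect(0, a$extent[1], 0, a$extent[2])
  repeat {
    x <- runif(1, region[["x0"]], region[["x1"]])
    y <- runif(1, region[["y0"]], region[["y1"]])
    in_zone <- any(vapply(a$reward_zones, function(z) in_rect(x, y, z$rect), logical(1)))
    in_wall <- any(vapply(a$walls, function(w) in_rect(x, y, w), logical(1)))
    if (!in_zone && !in_wall) break
  }
  env$pos <- c(x, y)
  env$vel <- c(0, 0)
  env$steps <- 0L
  env$subgoal_collected <- FALSE
  env$terminal <- FALSE
  env_obs(env)
}

env_obs <- function(env) c(env$pos, env$vel)

# Earliest entry parameter of segment p0 -> p1 into rectangle r (slab test);
# Inf when the segment does not enter.
segment_entry <- function(p0, p1, r) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  lo <- c(r[["x0"]], r[["y0"]]); hi <- c(r[["x1"]], r[["y1"]])
  for (i in 1:2) {
    if (d[i] == 0) {
      if (p0[i] < lo[i] || p0[i] >= hi[i]) return(Inf)
    } else {
      ta <- (lo[i] - p0[i]) / d[i]
      tb <- (hi[i] - p0[i]) / d[i]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(Inf)
    }
  }
  t0
}

#' Advance an environment by one action
#'
#' Applies the action's displacement (speed times the direction's weight,
#' along the action's angle), clamps the position to the arena extent,
#' blocks motion at walls, pays zone rewards and terminates the trial on
#' reward-zone entry or at the step cap. In the subgoal variant, the first
#' entry into the subgoal zone pays the intrinsic reward without ending the
#' trial.
#'
#' @param env An `rl_env` (not terminal).
#' @param action Action index in `1..n_actions`.
#' @return A list: `obs` (next observation), `reward`, `terminal`,
#'   `action` (the executed action index; differs from the input under the
#'   open-loop wrapper).
#' @export
env_step <- function(env, action) {
  if (env$terminal) abort("state error: env_step() called on a terminal episode; call env_reset()")
  if (!is.numeric(action) || length(action) != 1 ||
      action < 1 || action > env$actions$n_actions || action != round(action))
    abort(sprintf("input error: action must be an integer in [1, %d]", env$actions$n_actions))
  executed <- as.integer(action)
  if (!is.null(env$open_loop))
    executed <- with_stream(env$open_loop, sample.int(env$actions$n_actions, 1L))
  a <- env$arena
  disp <- c(env$actions$table$dx[executed], env$actions$table$dy[executed])
  p0 <- env$pos
  p1 <- pmin(pmax(p0 + disp, c(0, 0)), a$extent)
  if (length(a$walls) && any(p1 != p0)) {
    tmin <- Inf
    for (w in a$walls) tmin <- min(tmin, segment_entry(p0, p1, w))
    if (is.finite(tmin)) p1 <- p0 + max(tmin - 1e-9, 0) * (p1 - p0)
  }
  env$vel <- p1 - p0
  env$pos <- p1
  env$steps <- env$steps + 1L
  reward <- 0
  terminal <- FALSE
  for (z in a$reward_zones) {
    if (in_rect(p1[1], p1[2], z$rect)) { reward <- z$reward; terminal <- TRUE; break }
  }
  if (!terminal && !is.null(a$subgoal_zone) && !env$subgoal_collected &&
      in_rect(p1[1], p1[2], a$subgoal_zone$rect)) {
    reward <- reward + a$subgoal_zone$reward
    env$subgoal_collected <- TRUE
  }
  if (!terminal && env$steps >= a$max_steps) terminal <- TRUE
  env$terminal <- terminal
  list(obs = env_obs(env), reward = reward, terminal = terminal, action = executed)
}

#' Open-loop wrapper: replace commanded actions by seeded random ones
#'
#' The returned environment executes an action drawn uniformly at random
#' from its own seeded stream, regardless of the action supplied by the
#' caller; rewards and termination rules are unchanged, and the executed
#' action is reported in the step result.
#'
#' @param env An `rl_env` to wrap (a fresh copy is returned).
#' @param seed Integer seed of the wrapper's private action stream.
#' @return A new `rl_env` in open-loop mode.
#' @export
open_loop_env <- function(env, seed) {
  e <- make_env(env$arena$variant, arena = env$arena, actions = env$actions)
  e$open_loop <- rng_stream(seed)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach an intrinsic-reward (subgoal) zone to an arena
#'
#' @param arena An [arena_spec()].
#' @param zone Rectangle of the subgoal zone.
#' @param reward Intrinsic reward paid on first entry per trial.
#' @return The arena with `subgoal_zone` set (validated).
#' @export
with_subgoal <- function(arena, zone, reward = 1) {
  arena$subgoal_zone <- list(rect = zone, reward = reward, once = TRUE)
  validate_arena(arena)
  arena
}

#' Rectangle around the peak of a gridded map
#'
#' Finds the bin with the maximal (finite) value and returns a rectangle
#' of the requested size centered on it, clipped to the arena. Used to
#' turn the diverse-density maximum into an intrinsic-reward zone.
#'
#' @param map An `rl_map` (e.g. log diverse density).
#' @param size Numeric length-2 rectangle size (defaults to 2 x 2 bins).
#' @return A rectangle (see [arena_spec()] conventions).
#' @export
map_peak_rect <- function(map, size = NULL) {
  spec <- map$spec
  if (is.null(size))
    size <- c(2 * spec$extent[1] / spec$nx, 2 * spec$extent[2] / spec$ny)
  v <- map$values
  if (all(!is.finite(v))) abort("input error: map has no finite values")
  k <- which.max(ifelse(is.finite(v), v, -Inf))
  bc <- bin_centers(spec)
  cx <- bc$x[k]; cy <- bc$y[k]
  x0 <- min(max(cx - size[1] / 2, 0), spec$extent[1] - size[1])
  y0 <- min(max(cy - size[2] / 2, 0), spec$extent[2] - size[2])
  rect(x0, x0 + size[1], y0, y0 + size[2])
}

#' Roll out episodes and record a tabular trajectory
#'
#' Runs complete trials under a policy and records one row per visited
#' state: `trial`, `t` (0-based step), `x`, `y`, `action` taken at `t`
#' (`NA` on the final row), `reward` received on arriving at `t`, and
#' `terminal`. A trial's outcome is a hit when its terminal row carries a
#' positive reward.
#'
#' @param env An `rl_env`.
#' @param policy `"random"`, `"none"`, or a function mapping the
#'   4-dimensional observation to an action index.
#' @param n_trials Number of complete trials to run.
#' @param seed Optional integer seed (episode starts, random policies and
#'   policy sampling all flow from it).
#' @return A trajectory tibble.
#' @export
rollout <- function(env, policy = "random", n_trials = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pol <- if (is.function(policy)) policy
    else if (identical(policy, "random")) function(obs) sample.int(env$actions$n_actions, 1L)
    else if (identical(policy, "none")) function(obs) env$actions$none_action
    else abort("policy must be 'random', 'none' or a function")
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    obs <- env_reset(env)
    xs <- numeric(env$arena$max_steps + 1L); ys <- xs
    acts <- integer(env$arena$max_steps + 1L); rews <- xs
    t <- 0L
    xs[1] <- obs[1]; ys[1] <- obs[2]; rews[1] <- 0
    repeat {
      a <- pol(obs)
      res <- env_step(env, a)
      acts[t + 1L] <- res$action
      t <- t + 1L
      xs[t + 1L] <- res$obs[1]; ys[t + 1L] <- res$obs[2]; rews[t + 1L] <- res$reward
      obs <- res$obs
      if (res$terminal) break
    }
    tt <- t
    rows[[tr]] <- tibble(
      trial = tr, t = 0:tt, x = xs[1:(tt + 1L)], y = ys[1:(tt + 1L)],
      action = c(acts[seq_len(tt)], NA_integer_),
      reward = rews[1:(tt + 1L)],
      terminal = c(rep(FALSE, tt), TRUE)
    )
  }
  traj <- dplyr::bind_rows(rows)
  attr(traj, "extent") <- env$arena$extent
  attr(traj, "arena") <- env$arena
  traj
}

#' Per-trial summary of a trajectory
#'
#' @param traj A trajectory tibble from [rollout()] or [gen_trajectory()].
#' @return A tibble with one row per trial: end time `T`, terminal reward,
#'   hit flag, start position and path length.
#' @export
trial_summary <- function(traj) {
  traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      T = max(.data$t),
      terminal_reward = .data$reward[which.max(.data$t)],
      hit = .data$reward[which.max(.data$t)] > 0,
      x0 = .data$x[which.min(.data$t)],
      y0 = .data$y[which.min(.data$t)],
      path_length = sum(sqrt(diff(.data$x[order(.data$t)])^2 +
                               diff(.data$y[order(.data$t)])^2)),
      .groups = "drop"
    )
}

traj_extent <- function(traj, default = c(1, 1)) {
  attr(traj, "extent") %||% default
}
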