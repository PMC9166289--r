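#' Synthetic-session specification
#'
#' Describes a mouse-like object-manipulation session in a 10 x 10 cm
#' arena with a central 4 x 4 cm reward zone: trial-structured 2D object
#' trajectories simulated on a 10-ms grid, behavioral channels rendered at
#' 2000 Hz, imaging frames at 5.67 Hz. Policy modes: `"guided"` (drift
#' toward the reward zone), `"waypoint"` (visit a corner subgoal first),
#' `"random"` (open-loop-like movement decoupled from the joystick).
#' Movement speeds fall in the 1.4-21.3 cm/s range used for velocity
#' binning, and the per-direction speed weights reproduce the rig's
#' movement anisotropy.
#'
#' @param n_trials Number of trials.
#' @param extent Arena extent in cm.
#' @param zone Reward-zone rectangle (default central 4 x 4 cm).
#' @param policy Movement policy mode.
#' @param waypoint Waypoint center (cm) for `"waypoint"` mode.
#' @param waypoint_radius Pass radius (cm) around the waypoint.
#' @param frame_rate Imaging frame rate (Hz).
#' @param behavior_rate Behavior sampling rate (Hz).
#' @param speed_range Object speed range (cm/s); instantaneous speeds are
#'   drawn as `min(speed_range[1] + Exp(mean speed_mean), speed_range[2])`.
#' @param speed_mean Mean of the exponential speed draw above the minimum
#'   (cm/s); together with `pause_prob` this calibrates median trial
#'   durations to the ~2-s scale of expert behavior.
#' @param pause_prob Probability that a 300-ms movement bout is a pause
#'   (object stationary), emulating bout-like joystick use.
#' @param direction_weights Per-45-degree-bin speed multipliers.
#' @param trial_cap_s Trial cap in seconds (task maximum 5 min; the
#'   generator default keeps miss trials short).
#' @param reward_period_s,iti_s Reward-consumption and intertrial
#'   intervals (s), during which the object is stationary.
#' @param heading_sd Direction noise (radians) around the target heading.
#' @param seed Integer seed.
#' @return A `session_spec` list.
#' @export
session_spec <- function(n_trials = 60, extent = c(10, 10),
                         zone = rect(3, 7, 3, 7),
                         policy = c("guided", "waypoint", "random"),
                         waypoint = c(8, 2), waypoint_radius = 1.5,
                         frame_rate = 5.67, behavior_rate = 2000,
                         speed_range = c(1.4, 21.3), speed_mean = 3.5,
                         pause_prob = 0.35,
                         direction_weights = c(0.6, 0.2, 0.6, 1.0,
                                               0.6, 0.2, 0.6, 1.0),
                         trial_cap_s = 30, reward_period_s = 4, iti_s = 2,
                         heading_sd = 0.5, seed = 1L) {
  policy <- match.arg(policy)
  if (policy == "waypoint" && in_rect(waypoint[1], waypoint[2], zone))
    abort("configuration error: waypoint lies inside the reward zone")
  structure(list(n_trials = n_trials, extent = extent, zone = zone,
                 policy = policy, waypoint = waypoint,
                 waypoint_radius = waypoint_radius, frame_rate = frame_rate,
                 behavior_rate = behavior_rate, speed_range = speed_range,
                 speed_mean = speed_mean, pause_prob = pause_prob,
                 direction_weights = direction_weights,
                 trial_cap_s = trial_cap_s, reward_period_s = reward_period_s,
                 iti_s = iti_s, heading_sd = heading_sd, seed = seed),
            class = "session_spec")
}

# arena_spec-compatible wrapper so behavior-module validators apply
session_arena <- function(spec) {
  a <- structure(list(variant = "base", extent = spec$extent,
                      reward_zones = list(list(rect = spec$zone, reward = 1)),
                      walls = list(), subgoal_zone = NULL, door = NULL,
                      start_region = NULL,
                      max_steps = as.integer(spec$trial_cap_s * 100)),
                 class = "arena_spec")
  validate_arena(a)
  a
}

# bout-like speed draw: exponential above the minimum, capped at the
# maximum, with stationary pauses
draw_speed <- function(spec) {
  if (runif(1) < spec$pause_prob) return(0)
  min(spec$speed_range[1] + stats::rexp(1, 1 / spec$speed_mean),
      spec$speed_range[2])
}

# speed multiplier interpolated from the 45-degree direction weights
bias_weight <- function(angle, weights) {
  k <- (round(angle / (pi / 4)) %% 8) + 1
  weights[k]
}

#' Generate a synthetic behavioral session
#'
#' Simulates the object path on a 10-ms grid per trial (drift toward the
#' target with heading noise in guided/waypoint modes, a persistent random
#' walk in random mode; speeds resampled every 100 ms and scaled by the
#' direction bias), then renders 2000-Hz behavior channels by linear
#' interpolation, inserting stationary reward-consumption and intertrial
#' periods between trials. Joystick velocity equals the object velocity
#' plus noise in guided/waypoint modes and is an independent random
#' process in random (open-loop-like) mode. Everything is a pure function
#' of the spec's seed.
#'
#' @param spec A [session_spec()].
#' @return An `rl_session`: `trajectory` (10-ms rows within trials, the
#'   tabular format all map operations consume), `behavior` (2000-Hz
#'   channels over the full session), `events` (per-trial onset/offset/
#'   reward times), `frames` (imaging frame clock), and the spec.
#' @export
gen_trajectory <- function(spec = session_spec()) {
  set.seed(spec$seed)
  dt <- 0.01
  hold <- 30L # speed/heading update every 300 ms (sustained pushes)
  cap <- round(spec$trial_cap_s / dt)
  arena <- session_arena(spec)
  traj_rows <- vector("list", spec$n_trials)
  events <- vector("list", spec$n_trials)
  seg_pos <- vector("list", spec$n_trials)
  t_global <- 0
  for (tr in seq_len(spec$n_trials)) {
    repeat {
      p <- runif(2) * spec$extent
      if (!in_rect(p[1], p[2], spec$zone)) break
    }
    xs <- numeric(cap + 1); ys <- numeric(cap + 1)
    xs[1] <- p[1]; ys[1] <- p[2]
    heading <- runif(1, -pi, pi)
    speed <- draw_speed(spec)
    to_waypoint <- spec$policy == "waypoint"
    n_pts <- cap + 1
    hit <- FALSE
    for (k in seq_len(cap)) {
      if ((k - 1) %% hold == 0) {
        speed <- draw_speed(spec)
        if (spec$policy == "random") {
          heading <- heading + rnorm(1, 0, 0.8)
        } else {
          target <- if (to_waypoint) spec$waypoint else rect_center(spec$zone)
          heading <- atan2(target[2] - p[2], target[1] - p[1]) +
            rnorm(1, 0, spec$heading_sd)
        }
      }
      w <- bias_weight(heading, spec$direction_weights)
      cand <- p + speed * w * dt * c(cos(heading), sin(heading))
      if (to_waypoint && in_rect(cand[1], cand[2], spec$zone)) {
        # steer around the reward zone until the waypoint has been visited
        for (rot in c(pi / 2, -pi / 2, pi)) {
          h2 <- heading + rot
          cand <- p + speed * bias_weight(h2, spec$direction_weights) * dt *
            c(cos(h2), sin(h2))
          if (!in_rect(cand[1], cand[2], spec$zone)) { heading <- h2; break }
        }
      }
      p <- pmin(pmax(cand, 0), spec$extent)
      xs[k + 1] <- p[1]; ys[k + 1] <- p[2]
      if (to_waypoint &&
          sqrt(sum((p - spec$waypoint)^2)) < spec$waypoint_radius)
        to_waypoint <- FALSE
      if (in_rect(p[1], p[2], spec$zone)) { hit <- TRUE; n_pts <- k + 1; break }
    }
    n_steps <- n_pts - 1
    traj_rows[[tr]] <- tibble(
      trial = tr, t = 0:n_steps, x = xs[1:n_pts], y = ys[1:n_pts],
      action = NA_integer_,
      reward = c(rep(0, n_steps), as.numeric(hit)),
      terminal = c(rep(FALSE, n_steps), TRUE)
    )
    t_on <- t_global
    t_off <- t_on + n_steps * dt
    events[[tr]] <- tibble(trial = tr, t_on = t_on, t_off = t_off,
                           t_reward = if (hit) t_off else NA_real_,
                           hit = hit)
    seg_pos[[tr]] <- tibble(time = t_on + (0:n_steps) * dt,
                            x = xs[1:n_pts], y = ys[1:n_pts])
    t_global <- t_off + (if (hit) spec$reward_period_s else 0) + spec$iti_s
  }
  trajectory <- dplyr::bind_rows(traj_rows)
  attr(trajectory, "extent") <- spec$extent
  attr(trajectory, "arena") <- arena
  events <- dplyr::bind_rows(events)

  # 2000 Hz channels over the full session (stationary between trials)
  tb <- seq(0, t_global, by = 1 / spec$behavior_rate)
  allseg <- dplyr::bind_rows(seg_pos)
  bx <- approx(allseg$time, allseg$x, xout = tb, method = "linear",
               rule = 2, ties = "ordered")$y
  by <- approx(allseg$time, allseg$y, xout = tb, method = "linear",
               rule = 2, ties = "ordered")$y
  # freeze position outside trials (approx interpolates across gaps)
  in_trial <- rep(FALSE, length(tb))
  for (i in seq_len(nrow(events)))
    in_trial <- in_trial | (tb >= events$t_on[i] & tb <= events$t_off[i])
  if (any(!in_trial)) {
    run <- cumsum(in_trial) # last in-trial index at each point
    run[run == 0] <- 1
    last_idx <- which(in_trial)[pmax(run, 1)]
    bx[!in_trial] <- bx[last_idx[!in_trial]]
    by[!in_trial] <- by[last_idx[!in_trial]]
  }
  vx <- c(0, diff(bx)) * spec$behavior_rate
  vy <- c(0, diff(by)) * spec$behavior_rate
  # no object motion between trials, and no teleport spike at trial starts
  entering <- in_trial & !c(FALSE, in_trial[-length(in_trial)])
  vx[!in_trial | entering] <- 0
  vy[!in_trial | entering] <- 0
  if (spec$policy == "random") {
    jh <- cumsum(rnorm(length(tb), 0, 0.05))
    js <- pmax(approx(seq(0, t_global, length.out = 200),
                      runif(200, 0, spec$speed_range[2]), xout = tb,
                      rule = 2)$y, 0)
    jvx <- js * cos(jh); jvy <- js * sin(jh)
    jvx[!in_trial] <- 0; jvy[!in_trial] <- 0
  } else {
    jvx <- vx + rnorm(length(tb), 0, 0.5)
    jvy <- vy + rnorm(length(tb), 0, 0.5)
    jvx[!in_trial] <- 0; jvy[!in_trial] <- 0
  }
  behavior <- tibble(time = tb, x = bx, y = by, obj_vx = vx, obj_vy = vy,
                     joy_vx = jvx, joy_vy = jvy)
  frames <- tibble(time = seq(0, t_global, by = 1 / spec$frame_rate))
  frames$frame <- seq_len(nrow(frames))
  structure(list(spec = spec, trajectory = trajectory, behavior = behavior,
                 events = events, frames = frames, arena = arena),
            class = "rl_session")
}

#' @export
print.rl_session <- function(x, ...) {
  cat(sprintf("<rl_session: %d trials (%s policy), %d frames at %.2f Hz, %.0f-Hz behavior>\n",
              x$spec$n_trials, x$spec$policy, nrow(x$frames),
              x$spec$frame_rate, x$spec$behavior_rate))
  invisible(x)
}

#' Frame-rate task variables of a session
#'
#' Down-samples the 2000-Hz behavior channels by averaging within each
#' imaging frame and discretizes velocities into 8 direction channels
#' carrying the movement magnitude; trial onset/offset and reward onset
#' become per-frame flags. The result is the input of
#' [build_design_matrix()].
#'
#' @param session An `rl_session`.
#' @return A list: `trial_onset`, `trial_offset`, `reward_onset`,
#'   `object_velocity` (frames x 8), `joystick_velocity` (frames x 8),
#'   `x`, `y`, plus `frame_rate`, `in_trial` and the per-frame `trial` id.
#' @export
frame_variables <- function(session) {
  fr <- session$frames
  n <- nrow(fr)
  edges <- c(fr$time, Inf)
  fidx <- findInterval(session$behavior$time, edges, rightmost.closed = FALSE)
  fidx[fidx < 1] <- 1; fidx[fidx > n] <- n
  avg <- function(v) {
    s <- rowsum(v, fidx)
    cnt <- tabulate(fidx, n)
    out <- rep(0, n)
    out[as.integer(rownames(s))] <- s / pmax(cnt[as.integer(rownames(s))], 1)
    out
  }
  dir_channels <- function(vx, vy) {
    sp <- sqrt(vx^2 + vy^2)
    ang <- atan2(vy, vx)
    k <- (round(ang / (pi / 4)) %% 8) + 1
    M <- matrix(0, n, 8)
    moving <- sp > 0
    if (any(moving)) {
      s <- rowsum(cbind(sp[moving]), group = (fidx[moving] - 1) * 8 + k[moving])
      gid <- as.integer(rownames(s))
      cnt <- tabulate(fidx, n)
      M[cbind((gid - 1) %/% 8 + 1, (gid - 1) %% 8 + 1)] <-
        s / pmax(cnt[(gid - 1) %/% 8 + 1], 1)
    }
    M
  }
  flag <- function(times) {
    times <- times[is.finite(times)]
    f <- rep(0, n)
    f[pmin(pmax(findInterval(times, edges), 1), n)] <- 1
    f
  }
  frame_trial <- rep(NA_integer_, n)
  for (i in seq_len(nrow(session$events))) {
    sel <- fr$time >= session$events$t_on[i] & fr$time <= session$events$t_off[i]
    frame_trial[sel] <- session$events$trial[i]
  }
  list(trial_onset = flag(session$events$t_on),
       trial_offset = flag(session$events$t_off),
       reward_onset = flag(session$events$t_reward),
       object_velocity = dir_channels(session$behavior$obj_vx,
                                      session$behavior$obj_vy),
       joystick_velocity = dir_channels(session$behavior$joy_vx,
                                        session$behavior$joy_vy),
       x = avg(session$behavior$x), y = avg(session$behavior$y),
       frame_rate = session$spec$frame_rate,
       in_trial = !is.na(frame_trial), trial = frame_trial)
}

#' Ground-truth unit population specification
#'
#' @param n_place,n_border,n_velocity,n_value,n_policy,n_mixed,n_null
#'   Population counts by archetype: place (2D Gaussian field), border
#'   (border-hugging), velocity (von Mises direction x linear speed),
#'   value-coding (rate proportional to the session's state-value map),
#'   policy-coding (conjunctive space x direction), mixed
#'   (place + velocity) and null (constant-rate).
#' @param snr Signal-to-noise ratio: peak modulation over baseline rate.
#' @param baseline_rate Baseline event rate (events/s).
#' @param seed Integer seed for archetype parameters.
#' @return A `unit_spec` list.
#' @export
unit_spec <- function(n_place = 10, n_border = 5, n_velocity = 10,
                      n_value = 10, n_policy = 10, n_mixed = 5, n_null = 10,
                      snr = 3, baseline_rate = 0.5, seed = 1L) {
  structure(list(counts = c(place = n_place, border = n_border,
                            velocity = n_velocity, value = n_value,
                            policy = n_policy, mixed = n_mixed,
                            null = n_null),
                 snr = snr, baseline_rate = baseline_rate, seed = seed),
            class = "unit_spec")
}

#' Generate ground-truth units for a session
#'
#' Draws archetype parameters (field centers, preferred directions, etc.)
#' and attaches the session-derived state-value map needed by the
#' value-coding archetype. Parameters are stored as recoverable ground
#' truth.
#'
#' @param spec A [unit_spec()].
#' @param session An `rl_session` (context for the value map).
#' @param gamma Discount per 10-ms bin for the session value map.
#' @return An `rl_units` object: tibble `units` (unit, archetype, params
#'   list-column) plus the value map.
#' @export
gen_units <- function(spec, session, gamma = 0.99) {
  set.seed(spec$seed)
  ext <- session$spec$extent
  vmap <- state_value_map(session$trajectory, gamma = gamma,
                          bins = bin_spec(20, 20, ext))
  vmax <- max(vmap$values, na.rm = TRUE)
  rows <- list()
  uid <- 0
  for (arch in names(spec$counts)) {
    for (i in seq_len(spec$counts[[arch]])) {
      uid <- uid + 1
      params <- switch(arch,
        place = list(center = runif(2) * ext, sigma = runif(1, 0.8, 1.5)),
        border = list(sigma = runif(1, 0.5, 1.2)),
        velocity = list(mu = runif(1, -pi, pi), kappa = runif(1, 1.5, 3)),
        value = list(vmax = vmax),
        policy = list(center = runif(2) * ext, sigma = runif(1, 1.2, 2),
                      mu = runif(1, -pi, pi), kappa = runif(1, 1.5, 3)),
        mixed = list(center = runif(2) * ext, sigma = runif(1, 0.8, 1.5),
                     mu = runif(1, -pi, pi), kappa = runif(1, 1.5, 3)),
        null = list()
      )
      rows[[uid]] <- tibble(unit = uid, archetype = arch,
                            params = list(params))
    }
  }
  structure(list(units = dplyr::bind_rows(rows), spec = spec,
                 value_map = vmap, extent = ext),
            class = "rl_units")
}

# rate (events/s) of one unit along frame-level behavior
unit_rate <- function(arch, params, spec_u, x, y, vx, vy, value_at, ext,
                      speed_max) {
  base <- spec_u$baseline_rate
  A <- spec_u$snr * base
  sp <- sqrt(vx^2 + vy^2)
  ang <- atan2(vy, vx)
  r <- switch(arch,
    place = A * exp(-((x - params$center[1])^2 + (y - params$center[2])^2) /
                      (2 * params$sigma^2)),
    border = A * exp(-pmin(x, ext[1] - x, y, ext[2] - y) / params$sigma),
    velocity = A * (sp / speed_max) *
      exp(params$kappa * (cos(ang - params$mu) - 1)),
    value = A * value_at / max(params$vmax, 1e-9),
    policy = A * exp(-((x - params$center[1])^2 + (y - params$center[2])^2) /
                       (2 * params$sigma^2)) *
      exp(params$kappa * (cos(ang - params$mu) - 1)) *
      pmin(sp / (0.25 * speed_max), 1),
    mixed = 0.5 * A * exp(-((x - params$center[1])^2 + (y - params$center[2])^2) /
                            (2 * params$sigma^2)) +
      0.5 * A * (sp / speed_max) * exp(params$kappa * (cos(ang - params$mu) - 1)),
    null = 0
  )
  rate <- base + r
  if (any(rate < 0)) abort("generator bug: negative rate")
  rate
}

#' Render Poisson activity for a unit population
#'
#' Evaluates each unit's ground-truth rate along the session's
#' frame-averaged behavior and draws per-frame counts from a Poisson
#' distribution with mean `rate / frame_rate` (deconvolved-spike-like
#' non-negative activity).
#'
#' @param units An `rl_units` from [gen_units()].
#' @param session The `rl_session` the units belong to.
#' @param seed Integer seed for the Poisson draws.
#' @return A frames x units matrix of counts, with attribute `rates`
#'   (the underlying frames x units rate matrix, events/s).
#' @export
render_activity <- function(units, session, seed = 1L) {
  fv <- frame_variables(session)
  n <- length(fv$x)
  vx <- rowSums(fv$object_velocity *
                  matrix(cos((0:7) * pi / 4), n, 8, byrow = TRUE))
  vy <- rowSums(fv$object_velocity *
                  matrix(sin((0:7) * pi / 4), n, 8, byrow = TRUE))
  vmap <- units$value_map
  vbin <- bin_index(fv$x, fv$y, vmap$spec)
  value_at <- vmap$values[vbin]
  value_at[!is.finite(value_at)] <- 0
  value_at[!fv$in_trial] <- 0
  speed_max <- session$spec$speed_range[2]
  U <- nrow(units$units)
  rates <- matrix(0, n, U)
  for (i in seq_len(U)) {
    rates[, i] <- unit_rate(units$units$archetype[i], units$units$params[[i]],
                            units$spec, fv$x, fv$y, vx, vy, value_at,
                            units$extent, speed_max)
  }
  set.seed(seed)
  counts <- matrix(rpois(n * U, rates / session$spec$frame_rate), n, U)
  attr(counts, "rates") <- rates
  counts
}

#' Per-frame trajectory of a session (in-trial frames)
#'
#' Collapses the session to one row per in-trial imaging frame in the
#' tabular trajectory format, for use with [activity_samples()].
#'
#' @param session An `rl_session`.
#' @return A list: `trajectory` tibble (one row per in-trial frame) and
#'   `frame_index` (which activity-matrix rows those are).
#' @export
frame_trajectory <- function(session) {
  fv <- frame_variables(session)
  sel <- which(fv$in_trial)
  traj <- tibble(trial = fv$trial[sel], x = fv$x[sel], y = fv$y[sel]) |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(t = dplyr::row_number() - 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(action = NA_integer_, reward = 0, terminal = FALSE)
  attr(traj, "extent") <- session$spec$extent
  attr(traj, "arena") <- session$arena
  list(trajectory = traj, frame_index = sel)
}
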