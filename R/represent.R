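# Per-sample unit-activity container shared by the classification
# operations: `activity` is samples x units; `bin` the spatial bin of each
# sample; `dx`, `dy` the movement originating at each sample (NA at trial
# ends); `direction` the movement's 45-degree bin (1..8, NA when
# stationary); `speed` its magnitude.
new_unit_samples <- function(activity, x, y, spec, dx, dy,
                             edge_tol = 1e-9) {
  activity <- as.matrix(activity)
  stopifnot(nrow(activity) == length(x), length(x) == length(y))
  speed <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  direction <- (round(ang / (pi / 4)) %% 8) + 1L
  direction[is.na(speed) | speed == 0] <- NA_integer_
  # Movements clamped at the arena boundary carry distorted directions, and
  # excluding only the clamped ones selects against outward movements near
  # edges (coupling position to direction). Direction statistics therefore
  # use only samples farther from every edge than the largest observed
  # displacement, where clamping cannot occur and no selection is induced.
  ext <- spec$extent
  margin <- suppressWarnings(max(abs(dx), abs(dy), na.rm = TRUE))
  margin <- min(margin, 0.2 * min(ext)) # keep a workable interior
  if (is.finite(margin) && margin < min(ext) / 2) {
    near_edge <- x < margin | y < margin |
      x > ext[1] - margin | y > ext[2] - margin
    direction[near_edge] <- NA_integer_
  }
  structure(list(activity = activity, x = x, y = y,
                 bin = bin_index(x, y, spec), spec = spec,
                 dx = dx, dy = dy, speed = speed, direction = direction,
                 n_units = ncol(activity)),
            class = "unit_samples")
}

#' @export
print.unit_samples <- function(x, ...) {
  cat(sprintf("<unit_samples: %d samples x %d units, %d x %d bins>\n",
              nrow(x$activity), x$n_units, x$spec$nx, x$spec$ny))
  invisible(x)
}

#' Hidden-unit activity along an agent trajectory
#'
#' Evaluates every hidden unit of the model at each state visited in the
#' trajectory (dropout off) and pairs the activations with the spatial bin
#' and the movement taken at that state. This is the per-sample record the
#' classification operations permute to build their nulls.
#'
#' @param model An `agent_model`.
#' @param traj Trajectory tibble from [evaluate_agent()] / [rollout()].
#' @param bins A [bin_spec()]; defaults to 20 x 20 over the arena.
#' @return A `unit_samples` object (units ordered as [unit_table()]).
#' @export
agent_samples <- function(model, traj, bins = NULL) {
  ext <- traj_extent(traj)
  if (is.null(bins)) bins <- bin_spec(20, 20, ext)
  d <- traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(vx = .data$x - dplyr::lag(.data$x, default = dplyr::first(.data$x)),
                  vy = .data$y - dplyr::lag(.data$y, default = dplyr::first(.data$y)),
                  dx = dplyr::lead(.data$x) - .data$x,
                  dy = dplyr::lead(.data$y) - .data$y) |>
    dplyr::ungroup()
  X <- cbind(d$x, d$y, d$vx, d$vy)
  H <- hidden_activations(model, X)
  new_unit_samples(H, d$x, d$y, bins, d$dx, d$dy)
}

#' Neural-activity samples aligned to a trajectory
#'
#' Pairs an activity matrix (frames x units) with the positions and
#' frame-to-frame movements of an aligned trajectory.
#'
#' @param activity Frames x units matrix of non-negative activity.
#' @param traj Trajectory tibble with one row per frame, aligned to
#'   `activity`.
#' @param bins A [bin_spec()].
#' @return A `unit_samples` object.
#' @export
activity_samples <- function(activity, traj, bins = NULL) {
  activity <- as.matrix(activity)
  if (nrow(activity) != nrow(traj))
    abort("input error: activity frames and trajectory rows differ")
  ext <- traj_extent(traj)
  if (is.null(bins)) bins <- bin_spec(20, 20, ext)
  d <- traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(dx = dplyr::lead(.data$x) - .data$x,
                  dy = dplyr::lead(.data$y) - .data$y) |>
    dplyr::ungroup()
  new_unit_samples(activity, d$x, d$y, bins, d$dx, d$dy)
}

# mean activity per visited bin: returns list(maps = nb x U with NA
# unvisited, counts = nb).
samples_maps <- function(samples) {
  nb <- n_bins(samples$spec)
  sums <- rowsum(samples$activity, samples$bin)
  idx <- as.integer(rownames(sums))
  counts <- tabulate(samples$bin, nb)
  maps <- matrix(NA_real_, nb, samples$n_units)
  maps[idx, ] <- sums / counts[idx]
  list(maps = maps, counts = counts)
}

#' Occupancy-normalized spatial tuning from activity samples
#'
#' Mean activity per visited spatial bin for every unit; unvisited bins are
#' missing. Because each bin's mean divides by its visit count, occupancy
#' bias does not masquerade as tuning.
#'
#' @param samples A `unit_samples` object.
#' @return An `rl_tuning_set`: `maps` (bins x units), `counts`, `spec`,
#'   `active` (any nonzero activity), `source`.
#' @export
activity_tuning <- function(samples) {
  sm <- samples_maps(samples)
  structure(list(maps = sm$maps, counts = sm$counts, spec = samples$spec,
                 active = apply(samples$activity, 2, function(a) any(a > 0)),
                 source = "activity"),
            class = "rl_tuning_set")
}

#' @export
print.rl_tuning_set <- function(x, ...) {
  cat(sprintf("<rl_tuning_set (%s): %d units, %d x %d bins, %d active>\n",
              x$source, ncol(x$maps), x$spec$nx, x$spec$ny, sum(x$active)))
  invisible(x)
}

#' Extract one unit's spatial tuning map
#'
#' @param tunings An `rl_tuning_set`.
#' @param unit Unit index.
#' @return An `rl_tuning_map`.
#' @export
tuning_map <- function(tunings, unit) {
  new_map(tunings$maps[, unit], tunings$spec, "tuning",
          counts = tunings$counts,
          extra = list(unit = unit, active = tunings$active[unit]))
}

#' Probe spatial tuning of hidden units with uniform random states
#'
#' Feeds `n_states` uniformly distributed random state inputs (position
#' uniform over the arena, velocity components uniform over the achievable
#' per-step displacement range) through the frozen network (dropout off)
#' and averages each hidden unit's activation per spatial bin. This
#' captures activity in states the agent might never visit, so maps are
#' comparable across learning stages. A unit is flagged active when any
#' probe elicits a strictly positive response.
#'
#' @param model An `agent_model`.
#' @param arena An [arena_spec()] (for the extent).
#' @param actions An [action_spec()] (for the achievable speed range).
#' @param n_states Number of probe states (default 100000).
#' @param bins A [bin_spec()]; defaults to 40 x 40 over the arena.
#' @param seed Integer seed.
#' @param batch Probe batch size (results are independent of batching).
#' @return An `rl_tuning_set` with `source = "probe"`.
#' @export
probe_space_tuning <- function(model, arena = arena_spec("base"),
                               actions = action_spec(), n_states = 1e5,
                               bins = NULL, seed = 1L, batch = 2e4) {
  if (is.null(bins)) bins <- bin_spec(40, 40, arena$extent)
  vmax <- max(actions$speeds) * max(actions$direction_weights)
  set.seed(seed)
  nb <- n_bins(bins)
  U <- length(model$mask)
  # all probe states drawn up front so results are batch-partition invariant
  Xall <- cbind(runif(n_states, 0, arena$extent[1]),
                runif(n_states, 0, arena$extent[2]),
                runif(n_states, -vmax, vmax), runif(n_states, -vmax, vmax))
  ball <- bin_index(Xall[, 1], Xall[, 2], bins)
  sums <- matrix(0, nb, U)
  counts <- rep(0L, nb)
  active <- rep(FALSE, U)
  done <- 0
  while (done < n_states) {
    n <- min(batch, n_states - done)
    sel <- (done + 1):(done + n)
    H <- hidden_activations(model, Xall[sel, , drop = FALSE])
    b <- ball[sel]
    s <- rowsum(H, b)
    idx <- as.integer(rownames(s))
    sums[idx, ] <- sums[idx, ] + s
    counts <- counts + tabulate(b, nb)
    active <- active | apply(H, 2, function(h) any(h > 0))
    done <- done + n
  }
  maps <- sums / counts
  maps[counts == 0, ] <- NA_real_
  structure(list(maps = maps, counts = counts, spec = bins, active = active,
                 source = "probe"),
            class = "rl_tuning_set")
}

#' Spatial coherence of a tuning map
#'
#' Pearson correlation between each bin's value and the mean of its up to
#' eight available neighbors (missing neighbors excluded). Constant maps
#' are defined to have coherence 0.
#'
#' @param map An `rl_map`, or a numeric vector with `spec` supplied.
#' @param spec A [bin_spec()] when `map` is a bare vector.
#' @return Coherence in `[-1, 1]` (NA with fewer than 9 usable bins).
#' @export
spatial_coherence <- function(map, spec = NULL) {
  if (inherits(map, "rl_map")) { spec <- map$spec; v <- map$values }
  else v <- map
  if (sum(is.finite(v)) < 9) return(NA_real_)
  nmean <- neighbor_means(v, spec)
  ok <- is.finite(v) & is.finite(nmean)
  if (sum(ok) < 9) return(NA_real_)
  if (sd(v[ok]) == 0 || sd(nmean[ok]) == 0) return(0)
  cor(v[ok], nmean[ok])
}

neighbor_means <- function(v, spec) {
  m <- matrix(v, spec$nx, spec$ny) # column iy, row ix
  padded <- matrix(NA_real_, spec$nx + 2, spec$ny + 2)
  padded[2:(spec$nx + 1), 2:(spec$ny + 1)] <- m
  acc <- matrix(0, spec$nx, spec$ny)
  cnt <- matrix(0, spec$nx, spec$ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- padded[(2 + di):(spec$nx + 1 + di), (2 + dj):(spec$ny + 1 + dj)]
    ok <- is.finite(sh)
    acc[ok] <- acc[ok] + sh[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  as.numeric(out)
}

#' Border index of a tuning map
#'
#' The activity field is the set of bins whose z-scored activity exceeds
#' `z_thresh`. The index contrasts the maximal fractional coverage of any
#' of the four arena borders by the field with the mean distance of field
#' bins to their nearest border (in units of the larger arena dimension):
#' `(coverage - distance) / (coverage + distance)`. A field hugging a full
#' border scores 1; a central blob touching no border scores -1.
#'
#' @param map An `rl_map` or numeric vector with `spec`.
#' @param spec A [bin_spec()] when `map` is a bare vector.
#' @param z_thresh Field threshold on the z-scored map.
#' @return Border index in `[-1, 1]`; NA when the field is empty.
#' @export
border_index <- function(map, spec = NULL, z_thresh = 1) {
  if (inherits(map, "rl_map")) { spec <- map$spec; v <- map$values }
  else v <- map
  ok <- is.finite(v)
  if (sum(ok) < 2 || sd(v[ok]) == 0) return(NA_real_)
  z <- (v - mean(v[ok])) / sd(v[ok])
  field <- which(ok & z > z_thresh)
  if (length(field) == 0) return(NA_real_)
  bc <- bin_centers(spec)
  fx <- bc$ix[field]; fy <- bc$iy[field]
  cover <- max(
    length(unique(fy[fx == 1])) / spec$ny,
    length(unique(fy[fx == spec$nx])) / spec$ny,
    length(unique(fx[fy == 1])) / spec$nx,
    length(unique(fx[fy == spec$ny])) / spec$nx
  )
  ext <- spec$extent
  # bin distance to the nearest border: 0 for border-adjacent bins
  cell <- mean(c(ext[1] / spec$nx, ext[2] / spec$ny))
  d_border <- pmin(fx - 1, spec$nx - fx, fy - 1, spec$ny - fy) * cell / max(ext)
  d_mean <- mean(d_border)
  if (cover == 0 && d_mean == 0) return(NA_real_)
  (cover - d_mean) / (cover + d_mean)
}

#' Velocity tuning test
#'
#' Two-stage test on movement samples: a one-way ANOVA of activity across
#' the eight movement-direction bins identifies direction tuning
#' (`p < alpha`); the preferred direction is the bin with the highest mean
#' activity, and speed modulation is then confirmed by a Pearson
#' correlation test between binned speed and activity at the preferred
#' direction (`p < alpha`). Both stages are required.
#'
#' @param samples A `unit_samples` object.
#' @param units Unit indices to test (default all).
#' @param alpha Significance level of both stages.
#' @param n_speed_bins Speed bins at the preferred direction.
#' @return Tibble: `unit`, `preferred_direction` (degrees),
#'   `p_direction`, `r_speed`, `p_speed`, `velocity_tuned`.
#' @export
velocity_test <- function(samples, units = NULL, alpha = 0.05,
                          n_speed_bins = 8) {
  if (is.null(units)) units <- seq_len(samples$n_units)
  mv <- !is.na(samples$direction)
  dir_f <- factor(samples$direction[mv], levels = 1:8)
  speed <- samples$speed[mv]
  sp_breaks <- seq(min(speed), max(speed), length.out = n_speed_bins + 1)
  sp_bin <- findInterval(speed, sp_breaks, all.inside = TRUE)
  sp_centers <- (sp_breaks[-1] + sp_breaks[-length(sp_breaks)]) / 2
  purrr::map_dfr(units, function(u) {
    act <- samples$activity[mv, u]
    res <- tibble(unit = u, preferred_direction = NA_real_,
                  p_direction = NA_real_, r_speed = NA_real_,
                  p_speed = NA_real_, velocity_tuned = FALSE)
    tab <- table(dir_f)
    if (any(tab < 2) || sd(act) == 0) return(res)
    p_dir <- tryCatch(stats::oneway.test(act ~ dir_f, var.equal = TRUE)$p.value,
                      error = function(e) NA_real_)
    if (!is.finite(p_dir)) return(res)
    pref <- which.max(tapply(act, dir_f, mean))
    res$preferred_direction <- (pref - 1) * 45
    res$p_direction <- p_dir
    sel <- as.integer(dir_f) == pref
    if (sum(sel) >= 3 && sd(act[sel]) > 0 && sd(sp_centers[sp_bin[sel]]) > 0) {
      ct <- stats::cor.test(sp_centers[sp_bin[sel]], act[sel])
      res$r_speed <- unname(ct$estimate)
      res$p_speed <- ct$p.value
    }
    res$velocity_tuned <- isTRUE(p_dir < alpha) && isTRUE(res$p_speed < alpha)
    res
  })
}

# colwise Pearson correlation of map columns with a reference vector,
# restricted to rows where both are finite (precomputed index `rows`).
colwise_cor <- function(maps, ref) {
  rc <- ref - mean(ref)
  mc <- sweep(maps, 2, colMeans(maps), "-")
  num <- drop(crossprod(mc, rc))
  den <- sqrt(colSums(mc^2) * sum(rc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Classify units against a reference decision-variable map
#'
#' The observed statistic per unit is the Pearson correlation between its
#' occupancy-normalized spatial tuning and the reference map (state-value,
#' occupancy or log diverse-density), over bins visited in the trajectory
#' where the reference is defined. The null permutes the spatial-bin label
#' of every trajectory sample (a seeded per-point label permutation,
#' repeated `n_shuffles` times), recomputes the tuning and re-correlates.
#' One-tailed permutation p-values (floor `1/(n_shuffles+1)`) are
#' Benjamini-Hochberg adjusted within the call; units are classified at
#' adjusted `p < q`.
#'
#' @param samples A `unit_samples` object.
#' @param reference An `rl_map` on the same bin spec (non-constant).
#' @param n_shuffles Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param q BH false-discovery level.
#' @param units Unit indices to classify (default all).
#' @return An `rl_classification` tibble: `unit`, `r`, `p`, `p_adj`,
#'   `classified`, `n_shuffles`, `excluded` (constant-tuning reason code).
#' @export
classify_by_map <- function(samples, reference, n_shuffles = 1000, seed = 1L,
                            q = 0.05, units = NULL) {
  if (!same_bins(samples$spec, reference$spec))
    abort("input error: sample and reference bin specs differ")
  if (is.null(units)) units <- seq_len(samples$n_units)
  A <- samples$activity[, units, drop = FALSE]
  b <- samples$bin
  nb <- n_bins(samples$spec)
  counts <- tabulate(b, nb)
  visited <- which(counts > 0 & is.finite(reference$values))
  if (length(visited) < 3) abort("input error: too few visited bins")
  ref <- reference$values[visited]
  if (sd(ref) == 0) abort("input error: reference map is constant")
  make_maps <- function(bb) {
    s <- rowsum(A, bb)
    idx <- as.integer(rownames(s))
    m <- matrix(0, nb, length(units))
    m[idx, ] <- s / counts[idx]
    m[visited, , drop = FALSE]
  }
  maps_obs <- make_maps(b)
  const <- apply(maps_obs, 2, sd) == 0
  r_obs <- colwise_cor(maps_obs, ref)
  set.seed(seed)
  exceed <- rep(0L, length(units))
  for (s in seq_len(n_shuffles)) {
    bb <- b[sample.int(length(b))]
    r_null <- colwise_cor(make_maps(bb), ref)
    exceed <- exceed + (ifelse(is.na(r_null), -Inf, r_null) >=
                          ifelse(is.na(r_obs), Inf, r_obs))
  }
  p <- (1 + exceed) / (1 + n_shuffles)
  p[const | is.na(r_obs)] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- tibble(unit = units, r = r_obs, p = p, p_adj = p_adj,
                classified = !is.na(p_adj) & p_adj < q,
                n_shuffles = n_shuffles,
                excluded = ifelse(const, "constant_tuning", NA_character_))
  class(out) <- c("rl_classification", class(out))
  out
}

#' Classify policy-representing units
#'
#' For each unit, the agent's movement-direction distribution (8 bins) is
#' averaged over the unit's top-5% most active spatial bins, weighting each
#' bin's distribution by the unit's normalized activity there. The
#' observed statistic is the Pearson correlation between the unit's
#' direction tuning and that distribution; the null permutes the movement
#' direction labels across samples `n_shuffles` times and recomputes the
#' direction tuning. BH-adjusted decisions at `p < q`. Callers should
#' restrict `units` to conjunctively space- and velocity-tuned units (see
#' [velocity_test()]); by default all units with non-constant spatial maps
#' are scored.
#'
#' @param samples A `unit_samples` object.
#' @param n_shuffles Number of direction-label permutations.
#' @param seed Integer seed.
#' @param q BH false-discovery level.
#' @param top_frac Fraction of most-active bins defining a unit's preferred
#'   states (at least one bin is always used).
#' @param units Unit indices to classify.
#' @return An `rl_classification` tibble (as [classify_by_map()]).
#' @export
classify_policy <- function(samples, n_shuffles = 1000, seed = 1L, q = 0.05,
                            top_frac = 0.05, units = NULL) {
  if (is.null(units)) units <- seq_len(samples$n_units)
  mv <- which(!is.na(samples$direction))
  if (length(mv) < 16) abort("input error: too few movement samples")
  dirs <- samples$direction[mv]
  A <- samples$activity[mv, units, drop = FALSE]
  bins_mv <- samples$bin[mv]
  nb <- n_bins(samples$spec)
  # per-bin direction counts
  D <- matrix(0, nb, 8)
  for (k in 1:8) D[, k] <- tabulate(bins_mv[dirs == k], nb)
  sm <- samples_maps(samples)
  maps <- sm$maps[, units, drop = FALSE]
  dir_counts <- tabulate(dirs, 8)
  tune_obs <- rowsum_dir(A, dirs, dir_counts)
  target <- matrix(NA_real_, 8, length(units))
  excluded <- rep(NA_character_, length(units))
  for (j in seq_along(units)) {
    v <- maps[, j]
    okb <- which(is.finite(v) & rowSums(D) > 0)
    if (length(okb) == 0 || sd(v[okb]) == 0) {
      excluded[j] <- "constant_tuning"; next
    }
    thr <- quantile(v[okb], 1 - top_frac, type = 1)
    top <- okb[v[okb] >= thr]
    if (length(top) == 0) top <- okb[which.max(v[okb])]
    w <- v[top]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(top), length(top))
    dist <- D[top, , drop = FALSE] / pmax(rowSums(D[top, , drop = FALSE]), 1)
    target[, j] <- drop(crossprod(dist, w))
  }
  r_obs <- vapply(seq_along(units), function(j) {
    if (!is.na(excluded[j])) return(NA_real_)
    cor_finite(tune_obs[, j], target[, j])
  }, numeric(1))
  set.seed(seed)
  exceed <- rep(0L, length(units))
  for (s in seq_len(n_shuffles)) {
    dd <- dirs[sample.int(length(dirs))]
    tn <- rowsum_dir(A, dd, dir_counts)
    r_null <- vapply(seq_along(units), function(j) {
      if (!is.na(excluded[j])) return(-Inf)
      r <- cor_finite(tn[, j], target[, j])
      if (is.na(r)) -Inf else r
    }, numeric(1))
    exceed <- exceed + (r_null >= ifelse(is.na(r_obs), Inf, r_obs))
  }
  p <- (1 + exceed) / (1 + n_shuffles)
  p[is.na(r_obs)] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- tibble(unit = units, r = r_obs, p = p, p_adj = p_adj,
                classified = !is.na(p_adj) & p_adj < q,
                n_shuffles = n_shuffles, excluded = excluded)
  class(out) <- c("rl_classification", class(out))
  out
}

# mean activity per direction bin (8 x U)
rowsum_dir <- function(A, dirs, dir_counts) {
  s <- rowsum(A, dirs)
  out <- matrix(0, 8, ncol(A))
  out[as.integer(rownames(s)), ] <- s
  sweep(out, 1, pmax(dir_counts, 1), "/")
}

#' Chance classification fraction from spatial basis surrogates
#'
#' Estimates the classified fraction expected under spatially uniform
#' tuning by running the map-correlation classification on the spatial
#' raised-cosine basis maps (proxies for place fields tiling the arena):
#' each round correlates every basis map with the reference, builds its
#' null by shuffling the basis map's (visited) bins, and records the
#' BH-classified fraction. The spread over rounds yields a p-value for an
#' observed fraction.
#'
#' @param reference An `rl_map`.
#' @param basis_maps Bins x n_basis matrix of surrogate tunings evaluated
#'   on `reference$spec` (see [spatial_basis_maps()]).
#' @param n_rounds Number of surrogate rounds (default 1000).
#' @param n_shuffles Bin shuffles per basis map per round.
#' @param seed Integer seed.
#' @param q BH level.
#' @return List: `chance_fraction` (mean over rounds), `fractions`,
#'   `p_value(observed)` giving the permutation p that an observed
#'   fraction exceeds the surrogate distribution.
#' @export
chance_fraction <- function(reference, basis_maps, n_rounds = 1000,
                            n_shuffles = 200, seed = 1L, q = 0.05) {
  visited <- which(is.finite(reference$values))
  ref <- reference$values[visited]
  B <- basis_maps[visited, , drop = FALSE]
  K <- ncol(B)
  set.seed(seed)
  fractions <- vapply(seq_len(n_rounds), function(rd) {
    r_obs <- colwise_cor(B, ref)
    exceed <- rep(0L, K)
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(length(visited))
      r_null <- colwise_cor(B[perm, , drop = FALSE], ref)
      exceed <- exceed + (ifelse(is.na(r_null), -Inf, r_null) >=
                            ifelse(is.na(r_obs), Inf, r_obs))
    }
    p <- (1 + exceed) / (1 + n_shuffles)
    p_adj <- stats::p.adjust(p, method = "BH")
    mean(p_adj < q, na.rm = TRUE)
  }, numeric(1))
  list(chance_fraction = mean(fractions), fractions = fractions,
       p_value = function(observed) perm_p(observed, fractions))
}

#' Contrast index between two fractions
#'
#' `(A - B) / (A + B)`, the normalized difference used for two-reward
#' enrichment (high- vs low-reward-side peak fractions), open- vs
#' closed-loop normalized change, and subgoal-discovery vs control
#' door-region enrichment difference.
#'
#' @param frac_a,frac_b Non-negative fractions (flavor-specific operands).
#' @param flavor Label recording which comparison the operands came from.
#' @return A one-row tibble: `flavor`, `frac_a`, `frac_b`, `value`
#'   (NA when both operands are 0).
#' @export
contrast_index <- function(frac_a, frac_b,
                           flavor = c("two_reward", "open_loop", "subgoal")) {
  flavor <- match.arg(flavor)
  if (frac_a < 0 || frac_b < 0) abort("input error: fractions must be >= 0")
  value <- if (frac_a + frac_b == 0) NA_real_ else (frac_a - frac_b) / (frac_a + frac_b)
  tibble(flavor = flavor, frac_a = frac_a, frac_b = frac_b, value = value)
}

#' Peak-location quadrant enrichment
#'
#' Fraction of active space-tuned units whose tuning-map peak lies in the
#' quadrant of interest, among peaks over all quadrants (chance 0.25 under
#' uniform tuning). Peak ties break to the first bin in row-major order.
#'
#' @param tunings An `rl_tuning_set`.
#' @param quadrant `"bottom_left"`, `"bottom_right"`, `"top_left"` or
#'   `"top_right"`.
#' @param units Unit indices to include (default: active units).
#' @return List: `fraction` for the requested quadrant, `table` of all
#'   four quadrant fractions, `n` units used. Fraction is NA when no unit
#'   qualifies.
#' @export
quadrant_enrichment <- function(tunings, quadrant = c("bottom_right",
                                                      "bottom_left",
                                                      "top_left", "top_right"),
                                units = NULL) {
  quadrant <- match.arg(quadrant)
  if (is.null(units)) units <- which(tunings$active)
  spec <- tunings$spec
  bc <- bin_centers(spec)
  halfx <- spec$extent[1] / 2; halfy <- spec$extent[2] / 2
  quad_of <- function(bin) {
    x <- bc$x[bin]; y <- bc$y[bin]
    dplyr::case_when(
      x < halfx & y < halfy ~ "bottom_left",
      x >= halfx & y < halfy ~ "bottom_right",
      x < halfx & y >= halfy ~ "top_left",
      TRUE ~ "top_right"
    )
  }
  peaks <- vapply(units, function(u) {
    v <- tunings$maps[, u]
    if (all(!is.finite(v)) || max(v, na.rm = TRUE) == 0) return(NA_integer_)
    which.max(ifelse(is.finite(v), v, -Inf))
  }, integer(1))
  peaks <- peaks[!is.na(peaks)]
  if (length(peaks) == 0)
    return(list(fraction = NA_real_, table = NULL, n = 0))
  quads <- quad_of(peaks)
  tab <- table(factor(quads, levels = c("bottom_left", "bottom_right",
                                        "top_left", "top_right")))
  frac <- as.numeric(tab) / length(peaks)
  names(frac) <- names(tab)
  list(fraction = frac[[quadrant]],
       table = tibble(quadrant = names(frac), fraction = frac),
       n = length(peaks))
}

#' Fraction of active units
#'
#' Units are active when the uniform-state probe (or the provided samples)
#' elicited any strictly positive response; sparseness is
#' `1 - active_fraction`.
#'
#' @param tunings An `rl_tuning_set`.
#' @return Scalar in `[0, 1]`.
#' @export
active_fraction <- function(tunings) mean(tunings$active)

#' Retention of unit categories across learning stages
#'
#' Cross-tabulates a stage-1 binary category (e.g. state-value vs
#' non-state-value) against stage-2 activity and category membership for
#' the same units, reporting conditional retention fractions.
#'
#' @param stage1,stage2 Tibbles with columns `unit`, `category` (logical)
#'   and `active` (logical), covering identical unit sets.
#' @return Tibble with one row per stage-1 category level:
#'   `category1`, `n`, `frac_active2` (still active at stage 2),
#'   `frac_category2` (in the category at stage 2).
#' @export
retention_analysis <- function(stage1, stage2) {
  if (!setequal(stage1$unit, stage2$unit))
    abort("input error: stage-1 and stage-2 unit sets differ")
  d <- dplyr::inner_join(stage1, stage2, by = "unit",
                         suffix = c("1", "2"))
  d |>
    dplyr::group_by(category1 = .data$category1) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_active2 = mean(.data$active2),
                     frac_category2 = mean(.data$category2),
                     .groups = "drop")
}

#' Rank-score regions across variables
#'
#' For each variable, regions are ranked 1 (worst) to R (best) in the
#' variable's stated direction, ties sharing the mean rank; a region's
#' score is its mean rank across variables. Variables with any missing
#' cell are skipped for all regions.
#'
#' @param metrics Tibble: first column `region`, remaining columns numeric
#'   variables.
#' @param higher_better Named logical vector per variable (default all
#'   TRUE).
#' @return Tibble: `region`, `score`, `n_variables`.
#' @export
score_regions <- function(metrics, higher_better = NULL) {
  vars <- setdiff(names(metrics), "region")
  if (nrow(metrics) < 2 || length(vars) < 1)
    abort("input error: need >= 2 regions and >= 1 variable")
  if (is.null(higher_better))
    higher_better <- setNames(rep(TRUE, length(vars)), vars)
  ranks <- sapply(vars, function(v) {
    x <- metrics[[v]]
    if (any(is.na(x))) return(rep(NA_real_, length(x)))
    if (!isTRUE(higher_better[[v]])) x <- -x
    rank(x, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = nrow(metrics),
                  dimnames = list(NULL, vars))
  used <- colSums(is.na(ranks)) == 0
  tibble(region = metrics$region,
         score = rowMeans(ranks[, used, drop = FALSE]),
         n_variables = sum(used))
}
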