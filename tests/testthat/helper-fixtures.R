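# Shared fixtures and independent oracles. Expensive objects are built once
# per test run, lazily, and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# hand-built trajectory tibble in the package's tabular format
make_traj <- function(trials, extent = c(1, 1), arena = NULL) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    n <- nrow(tr$xy)
    tibble::tibble(
      trial = i, t = 0:(n - 1),
      x = tr$xy[, 1], y = tr$xy[, 2],
      action = NA_integer_,
      reward = c(rep(0, n - 1), as.numeric(tr$hit)),
      terminal = c(rep(FALSE, n - 1), TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "extent") <- extent
  attr(out, "arena") <- arena
  out
}

# naive triple-loop diverse-density oracle (distances in bin-size units)
dd_oracle <- function(traj, bins) {
  ts <- rlrep::trial_summary(traj)
  bc <- expand.grid(ix = seq_len(bins$nx), iy = seq_len(bins$ny))
  cellw <- mean(c(bins$extent[1] / bins$nx, bins$extent[2] / bins$ny))
  cx <- (bc$ix - 0.5) / bins$nx * bins$extent[1]
  cy <- (bc$iy - 0.5) / bins$ny * bins$extent[2]
  nb <- nrow(bc)
  logdd <- numeric(nb)
  for (b in seq_len(nb)) {
    acc <- 0
    for (i in ts$trial) {
      pts <- traj[traj$trial == i, ]
      lp <- 0
      for (j in seq_len(nrow(pts))) {
        d2 <- ((cx[b] - pts$x[j])^2 + (cy[b] - pts$y[j])^2) / cellw^2
        p <- min(exp(-d2), 1 - 1e-15)
        lp <- lp + log1p(-p)
      }
      if (ts$hit[ts$trial == i]) acc <- acc + log(max(-expm1(lp), 1e-300))
      else acc <- acc + lp
    }
    logdd[b] <- acc
  }
  logdd
}

# staged training of the selected agent (seed 1), shared by the heavier
# property tests (trained once per run)
expert_fixture <- function() {
  cached("expert", {
    list(staged = rlrep::staged_training(seed = 1, expert_steps = 4e5,
                                         n_eval = 200))
  })
}
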