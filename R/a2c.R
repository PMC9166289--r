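#' Hyperparameter configuration for an A2C agent
#'
#' Fixed algorithm constants follow the training recipe used throughout:
#' learning rate 1e-4, RMSprop (alpha 0.99, epsilon 1e-5), gradient-norm
#' clip 0.5, GAE lambda 0.95, 16 synchronous workers, actor-loss
#' coefficient 1.
#'
#' @param shared Logical: actor and critic share one trunk (`TRUE`) or use
#'   independent trunks.
#' @param n_layers Hidden layers per trunk (1-4).
#' @param dropout_location `"none"`, a layer index (as character or
#'   integer), or `"all"`.
#' @param dropout_fraction One of 0, 0.2, 0.4.
#' @param beta_critic Coefficient of the value-function loss.
#' @param beta_entropy Coefficient of the policy-entropy bonus.
#' @param n_steps Future steps used for the value-estimation rollout.
#' @param gamma Discount factor (0.95 base task; 0.99 two-room).
#' @param width Hidden-layer width (default 64; a free architecture
#'   choice, recorded in every result object).
#' @param learning_rate,gae_lambda,n_workers,grad_clip,rmsprop_eps,rmsprop_alpha,beta_actor
#'   Algorithm constants; overridable for experiments.
#' @return A `hyper_config` list.
#' @export
hyper_config <- function(shared = TRUE, n_layers = 3L,
                         dropout_location = "none", dropout_fraction = 0,
                         beta_critic = 0.2, beta_entropy = 0.2, n_steps = 8L,
                         gamma = 0.95, width = 64L,
                         learning_rate = 1e-4, gae_lambda = 0.95,
                         n_workers = 16L, grad_clip = 0.5,
                         rmsprop_eps = 1e-5, rmsprop_alpha = 0.99,
                         beta_actor = 1) {
  dropout_location <- as.character(dropout_location)
  stopifnot(n_layers %in% 1:4, dropout_fraction %in% c(0, 0.2, 0.4))
  if (!dropout_location %in% c("none", "all", as.character(1:4)))
    abort("configuration error: invalid dropout_location")
  if (!dropout_location %in% c("none", "all") &&
      as.integer(dropout_location) > n_layers)
    abort("configuration error: dropout_location exceeds n_layers")
  if (dropout_fraction == 0) dropout_location <- "none"
  if (dropout_location == "none") dropout_fraction <- 0
  if (n_layers == 1 && dropout_location == "all") dropout_location <- "1"
  structure(list(shared = shared, n_layers = as.integer(n_layers),
                 dropout_location = dropout_location,
                 dropout_fraction = dropout_fraction,
                 beta_critic = beta_critic, beta_entropy = beta_entropy,
                 n_steps = as.integer(n_steps), gamma = gamma,
                 width = as.integer(width), learning_rate = learning_rate,
                 gae_lambda = gae_lambda, n_workers = as.integer(n_workers),
                 grad_clip = grad_clip, rmsprop_eps = rmsprop_eps,
                 rmsprop_alpha = rmsprop_alpha, beta_actor = beta_actor),
            class = "hyper_config")
}

#' Enumerate the full hyperparameter grid
#'
#' Crosses shared/separate trunks, 1-4 layers, dropout location
#' (none, each valid layer index, all), dropout fraction (0, 0.2, 0.4),
#' value-loss coefficient (0, 0.1, 0.2), entropy coefficient (0, 0.2, 0.4)
#' and rollout length (1, 4, 8), then collapses duplicate effective
#' configurations: fraction 0 and location "none" are the same no-dropout
#' configuration, and for one-layer networks location "all" duplicates
#' location 1. Locations exceeding the depth are invalid and excluded.
#' The default grid has 1620 rows.
#'
#' @param n_seeds Seeds per configuration (used by `n_runs`).
#' @return A tibble of distinct configurations, lexicographically ordered,
#'   with a `config_id` key; attribute `n_runs` = rows times `n_seeds`.
#' @export
hyper_grid <- function(n_seeds = 4L) {
  g <- tidyr::expand_grid(
    shared = c(TRUE, FALSE),
    n_layers = 1:4,
    dropout_location = c("none", "1", "2", "3", "4", "all"),
    dropout_fraction = c(0, 0.2, 0.4),
    beta_critic = c(0, 0.1, 0.2),
    beta_entropy = c(0, 0.2, 0.4),
    n_steps = c(1L, 4L, 8L)
  )
  g <- g |>
    dplyr::filter(!(.data$dropout_location %in% as.character(1:4)) |
                    as.integer(ifelse(.data$dropout_location %in% as.character(1:4),
                                      .data$dropout_location, "1")) <= .data$n_layers) |>
    dplyr::mutate(
      dropout_location = ifelse(.data$dropout_fraction == 0, "none", .data$dropout_location),
      dropout_fraction = ifelse(.data$dropout_location == "none", 0, .data$dropout_fraction),
      dropout_location = ifelse(.data$n_layers == 1 & .data$dropout_location == "all",
                                "1", .data$dropout_location)
    ) |>
    dplyr::distinct() |>
    dplyr::arrange(dplyr::desc(.data$shared), .data$n_layers, .data$dropout_location,
                   .data$dropout_fraction, .data$beta_critic, .data$beta_entropy,
                   .data$n_steps) |>
    dplyr::mutate(config_id = dplyr::row_number(), .before = 1)
  attr(g, "n_seeds") <- as.integer(n_seeds)
  attr(g, "n_runs") <- nrow(g) * as.integer(n_seeds)
  g
}

# ---- network ---------------------------------------------------------------

init_layer <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = rep(0, n_out))
}

#' Build an actor-critic network
#'
#' A multilayer perceptron with rectifying activations. Shared
#' architectures use one trunk feeding both heads; separate architectures
#' use independent actor and critic trunks. The actor output bias is
#' initialized so that the initial policy assigns probability
#' `p_none` to the no-movement action, reproducing the strong initial
#' stillness bias of the task.
#'
#' @param config A [hyper_config()].
#' @param obs_dim Observation dimension (4: position and velocity).
#' @param n_actions Number of discrete actions (65 at defaults).
#' @param seed Integer seed for weight initialization.
#' @param p_none Initial policy probability of the no-movement action.
#' @return An `agent_model`.
#' @export
build_network <- function(config, obs_dim = 4L, n_actions = 65L, seed = 1L,
                          p_none = 0.75) {
  set.seed(seed)
  w <- config$width
  make_trunk <- function() {
    dims <- c(obs_dim, rep(w, config$n_layers))
    lapply(seq_len(config$n_layers), function(i) init_layer(dims[i], dims[i + 1]))
  }
  trunks <- if (config$shared) list(shared = make_trunk())
            else list(actor = make_trunk(), critic = make_trunk())
  actor_head <- init_layer(w, n_actions, scale = 0.01)
  # softmax bias: exp(b) / (exp(b) + (n-1)) = p_none
  actor_head$b[1] <- log(p_none / (1 - p_none) * (n_actions - 1))
  critic_head <- init_layer(w, 1L, scale = 0.01)
  n_hidden <- config$n_layers * w * length(trunks)
  model <- structure(list(
    config = config, obs_dim = as.integer(obs_dim),
    n_actions = as.integer(n_actions), seed = as.integer(seed),
    trunks = trunks, actor_head = actor_head, critic_head = critic_head,
    mask = rep(1, n_hidden), opt = NULL
  ), class = "agent_model")
  model
}

#' @export
print.agent_model <- function(x, ...) {
  cat(sprintf("<agent_model: %s, %d layer(s) x %d units, %d actions%s>\n",
              if (x$config$shared) "shared" else "separate",
              x$config$n_layers, x$config$width, x$n_actions,
              if (any(x$mask == 0)) sprintf(", %d units lesioned", sum(x$mask == 0)) else ""))
  invisible(x)
}

#' Hidden-unit index table of a model
#'
#' @param model An `agent_model`.
#' @return A tibble with global `unit` id, trunk name, `layer` and
#'   within-layer index; ids match the rows of probe/tuning outputs.
#' @export
unit_table <- function(model) {
  w <- model$config$width
  purrr::imap_dfr(model$trunks, function(trunk, name) {
    tibble(trunk = name,
           layer = rep(seq_along(trunk), each = w),
           index = rep(seq_len(w), times = length(trunk)))
  }) |>
    dplyr::mutate(unit = dplyr::row_number(), .before = 1)
}

# Per-trunk slices of the global hidden-unit mask.
mask_slices <- function(model) {
  w <- model$config$width
  sizes <- vapply(model$trunks, function(tr) length(tr) * w, numeric(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  lapply(seq_along(sizes), function(i) {
    matrix(model$mask[starts[i]:ends[i]], nrow = w) # w x n_layers
  })
}

# Forward pass. X: n x obs_dim matrix. Returns logits, value, per-layer
# activations (post ReLU/mask/dropout) and the dropout masks used.
forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  slices <- mask_slices(model)
  drop_here <- function(layer) {
    training && cfg$dropout_fraction > 0 &&
      (cfg$dropout_location == "all" || cfg$dropout_location == as.character(layer))
  }
  run_trunk <- function(trunk, msl) {
    acts <- vector("list", length(trunk))
    zs <- vector("list", length(trunk))
    dmasks <- vector("list", length(trunk))
    a <- X
    for (l in seq_along(trunk)) {
      z <- a %*% trunk[[l]]$W
      z <- sweep(z, 2, trunk[[l]]$b, "+")
      h <- pmax(z, 0)
      h <- sweep(h, 2, msl[, l], "*")
      if (drop_here(l)) {
        keep <- 1 - cfg$dropout_fraction
        dm <- matrix(runif(length(h)) < keep, nrow(h), ncol(h)) / keep
        h <- h * dm
        dmasks[[l]] <- dm
      }
      zs[[l]] <- z; acts[[l]] <- h
      a <- h
    }
    list(acts = acts, zs = zs, dmasks = dmasks, out = a)
  }
  if (cfg$shared) {
    tr <- run_trunk(model$trunks$shared, slices[[1]])
    logits <- sweep(tr$out %*% model$actor_head$W, 2, model$actor_head$b, "+")
    value <- drop(tr$out %*% model$critic_head$W) + model$critic_head$b
    list(logits = logits, value = value, trunk = list(shared = tr), X = X)
  } else {
    ta <- run_trunk(model$trunks$actor, slices[[1]])
    tc <- run_trunk(model$trunks$critic, slices[[2]])
    logits <- sweep(ta$out %*% model$actor_head$W, 2, model$actor_head$b, "+")
    value <- drop(tc$out %*% model$critic_head$W) + model$critic_head$b
    list(logits = logits, value = value,
         trunk = list(actor = ta, critic = tc), X = X)
  }
}

softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Policy probabilities and state values of a model
#'
#' @param model An `agent_model`.
#' @param X Observation matrix (`n` x 4) or a single observation vector.
#' @return List with `probs` (`n` x actions) and `value` (`n`).
#' @export
policy_value <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  fw <- forward(model, X, training = FALSE)
  list(probs = softmax(fw$logits), value = fw$value)
}

#' Hidden-unit activations of a model
#'
#' Outputs of every hidden layer after the rectifying activation (and any
#' inactivation mask); dropout is disabled.
#'
#' @param model An `agent_model`.
#' @param X Observation matrix (`n` x 4).
#' @return An `n` x `n_hidden` matrix, columns ordered as [unit_table()].
#' @export
hidden_activations <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  fw <- forward(model, X, training = FALSE)
  do.call(cbind, unlist(lapply(fw$trunk, `[[`, "acts"), recursive = FALSE))
}

# ---- GAE -------------------------------------------------------------------

#' Generalized advantage estimation
#'
#' Advantages are exponentially weighted sums of n-step TD errors:
#' `A_t = sum_k (gamma*lambda)^k * delta_{t+k}`, with
#' `delta_t = r_t + gamma * V_{t+1} * (1 - done_t) - V_t`. Returns targets
#' are `y = A + V`. With `lambda = 0` the advantage reduces to the one-step
#' TD error exactly.
#'
#' @param rewards,dones Numeric/logical vectors of length `T` (time-ordered).
#' @param values Value estimates of length `T + 1` (last entry bootstraps
#'   the state after the rollout; ignored past terminal steps).
#' @param gamma Discount factor.
#' @param lambda GAE mixing parameter.
#' @return A list with `advantages` and `returns` (both length `T`).
#' @export
gae_advantages <- function(rewards, values, dones, gamma, lambda = 0.95) {
  T_ <- length(rewards)
  if (length(values) != T_ + 1 || length(dones) != T_)
    abort("input error: need length(values) == length(rewards) + 1 == length(dones) + 1")
  adv <- numeric(T_)
  gae <- 0
  for (t in T_:1) {
    nonterm <- 1 - as.numeric(dones[t])
    delta <- rewards[t] + gamma * values[t + 1] * nonterm - values[t]
    gae <- delta + gamma * lambda * nonterm * gae
    adv[t] <- gae
  }
  list(advantages = adv, returns = adv + values[seq_len(T_)])
}

# ---- update ----------------------------------------------------------------

flatten_params <- function(model) {
  ps <- list()
  for (tn in names(model$trunks))
    for (l in seq_along(model$trunks[[tn]]))
      ps[[paste0(tn, l)]] <- model$trunks[[tn]][[l]]
  ps$actor_head <- model$actor_head
  ps$critic_head <- model$critic_head
  ps
}

zero_like <- function(ps) lapply(ps, function(p) list(W = p$W * 0, b = p$b * 0))

#' One A2C update step
#'
#' Performs a single RMSprop step on the total loss
#' `beta_critic * mean(A^2) + beta_actor * (-mean(log pi(a|s) * A))
#'  - beta_entropy * mean(H(pi(.|s)))`,
#' with the advantage treated as a constant in the actor term and the
#' global gradient norm clipped. Loss terms are batch means so the scale is
#' independent of batch size. Dropout (when configured) is active during
#' the update's forward pass only.
#'
#' @param model An `agent_model`.
#' @param batch List with `states` (n x 4 matrix), `actions` (n),
#'   `advantages` (n), `returns` (n).
#' @param config Optional [hyper_config()]; defaults to the model's.
#' @return List `model` (updated) and `loss` (one-row tibble with the three
#'   components and the entropy).
#' @export
a2c_update <- function(model, batch, config = model$config) {
  X <- batch$states
  n <- nrow(X)
  stopifnot(length(batch$actions) == n, length(batch$advantages) == n,
            length(batch$returns) == n)
  fw <- forward(model, X, training = TRUE)
  probs <- softmax(fw$logits)
  logp <- log(pmax(probs, 1e-12))
  idx <- cbind(seq_len(n), batch$actions)
  A <- batch$advantages
  y <- batch$returns
  v <- fw$value
  ent_t <- -rowSums(probs * logp)
  l_critic <- mean((v - y)^2)
  l_actor <- -mean(logp[idx] * A)
  entropy <- mean(ent_t)
  total <- config$beta_critic * l_critic + config$beta_actor * l_actor -
    config$beta_entropy * entropy
  if (!is.finite(total))
    abort(sprintf("training error: non-finite loss (critic %.3g actor %.3g entropy %.3g)",
                  l_critic, l_actor, entropy))

  # gradient wrt logits and value
  onehot_adv <- matrix(0, n, model$n_actions)
  onehot_adv[idx] <- A
  dlogits <- config$beta_actor * (probs * A - onehot_adv) / n
  # entropy bonus: d(-H)/dz_k = pi_k * (log pi_k + H_t)
  dlogits <- dlogits +
    config$beta_entropy * probs * (logp + ent_t) / n
  dv <- config$beta_critic * 2 * (v - y) / n

  grads <- zero_like(flatten_params(model))
  back_trunk <- function(tr_name, tr_fw, d_out) {
    trunk <- model$trunks[[tr_name]]
    da <- d_out
    for (l in rev(seq_along(trunk))) {
      a_prev <- if (l == 1) X else tr_fw$acts[[l - 1]]
      dz <- da
      if (!is.null(tr_fw$dmasks[[l]])) dz <- dz * tr_fw$dmasks[[l]]
      msl <- mask_slices(model)[[match(tr_name, names(model$trunks))]]
      dz <- sweep(dz, 2, msl[, l], "*")
      dz <- dz * (tr_fw$zs[[l]] > 0)
      grads[[paste0(tr_name, l)]]$W <<- crossprod(a_prev, dz)
      grads[[paste0(tr_name, l)]]$b <<- colSums(dz)
      da <- tcrossprod(dz, trunk[[l]]$W)
    }
  }
  if (model$config$shared) {
    aL <- fw$trunk$shared$out
    grads$actor_head$W <- crossprod(aL, dlogits)
    grads$actor_head$b <- colSums(dlogits)
    grads$critic_head$W <- crossprod(aL, matrix(dv, ncol = 1))
    grads$critic_head$b <- sum(dv)
    d_out <- tcrossprod(dlogits, model$actor_head$W) +
      matrix(dv, ncol = 1) %*% t(model$critic_head$W)
    back_trunk("shared", fw$trunk$shared, d_out)
  } else {
    aA <- fw$trunk$actor$out; aC <- fw$trunk$critic$out
    grads$actor_head$W <- crossprod(aA, dlogits)
    grads$actor_head$b <- colSums(dlogits)
    grads$critic_head$W <- crossprod(aC, matrix(dv, ncol = 1))
    grads$critic_head$b <- sum(dv)
    back_trunk("actor", fw$trunk$actor, tcrossprod(dlogits, model$actor_head$W))
    back_trunk("critic", fw$trunk$critic,
               matrix(dv, ncol = 1) %*% t(model$critic_head$W))
  }

  # global gradient-norm clip
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g$W^2) + sum(g$b^2), numeric(1))))
  scale <- if (gnorm > config$grad_clip) config$grad_clip / gnorm else 1

  if (is.null(model$opt)) model$opt <- zero_like(flatten_params(model))
  ps <- flatten_params(model)
  al <- config$rmsprop_alpha; eps <- config$rmsprop_eps; lr <- config$learning_rate
  for (nm in names(ps)) {
    gW <- grads[[nm]]$W * scale; gb <- grads[[nm]]$b * scale
    model$opt[[nm]]$W <- al * model$opt[[nm]]$W + (1 - al) * gW^2
    model$opt[[nm]]$b <- al * model$opt[[nm]]$b + (1 - al) * gb^2
    ps[[nm]]$W <- ps[[nm]]$W - lr * gW / (sqrt(model$opt[[nm]]$W) + eps)
    ps[[nm]]$b <- ps[[nm]]$b - lr * gb / (sqrt(model$opt[[nm]]$b) + eps)
  }
  for (tn in names(model$trunks))
    for (l in seq_along(model$trunks[[tn]]))
      model$trunks[[tn]][[l]] <- ps[[paste0(tn, l)]]
  model$actor_head <- ps$actor_head
  model$critic_head <- ps$critic_head

  list(model = model,
       loss = tibble(total = total, critic = l_critic, actor = l_actor,
                     entropy = entropy, grad_norm = gnorm))
}

# loss components without updating (used by tests)
a2c_loss <- function(model, batch, config = model$config, training = FALSE) {
  fw <- forward(model, batch$states, training = training)
  probs <- softmax(fw$logits)
  logp <- log(pmax(probs, 1e-12))
  idx <- cbind(seq_along(batch$actions), batch$actions)
  l_critic <- mean((fw$value - batch$returns)^2)
  l_actor <- -mean(logp[idx] * batch$advantages)
  entropy <- mean(-rowSums(probs * logp))
  tibble(total = config$beta_critic * l_critic + config$beta_actor * l_actor -
           config$beta_entropy * entropy,
         critic = l_critic, actor = l_actor, entropy = entropy)
}

# ---- training --------------------------------------------------------------

sample_actions <- function(probs) {
  cs <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
  u <- runif(nrow(probs))
  as.integer(1L + rowSums(cs < u * cs[, ncol(cs)]))
}

#' Train an A2C agent
#'
#' Runs synchronous workers for `total_steps` environment steps (counted
#' across workers), updating every `n_steps` with GAE advantages. Training
#' is a pure function of `(config, env_factory, total_steps, seed)`.
#' Checkpoint copies of the model are stored the first time the cumulative
#' step count crosses each value of `checkpoints` (naive 1.6e3 and
#' intermediate 1.6e4 by default, mirroring the staged evaluation recipe).
#'
#' @param config A [hyper_config()].
#' @param env_factory Zero-argument function returning a fresh `rl_env`
#'   (one per worker), or a single `rl_env` to be used as a template.
#' @param total_steps Total environment steps across workers.
#' @param seed Integer seed.
#' @param checkpoints Cumulative step counts at which to snapshot the model.
#' @param model Optional starting `agent_model` (continue training).
#' @return List: `model`, `log` (per-update tibble of losses and mean
#'   episode return), `checkpoints` (named list of models), `config`.
#' @export
train_agent <- function(config, env_factory, total_steps, seed = 1L,
                        checkpoints = c(naive = 1.6e3, intermediate = 1.6e4),
                        model = NULL) {
  if (inherits(env_factory, "rl_env")) {
    template <- env_factory
    env_factory <- function() make_env(template$arena$variant,
                                       arena = template$arena,
                                       actions = template$actions)
  }
  set.seed(seed)
  if (is.null(model))
    model <- build_network(config, seed = sample.int(.Machine$integer.max, 1))
  W <- config$n_workers
  envs <- lapply(seq_len(W), function(i) env_factory())
  obs <- t(vapply(envs, env_reset, numeric(4)))
  ep_ret <- numeric(W); ep_disc <- numeric(W); ep_t <- integer(W)
  finished_returns <- numeric(0)
  finished_totals <- numeric(0)
  steps_done <- 0
  ckpt_out <- list()
  logs <- list()
  upd <- 0L
  while (steps_done < total_steps) {
    n_s <- config$n_steps
    S <- array(0, c(n_s, W, 4))
    Acts <- matrix(0L, n_s, W); Rews <- matrix(0, n_s, W)
    Dones <- matrix(FALSE, n_s, W); Vals <- matrix(0, n_s + 1, W)
    for (t in seq_len(n_s)) {
      fw <- forward(model, obs, training = FALSE)
      probs <- softmax(fw$logits)
      acts <- sample_actions(probs)
      Vals[t, ] <- fw$value
      S[t, , ] <- obs
      Acts[t, ] <- acts
      for (w in seq_len(W)) {
        res <- env_step(envs[[w]], acts[w])
        Rews[t, w] <- res$reward
        Dones[t, w] <- res$terminal
        ep_ret[w] <- ep_ret[w] + res$reward
        ep_disc[w] <- ep_disc[w] + config$gamma^ep_t[w] * res$reward
        ep_t[w] <- ep_t[w] + 1L
        if (res$terminal) {
          finished_returns <- c(finished_returns, ep_disc[w])
          finished_totals <- c(finished_totals, ep_ret[w])
          ep_ret[w] <- 0; ep_disc[w] <- 0; ep_t[w] <- 0L
          obs_w <- env_reset(envs[[w]])
          obs[w, ] <- obs_w
        } else obs[w, ] <- res$obs
      }
      steps_done <- steps_done + W
      for (nm in names(checkpoints)) {
        if (is.null(ckpt_out[[nm]]) && steps_done >= checkpoints[[nm]])
          ckpt_out[[nm]] <- model
      }
    }
    Vals[n_s + 1, ] <- forward(model, obs, training = FALSE)$value
    adv <- matrix(0, n_s, W); ret <- matrix(0, n_s, W)
    for (w in seq_len(W)) {
      g <- gae_advantages(Rews[, w], Vals[, w], Dones[, w],
                          config$gamma, config$gae_lambda)
      adv[, w] <- g$advantages; ret[, w] <- g$returns
    }
    batch <- list(states = matrix(aperm(S, c(2, 1, 3)), n_s * W, 4),
                  actions = as.integer(t(Acts)),
                  advantages = as.numeric(t(adv)),
                  returns = as.numeric(t(ret)))
    # aperm flattens worker-major; order is irrelevant to the update
    up <- a2c_update(model, batch, config)
    model <- up$model
    upd <- upd + 1L
    logs[[upd]] <- dplyr::mutate(up$loss, update = upd, steps = steps_done,
      mean_return = if (length(finished_returns))
        mean(utils::tail(finished_returns, 50)) else NA_real_,
      mean_total_return = if (length(finished_totals))
        mean(utils::tail(finished_totals, 50)) else NA_real_)
  }
  log <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble(total = numeric(0), critic = numeric(0), actor = numeric(0),
           entropy = numeric(0), grad_norm = numeric(0), update = integer(0),
           steps = numeric(0), mean_return = numeric(0),
           mean_total_return = numeric(0))
  for (nm in names(checkpoints))
    if (is.null(ckpt_out[[nm]]) && total_steps > 0) ckpt_out[[nm]] <- model
  list(model = model, log = log, checkpoints = ckpt_out, config = config,
       seed = seed,
       episode_returns = tibble(discounted = finished_returns,
                                total = finished_totals))
}

#' Evaluate a frozen agent
#'
#' Runs complete trials with actions sampled from the policy (dropout
#' disabled, parameters frozen) and returns both summary statistics and
#' the full trajectory for downstream analysis.
#'
#' @param model An `agent_model`.
#' @param env An `rl_env` (reset per trial).
#' @param n_trials Number of evaluation trials (default 300).
#' @param seed Integer seed.
#' @param greedy Take the argmax action instead of sampling.
#' @return List: `stats` (one-row tibble: `n_trials`, `hit_rate`,
#'   `mean_return` (discounted), `median_duration`, `median_distance`)
#'   and `trajectory`.
#' @export
evaluate_agent <- function(model, env, n_trials = 300, seed = 1L,
                           greedy = FALSE) {
  pol <- function(obs) {
    pv <- policy_value(model, obs)
    if (greedy) which.max(pv$probs[1, ])
    else sample_actions(pv$probs)
  }
  traj <- rollout(env, policy = pol, n_trials = n_trials, seed = seed)
  ts <- trial_summary(traj)
  gamma <- model$config$gamma
  rets <- traj |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(disc = sum(gamma^(.data$t) * .data$reward),
                     total = sum(.data$reward), .groups = "drop")
  stats <- tibble(
    n_trials = n_trials,
    hit_rate = mean(ts$hit),
    mean_return = mean(rets$disc),
    total_return = mean(rets$total),
    median_duration = stats::median(ts$T),
    median_distance = stats::median(ts$path_length)
  )
  list(stats = stats, trajectory = traj, trials = ts)
}

#' Rank models by representation features
#'
#' Each feature (fraction of state-value units, fraction of policy units,
#' sparseness = 1 - active fraction) is min-max normalized to `[0, 1]`
#' across models and the three are summed; models are ranked by descending
#' score with ties broken by `model_id` (ascending).
#'
#' @param features Tibble with columns `model_id`, `frac_value`,
#'   `frac_policy`, `sparseness`.
#' @return The tibble with `score` and `rank` columns, ordered by rank.
#' @export
select_optimized <- function(features) {
  if (nrow(features) < 2) abort("ranking error: need at least 2 models")
  norm01 <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  features |>
    dplyr::mutate(score = norm01(.data$frac_value) + norm01(.data$frac_policy) +
                    norm01(.data$sparseness)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$model_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Lesion a fraction of classified hidden units
#'
#' Clamps the activations of a seeded random subset of the given units to
#' zero in every forward pass (copy-on-lesion; the input model is
#' untouched).
#'
#' @param model An `agent_model`.
#' @param unit_ids Global hidden-unit ids (see [unit_table()]).
#' @param fraction Fraction of `unit_ids` to silence.
#' @param seed Integer seed for the subset choice.
#' @return A new `agent_model` with the inactivation mask applied.
#' @export
inactivate_units <- function(model, unit_ids, fraction, seed = 1L) {
  if (length(unit_ids) == 0 && fraction > 0)
    abort("input error: empty unit_ids with fraction > 0")
  stopifnot(all(unit_ids >= 1), all(unit_ids <= length(model$mask)))
  n_off <- round(fraction * length(unit_ids))
  if (n_off > 0) {
    off <- with_stream(rng_stream(seed),
                       sample(unit_ids, n_off))
    model$mask[off] <- 0
  }
  model
}
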