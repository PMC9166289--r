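#' The task-performance-optimized agent configuration
#'
#' The configuration selected by the representation-based model-selection
#' procedure (see [select_optimized()]): shared actor-critic trunk, 3
#' hidden layers, dropout in the deepest layer at fraction 0.2, value-loss
#' coefficient 0.2, rollout length 8. In this implementation's
#' environment the entropy coefficient that maximizes the selection score
#' is 0 (higher entropy coefficients leave the policy too soft for value
#' and policy coding to emerge at the training budget); the coefficient is
#' exposed so other grid points can be studied.
#'
#' @param beta_entropy Entropy coefficient (default 0).
#' @param width Hidden width.
#' @param gamma Discount factor.
#' @return A [hyper_config()].
#' @export
selected_config <- function(beta_entropy = 0, width = 64L, gamma = 0.95) {
  hyper_config(shared = TRUE, n_layers = 3L, dropout_location = "3",
               dropout_fraction = 0.2, beta_critic = 0.2,
               beta_entropy = beta_entropy, n_steps = 8L, gamma = gamma,
               width = width)
}

#' Subgoal-discovery sample-efficiency experiment
#'
#' Runs the two-room comparison between the diverse-density subgoal
#' algorithm and a reward-matched control. One exploration agent is
#' trained for `pre_steps`, its trajectories (at an extended trial cap)
#' yield the DD-discovered subgoal zone, and `n_per_arm` paired seeds then
#' continue training from the same exploration agent either with the
#' intrinsic reward (1 at the subgoal, once per trial, plus the extrinsic
#' 1 at the goal) or with the control reward (extrinsic 2 at the goal, no
#' intrinsic). Sample efficiency per run is the mean total (undiscounted)
#' episode return over the continuation phase -- the area under the
#' learning curve at a matched budget.
#'
#' @param n_per_arm Seeds per arm.
#' @param pre_steps Exploration-phase steps.
#' @param phase_steps Continuation-phase steps per run.
#' @param seed Master seed.
#' @param explore_entropy Entropy coefficient of the exploration phase
#'   (keeps the policy mobile while rewards are rare).
#' @param phase_entropy Entropy coefficient of the continuation phase.
#' @param subgoal_size Size of the intrinsic-reward zone around the DD
#'   peak.
#' @param dd_trials,dd_cap Trials and trial cap of the DD-collection
#'   rollout.
#' @return List: `results` tibble (seed, arm, mean_return), `zone`, `dd`,
#'   and the per-arm means.
#' @export
subgoal_experiment <- function(n_per_arm = 8, pre_steps = 6e4,
                               phase_steps = 2e5, seed = 1L,
                               explore_entropy = 0.2, phase_entropy = 0.05,
                               subgoal_size = c(0.4, 0.6),
                               dd_trials = 40, dd_cap = 3000) {
  cfg <- selected_config(beta_entropy = explore_entropy, gamma = 0.99)
  cfg$dropout_location <- "none"; cfg$dropout_fraction <- 0
  cfg2 <- cfg; cfg2$beta_entropy <- phase_entropy
  arena <- arena_spec("two_room")
  env <- make_env("two_room", arena = arena)
  pre <- train_agent(cfg, env, total_steps = pre_steps, seed = seed)
  env_long <- make_env("two_room",
                       arena = arena_spec("two_room", max_steps = dd_cap))
  explo <- evaluate_agent(pre$model, env_long, n_trials = dd_trials,
                          seed = seed + 1L)
  sg <- discover_subgoal(explo$trajectory, arena, size = subgoal_size)
  env_sg <- make_env("two_room", arena = with_subgoal(arena, sg$zone, 1))
  arena_ctl <- arena
  arena_ctl$reward_zones[[1]]$reward <- 2
  env_ctl <- make_env("two_room", arena = arena_ctl)
  one <- function(envx, s) {
    r <- train_agent(cfg2, envx, total_steps = phase_steps,
                     seed = seed + 100L + s, model = pre$model)
    mean(r$episode_returns$total)
  }
  res <- purrr::map_dfr(seq_len(n_per_arm), function(s) {
    tibble(seed = s,
           arm = c("subgoal", "control"),
           mean_return = c(one(env_sg, s), one(env_ctl, s)))
  })
  means <- res |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(mean = mean(.data$mean_return), .groups = "drop")
  list(results = res, zone = sg$zone, dd = sg$dd, means = means)
}

#' Staged training of the selected agent with representation read-outs
#'
#' Trains the selected configuration on the base task, snapshots the
#' naive (1.6e3 steps), intermediate (1.6e4) and expert (final)
#' checkpoints, and computes at each stage: evaluation statistics, the
#' active-unit fraction (uniform-state probe), and the fractions of
#' state-value- and policy-classified hidden units.
#'
#' @param seed Training seed.
#' @param expert_steps Total training steps of the expert stage.
#' @param config A [hyper_config()]; default [selected_config()].
#' @param n_eval Evaluation trials per stage.
#' @param n_shuffles Permutation count for the classifications.
#' @param probe_states Probe states for the active-fraction read-out.
#' @param bins Spatial bins of maps and classification.
#' @param gamma_map Analysis discount of the empirical state-value map
#'   (0.9 by default, matched to expert trial-duration scale; see the
#'   methods vignette).
#' @return List with per-stage tibble `stages` (stage, hit_rate,
#'   mean_return, active_fraction, frac_value, frac_policy) and the
#'   stage models.
#' @export
staged_training <- function(seed = 1L, expert_steps = 4e5,
                            config = selected_config(), n_eval = 100,
                            n_shuffles = 200, probe_states = 2e4,
                            bins = bin_spec(20, 20, c(1, 1)),
                            gamma_map = 0.9) {
  env <- make_env("base")
  run <- train_agent(config, env, total_steps = expert_steps, seed = seed)
  models <- list(naive = run$checkpoints$naive,
                 intermediate = run$checkpoints$intermediate,
                 expert = run$model)
  stages <- purrr::imap_dfr(models, function(m, nm) {
    ev <- evaluate_agent(m, env, n_trials = n_eval, seed = seed + 7L)
    vm <- state_value_map(ev$trajectory, gamma = gamma_map, bins = bins)
    tun <- probe_space_tuning(m, n_states = probe_states, seed = seed + 8L)
    smp <- agent_samples(m, ev$trajectory, bins = bins)
    clv <- classify_by_map(smp, vm, n_shuffles = n_shuffles, seed = seed + 9L)
    clp <- classify_policy(smp, n_shuffles = n_shuffles, seed = seed + 10L)
    tibble(stage = nm, hit_rate = ev$stats$hit_rate,
           mean_return = ev$stats$mean_return,
           active_fraction = active_fraction(tun),
           frac_value = mean(clv$classified, na.rm = TRUE),
           frac_policy = mean(clp$classified, na.rm = TRUE))
  })
  list(stages = stages, models = models, env = env, run = run)
}

#' Open-loop dissociation of value and policy coding
#'
#' Compares the fractions of state-value- and policy-classified units of
#' a trained agent between closed-loop evaluation and an open-loop
#' condition in which executed actions are drawn at random regardless of
#' the policy. Reports the normalized change
#' `(open - closed) / (open + closed)` per category.
#'
#' @param model A trained `agent_model`.
#' @param env The agent's `rl_env`.
#' @param n_trials Evaluation trials per condition.
#' @param n_shuffles Permutation count for classification.
#' @param seed Integer seed.
#' @param bins Spatial bins.
#' @param gamma_map Analysis discount of the state-value map.
#' @return Tibble: `target` (state_value / policy), `frac_closed`,
#'   `frac_open`, `normalized_change`.
#' @export
open_loop_dissociation <- function(model, env, n_trials = 100,
                                   n_shuffles = 200, seed = 1L,
                                   bins = bin_spec(20, 20, c(1, 1)),
                                   gamma_map = 0.9) {
  fractions <- function(traj) {
    vm <- state_value_map(traj, gamma = gamma_map, bins = bins)
    smp <- agent_samples(model, traj, bins = bins)
    clv <- classify_by_map(smp, vm, n_shuffles = n_shuffles, seed = seed + 2L)
    clp <- classify_policy(smp, n_shuffles = n_shuffles, seed = seed + 3L)
    c(value = mean(clv$classified, na.rm = TRUE),
      policy = mean(clp$classified, na.rm = TRUE))
  }
  ev_closed <- evaluate_agent(model, env, n_trials = n_trials, seed = seed)
  env_ol <- open_loop_env(env, seed = seed + 1L)
  ev_open <- evaluate_agent(model, env_ol, n_trials = n_trials,
                            seed = seed)
  fc <- fractions(ev_closed$trajectory)
  fo <- fractions(ev_open$trajectory)
  tibble(
    target = c("state_value", "policy"),
    frac_closed = as.numeric(fc), frac_open = as.numeric(fo),
    normalized_change = c(
      contrast_index(fo[["value"]], fc[["value"]], "open_loop")$value,
      contrast_index(fo[["policy"]], fc[["policy"]], "open_loop")$value
    )
  )
}

#' Inactivation (lesion) curve of classified units
#'
#' Silences increasing fractions of a set of classified hidden units and
#' evaluates the lesioned agent, mirroring the functional test that
#' decision-variable representations are causally needed.
#'
#' @param model A trained `agent_model`.
#' @param env The agent's `rl_env`.
#' @param unit_ids Classified unit ids to lesion.
#' @param fractions Lesioned fractions (default 0.2..1).
#' @param n_trials Evaluation trials per fraction.
#' @param seed Integer seed.
#' @return Tibble: `fraction`, `hit_rate`, `mean_return`.
#' @export
lesion_curve <- function(model, env, unit_ids,
                         fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                         n_trials = 100, seed = 1L) {
  purrr::map_dfr(fractions, function(f) {
    les <- inactivate_units(model, unit_ids, f, seed = seed)
    ev <- evaluate_agent(les, env, n_trials = n_trials, seed = seed + 1L)
    tibble(fraction = f, hit_rate = ev$stats$hit_rate,
           mean_return = ev$stats$mean_return)
  })
}
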