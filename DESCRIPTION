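Package: rlrep
Title: Actor-Critic Agents and Neural Representation Analysis for a
    Sensorimotor Object-Manipulation Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a joystick-style object-manipulation task with a
    continuous state and a discrete, movement-biased action space; trains
    advantage actor-critic (A2C) agents over a hyperparameter grid with
    generalized advantage estimation; derives decision-variable maps from
    trajectories (state-value, policy and diverse-density subgoal maps);
    probes and classifies hidden-unit and neuronal tuning (space, velocity,
    state-value, policy, subgoal) with permutation nulls and false-discovery
    control; fits Poisson elastic-net encoding models with raised-cosine
    bases and pseudo-explained variance; and generates fully synthetic
    behavioral sessions and neural populations with planted ground truth so
    that every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
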