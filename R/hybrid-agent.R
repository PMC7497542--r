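#' Parameters of the hybrid model-free/model-based agent
#'
#' The five general parameters of the hybrid reinforcement-learning model:
#' learning rate `alpha` (0..1), eligibility trace `lam` (0..1), inverse
#' temperature `beta` (>= 0), model-basedness weight `omega` (0..1) and
#' perseveration `rho` (unbounded; positive values favour repeating the last
#' choice of the same set, negative values favour switching).
#'
#' @param alpha,lam,beta,omega,rho Numeric scalars, bounds as above.
#' @return A named list of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.21, lam = 0.96, beta = 1.95,
                         omega = 0.33, rho = 0.73) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  if (beta < 0) stop("beta must be >= 0")
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  structure(list(alpha = alpha, lam = lam, beta = beta, omega = omega,
                 rho = rho), class = "agent_params")
}

#' Fresh agent state
#'
#' Stage-2 stimulus values, stage-1 action values, set-specific transition
#' counters and last-action memory, all indexed set (1 = the truly
#' predictable set, 2 = the truly random set -- a labelling the agent itself
#' never observes) x action/picture (1, 2). Everything starts at zero /
#' "no previous action".
#'
#' @return A list of class `agent_state` with elements `q1` (2 x 2 matrix,
#'   set x action), `q2` (2 x 2, set x picture), `counters`
#'   (2 x 2 x 2 array, set x action x picture) and `last_action`
#'   (length-2 integer, `NA` = none).
#' @export
agent_state <- function() {
  structure(list(q1 = matrix(0, 2, 2), q2 = matrix(0, 2, 2),
                 counters = array(0L, c(2, 2, 2)),
                 last_action = c(NA_integer_, NA_integer_)),
            class = "agent_state")
}

#' Temporal-difference update of a stage-2 stimulus value
#'
#' `q2(p) <- q2(p) + alpha * (r - q2(p))`; the bracketed term is the reward
#' prediction error elicited by the feedback.
#'
#' @param state An [agent_state()].
#' @param set Set index (1 or 2).
#' @param picture Presented stage-2 picture (1 or 2).
#' @param r Reward, unit-coded (+1 win / -1 loss).
#' @param alpha Learning rate in \[0, 1\].
#' @return List with the updated `state` and the signed `rpe`.
#' @export
stage2_update <- function(state, set, picture, r, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  rpe <- r - state$q2[set, picture]
  state$q2[set, picture] <- state$q2[set, picture] + alpha * rpe
  list(state = state, rpe = rpe)
}

#' Eligibility-trace update of a stage-1 action value
#'
#' `q1(a) <- q1(a) + alpha * (q2(p) - q1(a)) + alpha * lam * (r - q2(p))`,
#' where both deltas reference the stage-2 value *before* its own update on
#' the same trial. Call this before [stage2_update()] (the composition is
#' then identical to updating stage 2 first with memorised pre-update
#' values).
#'
#' @inheritParams stage2_update
#' @param action Chosen stage-1 action (1 or 2).
#' @param lam Eligibility-trace parameter in \[0, 1\].
#' @return The updated state.
#' @export
stage1_update <- function(state, set, action, picture, r, alpha, lam) {
  q2_old <- state$q2[set, picture]
  state$q1[set, action] <- state$q1[set, action] +
    alpha * (q2_old - state$q1[set, action]) +
    alpha * lam * (r - q2_old)
  state
}

#' Forgetting decay of unvisited values
#'
#' Multiplies every stage-1 and stage-2 value of both sets by `(1 - alpha)`,
#' except the trial's chosen action and presented picture.
#'
#' @inheritParams stage1_update
#' @return The updated state.
#' @export
apply_forgetting <- function(state, set, action, picture, alpha) {
  decay <- 1 - alpha
  keep_q1 <- state$q1[set, action]
  keep_q2 <- state$q2[set, picture]
  state$q1 <- state$q1 * decay
  state$q2 <- state$q2 * decay
  state$q1[set, action] <- keep_q1
  state$q2[set, picture] <- keep_q2
  state
}

#' Update transition counters and infer the internal model
#'
#' Increments the (set, action, picture) transition counter, then computes
#' per set the difference
#' `d = (n[a1->p1] + n[a2->p2]) - (n[a1->p2] + n[a2->p1])`. The set with the
#' larger `|d|` is identified as predictable and receives 0.75/0.25 beliefs
#' oriented by `sign(d)`; the other set -- and both sets on an `|d|` tie or
#' when `d = 0` within the identified set -- hold 0.5/0.5 beliefs.
#'
#' @inheritParams stage1_update
#' @return List with the updated `state` and `beliefs`, itself a list with
#'   `p` (2 x 2 x 2 array, set x action x picture, rows summing to 1) and
#'   `predictable_set` (1, 2 or `NA` on tie).
#' @export
update_and_infer_model <- function(state, set, action, picture) {
  state$counters[set, action, picture] <-
    state$counters[set, action, picture] + 1L
  list(state = state, beliefs = infer_transition_beliefs(state))
}

#' @rdname update_and_infer_model
#' @export
infer_transition_beliefs <- function(state) {
  d <- vapply(1:2, function(s) {
    cn <- state$counters[s, , ]
    (cn[1, 1] + cn[2, 2]) - (cn[1, 2] + cn[2, 1])
  }, numeric(1))
  p <- array(0.5, c(2, 2, 2))
  pred <- NA_integer_
  if (abs(d[1]) != abs(d[2])) pred <- which.max(abs(d))
  if (!is.na(pred) && d[pred] != 0) {
    hi <- 0.75
    if (d[pred] > 0) {
      p[pred, 1, ] <- c(hi, 1 - hi)
      p[pred, 2, ] <- c(1 - hi, hi)
    } else {
      p[pred, 1, ] <- c(1 - hi, hi)
      p[pred, 2, ] <- c(hi, 1 - hi)
    }
  }
  list(p = p, predictable_set = pred)
}

#' Net stage-1 action values
#'
#' Model-based values by the one-step Bellman equation,
#' `Q_MB(a) = sum_p P(p | a) q2(p)`, mixed with the model-free values as
#' `Q_net(a) = omega * Q_MB(a) + (1 - omega) * q1(a)`.
#'
#' @param state An [agent_state()].
#' @param beliefs Transition beliefs as returned by
#'   [infer_transition_beliefs()].
#' @param set Set index (1 or 2).
#' @param omega Model-basedness weight in \[0, 1\].
#' @return Numeric length-2 vector of net values, one per action.
#' @export
net_action_values <- function(state, beliefs, set, omega) {
  stopifnot(omega >= 0, omega <= 1)
  q_mb <- beliefs$p[set, , ] %*% state$q2[set, ]
  drop(omega * q_mb + (1 - omega) * state$q1[set, ])
}

#' Softmax choice probabilities with perseveration
#'
#' `P(a)` proportional to `exp(beta * Q_net(a) + rho * rep(a))`, where
#' `rep(a)` is 1 if `a` equals the last chosen action of the same set and 0
#' otherwise. Normalisation is overflow-safe (max-subtracted).
#'
#' @param q_net Numeric length-2 net action values.
#' @param last_action Index of the previous same-set action, or `NA`.
#' @param beta Inverse temperature, >= 0.
#' @param rho Perseveration weight.
#' @return Numeric length-2 probability vector summing to 1.
#' @export
choice_probabilities <- function(q_net, last_action, beta, rho) {
  stopifnot(beta >= 0)
  if (any(!is.finite(q_net))) stop("non-finite net action values")
  rep_a <- as.numeric(seq_along(q_net) %in% last_action)
  z <- beta * q_net + rho * rep_a
  e <- exp(z - max(z))
  e / sum(e)
}

# Per-block structural randomisation: which picture commonly follows action 1
# of the predictable set, and which picture of each set is the high-reward
# one ("frame colors and sets were assigned randomly for each block").
block_structure <- function(n_blocks) {
  list(common_map = sample(0:1, n_blocks, replace = TRUE),
       hr_pic0 = sample(0:1, n_blocks, replace = TRUE),
       hr_pic1 = sample(0:1, n_blocks, replace = TRUE))
}

#' Simulate a full session of the hybrid agent
#'
#' Runs `n_blocks x trials_per_block` trials of the interleaved two-stage
#' task. Per trial: observe the presented set, choose by softmax over the net
#' action values, transition to a stage-2 picture, receive probabilistic
#' feedback, update stage-2 and stage-1 values (both deltas referencing the
#' pre-update stage-2 value), decay all unvisited values, and update the
#' transition counters that drive the internal-model inference. Q-values,
#' counters and last actions reset at every block boundary (sets are
#' re-assigned per block). Rewards are unit-coded (+1/-1) inside the model;
#' payoffs in ct are carried alongside for bonus accounting.
#'
#' @param params An [agent_params()] (or a list of two, one per set:
#'   `list(predictable = ..., random = ...)`).
#' @param config A [task_config()].
#' @param seed Integer seed; identical seed and parameters give an identical
#'   trial table.
#' @return A tibble with one row per trial: block, trial, condition, set,
#'   action, pic, stage2, transition, valence, expectancy, payoff,
#'   reward_unit, correct, rpe, abs_rpe, p_choice, q_net_A, q_net_B,
#'   predictable_set_flag (whether the agent's current internal model tags
#'   the truly predictable set as predictable).
#' @export
simulate_agent <- function(params, config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- split_params(params)
  n_b <- config$n_blocks
  struct <- block_structure(n_b)
  cond <- unlist(lapply(seq_len(n_b), function(b)
    generate_condition_sequence(config)))
  n <- length(cond)
  block0 <- rep(seq_len(n_b) - 1L, each = config$trials_per_block)
  set0 <- ifelse(cond == "predictable", 0L, 1L)

  res <- cpp_hybrid_run(block0, set0, integer(n), integer(n), numeric(n),
                        pp$set0, pp$set1, 1L,
                        struct$common_map, struct$hr_pic0, struct$hr_pic1,
                        config$p_common, config$p_reward_high)

  hr <- ifelse(set0 == 0L, struct$hr_pic0[block0 + 1L],
               struct$hr_pic1[block0 + 1L])
  stage2 <- ifelse(res$picture == hr, "high_reward", "low_reward")
  valence <- ifelse(res$reward > 0, "win", "loss")
  # correct first-stage action: the one whose common transition leads to the
  # high-reward picture (predictable condition only)
  corr_act <- ifelse(struct$common_map[block0 + 1L] == struct$hr_pic0[block0 + 1L],
                     0L, 1L)
  correct <- ifelse(set0 == 0L, as.integer(res$action == corr_act),
                    NA_integer_)
  tibble::tibble(
    block = block0 + 1L,
    trial = seq_len(n),
    trial_in_block = rep(seq_len(config$trials_per_block), n_b),
    condition = cond,
    set = set0 + 1L,
    action = c("A", "B")[res$action + 1L],
    pic = res$picture + 1L,
    stage2 = stage2,
    transition = ifelse(set0 == 0L,
                        c("common", "rare")[res$transition + 1L],
                        "undefined"),
    valence = valence,
    expectancy = label_expectancy(stage2, valence),
    payoff = ifelse(valence == "win", config$reward_win, config$reward_loss),
    reward_unit = res$reward,
    correct = correct,
    rpe = res$rpe,
    abs_rpe = abs(res$rpe),
    p_choice = res$p_choice,
    q_net_A = res$qnet_A,
    q_net_B = res$qnet_B,
    predictable_set_flag = res$inferred_pred_set == 0L
  )
}

# Normalise params argument to the two per-set numeric vectors the C++ core
# expects (order: alpha, lam, beta, omega, rho).
split_params <- function(params) {
  as_vec <- function(p) unlist(p[c("alpha", "lam", "beta", "omega", "rho")])
  if (!is.null(params$alpha)) {
    v <- as_vec(params)
    list(set0 = v, set1 = v)
  } else {
    list(set0 = as_vec(params$predictable), set1 = as_vec(params$random))
  }
}

# Replay an observed trial table through the deterministic state recursion.
# Returns the raw C++ result (per-trial logp, p_choice, rpe, ...).
replay_agent <- function(params, trials) {
  pp <- split_params(params)
  cpp_hybrid_run(trials$block - 1L, trials$set - 1L,
                 as.integer(match(trials$action, c("A", "B")) - 1L),
                 trials$pic - 1L, trials$reward_unit,
                 pp$set0, pp$set1, 0L,
                 integer(max(trials$block)), integer(max(trials$block)),
                 integer(max(trials$block)), 0.75, 0.7)
}
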