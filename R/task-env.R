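#' Task configuration for the two-stage, one-decision Markov task
#'
#' Builds the configuration of the modified two-stage task: two interleaved
#' stimulus sets, one with a predictable transition structure (75/25 common vs.
#' rare) and one with a random structure (50/50), both sharing an identical
#' reward structure (70/30) with symmetric payoffs of +3 / -3 ct.
#'
#' @param p_common Probability of the common transition in the predictable
#'   condition. Default 0.75.
#' @param p_random Stage-2 stimulus probability in the random condition
#'   (both stimuli equiprobable). Default 0.5.
#' @param p_reward_high Probability that the high-reward stage-2 stimulus
#'   yields a win (and the low-reward stimulus a loss). Default 0.7.
#' @param reward_win,reward_loss Payoffs in cents. Defaults +3 / -3.
#' @param trials_per_block Trials per block. Default 100.
#' @param trials_per_condition Trials of each condition per block. Default 50.
#' @param max_run Maximum run length of one condition. Default 3.
#' @param n_blocks Number of blocks. Default 4.
#' @return A list of class `task_config`.
#' @export
task_config <- function(p_common = 0.75, p_random = 0.5, p_reward_high = 0.7,
                        reward_win = 3, reward_loss = -3,
                        trials_per_block = 100, trials_per_condition = 50,
                        max_run = 3, n_blocks = 4) {
  probs <- c(p_common = p_common, p_random = p_random,
             p_reward_high = p_reward_high)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (2L * trials_per_condition != trials_per_block)
    stop("trials_per_condition x 2 must equal trials_per_block")
  if (max_run < 1) stop("max_run must be >= 1")
  structure(list(p_common = p_common, p_random = p_random,
                 p_reward_high = p_reward_high,
                 reward_win = reward_win, reward_loss = reward_loss,
                 trials_per_block = trials_per_block,
                 trials_per_condition = trials_per_condition,
                 max_run = max_run, n_blocks = n_blocks),
            class = "task_config")
}

#' Generate an interleaved condition sequence for one block
#'
#' Draws a random ordering of `trials_per_condition` predictable and
#' `trials_per_condition` random trials under the constraint that one
#' condition never occurs more than `max_run` times in a row. Sampling is
#' sequential and rejection-free: at every position the next label is drawn
#' uniformly from the labels that keep the remaining suffix arrangeable
#' (label counts `n1`, `n2` are arrangeable with run cap `m` iff
#' `n1 <= m * (n2 + 1)` and vice versa).
#'
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Character vector of length `trials_per_block` with values
#'   `"predictable"` / `"random"`.
#' @export
generate_condition_sequence <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$max_run
  remaining <- c(predictable = config$trials_per_condition,
                 random = config$trials_per_condition)
  if (max(remaining) > m * (min(remaining) + 1))
    stop("infeasible constraint combination: max_run too small for counts")
  labels <- names(remaining)
  out <- character(config$trials_per_block)
  run_label <- ""
  run_len <- 0L
  for (i in seq_along(out)) {
    ok <- vapply(labels, function(l) {
      if (remaining[[l]] == 0L) return(FALSE)
      if (l == run_label && run_len >= m) return(FALSE)
      rem <- remaining
      rem[[l]] <- rem[[l]] - 1L
      # after placing l the current run of l has some length; the other label
      # must be able to break subsequent runs: arrangeability of the suffix
      other <- setdiff(labels, l)
      new_run <- if (l == run_label) run_len + 1L else 1L
      head_cap <- m - new_run       # further l's allowed before an `other`
      if (rem[[l]] > head_cap + m * rem[[other]]) return(FALSE)
      rem[[other]] <= m * (rem[[l]] + 1L)
    }, logical(1))
    pick <- sample(labels[ok], 1L)
    out[i] <- pick
    remaining[[pick]] <- remaining[[pick]] - 1L
    if (pick == run_label) run_len <- run_len + 1L else {
      run_label <- pick
      run_len <- 1L
    }
  }
  out
}

#' Sample a stage-1 to stage-2 transition
#'
#' In the predictable condition the chosen action leads to its mapped stage-2
#' stimulus with probability `p_common` (labelled `"common"`), otherwise to
#' the alternative (`"rare"`). In the random condition both stimuli are
#' equiprobable and the transition label is `"undefined"`.
#'
#' @param condition `"predictable"` or `"random"`.
#' @param action `"A"` or `"B"`.
#' @param direction_map Named character vector mapping each action to the
#'   stage-2 stimulus it commonly leads to, e.g.
#'   `c(A = "high_reward", B = "low_reward")`. Required for the predictable
#'   condition.
#' @param config A [task_config()].
#' @return List with `stage2` (stimulus label) and `transition`.
#' @export
sample_transition <- function(condition, action, direction_map = NULL,
                              config = task_config()) {
  stimuli <- c("high_reward", "low_reward")
  if (condition == "predictable") {
    if (is.null(direction_map) || is.na(direction_map[action]))
      stop("direction_map must be defined for the predictable condition")
    mapped <- unname(direction_map[action])
    common <- stats::runif(1) < config$p_common
    list(stage2 = if (common) mapped else setdiff(stimuli, mapped),
         transition = if (common) "common" else "rare")
  } else if (condition == "random") {
    list(stage2 = stimuli[1L + (stats::runif(1) >= config$p_random)],
         transition = "undefined")
  } else stop("unknown condition label: ", condition)
}

#' Sample feedback from the reward structure
#'
#' The high-reward stage-2 stimulus yields a win with probability
#' `p_reward_high`; the low-reward stimulus yields a loss with the same
#' probability. Payoffs are `reward_win` / `reward_loss` cents.
#'
#' @param stage2 `"high_reward"` or `"low_reward"`.
#' @param config A [task_config()].
#' @return List with `valence` (`"win"`/`"loss"`) and `payoff` in ct.
#' @export
sample_feedback <- function(stage2, config = task_config()) {
  stopifnot(stage2 %in% c("high_reward", "low_reward"))
  u <- stats::runif(1)
  win <- if (stage2 == "high_reward") u < config$p_reward_high
         else u >= config$p_reward_high
  list(valence = if (win) "win" else "loss",
       payoff = if (win) config$reward_win else config$reward_loss)
}

#' Assign the expectancy label of an outcome
#'
#' Wins after the high-probability-reward stimulus and losses after the
#' low-probability-reward stimulus are expected (70% cells); the two
#' complementary cells (30%) are unexpected. Expectancy depends only on the
#' fixed reward structure and is therefore identical across conditions.
#'
#' @param stage2 `"high_reward"` or `"low_reward"`.
#' @param valence `"win"` or `"loss"`.
#' @return `"expected"` or `"unexpected"`.
#' @export
label_expectancy <- function(stage2, valence) {
  stopifnot(stage2 %in% c("high_reward", "low_reward"),
            valence %in% c("win", "loss"))
  ifelse((stage2 == "high_reward") == (valence == "win"),
         "expected", "unexpected")
}

#' Analytic chance-level payoff in the random condition
#'
#' Expected payoff per trial of a uniformly random policy in the random
#' condition: both stage-2 stimuli are reached with probability 1/2,
#' the high-reward stimulus pays `p_reward_high * reward_win +
#' (1 - p_reward_high) * reward_loss` and the low-reward stimulus the mirror
#' image, so the expectation cancels exactly to 0 under the symmetric default
#' payoffs.
#'
#' @param config A [task_config()].
#' @return Expected payoff in ct (a scalar).
#' @export
chance_level_payoff <- function(config = task_config()) {
  ev_high <- config$p_reward_high * config$reward_win +
    (1 - config$p_reward_high) * config$reward_loss
  ev_low <- (1 - config$p_reward_high) * config$reward_win +
    config$p_reward_high * config$reward_loss
  0.5 * ev_high + 0.5 * ev_low
}
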