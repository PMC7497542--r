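# Independent reference implementations used as oracles.

# Full agent recursion composed from the exported R-level operations, in the
# per-trial order: beliefs -> net values -> softmax -> (observed outcome) ->
# stage-1 update -> stage-2 update (pre-update q2 in both deltas) ->
# forgetting -> counters. Returns per-trial probability of the observed
# choice and the RPE sequence. Used to check the C++ replay against an
# independent composition of the documented primitives.
r_reference_replay <- function(params, trials) {
  st <- agent_state()
  cur_block <- -1L
  n <- nrow(trials)
  p_choice <- rpe <- numeric(n)
  act <- match(trials$action, c("A", "B"))
  for (t in seq_len(n)) {
    if (trials$block[t] != cur_block) {
      st <- agent_state()
      cur_block <- trials$block[t]
    }
    s <- trials$set[t]
    a <- act[t]
    p <- trials$pic[t]
    r <- trials$reward_unit[t]
    beliefs <- infer_transition_beliefs(st)
    qn <- net_action_values(st, beliefs, s, params$omega)
    pr <- choice_probabilities(qn, st$last_action[s], params$beta,
                               params$rho)
    p_choice[t] <- pr[a]
    st <- stage1_update(st, s, a, p, r, params$alpha, params$lam)
    up <- stage2_update(st, s, p, r, params$alpha)
    st <- up$state
    rpe[t] <- up$rpe
    st <- apply_forgetting(st, s, a, p, params$alpha)
    st <- update_and_infer_model(st, s, a, p)$state
    st$last_action[s] <- a
  }
  list(p_choice = p_choice, rpe = rpe)
}

# Minimal one-step TD oracle for the omega = 0, lambda = 1 reduction:
# q1[chosen] moves straight toward r, everything else (both sets) decays by
# (1 - alpha); choice is softmax(beta * q1 + rho * rep).
minimal_td_probs <- function(alpha, beta, rho, trials) {
  q1 <- matrix(0, 2, 2)
  last <- c(NA_integer_, NA_integer_)
  cur_block <- -1L
  act <- match(trials$action, c("A", "B"))
  p_choice <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    if (trials$block[t] != cur_block) {
      q1 <- matrix(0, 2, 2)
      last <- c(NA_integer_, NA_integer_)
      cur_block <- trials$block[t]
    }
    s <- trials$set[t]
    a <- act[t]
    r <- trials$reward_unit[t]
    z <- beta * q1[s, ] + rho * (seq_len(2) %in% last[s])
    e <- exp(z - max(z))
    p_choice[t] <- (e / sum(e))[a]
    q1_new <- q1 * (1 - alpha)
    q1_new[s, a] <- q1[s, a] + alpha * (r - q1[s, a])
    q1 <- q1_new
    last[s] <- a
  }
  p_choice
}

# Brute-force within-subject ANOVA for fully-crossed two-level designs:
# every effect F equals the squared paired t statistic of its contrast
# scores, an independent route to the sums-of-squares decomposition.
anova_by_contrasts <- function(cells, dv, id, within) {
  d <- as.data.frame(cells)
  out <- list()
  effects <- unlist(lapply(seq_along(within), function(k)
    combn(within, k, paste, collapse = ":", simplify = FALSE)),
    recursive = FALSE)
  for (ef in effects) {
    facs <- strsplit(ef, ":")[[1]]
    sign <- rep(1, nrow(d))
    for (f in facs) {
      lv <- sort(unique(d[[f]]))
      sign <- sign * ifelse(d[[f]] == lv[1], 1, -1)
    }
    score <- tapply(sign * d[[dv]], d[[id]], mean)
    tt <- t.test(score)
    out[[length(out) + 1L]] <- data.frame(
      effect = gsub(":", " x ", ef),
      F = unname(tt$statistic)^2,
      df1 = 1, df2 = unname(tt$parameter),
      p_value = tt$p.value)
  }
  do.call(rbind, out)
}

# Small agent cohort used by several tests.
sim_cohort <- function(n_subjects, params = agent_params(),
                       config = task_config(), seed0 = 5000) {
  lapply(seq_len(n_subjects), function(j)
    simulate_agent(params, config, seed = seed0 + j))
}

cohort_table <- function(datasets) {
  dplyr::bind_rows(lapply(seq_along(datasets), function(j) {
    d <- datasets[[j]]
    d$subject <- j
    d
  }))
}
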