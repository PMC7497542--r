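test_that("stage-2 TD update follows the delta rule", {
  st <- agent_state()
  up <- stage2_update(st, 1, 1, r = 1, alpha = 0.21)
  expect_equal(up$rpe, 1)
  expect_equal(up$state$q2[1, 1], 0.21)

  up0 <- stage2_update(st, 1, 1, r = 1, alpha = 0)
  expect_equal(up0$state$q2, st$q2)
  expect_equal(up0$rpe, 1)

  # repeated wins drive the value to the fixed point r = 1 monotonically
  q_iter <- numeric(60)
  s <- agent_state()
  for (i in 1:60) {
    u <- stage2_update(s, 1, 1, 1, 0.21)
    s <- u$state
    q_iter[i] <- s$q2[1, 1]
  }
  expect_true(all(diff(q_iter) > 0))
  expect_equal(q_iter[60], 1 - (1 - 0.21)^60) # closed form of the recursion
  expect_lt(1 - q_iter[60], 1e-5)
})

test_that("stage-1 update uses trace-weighted pre-update stage-2 values", {
  st <- agent_state()
  st$q2[1, 1] <- 0.5
  st <- stage1_update(st, 1, 1, 1, r = 1, alpha = 0.2, lam = 0.5)
  expect_equal(st$q1[1, 1], 0.2 * 0.5 + 0.2 * 0.5 * 0.5) # 0.15

  # lam = 0: reward is ignored, only the stage-2 value propagates
  st0 <- agent_state()
  st0$q2[1, 2] <- 0.8
  a <- stage1_update(st0, 1, 1, 2, r = 1, alpha = 0.3, lam = 0)
  b <- stage1_update(st0, 1, 1, 2, r = -1, alpha = 0.3, lam = 0)
  expect_equal(a$q1, b$q1)

  # alpha = 0: no movement
  expect_equal(stage1_update(st0, 1, 1, 2, 1, 0, 1)$q1, st0$q1)
})

test_that("forgetting decays exactly the unvisited entries", {
  st <- agent_state()
  st$q1[] <- 1
  st$q2[] <- 1
  out <- apply_forgetting(st, set = 1, action = 1, picture = 2, alpha = 0.21)
  expect_equal(out$q1[1, 1], 1)            # chosen action kept
  expect_equal(out$q2[1, 2], 1)            # presented picture kept
  expect_equal(out$q1[1, 2], 0.79)
  expect_equal(out$q2[2, 1], 0.79)         # other set decays too

  expect_equal(apply_forgetting(st, 1, 1, 2, 0)$q1, st$q1)

  # closed form (1 - alpha)^T against iteration
  s <- st
  for (i in 1:25) s <- apply_forgetting(s, 1, 1, 1, 0.1)
  expect_equal(s$q2[2, 2], (1 - 0.1)^25)
})

test_that("counter inference identifies the more predictable set", {
  st <- agent_state()
  st$counters[1, , ] <- matrix(c(6, 2, 1, 5), 2, 2, byrow = TRUE)
  # d1 = (6 + 5) - (2 + 1) = 8
  st$counters[2, , ] <- matrix(c(3, 3, 3, 4), 2, 2, byrow = TRUE)
  # d2 = (3 + 4) - (3 + 3) = 1
  b <- infer_transition_beliefs(st)
  expect_equal(b$predictable_set, 1)
  expect_equal(b$p[1, 1, ], c(0.75, 0.25)) # oriented toward p_A | a_A
  expect_equal(b$p[1, 2, ], c(0.25, 0.75))
  expect_equal(b$p[2, 1, ], c(0.5, 0.5))

  # all-zero start: |d| tie, both sets at chance
  b0 <- infer_transition_beliefs(agent_state())
  expect_true(is.na(b0$predictable_set))
  expect_true(all(b0$p == 0.5))

  # sign flip swaps the 0.75/0.25 orientation
  st$counters[1, , ] <- matrix(c(2, 6, 5, 1), 2, 2, byrow = TRUE) # d = -8
  bf <- infer_transition_beliefs(st)
  expect_equal(bf$p[1, 1, ], c(0.25, 0.75))

  # rows always sum to 1
  expect_true(all(abs(apply(bf$p, c(1, 2), sum) - 1) < 1e-12))
})

test_that("counter inference is permutation-equivariant", {
  set.seed(41)
  for (rep in 1:20) {
    st <- agent_state()
    st$counters[] <- sample(0:9, 8, replace = TRUE)
    b <- infer_transition_beliefs(st)
    # consistently relabel actions and pictures of both sets
    st2 <- st
    st2$counters <- st$counters[, 2:1, 2:1, drop = FALSE]
    dim(st2$counters) <- c(2, 2, 2)
    b2 <- infer_transition_beliefs(st2)
    expect_equal(b2$p, b$p[, 2:1, 2:1, drop = FALSE], ignore_attr = TRUE)
    expect_equal(b2$predictable_set, b$predictable_set)
  }
})

test_that("net action values mix Bellman and model-free values", {
  st <- agent_state()
  st$q2[1, ] <- c(1, 0)
  b <- infer_transition_beliefs(st)
  b$p[1, 1, ] <- c(0.75, 0.25)
  expect_equal(net_action_values(st, b, 1, omega = 1)[1], 0.75)

  st$q1[1, ] <- c(0.4, -0.2)
  expect_equal(net_action_values(st, b, 1, omega = 0), c(0.4, -0.2))

  # with chance beliefs and omega = 1 both actions are equivalued
  b$p[1, , ] <- 0.5
  qn <- net_action_values(st, b, 1, omega = 1)
  expect_equal(qn[1], qn[2])
})

test_that("softmax choice is normalised, shift-invariant and perseverative", {
  expect_equal(choice_probabilities(c(3, -1), NA, beta = 0, rho = 0),
               c(0.5, 0.5))
  p <- choice_probabilities(c(1, 0), NA, beta = 1, rho = 0)
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1))

  set.seed(42)
  for (i in 1:20) {
    q <- rnorm(2)
    c0 <- runif(1, -5, 5)
    p1 <- choice_probabilities(q, 1, beta = 2, rho = 0.5)
    p2 <- choice_probabilities(q + c0, 1, beta = 2, rho = 0.5)
    expect_equal(sum(p1), 1)
    expect_equal(p1, p2)
  }

  # strong perseveration pins the previous action
  expect_gt(choice_probabilities(c(0, 0), 2, beta = 1, rho = 50)[2], 1 - 1e-10)
  expect_error(choice_probabilities(c(NaN, 0), NA, 1, 0), "non-finite")
})

test_that("simulation is reproducible and respects the task design", {
  p <- agent_params()
  t1 <- simulate_agent(p, seed = 3)
  t2 <- simulate_agent(p, seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 400)
  counts <- table(t1$condition, t1$block)
  expect_true(all(counts == 50))
  expect_true(all(t1$payoff %in% c(-3, 3)))
  expect_true(all((t1$transition == "undefined") ==
                    (t1$condition == "random")))
  expect_equal(t1$expectancy,
               label_expectancy(t1$stage2, t1$valence))
  # wins give positive RPEs whenever the current value is below +1
  expect_true(all(t1$rpe[t1$valence == "win"] > 0))
  expect_true(all(t1$abs_rpe >= 0 & t1$abs_rpe <= 2))
})

test_that("a zero-temperature agent stays at chance", {
  tr <- simulate_agent(agent_params(beta = 0, rho = 0), seed = 8)
  st <- build_stay_table(tr)
  stay <- tapply(st$stay, st$condition, mean)
  expect_true(all(abs(stay - 0.5) < 0.12))
  expect_true(all(tr$p_choice == 0.5))
})

test_that("a model-based agent shows the common/rare x reward signature", {
  # omega = 1, fast learning: stay after common-win should exceed stay after
  # rare-win (transition-sensitive crediting)
  p <- agent_params(alpha = 0.6, lam = 0.9, beta = 4, omega = 1, rho = 0)
  set.seed(77)
  stays <- replicate(12, {
    tr <- simulate_agent(p)
    tr <- tr[tr$condition == "predictable", ]
    prev <- tr[-nrow(tr), ]
    cur <- tr[-1, ]
    same_block <- prev$block == cur$block
    stay <- (cur$action == prev$action)[same_block]
    pw <- (prev$valence == "win")[same_block]
    pc <- (prev$transition == "common")[same_block]
    c(cw = mean(stay[pw & pc]), rw = mean(stay[pw & !pc]))
  })
  expect_gt(mean(stays["cw", ] - stays["rw", ]), 0)
  expect_gt(mean(stays["cw", ] > stays["rw", ]), 0.5)
})

test_that("the C++ recursion equals the composition of the R primitives", {
  p <- agent_params(alpha = 0.3, lam = 0.7, beta = 2.5, omega = 0.5,
                    rho = -0.4)
  tr <- simulate_agent(p, task_config(n_blocks = 2), seed = 21)
  ref <- r_reference_replay(p, tr)
  expect_lt(max(abs(ref$p_choice - tr$p_choice)), 1e-10)
  expect_lt(max(abs(ref$rpe - tr$rpe)), 1e-10)
})

test_that("with omega = 0 and lambda = 1 the model is one-step TD", {
  p <- agent_params(alpha = 0.35, lam = 1, beta = 3, omega = 0, rho = 0.5)
  tr <- simulate_agent(p, task_config(n_blocks = 1), seed = 31)
  oracle <- minimal_td_probs(0.35, 3, 0.5, tr)
  expect_lt(max(abs(oracle - tr$p_choice)), 1e-10)
})
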