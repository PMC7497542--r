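## Parameter transforms: bounded model parameters are fitted on an
## unconstrained scale -- logit for [0,1] (alpha, lam, omega), log for beta,
## identity for rho. Group-level (hierarchical) distributions are Gaussian on
## this transformed scale.

theta_to_params <- function(theta) {
  agent_params(alpha = stats::plogis(theta[1]), lam = stats::plogis(theta[2]),
               beta = exp(theta[3]), omega = stats::plogis(theta[4]),
               rho = theta[5])
}

params_to_theta <- function(params) {
  c(stats::qlogis(params$alpha), stats::qlogis(params$lam),
    log(params$beta), stats::qlogis(params$omega), params$rho)
}

param_names <- c("alpha", "lam", "beta", "omega", "rho")

#' Negative log-likelihood of observed stage-1 choices
#'
#' Replays the deterministic state recursion of the hybrid agent (value
#' updates, forgetting, transition counters, internal-model beliefs) over the
#' observed choices and outcomes in presentation order and sums the negative
#' log probability of every observed stage-1 action under the softmax choice
#' rule. Stage 2 involves no choice and contributes no likelihood term.
#' Choice probabilities are clamped at 1e-12 before the log to guard
#' underflow. The replay shares its implementation with [simulate_agent()],
#' so the likelihood is exactly the probability model of the simulator.
#'
#' @param params An [agent_params()] (or per-set list, see
#'   [simulate_agent()]).
#' @param trials A trial table as produced by [simulate_agent()] (columns
#'   `block`, `set`, `action`, `pic`, `reward_unit` in presentation order).
#' @return Scalar negative log-likelihood (>= 0).
#' @export
negative_log_likelihood <- function(params, trials) {
  -sum(replay_agent(params, trials)$logp)
}

#' Derive trial-wise reward prediction errors from fitted parameters
#'
#' Feeds a parameter vector back through the same state recursion used for
#' fitting and emits the stage-2 prediction error `r(t) - q2(p_x, t)` of
#' every trial (unit reward coding).
#'
#' @inheritParams negative_log_likelihood
#' @return A tibble with columns `trial`, `rpe`, `abs_rpe`.
#' @export
derive_rpes <- function(params, trials) {
  r <- replay_agent(params, trials)
  tibble::tibble(trial = seq_along(r$rpe), rpe = r$rpe, abs_rpe = abs(r$rpe))
}

#' Fit the hybrid model to one subject by penalised maximum likelihood
#'
#' Maximum-likelihood (`method = "mle"`) or maximum-a-posteriori
#' (`method = "map"`, Normal(0, 1.5) prior on every transformed parameter)
#' point estimation, best of `n_restarts` BFGS runs from random start values.
#' Bounds are enforced by the transforms.
#'
#' @inheritParams negative_log_likelihood
#' @param method `"map"` (default) or `"mle"`.
#' @param n_restarts Number of optimisation restarts. Default 3.
#' @param seed Optional integer seed controlling the start values.
#' @return A list of class `fit_result` with elements `params`
#'   (point-estimate [agent_params()]), `theta` (transformed scale), `nll`
#'   (negative log-likelihood at the estimate), `method` and `convergence`.
#' @export
fit_subject <- function(trials, method = c("map", "mle"), n_restarts = 3,
                        seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  obj <- function(theta) {
    nll <- negative_log_likelihood(theta_to_params(theta), trials)
    if (method == "map")
      nll <- nll - sum(stats::dnorm(theta, 0, 1.5, log = TRUE))
    nll
  }
  starts <- lapply(seq_len(n_restarts), function(i)
    stats::rnorm(5, 0, c(1, 1, 0.5, 1, 1)))
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, obj, method = "BFGS",
                          control = list(maxit = 500)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimiser failed on all restarts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- best$par
  structure(list(params = theta_to_params(theta), theta = theta,
                 nll = negative_log_likelihood(theta_to_params(theta),
                                               trials),
                 method = method, convergence = best$convergence),
            class = "fit_result")
}

## ---- hierarchical MCMC --------------------------------------------------

# Per-unit log-likelihood closure. A unit is a subject (set_filter = NULL,
# one shared parameter vector) or a subject x set combination (set_filter in
# {1, 2}); the set factorisation is exact because the counter/belief
# recursion depends only on the data, never on the parameters.
unit_loglik <- function(trials, set_filter = NULL) {
  keep <- if (is.null(set_filter)) rep(TRUE, nrow(trials))
          else trials$set == set_filter
  force(keep)
  function(theta) {
    p <- theta_to_params(theta)
    sum(replay_agent(p, trials)$logp[keep])
  }
}

#' Hierarchical Bayesian fit of the hybrid model by MCMC
#'
#' Fits subject-level (or subject-by-set-level) parameters under a
#' per-parameter Gaussian group distribution on the transformed scale, with
#' weakly-informative Normal(0, 1.5) hyperpriors on the group means and
#' half-Normal(0, 1.5) hyperpriors on the group scales. Sampling is
#' Metropolis-within-Gibbs: per-parameter Gaussian random-walk updates for
#' the unit-level parameters (proposal scales adapted towards 44% acceptance
#' during warm-up, then frozen), conjugate Gibbs draws for the group means
#' and log-scale random-walk updates for the group standard deviations.
#'
#' @param datasets A list of per-subject trial tables (>= 2 subjects).
#' @param chains Number of chains. Default 4.
#' @param iterations Total iterations per chain. Default 2000.
#' @param warmup Warm-up (adaptation) iterations discarded from the draws.
#'   Default 1000.
#' @param units `"subject"` (one parameter vector per subject) or
#'   `"subject_set"` (one per subject x set, all drawn from the same group
#'   distribution per parameter).
#' @param seed Integer seed.
#' @return A list of class `hier_fit` with `draws` (post-warmup array
#'   iterations x chains x parameters, transformed scale), `rhat` (split-Rhat
#'   per parameter), `ess` (crude effective sample size), `summary` (a tibble
#'   of posterior-mean point estimates per unit on the natural scale) and
#'   `hyper` (posterior means of group-level location/scale).
#' @export
fit_hierarchical <- function(datasets, chains = 4, iterations = 2000,
                             warmup = 1000, units = c("subject",
                                                      "subject_set"),
                             seed = 1) {
  units <- match.arg(units)
  stopifnot(length(datasets) >= 2, warmup < iterations)
  set.seed(seed)

  if (units == "subject") {
    lls <- lapply(datasets, unit_loglik)
    unit_ids <- sprintf("s%02d", seq_along(datasets))
  } else {
    lls <- list()
    unit_ids <- character(0)
    for (j in seq_along(datasets)) for (s in 1:2) {
      lls[[length(lls) + 1L]] <- unit_loglik(datasets[[j]], s)
      unit_ids <- c(unit_ids, sprintf("s%02d_set%d", j, s))
    }
  }
  J <- length(lls)
  n_post <- iterations - warmup
  p_names <- c(as.vector(outer(param_names, unit_ids,
                               function(p, u) paste(u, p, sep = "."))),
               paste0("mu.", param_names), paste0("sigma.", param_names))
  draws <- array(NA_real_, c(n_post, chains, length(p_names)),
                 dimnames = list(NULL, NULL, p_names))

  for (ch in seq_len(chains)) {
    theta <- matrix(stats::rnorm(J * 5, 0, 0.5), J, 5)
    mu <- stats::rnorm(5, 0, 0.5)
    sigma <- rep(1, 5)
    cur_ll <- vapply(seq_len(J), function(j) lls[[j]](theta[j, ]),
                     numeric(1))
    scale_theta <- matrix(0.5, J, 5)
    scale_lsig <- rep(0.3, 5)
    scale_nc <- rep(0.2, 5)
    acc_theta <- matrix(0, J, 5)
    acc_lsig <- rep(0, 5)
    acc_nc <- rep(0, 5)
    n_adapt <- 0L

    for (it in seq_len(iterations)) {
      # unit-level parameters, one coordinate at a time
      for (j in seq_len(J)) {
        for (p in 1:5) {
          prop <- theta[j, ]
          prop[p] <- prop[p] + scale_theta[j, p] * stats::rnorm(1)
          ll_new <- lls[[j]](prop)
          lr <- ll_new - cur_ll[j] +
            stats::dnorm(prop[p], mu[p], sigma[p], log = TRUE) -
            stats::dnorm(theta[j, p], mu[p], sigma[p], log = TRUE)
          if (log(stats::runif(1)) < lr) {
            theta[j, ] <- prop
            cur_ll[j] <- ll_new
            acc_theta[j, p] <- acc_theta[j, p] + 1
          }
        }
      }
      # group means: conjugate normal draw (prior N(0, 1.5^2))
      for (p in 1:5) {
        v <- 1 / (J / sigma[p]^2 + 1 / 1.5^2)
        m <- v * sum(theta[, p]) / sigma[p]^2
        mu[p] <- stats::rnorm(1, m, sqrt(v))
      }
      # group scales: random walk on log(sigma), half-Normal(0, 1.5) prior
      for (p in 1:5) {
        lsig_new <- log(sigma[p]) + scale_lsig[p] * stats::rnorm(1)
        s_new <- exp(lsig_new)
        lr <- sum(stats::dnorm(theta[, p], mu[p], s_new, log = TRUE)) -
          sum(stats::dnorm(theta[, p], mu[p], sigma[p], log = TRUE)) +
          stats::dnorm(s_new, 0, 1.5, log = TRUE) -
          stats::dnorm(sigma[p], 0, 1.5, log = TRUE) +
          lsig_new - log(sigma[p]) # Jacobian of the log transform
        if (log(stats::runif(1)) < lr) {
          sigma[p] <- s_new
          acc_lsig[p] <- acc_lsig[p] + 1
        }
      }
      # interleaved non-centered step (ASIS): holding the standardized unit
      # effects eta = (theta - mu) / sigma fixed, jointly move (mu, sigma);
      # this breaks the location/scale funnel the centered updates mix
      # poorly in
      for (p in 1:5) {
        eta <- (theta[, p] - mu[p]) / sigma[p]
        mu_new <- mu[p] + scale_nc[p] * stats::rnorm(1)
        lsig_new <- log(sigma[p]) + scale_nc[p] * stats::rnorm(1)
        s_new <- exp(lsig_new)
        th_new <- theta
        th_new[, p] <- mu_new + s_new * eta
        ll_new <- vapply(seq_len(J), function(j) lls[[j]](th_new[j, ]),
                         numeric(1))
        lr <- sum(ll_new) - sum(cur_ll) +
          stats::dnorm(mu_new, 0, 1.5, log = TRUE) -
          stats::dnorm(mu[p], 0, 1.5, log = TRUE) +
          stats::dnorm(s_new, 0, 1.5, log = TRUE) -
          stats::dnorm(sigma[p], 0, 1.5, log = TRUE) +
          lsig_new - log(sigma[p])
        if (log(stats::runif(1)) < lr) {
          theta <- th_new
          cur_ll <- ll_new
          mu[p] <- mu_new
          sigma[p] <- s_new
          acc_nc[p] <- acc_nc[p] + 1
        }
      }
      # proposal-scale adaptation, warm-up only
      n_adapt <- n_adapt + 1L
      if (it <= warmup && n_adapt == 50L) {
        scale_theta <- scale_theta * exp((acc_theta / 50 - 0.44))
        scale_lsig <- scale_lsig * exp((acc_lsig / 50 - 0.44))
        scale_nc <- scale_nc * exp((acc_nc / 50 - 0.25))
        acc_theta[] <- 0
        acc_lsig[] <- 0
        acc_nc[] <- 0
        n_adapt <- 0L
      } else if (n_adapt >= 50L) n_adapt <- 0L
      if (it > warmup)
        draws[it - warmup, ch, ] <- c(t(theta), mu, sigma)
    }
  }

  rhat <- apply(draws, 3, function(x) split_rhat(x))
  ess <- apply(draws, 3, function(x) ess_basic(x))

  # posterior-mean point estimates on the natural scale
  unit_par <- lapply(seq_len(J), function(j) {
    idx <- (j - 1L) * 5L + (1:5)
    th <- apply(draws[, , idx, drop = FALSE], 3, mean)
    theta_to_params(th)
  })
  summary <- tibble::tibble(
    unit = unit_ids,
    alpha = vapply(unit_par, `[[`, numeric(1), "alpha"),
    lam = vapply(unit_par, `[[`, numeric(1), "lam"),
    beta = vapply(unit_par, `[[`, numeric(1), "beta"),
    omega = vapply(unit_par, `[[`, numeric(1), "omega"),
    rho = vapply(unit_par, `[[`, numeric(1), "rho"))
  hyper <- tibble::tibble(
    param = param_names,
    mu = apply(draws[, , paste0("mu.", param_names), drop = FALSE], 3, mean),
    sigma = apply(draws[, , paste0("sigma.", param_names), drop = FALSE], 3,
                  mean))

  structure(list(draws = draws, rhat = rhat, ess = ess, summary = summary,
                 hyper = hyper, units = units, unit_ids = unit_ids),
            class = "hier_fit")
}

#' Split-Rhat convergence diagnostic
#'
#' Potential-scale-reduction statistic computed after splitting every chain
#' in half, so within-chain trends register as apparent non-convergence.
#' Values near 1 indicate mixing; the conventional acceptance bound is 1.1.
#'
#' @param x Matrix of posterior draws, iterations x chains.
#' @return Scalar split-Rhat (>= 1 up to floating point; `NA` for constant
#'   draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Crude effective sample size: pooled draws divided by the integrated
# autocorrelation time estimated per chain (initial positive sequence).
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  tau <- mean(apply(x, 2, function(v) {
    if (stats::var(v) == 0) return(1)
    ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    k <- if (length(pos)) pos[1] - 1L else length(ac)
    1 + 2 * sum(ac[seq_len(k)])
  }))
  n * ncol(x) / max(tau, 1)
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 * sum_i [ log mean_s exp(ll_si) - var_s(ll_si) ]` over trials
#' `i` and posterior draws `s` (pointwise variance penalty, pWAIC2). Lower
#' values indicate better estimated out-of-sample predictive fit.
#'
#' @param loglik_draws Matrix of pointwise log-likelihoods, draws x trials.
#' @return List with `waic`, `se` (standard error over trials), `lppd` and
#'   `p_waic`.
#' @export
waic <- function(loglik_draws) {
  ll <- as.matrix(loglik_draws)
  if (nrow(ll) < 2)
    stop("WAIC needs at least two posterior draws (variance penalty)")
  lppd_i <- apply(ll, 2, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  })
  p_i <- apply(ll, 2, stats::var)
  elpd_i <- lppd_i - p_i
  list(waic = -2 * sum(elpd_i),
       se = 2 * sqrt(ncol(ll) * stats::var(elpd_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i))
}

#' Pointwise log-likelihood draws for WAIC
#'
#' Replays thinned posterior draws of a hierarchical fit through the
#' likelihood and returns the per-trial log-likelihood matrix pooled over
#' subjects (stage-1 choices only).
#'
#' @param fit A `hier_fit` from [fit_hierarchical()].
#' @param datasets The per-subject trial tables the fit was run on.
#' @param thin Keep every `thin`-th draw per chain. Default 10.
#' @return Matrix draws x trials.
#' @export
loglik_draws <- function(fit, datasets, thin = 10) {
  stopifnot(fit$units == "subject")
  keep <- seq(1, dim(fit$draws)[1], by = thin)
  out <- NULL
  for (ch in seq_len(dim(fit$draws)[2])) {
    for (i in keep) {
      row <- unlist(lapply(seq_along(datasets), function(j) {
        idx <- (j - 1L) * 5L + (1:5)
        replay_agent(theta_to_params(fit$draws[i, ch, idx]),
                     datasets[[j]])$logp
      }))
      out <- rbind(out, row)
    }
  }
  unname(out)
}
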