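# build a bare epoch_set around a trials x channels x samples array
make_epochs <- function(data, srate = 512, t0 = -1,
                        channels = c("FCz", "Pz")) {
  n <- dim(data)[3]
  structure(list(data = data, srate = srate,
                 times = t0 + (seq_len(n) - 1) / srate,
                 channels = channels,
                 trial_meta = tibble::tibble(trial = seq_len(dim(data)[1]))),
            class = "epoch_set")
}

gauss_bump <- function(times, center, width, amp) {
  amp * exp(-(times - center)^2 / (2 * width^2))
}

test_that("artifact rejection removes only epochs beyond the threshold", {
  times_n <- 1280
  data <- array(stats::rnorm(20 * 2 * times_n, sd = 5), c(20, 2, times_n))
  ep <- make_epochs(data)
  clean <- reject_artifacts(ep, threshold = 300)
  expect_equal(dim(clean$data)[1], 20)

  ep$data[7, 2, 100:160] <- 400
  dirty <- reject_artifacts(ep, threshold = 300)
  expect_equal(dim(dirty$data)[1], 19)
  expect_equal(attr(dirty, "n_rejected"), 1)

  # a huge threshold keeps everything; exempt channels are ignored
  expect_equal(dim(reject_artifacts(ep, threshold = 1e9)$data)[1], 20)
  expect_equal(dim(reject_artifacts(ep, threshold = 300,
                                    exempt = "Pz")$data)[1], 20)
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  data <- array(7, c(3, 2, 1280))
  ep <- make_epochs(data)
  b1 <- baseline_correct(ep)
  sel <- b1$times >= -0.2 & b1$times <= 0
  expect_lt(max(abs(b1$data[, , sel])), 1e-12)
  expect_equal(b1$data[1, 1, 1], -7 + 7) # constant offset removed entirely
  expect_true(all(abs(b1$data) < 1e-12))
  b2 <- baseline_correct(b1)
  expect_equal(b1$data, b2$data)
})

test_that("FRN peak-to-peak matches hand-computed constructed waveforms", {
  srate <- 512
  times <- seq(-1, 1.498, by = 1 / srate)
  x <- gauss_bump(times, 0.180, 0.018, 5) +
    gauss_bump(times, 0.260, 0.018, -3) +
    gauss_bump(times, 0.380, 0.018, 4)
  r <- frn_peak_to_peak(x, times)
  expect_equal(r$p2p, -3 - (5 + 4) / 2, tolerance = 0.05)
  expect_equal(r$t_frn, 0.260, tolerance = 0.005)
  expect_equal(r$t_pre, 0.180, tolerance = 0.005)
  expect_equal(r$t_post, 0.380, tolerance = 0.005) # found via widening
  expect_false(r$fallback)

  # flat waveform: fallback flagged, zero amplitude
  r0 <- frn_peak_to_peak(rep(0, length(times)), times)
  expect_equal(r0$p2p, 0)
  expect_true(r0$fallback)

  # monotone ramp: no local minimum, widening runs to the 300 ms cap
  rr <- frn_peak_to_peak(times, times)
  expect_true(rr$fallback)
  expect_equal(rr$t_post - rr$t_frn, 0.3, tolerance = 0.005)

  # translation invariance
  rshift <- frn_peak_to_peak(x + 11.3, times)
  expect_equal(rshift$p2p, r$p2p)
})

test_that("P3 mean amplitude is the 300-500 ms window mean and is linear", {
  times <- seq(-1, 1.498, by = 1 / 512)
  expect_equal(p3_mean_amplitude(rep(2, length(times)), times), 2)
  a <- gauss_bump(times, 0.4, 0.06, 3)
  b <- gauss_bump(times, 0.45, 0.1, -1)
  expect_equal(p3_mean_amplitude(a + b, times),
               p3_mean_amplitude(a, times) + p3_mean_amplitude(b, times))
  # closed-form Gaussian window mean vs the numeric result
  w <- 0.06
  expected <- 3 * w * sqrt(2 * pi) *
    (stats::pnorm(0.1 / w) - stats::pnorm(-0.1 / w)) / 0.2
  expect_equal(p3_mean_amplitude(a, times), expected, tolerance = 5e-3)
})

test_that("Morlet power peaks at the stimulus frequency with a 50-step grid", {
  fr <- morlet_freqs()
  expect_length(fr, 50)
  expect_equal(fr[1], 1)
  expect_equal(fr[50], 50)
  expect_true(all(diff(fr) > 0))

  times <- seq(-1, 1.498, by = 1 / 512)
  sine <- sin(2 * pi * 6 * times)
  dat <- array(0, c(1, 2, length(times)))
  dat[1, 1, ] <- sine
  dat[1, 2, ] <- sine
  ep <- make_epochs(dat)
  tf <- morlet_power(ep, "FCz", baseline_window = NULL)
  mid <- which(abs(tf$times) < 0.4)
  prof <- apply(tf$power[1, , mid, drop = FALSE], 2, mean)
  expect_equal(which.max(prof), which.min(abs(fr - 6)))
  expect_true(all(tf$power >= 0)) # raw power is non-negative
})

test_that("stationary noise is flat in dB relative to its own baseline", {
  set.seed(9)
  times_n <- 1280
  data <- array(stats::rnorm(60 * 2 * times_n), c(60, 2, times_n))
  ep <- make_epochs(data)
  tf <- morlet_power(ep, "FCz", freqs = morlet_freqs()[10:30])
  # trial-averaged power expressed in dB stays near 0 throughout the epoch
  # (single-trial log power carries the usual negative Jensen offset, which
  # is identical in the baseline and therefore cancels on the power scale)
  lin <- 10^(tf$power / 10)
  profile <- 10 * log10(apply(lin, 3, mean))
  inb <- ep$times > -0.5 & ep$times < 1
  expect_lt(max(abs(profile[inb])), 1)
  expect_lt(abs(mean(profile[inb])), 0.4)
  # doubling the signal cancels in dB (baseline scales identically)
  ep2 <- ep
  ep2$data <- ep$data * 2
  tf2 <- morlet_power(ep2, "FCz", freqs = morlet_freqs()[10:30])
  expect_equal(tf2$power, tf$power, tolerance = 1e-8)
})

test_that("band/window averaging selects exactly the requested bins", {
  fr <- morlet_freqs()
  tfr <- structure(list(power = array(3, c(5, 50, 100)), freqs = fr,
                        times = seq(0, 0.99, by = 0.01), channel = "FCz",
                        units = "dB"), class = "tfr")
  expect_equal(band_window_average(tfr, c(4, 8), c(0.2, 0.4)), rep(3, 5))
  # mark the theta bins only and verify the selection boundary
  tfr$power[, fr < 4 | fr > 8, ] <- -99
  expect_equal(band_window_average(tfr, c(4, 8), c(0.2, 0.4)), rep(3, 5))
  expect_error(band_window_average(tfr, c(60, 70), c(0.2, 0.4)), "empty")
})

test_that("a 6 Hz burst raises theta but not delta band power", {
  s_trials <- simulate_agent(agent_params(), task_config(n_blocks = 1),
                             seed = 44)
  rp <- derive_rpes(agent_params(), s_trials)
  base <- eeg_gen_config()$components
  cfg_off <- eeg_gen_config(noise_amp = 6, components = base["p3"])
  cfg_on <- eeg_gen_config(noise_amp = 6,
                           components = base[c("p3", "theta")])
  set.seed(10)
  ep_off <- generate_epochs(s_trials, rp, cfg_off)
  set.seed(10)
  ep_on <- generate_epochs(s_trials, rp, cfg_on)
  f_off <- trial_features(ep_off, c("theta", "delta"))
  f_on <- trial_features(ep_on, c("theta", "delta"))
  d_theta <- mean(f_on$theta_db - f_off$theta_db)
  d_delta <- mean(f_on$delta_db - f_off$delta_db)
  expect_gt(d_theta, 1)
  expect_lt(abs(d_delta), d_theta / 5)
})

test_that("trial features preserve metadata and row counts", {
  s_trials <- simulate_agent(agent_params(), task_config(n_blocks = 1),
                             seed = 45)
  rp <- derive_rpes(agent_params(), s_trials)
  ep <- baseline_correct(generate_epochs(s_trials, rp))
  ft <- trial_features(ep, measures = c("frn", "p3"))
  expect_equal(nrow(ft), dim(ep$data)[1])
  expect_identical(ft$condition, s_trials$condition)
  expect_identical(ft$valence, s_trials$valence)
  expect_identical(ft$expectancy, s_trials$expectancy)
  expect_identical(ft$rpe, rp$rpe)
  # measurement path is deterministic: bit-identical on re-run
  ft2 <- trial_features(ep, measures = c("frn", "p3"))
  expect_identical(ft$frn_p2p, ft2$frn_p2p)
})

test_that("the within-subject ANOVA matches a brute-force contrast oracle", {
  # hand-checkable integer dataset, 4 subjects x 8 cells
  set.seed(12)
  cells <- expand.grid(subject = 1:4, condition = c("p", "r"),
                       expectancy = c("e", "u"), valence = c("w", "l"),
                       stringsAsFactors = FALSE)
  cells$y <- c(2, 3, 1, 4)[cells$subject] +
    2 * (cells$condition == "p") * (cells$expectancy == "u") +
    (cells$valence == "w") + sample(0:2, nrow(cells), replace = TRUE)
  got <- rm_anova(cells, dv = "y", id = "subject",
                  within = c("condition", "expectancy", "valence"))
  want <- anova_by_contrasts(cells, dv = "y", id = "subject",
                             within = c("condition", "expectancy",
                                        "valence"))
  for (i in seq_len(nrow(want))) {
    row <- got[got$effect == want$effect[i], ]
    expect_equal(row$F, want$F[i], tolerance = 1e-8)
    expect_equal(row$p_value, want$p_value[i], tolerance = 1e-8)
    expect_equal(row$df2, want$df2[i])
  }

  # identical cell patterns for every subject: all effects give F ~ 0 ...
  flat <- cells
  flat$y <- 5 + 0.001 * stats::rnorm(nrow(flat))
  gflat <- rm_anova(flat, dv = "y", id = "subject",
                    within = c("condition", "expectancy", "valence"))
  expect_true(all(gflat$p_value > 0.01))
})

test_that("cell_anova drops subjects with missing cells, with a warning", {
  set.seed(13)
  feats <- tibble::tibble(
    subject = rep(1:3, each = 16),
    condition = rep(rep(c("predictable", "random"), each = 8), 3),
    expectancy = rep(rep(c("expected", "unexpected"), each = 4), 6),
    valence = rep(rep(c("win", "loss"), each = 2), 12),
    p3_mean = stats::rnorm(48))
  full <- cell_anova(feats, "p3_mean")
  expect_equal(nrow(full), 7) # 3 mains + 3 two-way + 1 three-way
  crippled <- feats[!(feats$subject == 3 & feats$condition == "random"), ]
  expect_warning(cell_anova(crippled, "p3_mean"), "missing cells")
})
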