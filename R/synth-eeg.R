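#' Configuration of the synthetic feedback-locked EEG generator
#'
#' Defines ground-truth components embedded in every synthetic epoch on top
#' of 1/f background noise. ERP components (FRN, P3) are Gaussian-windowed
#' deflections; oscillatory components (theta, delta) are amplitude-modulated
#' sinusoids with per-trial random phase (a configurable fraction is
#' phase-locked), so evoked and induced measures can dissociate. Each
#' component's per-trial amplitude follows a linear model in outcome valence,
#' expectancy, condition and the trial's absolute reward prediction error:
#'
#' `amp = base + loss_effect * I(loss) + expectancy_effect[condition] *
#' I(unexpected) + coupling[condition] * |rpe|`
#'
#' The defaults encode the dissociation this pipeline is built to detect:
#' FRN and theta carry expectancy/|RPE| signal in *both* conditions
#' (condition-blind unsigned-RPE correlates), while P3 and delta carry
#' expectancy and |RPE| signal in the predictable condition only. Amplitudes
#' are in measurement units: the P3 template is calibrated so its 300-500 ms
#' window mean equals the nominal amplitude, and the FRN template has unit
#' (negative) peak.
#'
#' @param noise_amp RMS of the 1/f background noise per channel, in µV.
#'   Default 10.
#' @param srate Sampling rate in Hz. Default 512.
#' @param window Epoch span in seconds around feedback onset.
#'   Default c(-1, 1.5).
#' @param channels Channel labels. Default FCz, Pz.
#' @param phase_locking Fraction of trials whose oscillatory components are
#'   phase-locked (zero phase). Default 0.2.
#' @param components Named list of component definitions; see the function
#'   body for the default structure (`kind`, `latency`, `width`, `freq`,
#'   `weights`, `base`, `loss_effect`, `expectancy_effect`, `coupling`).
#' @return A list of class `eeg_gen_config`.
#' @export
eeg_gen_config <- function(noise_amp = 10, srate = 512,
                           window = c(-1, 1.5),
                           channels = c("FCz", "Pz"),
                           phase_locking = 0.2,
                           components = NULL) {
  if (noise_amp < 0) stop("noise_amp must be >= 0")
  if (is.null(components)) components <- list(
    frn = list(kind = "erp", latency = 0.270, width = 0.035,
               weights = c(FCz = 1, Pz = 0.2),
               base = -2, loss_effect = -1.5,
               expectancy_effect = c(predictable = -1.5, random = -1.5),
               coupling = c(predictable = -2, random = -2)),
    p3 = list(kind = "erp", latency = 0.400, width = 0.060,
              weights = c(FCz = 0.3, Pz = 1),
              base = 6, loss_effect = 0,
              expectancy_effect = c(predictable = 3, random = 0),
              coupling = c(predictable = 2, random = 0)),
    theta = list(kind = "burst", freq = 6, latency = 0.300, width = 0.080,
                 weights = c(FCz = 1, Pz = 0.2),
                 base = 3, loss_effect = 0.5,
                 expectancy_effect = c(predictable = 1.5, random = 1.5),
                 coupling = c(predictable = 2, random = 2)),
    delta = list(kind = "burst", freq = 2.5, latency = 0.400, width = 0.100,
                 weights = c(FCz = 0.3, Pz = 1),
                 base = 3, loss_effect = -1,
                 expectancy_effect = c(predictable = 1.5, random = 0),
                 coupling = c(predictable = 1, random = 0)))
  for (cm in components) if (cm$width <= 0) stop("component widths must be > 0")
  structure(list(noise_amp = noise_amp, srate = srate, window = window,
                 channels = channels, phase_locking = phase_locking,
                 components = components),
            class = "eeg_gen_config")
}

epoch_times <- function(cfg) {
  n <- round(cfg$srate * diff(cfg$window))
  cfg$window[1] + (seq_len(n) - 1L) / cfg$srate
}

# 1/f background noise, samples x trials (periodogram slope -1.0 over the
# in-band range), generated by a calibrated first-order filter cascade in
# C++; per-sample RMS equals `amp`.
pink_noise <- function(n, trials, srate, amp) {
  cpp_pink_noise(n, trials, amp)
}

#' Generate synthetic feedback-locked EEG epochs
#'
#' Builds one multichannel epoch per trial: 1/f noise plus the configured
#' component waveforms, whose per-trial amplitudes follow the linear
#' ground-truth model of [eeg_gen_config()] evaluated on the trial's
#' condition, valence, expectancy and |RPE|. The injected amplitudes are
#' returned as a ground-truth ledger for recovery testing.
#'
#' @param trials A trial table from [simulate_agent()] (columns `condition`,
#'   `valence`, `expectancy` are used; `subject` is carried through).
#' @param rpes A tibble from [derive_rpes()] aligned with `trials` (same
#'   number of rows, presentation order).
#' @param cfg An [eeg_gen_config()].
#' @return A list of class `epoch_set`: `data` (trials x channels x samples
#'   array, µV), `srate`, `times` (s, 0 = feedback onset), `channels`,
#'   `trial_meta` (the trial table plus `rpe`, `abs_rpe`, `artifact`), and
#'   `ledger` (per-trial injected component amplitudes).
#' @export
generate_epochs <- function(trials, rpes, cfg = eeg_gen_config()) {
  if (nrow(trials) != nrow(rpes))
    stop("trials and rpes must have the same number of rows")
  times <- epoch_times(cfg)
  n <- length(times)
  nt <- nrow(trials)
  nc <- length(cfg$channels)

  unexpected <- as.numeric(trials$expectancy == "unexpected")
  loss <- as.numeric(trials$valence == "loss")
  cond <- trials$condition
  absrpe <- rpes$abs_rpe

  ledger <- tibble::tibble(trial = seq_len(nt))
  data <- array(0, c(nt, nc, n),
                dimnames = list(NULL, cfg$channels, NULL))
  for (ci in seq_len(nc))
    data[, ci, ] <- t(pink_noise(n, nt, cfg$srate, cfg$noise_amp))

  for (nm in names(cfg$components)) {
    cm <- cfg$components[[nm]]
    amp <- cm$base + cm$loss_effect * loss +
      cm$expectancy_effect[cond] * unexpected +
      cm$coupling[cond] * absrpe
    ledger[[paste0(nm, "_amp")]] <- unname(amp)
    env <- exp(-(times - cm$latency)^2 / (2 * cm$width^2))
    if (cm$kind == "erp" && nm == "p3") {
      w <- times >= 0.3 & times <= 0.5
      env <- env / mean(env[w]) # calibrate: window mean of template = 1
    }
    sup <- which(env > 1e-8) # Gaussian envelope support; zero elsewhere
    if (cm$kind == "erp") {
      sig <- outer(amp, env[sup]) # trials x support samples
    } else {
      phase <- ifelse(stats::runif(nt) < cfg$phase_locking, 0,
                      stats::runif(nt, 0, 2 * pi))
      carrier <- cos(outer(phase, 2 * pi * cm$freq * times[sup], `+`))
      sig <- (amp * carrier) * rep(env[sup], each = nt)
    }
    for (ci in seq_len(nc)) {
      w <- cm$weights[cfg$channels[ci]]
      if (is.na(w)) w <- 0
      data[, ci, sup] <- data[, ci, sup] + w * sig
    }
  }

  meta <- trials
  meta$rpe <- rpes$rpe
  meta$abs_rpe <- absrpe
  meta$artifact <- FALSE
  structure(list(data = data, srate = cfg$srate, times = times,
                 channels = cfg$channels, trial_meta = meta,
                 ledger = ledger),
            class = "epoch_set")
}

#' Inject gross artifacts into an epoch set
#'
#' Adds a large square-pulse deviation (default well beyond the ±300 µV
#' rejection criterion) to a seeded random subset of epochs on the first
#' channel, and flags those epochs in the metadata so round-trip rejection
#' can be verified.
#'
#' @param epochs An `epoch_set`.
#' @param fraction Fraction of epochs to contaminate, in \[0, 1\].
#' @param magnitude Pulse height in µV. Default 500.
#' @param seed Optional integer seed.
#' @return The modified `epoch_set` with updated `trial_meta$artifact`.
#' @export
inject_artifacts <- function(epochs, fraction, magnitude = 500,
                             seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  nt <- dim(epochs$data)[1]
  hit <- which(stats::runif(nt) < fraction)
  if (length(hit)) {
    span <- seq(floor(length(epochs$times) / 2),
                length.out = min(50L, length(epochs$times)))
    epochs$data[hit, 1, span] <- epochs$data[hit, 1, span] + magnitude
    epochs$trial_meta$artifact[hit] <- TRUE
  }
  epochs
}

# Subset an epoch_set by trial index, keeping metadata and ledger aligned.
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[idx, , drop = FALSE]
  if (!is.null(epochs$ledger))
    epochs$ledger <- epochs$ledger[idx, , drop = FALSE]
  epochs
}
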