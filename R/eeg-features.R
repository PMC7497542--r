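#' Reject epochs with gross amplitude artifacts
#'
#' Removes every epoch in which any non-exempt channel deviates more than
#' ±`threshold` µV from that epoch's channel mean. Frontal channels that are
#' typically contaminated by blinks can be exempted by name.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Rejection threshold in µV (> 0). Default 300.
#' @param exempt Character vector of channel names excluded from the check.
#' @return The cleaned `epoch_set`; the number of removed epochs is stored
#'   in attribute `n_rejected`.
#' @export
reject_artifacts <- function(epochs, threshold = 300, exempt = character()) {
  stopifnot(threshold > 0)
  use <- !(epochs$channels %in% exempt)
  dev <- apply(epochs$data[, use, , drop = FALSE], c(1, 2),
               function(x) max(abs(x - mean(x))))
  keep <- apply(dev <= threshold, 1, all)
  out <- subset_epochs(epochs, keep)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-feedback baseline
#' window (default -200..0 ms). Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @param window Baseline window in seconds. Default c(-0.2, 0).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(bl) # recycles over samples
  epochs
}

#' Zero-phase low-pass Butterworth filter
#'
#' Second-order Butterworth low-pass (default 15 Hz), applied forward and
#' backward so peak latencies are not shifted.
#'
#' @param x Numeric vector or samples-x-trials matrix.
#' @param srate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz. Default 15.
#' @return Filtered object of the same shape.
#' @export
lowpass_butter <- function(x, srate, cutoff = 15) {
  bf <- signal::butter(2, cutoff / (srate / 2), type = "low")
  xm <- as.matrix(x)
  out <- cpp_filtfilt_cols(xm, bf$b, bf$a)
  if (is.null(dim(x))) drop(out) else out
}

# earliest index of the most negative local minimum within idx; a genuine
# minimum is no greater than both neighbours and strictly less than at least
# one (so constant stretches do not count); NA if none
local_min_idx <- function(x, idx) {
  cand <- idx[idx > 1 & idx < length(x)]
  cand <- cand[x[cand] <= x[cand - 1] & x[cand] <= x[cand + 1] &
                 (x[cand] < x[cand - 1] | x[cand] < x[cand + 1])]
  if (!length(cand)) return(NA_integer_)
  cand[which.min(x[cand])]
}

#' Peak-to-peak FRN amplitude
#'
#' Quantifies the feedback-related negativity of a single (already low-pass
#' filtered) waveform: (1) find the most negative local peak within
#' 200-350 ms after feedback onset; (2) subtract the average of the
#' preceding and succeeding positive peaks, each sought as the window
#' maximum within 100 ms before/after the FRN peak. If a flank maximum lies
#' on the outer edge of its window, that window is widened outward in 10 ms
#' steps up to a total width of 300 ms. If no negative local extremum exists
#' in the search window, the window minimum is used and the result flagged.
#'
#' @param x Numeric waveform (single channel), µV.
#' @param times Time vector in seconds, 0 = feedback onset; must cover at
#'   least -100..+650 ms.
#' @param search FRN search window in seconds. Default c(0.2, 0.35).
#' @return List with `p2p` (µV; FRN peak minus mean flank amplitude),
#'   `t_pre`, `t_frn`, `t_post` (latencies in s) and `fallback` (logical).
#' @export
frn_peak_to_peak <- function(x, times, search = c(0.2, 0.35)) {
  if (times[1] > -0.1 || times[length(times)] < 0.65)
    stop("waveform must cover at least -100..+650 ms")
  win <- which(times >= search[1] & times <= search[2])
  i_frn <- local_min_idx(x, win)
  fallback <- is.na(i_frn)
  if (fallback) i_frn <- win[which.min(x[win])]
  t_frn <- times[i_frn]

  flank <- function(direction) { # -1 preceding, +1 succeeding
    width <- 0.1
    repeat {
      if (direction < 0)
        idx <- which(times >= t_frn - width & times <= t_frn)
      else
        idx <- which(times >= t_frn & times <= t_frn + width)
      i_max <- idx[which.max(x[idx])]
      outer_edge <- if (direction < 0) idx[1] else idx[length(idx)]
      if (i_max != outer_edge || width >= 0.3) return(i_max)
      width <- width + 0.01
    }
  }
  i_pre <- flank(-1)
  i_post <- flank(+1)
  list(p2p = x[i_frn] - mean(c(x[i_pre], x[i_post])),
       t_pre = times[i_pre], t_frn = t_frn, t_post = times[i_post],
       fallback = fallback)
}

#' Mean-amplitude P3
#'
#' Arithmetic mean of a waveform over 300-500 ms after feedback onset.
#'
#' @param x Numeric waveform, µV.
#' @param times Time vector in seconds.
#' @param window Averaging window in seconds. Default c(0.3, 0.5).
#' @return Mean amplitude in µV.
#' @export
p3_mean_amplitude <- function(x, times, window = c(0.3, 0.5)) {
  sel <- times >= window[1] & times <= window[2]
  mean(x[sel])
}

#' Canonical wavelet frequency grid
#'
#' 50 logarithmically spaced frequencies from 1 to 50 Hz.
#' @return Numeric vector of length 50.
#' @export
morlet_freqs <- function() 10^seq(log10(1), log10(50), length.out = 50)

#' Morlet wavelet time-frequency power
#'
#' Convolves every epoch of one channel with a family of complex Morlet
#' wavelets `exp(-i 2 pi t f) * exp(-t^2 / (2 sigma^2))` with
#' `sigma = 4 / (2 pi f)` via FFT, squares the magnitude, and converts to
#' decibels relative to the trial-averaged baseline power per frequency
#' (`10 * log10(power / baseline)`), baseline -300..-200 ms before feedback
#' onset. Samples within half a wavelet support of the epoch edges are
#' flagged (attribute `edge` per frequency), not removed.
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel name. Default `"FCz"`.
#' @param freqs Frequencies in Hz; default the canonical 50-step grid of
#'   [morlet_freqs()].
#' @param baseline_window Baseline window in seconds. Default
#'   c(-0.3, -0.2). `NULL` returns raw power (µV²).
#' @return A list of class `tfr`: `power` (trials x frequencies x samples;
#'   dB, or µV² without baselining), `freqs`, `times`, `channel`, `units`.
#' @export
morlet_power <- function(epochs, channel = "FCz", freqs = morlet_freqs(),
                         baseline_window = c(-0.3, -0.2)) {
  stopifnot(channel %in% epochs$channels)
  x <- epochs$data[, match(channel, epochs$channels), , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1) # single trial
  x <- t(x) # samples x trials
  n <- nrow(x)
  nt <- ncol(x)
  srate <- epochs$srate

  sigma <- 4 / (2 * pi * freqs)
  half <- ceiling(3.5 * max(sigma) * srate)
  nfft <- 2^ceiling(log2(n + 2 * half))
  fx <- stats::mvfft(rbind(x, matrix(0, nfft - n, nt)))

  pow <- array(NA_real_, c(nt, length(freqs), n))
  edge <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    hw <- ceiling(3.5 * sigma[k] * srate)
    tw <- (-hw:hw) / srate
    w <- exp(-1i * 2 * pi * tw * freqs[k]) * exp(-tw^2 / (2 * sigma[k]^2))
    w <- w / sum(abs(w)) # unit-gain normalisation (cancels in dB)
    fw <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(fx * fw, inverse = TRUE) / nfft
    z <- conv[hw + seq_len(n), , drop = FALSE] # centre-aligned output
    pow[, k, ] <- t(Mod(z)^2)
    edge[k] <- hw
  }

  units <- "uV^2"
  if (!is.null(baseline_window)) {
    sel <- epochs$times >= baseline_window[1] &
      epochs$times <= baseline_window[2]
    if (!any(sel)) stop("baseline window contains no samples")
    for (k in seq_along(freqs)) {
      bl <- mean(pow[, k, sel]) # trial-averaged baseline power
      pow[, k, ] <- 10 * log10(pow[, k, ] / bl)
    }
    units <- "dB"
  }
  structure(list(power = pow, freqs = freqs, times = epochs$times,
                 channel = channel, units = units, edge = edge),
            class = "tfr")
}

#' Band- and window-averaged power
#'
#' Mean power over the time-frequency bins inside a frequency band and time
#' window, one value per trial.
#'
#' @param tfr A `tfr` from [morlet_power()].
#' @param band Frequency band in Hz, e.g. c(4, 8).
#' @param window Time window in seconds, e.g. c(0.2, 0.4).
#' @return Numeric vector, one value per trial.
#' @export
band_window_average <- function(tfr, band, window) {
  fs <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  ts <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(fs) || !any(ts)) stop("empty band/window selection")
  apply(tfr$power[, fs, ts, drop = FALSE], 1, mean)
}

#' Single-trial component amplitudes
#'
#' Quantifies all four feedback-locked components per trial with the same
#' measures used for averaged data: peak-to-peak FRN on the 15 Hz low-pass
#' filtered FCz waveform, P3 mean amplitude (300-500 ms) at Pz, and Morlet
#' band power in dB for theta (4-8 Hz, 200-400 ms, FCz) and delta (1-4 Hz,
#' 300-500 ms, Pz), and attaches the trial metadata.
#'
#' @param epochs A preprocessed (artifact-rejected, baseline-corrected)
#'   `epoch_set` containing channels FCz and Pz.
#' @param measures Character subset of c("frn", "p3", "theta", "delta");
#'   computing only the measures needed saves the time-frequency transform.
#' @return A tibble with one row per surviving epoch: the requested
#'   component columns (`frn_p2p`, `p3_mean`, `theta_db`, `delta_db`) plus
#'   the `trial_meta` columns.
#' @export
trial_features <- function(epochs, measures = c("frn", "p3", "theta",
                                                "delta")) {
  out <- epochs$trial_meta
  grid <- morlet_freqs()
  if ("frn" %in% measures) {
    fcz <- epochs$data[, match("FCz", epochs$channels), , drop = TRUE]
    if (is.null(dim(fcz))) fcz <- matrix(fcz, nrow = 1)
    filt <- lowpass_butter(t(fcz), epochs$srate)
    res <- cpp_frn_cols(filt, epochs$times, 0.2, 0.35)
    out$frn_p2p <- res$p2p
    out$frn_fallback <- res$fallback
  }
  if ("p3" %in% measures) {
    pz <- epochs$data[, match("Pz", epochs$channels), , drop = TRUE]
    if (is.null(dim(pz))) pz <- matrix(pz, nrow = 1) # single trial
    sel <- epochs$times >= 0.3 & epochs$times <= 0.5
    out$p3_mean <- rowMeans(pz[, sel, drop = FALSE])
  }
  if ("theta" %in% measures) {
    tf <- morlet_power(epochs, "FCz", freqs = grid[grid >= 4 & grid <= 8])
    out$theta_db <- band_window_average(tf, c(4, 8), c(0.2, 0.4))
  }
  if ("delta" %in% measures) {
    tf <- morlet_power(epochs, "Pz", freqs = grid[grid >= 1 & grid <= 4])
    out$delta_db <- band_window_average(tf, c(1, 4), c(0.3, 0.5))
  }
  out
}

#' Within-subject factorial ANOVA on component cell means
#'
#' Repeated-measures ANOVA of a component measure over the full
#' condition x expectancy x valence within-subject design, computed from
#' per-subject cell means. Subjects missing any of the 8 cells are dropped
#' with a warning.
#'
#' @param features A tibble of single-trial features (from
#'   [trial_features()]) with columns `subject`, `condition`, `expectancy`,
#'   `valence` and the measure.
#' @param measure Column name of the dependent measure, e.g. `"p3_mean"`.
#' @return A tibble with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p_value`.
#' @export
cell_anova <- function(features, measure) {
  cells <- features |>
    dplyr::group_by(.data$subject, .data$condition, .data$expectancy,
                    .data$valence) |>
    dplyr::summarise(y = mean(.data[[measure]]), .groups = "drop")
  counts <- table(cells$subject)
  bad <- names(counts)[counts < 8]
  if (length(bad)) {
    warning("dropping subjects with missing cells: ",
            paste(bad, collapse = ", "))
    cells <- cells[!(cells$subject %in% bad), ]
  }
  rm_anova(cells, dv = "y", id = "subject",
           within = c("condition", "expectancy", "valence"))
}

#' Repeated-measures ANOVA (fully-crossed within-subject design)
#'
#' Univariate within-subject ANOVA from one observation per subject x cell,
#' each effect tested against its own subject-by-effect interaction stratum.
#'
#' @param data Data frame with one row per subject x cell.
#' @param dv Name of the dependent-variable column.
#' @param id Name of the subject column.
#' @param within Character vector of within-subject factor columns.
#' @return Tidy tibble: `effect`, `df1`, `df2`, `F`, `p_value`.
#' @export
rm_anova <- function(data, dv, id, within) {
  d <- as.data.frame(data)
  d[[id]] <- factor(d[[id]])
  for (w in within) d[[w]] <- factor(d[[w]])
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s / (%s))",
                                   dv, rhs, id, rhs))
  fit <- stats::aov(fml, data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals" || is.na(tab[i, "F value"])) next
      out[[length(out) + 1L]] <- tibble::tibble(
        effect = gsub(":", " x ", terms[i]),
        df1 = tab[i, "Df"],
        df2 = tab[terms == "Residuals", "Df"],
        F = tab[i, "F value"],
        p_value = tab[i, "Pr(>F)"])
    }
  }
  dplyr::bind_rows(out)
}
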