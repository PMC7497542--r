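#' Build the stay/switch table
#'
#' For every trial that has a preceding trial *of the same condition* within
#' the same block (not necessarily the preceding trial of the experiment,
#' because conditions are randomly interleaved), records whether the current
#' stage-1 choice repeats that predecessor's choice (`stay`, coded 0/1),
#' together with the predecessor's reward type (win = +1, loss = -1) and --
#' for the predictable condition -- its transition type (common = +1,
#' rare = -1).
#'
#' @param trials A trial table from [simulate_agent()], optionally with a
#'   `subject` column (added as-is to the output; defaults to 1).
#' @return A tibble with columns `subject`, `block`, `condition`, `stay`,
#'   `prev_reward`, `prev_transition` (`NA` in the random condition).
#' @export
build_stay_table <- function(trials) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  trials |>
    dplyr::group_by(.data$subject, .data$block, .data$condition) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      stay = as.integer(.data$action == dplyr::lag(.data$action)),
      prev_reward = dplyr::lag(ifelse(.data$valence == "win", 1, -1)),
      prev_transition = dplyr::lag(dplyr::case_when(
        .data$transition == "common" ~ 1,
        .data$transition == "rare" ~ -1,
        .default = NA_real_))) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$stay)) |>
    dplyr::select("subject", "block", "condition", "stay", "prev_reward",
                  "prev_transition")
}

#' Logistic regression of stay behaviour
#'
#' Predicts stay (0/1) from the previous same-condition trial's reward type
#' and -- in the predictable condition -- transition type and their
#' interaction, predictors coded +1/-1. In `"hierarchical"` mode a
#' mixed-effects logistic regression is fitted with all within-subject terms
#' as random effects across subjects; in `"per_subject"` mode a separate
#' logistic regression is fitted per subject and group-level inference is a
#' one-sample t-test on the per-subject coefficients.
#'
#' @param records Output of [build_stay_table()] (>= 2 subjects for
#'   hierarchical mode).
#' @param condition `"predictable"` (full design) or `"random"` (transition
#'   terms omitted).
#' @param mode `"hierarchical"` or `"per_subject"`.
#' @return A tibble with one row per term: `term`, `estimate`, `statistic`
#'   (Wald z in hierarchical mode, one-sample t in per-subject mode),
#'   `p_value`, `condition`, `mode`.
#' @export
fit_stay_regression <- function(records,
                                condition = c("predictable", "random"),
                                mode = c("hierarchical", "per_subject")) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  d <- records[records$condition == condition, ]
  form_fixed <- if (condition == "predictable")
    stay ~ prev_reward * prev_transition else stay ~ prev_reward
  if (mode == "hierarchical") {
    if (length(unique(d$subject)) < 2)
      stop("hierarchical mode needs >= 2 subjects")
    form <- if (condition == "predictable")
      stay ~ prev_reward * prev_transition +
        (prev_reward * prev_transition | subject)
    else stay ~ prev_reward + (prev_reward | subject)
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(form, data = d, family = stats::binomial,
                  control = lme4::glmerControl(calc.derivs = FALSE))))
    co <- summary(fit)$coefficients
    tibble::tibble(term = rownames(co), estimate = co[, 1],
                   statistic = co[, 3], p_value = co[, 4],
                   condition = condition, mode = mode)
  } else {
    coefs <- lapply(split(d, d$subject), function(ds) {
      fit <- suppressWarnings(
        stats::glm(form_fixed, data = ds, family = stats::binomial))
      stats::coef(fit)
    })
    cm <- do.call(rbind, coefs)
    # separation can inflate per-subject coefficients; flag, do not crash
    flagged <- abs(cm) > 10
    res <- lapply(colnames(cm), function(term) {
      v <- cm[, term]
      tt <- stats::t.test(v)
      tibble::tibble(term = term, estimate = mean(v),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    })
    out <- dplyr::bind_rows(res)
    out$condition <- condition
    out$mode <- mode
    attr(out, "n_flagged") <- sum(flagged)
    out
  }
}

#' Performance metrics: bonus and subblock learning curves
#'
#' Bonus is the summed payoff per condition and block, converted from ct to
#' EUR. The learning curve splits the 50 predictable-condition trials of
#' each block, in presentation order, into ten subblocks of five trials and
#' averages correctness (choice of the first-stage stimulus whose common
#' transition leads to the high-reward stage-2 stimulus); correctness is
#' undefined for the random condition.
#'
#' @param trials A trial table from [simulate_agent()].
#' @return List with `bonus` (tibble: block, condition, bonus_eur) and
#'   `learning_curve` (tibble: subblock 1..10, prop_correct averaged over
#'   blocks).
#' @export
performance_metrics <- function(trials) {
  bonus <- trials |>
    dplyr::group_by(.data$block, .data$condition) |>
    dplyr::summarise(bonus_eur = sum(.data$payoff) / 100, .groups = "drop")
  n_sub <- 10L
  lc <- trials |>
    dplyr::filter(.data$condition == "predictable") |>
    dplyr::group_by(.data$block) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(subblock = ceiling(dplyr::row_number() /
                                       (dplyr::n() / n_sub))) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$subblock) |>
    dplyr::summarise(prop_correct = mean(.data$correct), .groups = "drop")
  list(bonus = bonus, learning_curve = lc)
}

#' Exclude blocks with misjudged set identity
#'
#' Removes all trials of blocks in which the (synthetic) end-of-block
#' judgment failed to identify which set had the predictable transition
#' structure, and reports the excluded fraction.
#'
#' @param trials A trial table (optionally with a `subject` column).
#' @param judgments A data frame with columns `subject` (optional if trials
#'   have none), `block` and `correct` (logical: set identified correctly).
#' @return The filtered trial table with attribute `excluded_fraction`.
#' @export
filter_valid_blocks <- function(trials, judgments) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  if (!"subject" %in% names(judgments)) judgments$subject <- 1L
  key <- paste(trials$subject, trials$block)
  jkey <- paste(judgments$subject, judgments$block)
  if (!all(key %in% jkey))
    stop("missing judgment for at least one subject x block")
  ok <- judgments$correct[match(key, jkey)]
  out <- trials[ok, , drop = FALSE]
  attr(out, "excluded_fraction") <- mean(!ok)
  out
}
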