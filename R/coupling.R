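#' Single-trial regressions of component amplitude on |RPE|
#'
#' For every subject x condition x RPE-sign cell, regresses the standardized
#' single-trial component amplitude on the standardized absolute reward
#' prediction error (ordinary least squares; with one predictor the
#' standardized slope equals the Pearson correlation). Splitting by RPE sign
#' while using |RPE| lets signed and unsigned coding dissociate: unsigned
#' coupling gives same-sign slopes for positive and negative RPEs, signed
#' coupling opposite signs. Cells with fewer than `min_trials` trials are
#' omitted.
#'
#' @param features A tibble of single-trial features with columns `subject`,
#'   `condition`, `rpe` and the component measure (as from
#'   [trial_features()], whose metadata carries the model RPEs).
#' @param component Column name of the component measure.
#' @param min_trials Minimum trials per regression cell. Default 8.
#' @return A tibble: `subject`, `component`, `condition`, `rpe_sign`
#'   (`"positive"`/`"negative"`), `slope`, `n_trials`.
#' @export
rpe_regression <- function(features, component, min_trials = 8) {
  d <- features[features$rpe != 0, ]
  d$rpe_sign <- ifelse(d$rpe > 0, "positive", "negative")
  d |>
    dplyr::group_by(.data$subject, .data$condition, .data$rpe_sign) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      slope = if (dplyr::n() >= min_trials &&
                  stats::sd(abs(.data$rpe)) > 0 &&
                  stats::sd(.data[[component]]) > 0)
        stats::cor(abs(.data$rpe), .data[[component]]) else NA_real_,
      .groups = "drop") |>
    dplyr::filter(!is.na(.data$slope)) |>
    dplyr::mutate(component = component) |>
    dplyr::select("subject", "component", "condition", "rpe_sign", "slope",
                  "n_trials")
}

#' Group-level inference on RPE-coupling slopes
#'
#' One-sample t-tests of the mean standardized slope against zero -- overall
#' (per-subject mean over all cells), per condition, and per condition x
#' sign cell -- plus a within-subject 2x2 ANOVA with factors RPE sign
#' (valence of the feedback driving the RPE) and condition.
#'
#' @param slopes Output of [rpe_regression()] (>= 3 subjects).
#' @return List with `t_tests` (tibble: scope, mean_slope, t, df, p_value)
#'   and `anova` (tidy within-subject ANOVA table).
#' @export
group_inference <- function(slopes) {
  if (length(unique(slopes$subject)) < 3)
    stop("group inference needs >= 3 subjects")
  one_t <- function(v, scope) {
    if (stats::sd(v) == 0) {
      # degenerate variance: t is infinite unless the mean is 0 too
      return(tibble::tibble(scope = scope, mean_slope = mean(v),
                            t = ifelse(mean(v) == 0, 0, Inf),
                            df = length(v) - 1, p_value = NA_real_))
    }
    tt <- stats::t.test(v)
    tibble::tibble(scope = scope, mean_slope = mean(v),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  }
  per_subj <- slopes |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
  tests <- list(one_t(per_subj$slope, "overall"))
  for (cond in unique(slopes$condition)) {
    v <- slopes[slopes$condition == cond, ] |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
    tests[[length(tests) + 1L]] <- one_t(v$slope, cond)
    for (sgn in unique(slopes$rpe_sign)) {
      vv <- slopes$slope[slopes$condition == cond & slopes$rpe_sign == sgn]
      tests[[length(tests) + 1L]] <- one_t(vv, paste(cond, sgn, sep = "."))
    }
  }
  anova <- rm_anova(as.data.frame(slopes), dv = "slope", id = "subject",
                    within = c("rpe_sign", "condition"))
  list(t_tests = dplyr::bind_rows(tests), anova = anova)
}
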