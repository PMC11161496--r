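# Mixed-model inference: per-outcome linear mixed models with a subject
# random intercept, Wald chi-square tests (Type II), Tukey-adjusted marginal
# contrasts of the four condition cells averaged over composition style, and
# simple-slope moderation analyses of reward on the motor measures.

TERM_LABELS <- c(
  playing_condition = "playing",
  accompaniment = "accompaniment",
  `playing_condition:accompaniment` = "interaction",
  style = "style",
  bmrq_z = "bmrq",
  gold_z = "gold_msi",
  accel_z = "total_acceleration"
)

# Coerce condition columns to factors with the reference levels used
# throughout (Beat / Recorded / March) and standardize continuous covariates.
prepare_model_data <- function(measures, outcome, extra = character(0)) {
  d <- as_tibble(measures)
  need <- c("subject_id", "playing_condition", "accompaniment", "style",
            "bmrq_total", "gold_msi_training", outcome, extra)
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("measures table missing column(s): ", paste(miss, collapse = ", ")))
  d$playing_condition <- factor(d$playing_condition, PLAYING_LEVELS)
  d$accompaniment <- factor(d$accompaniment, ACCOMP_LEVELS)
  d$style <- factor(d$style, STYLE_LEVELS)
  d$subject_id <- factor(d$subject_id)
  keep <- stats::complete.cases(d[, c(outcome, extra)])
  d <- d[keep, , drop = FALSE]
  if (all(is.na(d[[outcome]])) || nrow(d) == 0L)
    abort(sprintf("outcome '%s' has no non-missing values", outcome))
  scale_info <- list()
  zcol <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) abort("degenerate (constant) continuous predictor")
    (v - mean(v)) / s
  }
  d$bmrq_z <- zcol(d$bmrq_total)
  d$gold_z <- zcol(d$gold_msi_training)
  scale_info$bmrq <- c(mean = mean(d$bmrq_total), sd = sd(d$bmrq_total))
  scale_info$gold <- c(mean = mean(d$gold_msi_training), sd = sd(d$gold_msi_training))
  for (v in extra) {
    s <- sd(d[[v]])
    if (is.na(s) || s == 0)
      abort(sprintf("degenerate covariate '%s' (zero variance)", v))
    scale_info[[v]] <- c(mean = mean(d[[v]]), sd = s)
    d[[paste0(v, "_z")]] <- (d[[v]] - mean(d[[v]])) / s
  }
  list(data = d, scale_info = scale_info)
}

wald_table <- function(fit) {
  a <- suppressMessages(car::Anova(fit, type = 2))
  tibble(
    term = unname(TERM_LABELS[rownames(a)] %|NA|% rownames(a)),
    chisq = a$Chisq, df = a$Df, p = a$`Pr(>Chisq)`
  )
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

new_drum_lmm <- function(fit, wald, outcome, data, scale_info, kind,
                         df_method, motor_var = NULL) {
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(fit = fit, wald = wald, outcome = outcome, data = data,
         scale_info = scale_info, kind = kind, motor_var = motor_var,
         fit_meta = list(
           method = "REML",
           df_method = df_method,
           converged = is.null(msgs),
           messages = msgs %||% character(0),
           singular = lme4::isSingular(fit),
           n_obs = stats::nobs(fit),
           n_subjects = nlevels(data$subject_id))),
    class = "drum_lmm")
}

#' Fit the per-outcome condition model
#'
#' Linear mixed model of one trial-level outcome on playing condition
#' (Improvise vs. Beat), accompaniment (Live vs. Recorded) and their
#' interaction, controlling for musical training (Gold-MSI), musical reward
#' sensitivity (BMRQ) and composition style, with a random intercept per
#' subject (REML). For the autonomic outcomes (tonic EDA change, BPM, RMSSD),
#' total acceleration is additionally required as a covariate so motion cannot
#' explain autonomic effects. Fixed effects are tested with Type II Wald
#' chi-squares; continuous covariates are standardized internally.
#'
#' @param measures Per-trial measures tibble (see [derive_measures()]).
#' @param outcome Name of the outcome column.
#' @param include_acceleration Add total acceleration as covariate; defaults
#'   to `TRUE` for `tonic_eda_delta`, `bpm`, `rmssd`.
#' @param df_method Degrees-of-freedom method passed to emmeans for follow-up
#'   contrasts: `"satterthwaite"` (default) or `"asymptotic"`.
#' @return A `drum_lmm` object; `tidy()` gives the Wald table, `glance()` the
#'   fit metadata.
#' @export
fit_condition_model <- function(measures, outcome,
                                include_acceleration = NULL,
                                df_method = c("satterthwaite", "asymptotic")) {
  df_method <- match.arg(df_method)
  if (is.null(include_acceleration))
    include_acceleration <- outcome %in% c("tonic_eda_delta", "bpm", "rmssd")
  extra <- if (include_acceleration) "total_acceleration" else character(0)
  prep <- prepare_model_data(measures, outcome, extra)
  rhs <- "playing_condition * accompaniment + style + bmrq_z + gold_z"
  if (include_acceleration) rhs <- paste(rhs, "+ accel_z")
  d <- prep$data
  if (include_acceleration) d$accel_z <- d$total_acceleration_z
  if (nlevels(droplevels(d$subject_id)) < 2L)
    abort("fit_condition_model: need at least 2 subjects")
  form <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  new_drum_lmm(fit, wald_table(fit), outcome, d, prep$scale_info,
               kind = "condition", df_method = df_method)
}

#' Tukey-adjusted pairwise contrasts of the condition cells
#'
#' Estimated marginal means of the four playing x accompaniment cells,
#' averaged over composition style with continuous controls at their means,
#' and all six pairwise differences with Tukey-family adjustment.
#'
#' @param x A fitted `drum_lmm` from [fit_condition_model()].
#' @return Tibble of 6 contrasts (`contrast`, `estimate`, `se`, `df`,
#'   `t`, `p_adj`); the cell means are attached as attribute `"emmeans"`.
#' @export
pairwise_contrasts <- function(x) {
  stopifnot(inherits(x, "drum_lmm"))
  emm <- suppressMessages(
    emmeans::emmeans(x$fit, ~ playing_condition * accompaniment,
                     lmer.df = x$fit_meta$df_method))
  ct <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  out <- tibble(
    contrast = as.character(ct$contrast),
    estimate = ct$estimate, se = ct$SE, df = ct$df,
    t = ct$t.ratio, p_adj = ct$p.value
  )
  attr(out, "emmeans") <- as_tibble(as.data.frame(emm))
  out
}

#' Fit a reward-moderation model for one motor measure
#'
#' Mixed model of reported reward (first principal component of the survey)
#' on a motor measure, playing condition, accompaniment and their three-way
#' interaction, with the usual controls and subject random intercept. The
#' motor measure is standardized before fitting; simple slopes are
#' back-transformed to the measure's original units by [simple_slopes()].
#'
#' @param measures Per-trial measures tibble with PC scores.
#' @param motor_var One of `"total_acceleration"`, `"mean_emg_pct_mvc"`,
#'   `"strike_count"`.
#' @param outcome Outcome column (default `"pc_reward"`).
#' @inheritParams fit_condition_model
#' @return A `drum_lmm` of kind `"moderation"`.
#' @export
fit_moderation_model <- function(measures, motor_var,
                                 outcome = "pc_reward",
                                 df_method = c("satterthwaite", "asymptotic")) {
  df_method <- match.arg(df_method)
  prep <- prepare_model_data(measures, outcome, extra = motor_var)
  d <- prep$data
  d$motor_z <- d[[paste0(motor_var, "_z")]]
  form <- stats::as.formula(paste(
    outcome, "~ motor_z * playing_condition * accompaniment",
    "+ style + bmrq_z + gold_z + (1 | subject_id)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  a <- suppressMessages(car::Anova(fit, type = 2))
  lab <- rownames(a)
  lab <- gsub("motor_z", motor_var, lab, fixed = TRUE)
  lab <- gsub("playing_condition", "playing", lab, fixed = TRUE)
  lab <- gsub("bmrq_z", "bmrq", lab, fixed = TRUE)
  lab <- gsub("gold_z", "gold_msi", lab, fixed = TRUE)
  wald <- tibble(term = lab, chisq = a$Chisq, df = a$Df, p = a$`Pr(>Chisq)`)
  new_drum_lmm(fit, wald, outcome, d, prep$scale_info,
               kind = "moderation", df_method = df_method,
               motor_var = motor_var)
}

#' Simple slopes of reward on a motor measure by playing condition
#'
#' Conditional linear trends of the outcome on the motor measure within the
#' Improvise and Beat conditions, averaged over accompaniment and style, with
#' 95% confidence intervals and the slope-difference test. The moderation
#' (motor x playing) Wald p-value is reported raw and Bonferroni-adjusted
#' across the `m` motor measures analysed (3 by default).
#'
#' @param x A `drum_lmm` of kind `"moderation"`.
#' @param conf_level Confidence level for slope intervals.
#' @param m Bonferroni family size across motor measures.
#' @return A list with `slopes` (per-condition tibble, standardized and
#'   per-original-unit scales), `difference` (slope-difference test) and
#'   `moderation` (raw and Bonferroni-adjusted interaction p).
#' @export
simple_slopes <- function(x, conf_level = 0.95, m = 3) {
  stopifnot(inherits(x, "drum_lmm"), x$kind == "moderation")
  tr <- suppressMessages(
    emmeans::emtrends(x$fit, ~ playing_condition, var = "motor_z",
                      lmer.df = x$fit_meta$df_method))
  s <- summary(tr, infer = c(TRUE, TRUE), level = conf_level)
  lcl <- s$lower.CL %||% s$asymp.LCL
  ucl <- s$upper.CL %||% s$asymp.UCL
  sd_motor <- x$scale_info[[x$motor_var]][["sd"]]
  slopes <- tibble(
    playing_condition = as.character(s$playing_condition),
    slope = s$motor_z.trend, se = s$SE, df = s$df,
    conf_low = lcl, conf_high = ucl,
    slope_per_unit = s$motor_z.trend / sd_motor,
    conf_low_per_unit = lcl / sd_motor,
    conf_high_per_unit = ucl / sd_motor
  )
  pd <- summary(emmeans::contrast(tr, method = "pairwise"),
                infer = c(TRUE, TRUE))
  difference <- tibble(
    contrast = as.character(pd$contrast),
    estimate = pd$estimate, se = pd$SE, df = pd$df,
    t = pd$t.ratio, p = pd$p.value
  )
  int_row <- grepl(paste0(x$motor_var, ":playing$"), x$wald$term)
  p_raw <- if (any(int_row)) x$wald$p[int_row][1] else NA_real_
  list(
    slopes = slopes,
    difference = difference,
    moderation = tibble(motor_var = x$motor_var, p = p_raw,
                        p_bonferroni = pmin(1, m * p_raw))
  )
}

#' @export
print.drum_lmm <- function(x, ...) {
  cat(sprintf("<drum_lmm (%s): %s, %d obs / %d subjects%s>\n",
              x$kind, x$outcome, x$fit_meta$n_obs, x$fit_meta$n_subjects,
              if (x$fit_meta$singular) ", singular fit" else ""))
  print(x$wald)
  invisible(x)
}

#' @export
tidy.drum_lmm <- function(x, ...) x$wald

#' @export
glance.drum_lmm <- function(x, ...) {
  tibble(outcome = x$outcome, kind = x$kind,
         n_obs = x$fit_meta$n_obs, n_subjects = x$fit_meta$n_subjects,
         sigma = stats::sigma(x$fit), singular = x$fit_meta$singular,
         converged = x$fit_meta$converged, df_method = x$fit_meta$df_method)
}

#' Plot condition-cell marginal means
#'
#' Estimated marginal means of the four condition cells with 95% confidence
#' intervals.
#'
#' @param object A `drum_lmm` of kind `"condition"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drum_lmm <- function(object, ...) {
  stopifnot(object$kind == "condition")
  emm <- as_tibble(as.data.frame(
    emmeans::emmeans(object$fit, ~ playing_condition * accompaniment,
                     lmer.df = object$fit_meta$df_method)))
  ggplot(emm, aes(x = .data$playing_condition, y = .data$emmean,
                  colour = .data$accompaniment)) +
    geom_point(position = position_dodge(0.3)) +
    geom_errorbar(aes(ymin = .data$lower.CL, ymax = .data$upper.CL),
                  width = 0.15, position = position_dodge(0.3)) +
    labs(x = NULL, y = object$outcome, colour = "Accompaniment") +
    theme_minimal()
}
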