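null_cfg <- function(n = 12) sim_config(
  n_subjects = n, effects = null_effects(),
  coupling = list(motor = "total_acceleration",
                  slope = c(Beat = 0, Improvise = 0)))

test_that("condition model recovers a no-effect world as near-zero estimates", {
  m <- simulate_measures(null_cfg(20), seed = 31)
  # outcome identical across conditions within subject
  m$total_acceleration <- as.numeric(factor(m$subject_id)) * 10
  fit <- fit_condition_model(m, "total_acceleration",
                             df_method = "asymptotic")
  fe <- lme4::fixef(fit$fit)
  cond_terms <- grep("playing|accompaniment", names(fe))
  expect_true(all(abs(fe[cond_terms]) < 1e-6))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(all(c("playing", "accompaniment", "interaction", "style",
                    "bmrq", "gold_msi") %in% tidy(fit)$term))
})

test_that("autonomic outcomes require the acceleration covariate", {
  m <- simulate_measures(null_cfg(12), seed = 5)
  fit <- fit_condition_model(m, "bpm", df_method = "asymptotic")
  expect_true("total_acceleration" %in% tidy(fit)$term)
  fit2 <- fit_condition_model(m, "pc_reward", df_method = "asymptotic")
  expect_false("total_acceleration" %in% tidy(fit2)$term)
})

test_that("pairwise contrasts: 6 Tukey-adjusted cell differences, winner as planted", {
  cfg <- sim_config(n_subjects = 20,
                    effects = utils::modifyList(
                      null_effects(),
                      list(total_acceleration = list(
                        playing = 0.3, accomp = 0.3, interaction = 1.5,
                        style = c(March = 0, Waltz = 0, Salsa = 0, Rock = 0),
                        bmrq = 0))),
                    coupling = list(motor = "total_acceleration",
                                    slope = c(Beat = 0, Improvise = 0)))
  m <- simulate_measures(cfg, seed = 7)
  fit <- fit_condition_model(m, "total_acceleration", df_method = "asymptotic")
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 6L)
  emm <- attr(ct, "emmeans")
  expect_equal(nrow(emm), 4L)
  top <- emm[which.max(emm$emmean), ]
  expect_equal(as.character(top$playing_condition), "Improvise")
  expect_equal(as.character(top$accompaniment), "Live")
  il <- grepl("Improvise Live", ct$contrast)
  expect_equal(sum(il), 3L)
  expect_true(all(ct$p_adj[il] < 0.05))

  # Tukey-adjusted p never below the unadjusted p
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(fit$fit, ~ playing_condition * accompaniment,
                     lmer.df = "asymptotic"),
    method = "pairwise", adjust = "none"))
  expect_true(all(ct$p_adj >= raw$p.value - 1e-12))
})

test_that("contrast estimates are invariant to factor recoding of the input", {
  m <- simulate_measures(sim_config(n_subjects = 12), seed = 13)
  m2 <- m
  m2$playing_condition <- factor(as.character(m2$playing_condition),
                                 c("Improvise", "Beat"))
  m2$style <- factor(as.character(m2$style), rev(STYLE <- c("March", "Waltz", "Salsa", "Rock")))
  f1 <- fit_condition_model(m, "strike_count", df_method = "asymptotic")
  f2 <- fit_condition_model(m2, "strike_count", df_method = "asymptotic")
  expect_equal(pairwise_contrasts(f1)$estimate,
               pairwise_contrasts(f2)$estimate, tolerance = 1e-8)
})

test_that("moderation model detects Improvise-only coupling; slopes back-transform", {
  cfg <- sim_config(n_subjects = 30,
                    coupling = list(motor = "total_acceleration",
                                    slope = c(Beat = 0, Improvise = 0.5)))
  m <- simulate_measures(cfg, seed = 21)
  fit <- fit_moderation_model(m, "total_acceleration",
                              df_method = "asymptotic")
  w <- tidy(fit)
  expect_true("total_acceleration:playing" %in% w$term)
  expect_lt(w$p[w$term == "total_acceleration:playing"], 0.05)

  ss <- simple_slopes(fit)
  imp <- ss$slopes[ss$slopes$playing_condition == "Improvise", ]
  beat <- ss$slopes[ss$slopes$playing_condition == "Beat", ]
  expect_gt(imp$slope, beat$slope)
  expect_true(imp$conf_low <= 0.5 && 0.5 <= imp$conf_high)
  expect_true(beat$conf_low <= 0 && 0 <= beat$conf_high)
  # per-unit slopes are the standardized slopes divided by the motor SD
  expect_equal(imp$slope_per_unit,
               imp$slope / sd(fit$data$total_acceleration))
  # Bonferroni across 3 motor measures
  expect_equal(ss$moderation$p_bonferroni, min(1, 3 * ss$moderation$p))
})

test_that("planted interaction effects are recovered with small bias", {
  # effect grid in residual-SD units; the generator maps the latent onto the
  # acceleration scale as 400 + 60*eta, so the measure-scale residual SD is 60
  for (beta in c(0, 0.5, 1)) {
    cfg <- sim_config(
      n_subjects = 30,
      effects = utils::modifyList(null_effects(), list(
        total_acceleration = list(playing = 0, accomp = 0, interaction = beta,
                                  style = c(March = 0, Waltz = 0, Salsa = 0,
                                            Rock = 0), bmrq = 0))),
      coupling = list(motor = "total_acceleration",
                      slope = c(Beat = 0, Improvise = 0)))
    est <- vapply(1:100, function(s) {
      m <- simulate_measures(cfg, seed = 9000 + 100 * beta + s)
      fit <- fit_condition_model(m, "total_acceleration",
                                 df_method = "asymptotic")
      unname(lme4::fixef(fit$fit)[["playing_conditionImprovise:accompanimentLive"]])
    }, numeric(1)) / 60
    expect_lt(abs(mean(est) - beta), 0.1,
              label = sprintf("mean bias at beta = %g", beta))
  }
})

test_that("degenerate motor covariates are rejected, synchrony outcome runs", {
  m <- simulate_measures(sim_config(n_subjects = 8), seed = 3)
  m$strike_count <- 50L
  expect_error(fit_moderation_model(m, "strike_count"), "degenerate")

  fit <- fit_condition_model(m, "synchrony_rating", df_method = "asymptotic")
  expect_true(all(tidy(fit)$df > 0))
  expect_true(all(tidy(fit)$p >= 0 & tidy(fit)$p <= 1))
})
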