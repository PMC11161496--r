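test_that("the default design yields 480 playing trials plus 30 listen-only", {
  st <- simulate_study(sim_config(), seed = 11)
  expect_equal(nrow(st$trials), 480L)
  expect_equal(nrow(st$listen), 30L)
  expect_true(all(st$trials$strike_count >= 1))
  expect_true(all(st$trials$mean_emg_pct_mvc > 0))
  expect_true(all(st$trials$rmssd > 0))
})

test_that("the generator is deterministic per seed", {
  a <- simulate_study(sim_config(n_subjects = 2), seed = 99)
  b <- simulate_study(sim_config(n_subjects = 2), seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$surveys, b$surveys)
  ra <- simulate_trial_signals(a, a$trials$trial_id[3])
  rb <- simulate_trial_signals(b, b$trials$trial_id[3])
  expect_identical(ra$channels$ecg$samples, rb$channels$ecg$samples)
  expect_identical(ra$midi, rb$midi)

  c <- simulate_study(sim_config(n_subjects = 2), seed = 100)
  expect_false(identical(a$trials$strike_count, c$trials$strike_count))

  ma <- simulate_measures(sim_config(n_subjects = 3), seed = 7)
  mb <- simulate_measures(sim_config(n_subjects = 3), seed = 7)
  expect_identical(ma, mb)
})

test_that("written datasets are byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(sim_config(n_subjects = 1), seed = 4), d1)
  write_study(simulate_study(sim_config(n_subjects = 1), seed = 4), d2)
  f1 <- sort(list.files(d1))
  expect_true(length(f1) > 10)
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = f)
})

test_that("infeasible heart-rate variability is rejected", {
  expect_error(drumlab:::sim_ibis(60, 0.4, 0.3), "non-physiological")
})

test_that("strike times respect ordering and spacing for both conditions", {
  set.seed(1)
  for (cond in c("Beat", "Improvise")) for (n in c(40, 90, 150)) {
    t <- drumlab:::sim_strike_times(n, 60, cond)
    expect_equal(length(t), n)
    expect_true(all(diff(t) > 0.1))
    expect_true(min(t) >= 1 && max(t) <= 59)
  }
})

test_that("survey synthesis maps latents onto anchored items", {
  high <- simulate_survey(matrix(c(3, 0), 1), seed = 2)
  expect_gte(high[, "pleasure"], 4L)
  low <- simulate_survey(matrix(c(-3, 0), 1), seed = 2)
  expect_lte(low[, "pleasure"], 2L)

  # zero noise: PCA on continuous two-factor structure recovers loadings
  set.seed(6)
  lat <- matrix(rnorm(1000), 500, 2)
  L <- default_survey_loadings()
  X <- lat %*% t(L)            # noiseless, undiscretized limit
  cm <- orient_and_label(fit_pca(X + matrix(rnorm(6000, 0, 1e-8), 500), 2))
  expect_gt(tucker_phi(cm$loadings[, "reward"], L[, "reward"]), 0.99)
  expect_gt(tucker_phi(cm$loadings[, "challenge"], L[, "challenge"]), 0.99)
})

test_that("QC scenarios inject the artifacts they claim", {
  st0 <- simulate_study(sim_config(n_subjects = 1), seed = 17)
  ids <- st0$trials$trial_id[1:2]
  st <- simulate_study(sim_config(
    n_subjects = 1,
    qc_scenarios = list(eda_ceiling = ids[1], ecg_low_snr = ids[2])),
    seed = 17)
  r1 <- simulate_trial_signals(st, ids[1])
  expect_true("eda_ceiling" %in% autonomic_qc(r1$channels$eda, "eda"))
  r2 <- simulate_trial_signals(st, ids[2])
  expect_true("ecg_low_snr" %in% autonomic_qc(r2$channels$ecg, "ecg"))
  clean <- simulate_trial_signals(st, st$trials$trial_id[3])
  expect_length(autonomic_qc(clean$channels$eda, "eda"), 0)
  expect_length(autonomic_qc(clean$channels$ecg, "ecg"), 0)
})
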