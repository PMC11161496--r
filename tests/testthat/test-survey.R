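# Planted two-factor Likert data at the study's scale (480 trials).
planted_survey <- function(seed, n = 480) {
  lat <- matrix(rnorm(n * 2), n, 2)
  simulate_survey(lat, noise_sd = 0.5, seed = seed)
}

test_that("parallel analysis retains the planted component count", {
  expect_equal(parallel_analysis(planted_survey(1), n_iter = 300,
                                 seed = 101)$n_components, 2L)

  noise <- matrix(rnorm(480 * 12), 480, 12,
                  dimnames = list(NULL, survey_items))
  set.seed(42)
  expect_equal(parallel_analysis(noise, n_iter = 300, seed = 102)$n_components, 0L)

  one <- matrix(rnorm(480), 480, 1) %*% t(rep(0.8, 12)) +
    matrix(rnorm(480 * 12, 0, 0.5), 480, 12)
  colnames(one) <- survey_items
  expect_equal(parallel_analysis(one, n_iter = 300, seed = 103)$n_components, 1L)

  const <- noise
  const[, 3] <- 2
  expect_error(parallel_analysis(const, n_iter = 50), "zero-variance")
})

test_that("PCA variance fractions behave and planted loadings are recovered", {
  X <- planted_survey(7)
  pa <- parallel_analysis(X, n_iter = 300, seed = 104)
  cm <- fit_pca(X, max(2, pa$n_components))

  expect_true(all(diff(cm$var_explained) <= 0))
  expect_true(all(cm$var_explained > 0 & cm$var_explained <= 1))
  expect_equal(sum(cm$var_explained_full), 1, tolerance = 1e-10)
  expect_equal(apply(cm$scores, 2, sd), c(PC1 = 1, PC2 = 1), tolerance = 1e-10)
  # orthonormal loadings
  expect_equal(crossprod(cm$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # duplicating every row changes nothing
  cm2 <- fit_pca(X[rep(1:nrow(X), 2), ], 2)
  expect_equal(abs(cm2$loadings), abs(cm$loadings), tolerance = 1e-10)
  expect_equal(cm2$var_explained, cm$var_explained, tolerance = 1e-10)

  # Tucker congruence with the planted structure
  L <- default_survey_loadings()
  cm <- orient_and_label(cm)
  expect_gt(tucker_phi(cm$loadings[, "reward"], L[, "reward"]), 0.9)
  expect_gt(tucker_phi(cm$loadings[, "challenge"], L[, "challenge"]), 0.9)
})

test_that("orientation anchors pleasure-positive reward and difficulty-positive challenge", {
  X <- planted_survey(3)
  cm <- fit_pca(X, 2)
  # force both orientations and check the anchor ends up positive either way
  flipped <- cm
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$scores[, 1] <- -flipped$scores[, 1]
  o1 <- orient_and_label(cm)
  o2 <- orient_and_label(flipped)
  expect_gt(o1$loadings["pleasure", "reward"], 0)
  expect_gt(o2$loadings["pleasure", "reward"], 0)
  expect_equal(o1$loadings, o2$loadings)
  expect_gt(o1$loadings["difficulty", "challenge"], 0)
  expect_gt(cor(o1$scores[, "reward"],
                X %*% default_survey_loadings()[, "reward"]), 0.8)

  # scores flip with loadings: projection consistency
  expect_equal(sign(cor(o1$scores[, "reward"], X[, "pleasure"])), 1)

  # near-zero anchor loading warns and leaves orientation alone
  degenerate <- cm
  degenerate$loadings["pleasure", 1] <- 0.01
  expect_warning(orient_and_label(degenerate), "near zero")
})

test_that("tidy and glance expose loadings and variance fractions", {
  X <- planted_survey(5)
  cm <- orient_and_label(fit_pca(X, 2))
  td <- tidy(cm)
  expect_equal(nrow(td), 24L)
  expect_named(td, c("item", "component", "loading"))
  g <- glance(cm)
  expect_equal(g$n_components, 2L)
  expect_true(g$var_explained_pc1 >= g$var_explained_pc2)
  expect_s3_class(autoplot(cm), "ggplot")
})
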