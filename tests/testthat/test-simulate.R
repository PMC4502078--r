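test_that("simulated respondents are deterministic and cover the 23-card task", {
  cfg <- sim_config()
  r1 <- simulate_respondent(cfg, "Green", "g1", seed = 42)
  r2 <- simulate_respondent(cfg, "Green", "g1", seed = 42)
  expect_identical(r1, r2)
  # without holdouts the canonical task has 21 cards; with 2 holdouts, 23
  expect_setequal(r1$state, presented_states(cfg$sets$Green))
  cfg23 <- sim_config(sets = list(
    Green = valuation_set(green_states(), holdouts = c("21113", "32132"), name = "Green"),
    Blue = valuation_set(blue_states(), holdouts = c("12213", "23231"), name = "Blue")))
  r3 <- simulate_respondent(cfg23, "Green", "g1", seed = 42)
  expect_equal(nrow(r3), 23)
  expect_true(all(r3$vas_raw >= 0 & r3$vas_raw <= 100))
  expect_setequal(r3$rank, 1:23)
})

test_that("a degenerate noiseless study reproduces 100 x latent values exactly", {
  cfg <- noiseless_config(n_green = 1, n_blue = 1)
  st <- simulate_study(cfg, seed = 3)
  u <- eqvas:::latent_values(cfg, st$state)
  expect_equal(st$vas_raw, unname(100 * u))
})

test_that("studies have two arms of the configured sizes and are seed-reproducible", {
  cfg <- sim_config(n_green = 7, n_blue = 5)
  st <- simulate_study(cfg, seed = 10)
  expect_equal(length(unique(st$respondent_id)), 12)
  expect_equal(length(unique(st$respondent_id[st$set == "Green"])), 7)
  expect_equal(length(unique(st$respondent_id[st$set == "Blue"])), 5)
  expect_identical(st, simulate_study(cfg, seed = 10))
  expect_false(identical(st$vas_raw, simulate_study(cfg, seed = 11)$vas_raw))
})

test_that("invalid generating coefficients are rejected under the monotone flag", {
  beta <- coef(fixture_model("N3"))
  beta["UA3"] <- -0.01 # weaker than UA2: not internally valid
  expect_error(sim_config(true_coefficients = beta), "internally valid")
  expect_s3_class(sim_config(true_coefficients = beta, monotone = FALSE),
                  "sim_config")
})

test_that("estimate precision improves with arm size", {
  cfg_small <- sim_config(n_green = 40, n_blue = 40)
  cfg_large <- sim_config(n_green = 400, n_blue = 400)
  re_s <- recovery_experiment(cfg_small, R = 6, seed = 5)
  re_l <- recovery_experiment(cfg_large, R = 6, seed = 5)
  # sampling spread shrinks roughly as 1/sqrt(n)
  expect_lt(mean(apply(re_l$estimates, 2, stats::sd)),
            mean(apply(re_s$estimates, 2, stats::sd)) / 2)
  expect_lt(mean(re_l$rmse), mean(re_s$rmse))
})

test_that("noiseless recovery has zero bias and rmse", {
  cfg <- noiseless_config(n_green = 2, n_blue = 2)
  re <- recovery_experiment(cfg, R = 2, seed = 1)
  expect_equal(max(abs(re$bias)), 0, tolerance = 1e-9)
  expect_equal(max(re$rmse), 0, tolerance = 1e-9)
  expect_equal(re$validity_rate, 1)
})

test_that("rank-task agreement is perfect without noise and degrades with ranking noise", {
  base <- list(n_green = 15, n_blue = 15)
  mean_sp <- sapply(c(0, 0.15, 0.45), function(rn) {
    cfg <- sim_config(noise_sd = 0, heterogeneity_sd = 0, ranking_noise = rn,
                      full_anchor = c(mean = 100, sd = 0),
                      dead_anchor = c(mean = 0, sd = 0), round_vas = FALSE,
                      n_green = base$n_green, n_blue = base$n_blue)
    rank_consistency(simulate_study(cfg, seed = 8))
  })
  expect_equal(mean_sp[["mean_spearman", 1]], 1)
  expect_equal(mean_sp[["pct_preserved", 1]], 100)
  expect_gt(mean_sp[["mean_spearman", 1]], mean_sp[["mean_spearman", 2]])
  expect_gt(mean_sp[["mean_spearman", 2]], mean_sp[["mean_spearman", 3]])
  expect_lt(mean_sp[["pct_preserved", 3]], mean_sp[["pct_preserved", 1]])
})

test_that("simulate() on a fitted model generates a study from its coefficients", {
  m <- fixture_model("N3")
  st <- simulate(m, seed = 2, n_green = 3, n_blue = 3)
  expect_equal(length(unique(st$respondent_id)), 6)
  expect_true(all(st$vas_raw >= 0 & st$vas_raw <= 100))
})
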