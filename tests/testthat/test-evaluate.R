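test_that("mae, exceedance percentage and correlation follow their definitions", {
  p <- c(a = 10, b = 20, c = 30, d = 40)
  names(p) <- c("11111", "21111", "31111", "33333")
  expect_equal(mae(p, p), 0)
  obs <- p + c(2, -4, 0, 0)
  expect_equal(mae(p, obs), 1.5)
  expect_equal(mae(p[c(1, 2)], obs[c(1, 2)]), 3)
  obs2 <- p + c(6, 4, 3, 1)
  expect_equal(pct_residuals_above(p, obs2, 5), 25)
  expect_equal(pct_residuals_above(p, p, 5), 0)
  expect_equal(value_correlation(p, obs), stats::cor(p, obs))
  anti <- stats::setNames(rev(unname(p)), names(p))
  expect_equal(value_correlation(p, anti, method = "spearman"), -1)
  expect_error(mae(p[1:3], obs), "keys differ")
  expect_error(value_correlation(p, stats::setNames(rep(1, 4), names(p))),
               "zero variance")
})

test_that("criteria are permutation-invariant and symmetric in residual sign", {
  set.seed(5)
  states <- sample(all_states(), 12)
  p <- stats::setNames(runif(12), states)
  o <- p + rnorm(12, 0, 0.05)
  perm <- sample(12)
  expect_equal(mae(p, o), mae(p[perm], o[perm]))
  expect_equal(pct_residuals_above(p, o, 0.03),
               pct_residuals_above(p[perm], o[perm], 0.03))
  expect_equal(mae(p, o), mae(o, p))
  expect_equal(pct_residuals_above(p, o, 0.03), pct_residuals_above(o, p, 0.03))
})

test_that("evaluating a model against its own training data is the within-sample battery", {
  tab <- fixture_table()
  m <- vas_model(tab, scale = "individual", extra = "N3")
  ev1 <- evaluate(m, anchor_full_health = FALSE)
  ev2 <- evaluate(m, observed = tab, anchor_full_health = FALSE)
  expect_equal(ev1$mae, ev2$mae)
  expect_equal(ev1$pearson, ev2$pearson)
  expect_equal(ev1$mae_pct, 100 * ev1$mae)
  expect_equal(ev1$threshold, 0.05)
})

test_that("cross-set evaluation uses the other set's states and rejects scale mismatch", {
  tab <- fixture_table()
  green <- tab[tab$set %in% c("Green", "Both"), ]
  blue <- tab[tab$set %in% c("Blue", "Both"), ]
  m <- vas_model(green, scale = "raw", states = c(green_states(), "11111", "33333"),
                 weights = rep(1, 20))
  ev <- cross_evaluate(m, blue, states = c(blue_states(), "11111", "33333"))
  expect_equal(ev$n, 20)
  # raw model vs a table lacking raw means errors
  norawcol <- blue[, setdiff(names(blue), c("raw_mean"))]
  expect_error(cross_evaluate(m, norawcol), "raw_mean")
  # degenerate reuse equals the within-sample battery
  ev_self <- cross_evaluate(m, green, states = m$states)
  expect_equal(ev_self$mae, evaluate(m)$mae)
})

test_that("holdout evaluation requires disjoint holdouts and counts only them", {
  tab <- fixture_table()
  m <- vas_model(tab, scale = "individual", extra = "N3",
                 states = c(green_states(), blue_states(), "11111", "33333"))
  hold <- stats::setNames(c(0.62, 0.25), c("21113", "32132"))
  expect_equal(holdout_evaluate(m, hold),
               mean(abs(predict(m, names(hold), anchor_full_health = TRUE) - hold)))
  expect_error(holdout_evaluate(m, stats::setNames(0.7, "11123")), "used in fitting")
})

test_that("comparison tables collect coefficients and criteria without recomputation drift", {
  t4 <- suppressMessages(reproduce_table4(extras = c("none", "N3")))
  m <- vas_model(fixture_table(), scale = "individual", extra = "N3")
  ev <- evaluate(m, anchor_full_health = FALSE)
  expect_equal(t4["Correl Model vs Observed", "N3"], ev$pearson)
  expect_equal(t4["% MAE Model vs Observed", "N3"], ev$mae_pct)
  expect_equal(t4["N3", "N3"], unname(coef(m)["N3"]))
  expect_true(is.na(t4["N3", "Baseline"]))
  # single-model input gives a single-column table
  single <- comparison_table(m)
  expect_equal(ncol(single), 1)
})

test_that("rank consistency is 1 for agreeing tasks, -1 for reversal, and needs ranks", {
  agree <- data.frame(respondent_id = "r", state = c("11111", "21111", "33333", "DEAD"),
                      vas_raw = c(95, 70, 20, 0), rank = 1:4)
  rc <- rank_consistency(agree)
  expect_equal(rc$mean_spearman, 1)
  expect_equal(rc$pct_preserved, 100)
  reversed <- transform(agree, rank = 4:1)
  expect_equal(rank_consistency(reversed)$mean_spearman, -1)
  expect_error(rank_consistency(agree[, 1:3]), "rank")
})
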