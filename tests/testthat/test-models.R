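test_that("respondent-level pooled OLS equals the weighted state-means fit", {
  # independent oracle: plain lm() on the long respondent data
  cfg <- sim_config(n_green = 25, n_blue = 25)
  st <- suppressWarnings(simulate_study(cfg, seed = 123))
  incl <- c(green_states(), blue_states(), "33333")
  m <- vas_model(st, scale = "individual", constant = TRUE, extra = "N3",
                 states = incl)
  long <- suppressWarnings(rescale_individual(st))
  long <- long[long$state %in% incl, ]
  X <- design_matrix(long$state, extra = "N3", constant = FALSE)
  oracle <- stats::lm(long$vas_ind ~ X)
  expect_equal(unname(coef(m)[c("Constant", colnames(X))]),
               unname(coef(oracle)), tolerance = 1e-10)
  # same identity on the raw scale, through the origin
  m2 <- vas_model(st, scale = "raw", constant = FALSE, states = incl)
  keep <- st$state %in% incl
  X2 <- design_matrix(st$state[keep], constant = FALSE)
  oracle2 <- stats::lm(I(100 - st$vas_raw[keep]) ~ X2 - 1)
  expect_equal(unname(coef(m2)), unname(coef(oracle2)), tolerance = 1e-10)
})

test_that("coefficients are invariant to column ordering of the data", {
  tab <- fixture_table()
  m1 <- vas_model(tab, scale = "individual")
  m2 <- vas_model(tab[rev(seq_len(nrow(tab))), ], scale = "individual")
  expect_equal(coef(m1), coef(m2), tolerance = 1e-12)
})

test_that("noise-free additive data are interpolated exactly", {
  cfg <- noiseless_config(n_green = 2, n_blue = 2)
  st <- simulate_study(cfg, seed = 1)
  m <- vas_model(st, scale = "individual", constant = TRUE, extra = "N3",
                 states = c(green_states(), blue_states(), "33333"))
  expect_equal(coef(m), cfg$true_coefficients[names(coef(m))],
               tolerance = 1e-9)
  hold <- predict(cfg$truth_model, c("21111", "21311"))
  expect_equal(holdout_evaluate(m, hold), 0, tolerance = 1e-9)
})

test_that("rank-deficient designs error by default and alias with singular_ok", {
  tab <- fixture_table()
  expect_error(vas_model(tab, scale = "individual", extra = "C2"),
               "rank-deficient.*C2")
  m <- vas_model(tab, scale = "individual", extra = "C2", singular_ok = TRUE)
  expect_equal(m$aliased, "C2")
  expect_false(internal_validity(m)$valid)
})

test_that("prediction applies the linear form, with optional full-health anchoring", {
  nm <- fixture_model("N3")
  expect_equal(unname(predict(nm, "11111")), 0.9279)
  expect_equal(unname(predict(nm, "33333")),
               0.9279 - 0.3749 - 0.1394 - 0.0673 - 0.1265 - 0.0720 - 0.1119)
  expect_equal(unname(predict(nm, "11111", anchor_full_health = TRUE)), 1)
  # a through-origin raw model predicts full health at 100 with no anchoring
  tab <- fixture_table()
  m0 <- vas_model(set_green <- tab[tab$set %in% c("Green", "Both"), ],
                  scale = "raw", constant = FALSE,
                  states = c(green_states(), "11111", "33333"),
                  weights = rep(1, 20))
  expect_equal(unname(predict(m0, "11111")), 100)
})

test_that("tariffs cover the state space and are monotone for monotone models", {
  nm <- fixture_model("N3")
  tf <- tariff(nm)
  expect_equal(nrow(tf), 243)
  expect_equal(tf$state, all_states())
  expect_equal(tf$value[tf$state == "11111"], unname(coef(nm)["Constant"]))
  # worsening any single dimension never increases the predicted value
  vals <- stats::setNames(tf$value, tf$state)
  lev <- state_levels(all_states())
  for (d in 1:5) {
    for (s in all_states()) {
      l <- lev[s, ]
      if (l[d] < 3) {
        worse <- l
        worse[d] <- worse[d] + 1L
        expect_lte(vals[paste0(worse, collapse = "")], vals[s])
      }
    }
  }
})

test_that("internal validity flags counterintuitive and aliased models", {
  expect_true(internal_validity(fixture_model("N3"))$valid)
  bad <- as_vas_model(c(MO2 = -0.1, MO3 = -0.3, SC2 = -0.05, SC3 = -0.1,
                        UA2 = -0.10, UA3 = -0.05, PD2 = -0.05, PD3 = -0.1,
                        AD2 = -0.02, AD3 = -0.05, Constant = 0.9))
  iv <- internal_validity(bad)
  expect_false(iv$valid)
  expect_equal(iv$violations$dimension, "UA")
})

test_that("adjusted R-squared follows the centred and through-origin conventions", {
  set.seed(21)
  states <- sample(all_states(), 30)
  vals <- 0.9 - 0.04 * code_score(states) + rnorm(30, 0, 0.05)
  tab <- data.frame(state = states, ind_mean = vals, n = 1)
  mc <- vas_model(tab, scale = "individual", constant = TRUE)
  m0 <- vas_model(tab, scale = "individual", constant = FALSE)
  # oracle via lm on the same responses
  X <- design_matrix(states, constant = FALSE)
  oc <- summary(stats::lm(vals ~ X))$adj.r.squared
  o0 <- summary(stats::lm(I(1 - vals) ~ X - 1))$adj.r.squared
  expect_equal(adjusted_r_squared(mc), oc, tolerance = 1e-10)
  expect_equal(adjusted_r_squared(m0), o0, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(oc, o0)))
  # a perfect fit scores 1
  perfect <- data.frame(state = states,
                        ind_mean = drop(design_matrix(states) %*%
                                          c(rep(-0.05, 10), 0.95)))
  expect_equal(adjusted_r_squared(vas_model(perfect, scale = "individual")), 1,
               tolerance = 1e-9)
})

test_that("adding a constant never increases the residual sum of squares", {
  tab <- fixture_table()
  for (sc in c("raw", "individual", "aggregate")) {
    m1 <- vas_model(tab, scale = sc, constant = TRUE)
    m0 <- vas_model(tab, scale = sc, constant = FALSE)
    expect_lte(m1$rss, m0$rss)
  }
})

test_that("published coefficient vectors round-trip through as_vas_model", {
  beta <- coef(fixture_model("N1"))
  m <- as_vas_model(beta, extra = "N1")
  expect_equal(coef(m), beta)
  expect_error(as_vas_model(beta[-1], extra = "N1"), "coefficient names")
})
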