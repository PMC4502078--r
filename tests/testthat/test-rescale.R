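test_that("individual rescaling maps anchors exactly and preserves worse-than-dead values", {
  rec <- data.frame(respondent_id = "r1", state = c("21111", "22222", "11111", "DEAD"),
                    vas_raw = c(60, 5, 100, 20))
  out <- rescale_individual(rec)
  v <- stats::setNames(out$vas_ind, out$state)
  expect_equal(unname(v["21111"]), (60 - 20) / 80)
  expect_equal(unname(v["11111"]), 1)
  expect_equal(unname(v["DEAD"]), 0)
  expect_lt(v["22222"], 0) # rated worse than dead, kept negative
  # formula cases
  rec2 <- data.frame(respondent_id = "a", state = c("21111", "31111", "11111", "DEAD"),
                     vas_raw = c(60, 5, 90, 10))
  v2 <- rescale_individual(rec2)
  expect_equal(v2$vas_ind[v2$state == "31111"], -0.0625)
  expect_equal(v2$vas_ind[v2$state == "21111"], 0.625)
})

test_that("individual rescaling is invariant to a joint affine re-coding of the raw scale", {
  set.seed(4)
  raw <- c(runif(6, 10, 90), 95, 2)
  rec <- data.frame(respondent_id = "r", state = c(green_states()[1:6], "11111", "DEAD"),
                    vas_raw = raw)
  # affine map y = a + b x applied to every rating leaves the ratio unchanged
  rec2 <- rec
  rec2$vas_raw <- (rec$vas_raw * 0.8) + 5
  expect_equal(rescale_individual(rec)$vas_ind, rescale_individual(rec2)$vas_ind)
})

test_that("respondents with non-positive anchor separation are excluded, missing anchors error", {
  rec <- rbind(tiny_records(),
               data.frame(respondent_id = "bad", set = "Green",
                          state = c("21111", "11111", "DEAD"),
                          vas_raw = c(50, 30, 60)))
  expect_warning(out <- rescale_individual(rec), "excluded 1 respondent")
  expect_equal(attr(out, "excluded"), "bad")
  expect_false("bad" %in% out$respondent_id)
  expect_error(
    rescale_individual(data.frame(respondent_id = "x", state = c("21111", "11111"),
                                  vas_raw = c(50, 90))),
    "lacks a rating for Dead")
})

test_that("aggregate rescaling matches the anchor transformation and rejects degenerate anchors", {
  expect_equal(rescale_aggregate(73.1, 1.5, 97.5), (73.1 - 1.5) / 96)
  expect_equal(rescale_aggregate(1.5, 1.5, 97.5), 0)
  expect_equal(rescale_aggregate(97.5, 1.5, 97.5), 1)
  expect_error(rescale_aggregate(50, 90, 10), "degenerate")
})

test_that("aggregate_table reports per-set and pooled rows with n-1 standard deviations", {
  tab <- aggregate_table(tiny_records())
  r <- tab[tab$state == "22222", ]
  expect_equal(r$n, 2L)
  expect_equal(r$raw_mean, 50)
  expect_equal(r$raw_sd, stats::sd(c(55, 45)))
  # every respondent's 11111 maps to exactly 1
  expect_equal(tab$ind_mean[tab$state == "11111"], 1)
  expect_equal(tab$ind_sd[tab$state == "11111"], 0)
  expect_equal(tab$ind_mean[tab$state == "DEAD"], 0)
  # two-arm pooling: shared states appear once as Both with summed n
  cfg <- noiseless_config(n_green = 3, n_blue = 4, ranking_noise = 0)
  st <- simulate_study(cfg, seed = 1)
  tab2 <- aggregate_table(st)
  both <- tab2[tab2$set == "Both", ]
  expect_setequal(both$state, c("11111", "33333", "DEAD"))
  expect_equal(both$n[both$state == "11111"], 7L)
  expect_equal(sum(tab2$set == "Green"), 18)
  expect_equal(sum(tab2$set == "Blue"), 18)
})

test_that("simulated state means converge to the generating values", {
  cfg <- sim_config(n_green = 1200, n_blue = 1200, ranking_noise = 0)
  st <- simulate_study(cfg, seed = 99)
  tab <- suppressWarnings(aggregate_table(st))
  u <- eqvas:::latent_values(cfg, tab$state)
  mid <- tab$ind_mean > 0.25 & tab$ind_mean < 0.8 # away from the truncation ends
  expect_lt(max(abs(tab$ind_mean[mid] - u[mid])), 0.02)
})

test_that("dependent variable follows the six model conventions", {
  expect_equal(dependent_variable(73.1, 1), 26.9)
  expect_equal(dependent_variable(73.1, 2), 73.1)
  expect_equal(dependent_variable(0.7404, 4), 0.7404)
  expect_equal(dependent_variable(1.0, 5), 0)
  expect_equal(dependent_variable(0.3, 3), 0.7)
  expect_error(dependent_variable(0.5, 7), "model_id")
})
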