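test_that("simulation is reproducible and respects the design bookkeeping", {
  b1 <- small_bws(n = 20, seed = 3)
  b2 <- small_bws(n = 20, seed = 3)
  expect_identical(b1, b2)
  expect_false(identical(b1, small_bws(n = 20, seed = 4)))
  # 20 respondents x 8 profiles x (7+6+5+4) alternative rows
  expect_equal(nrow(b1), 20 * 8 * 22)
  # one chosen per case; chosen domains distinct within a profile valuation
  key <- paste(b1$respondent, b1$profile, b1$stage)
  expect_true(all(tapply(b1$chosen, key, sum) == 1))
  ch <- b1[b1$chosen == 1L, ]
  expect_true(all(tapply(ch$domain, paste(ch$respondent, ch$profile),
                         anyDuplicated) == 0))
})

test_that("with equal utilities every item is chosen best at rate ~ 1/7", {
  cfg <- simulation_config(n_respondents = 600,
                           true_params = utility_params(rep(0, 7), rep(0, 20)),
                           seed = 5)
  b <- simulate_bws_dataset(cfg, bws_design(seed = 5))
  ch <- b[b$stage == "best" & b$chosen == 1L, ]
  freq <- table(factor(ch$domain, levels = 1:7)) / nrow(ch)
  expect_true(all(abs(freq - 1 / 7) < 0.02))
})

test_that("a dominant item is always best and never a worst-type choice", {
  pr <- utility_params(c(50, rep(0, 6)), rep(0, 20))
  cfg <- simulation_config(n_respondents = 50, true_params = pr, seed = 6)
  b <- simulate_bws_dataset(cfg, bws_design(seed = 6))
  ch <- b[b$chosen == 1L, ]
  expect_true(all(ch$domain[ch$stage == "best"] == 1))
  expect_false(any(ch$domain[ch$sense == -1L] == 1))
})

test_that("stage-1 choice frequencies match the logit closed form on a toy", {
  ti <- toy_instrument(3, 3)
  # one fixed profile "121": item utilities under these params
  pr <- utility_params(c(0.5, 0.2, -0.3), c(1, 0.6, 0, 0.3, 0.4),
                       instrument = ti)
  design <- structure(list(profiles = "121", blocks = list(1L),
                           instrument = ti, seed = 1L), class = "bws_design")
  cfg <- simulation_config(n_respondents = 4000, true_params = pr, seed = 9,
                           instrument = ti)
  b <- simulate_bws_dataset(cfg, design)
  U <- item_utilities(pr, ti)
  v <- U[cbind(1:3, c(1, 2, 1))]
  p_true <- exp(v) / sum(exp(v))
  ch <- b[b$stage == "best" & b$chosen == 1L, ]
  freq <- as.numeric(table(factor(ch$domain, levels = 1:3)) / nrow(ch))
  expect_true(all(abs(freq - p_true) < 0.025))
})

test_that("respondent heterogeneity persists across a respondent's cases", {
  pr <- utility_params(rep(0, 7), rep(0, 20), c(3, rep(0, 6)))
  cfg <- simulation_config(n_respondents = 200, true_params = pr, seed = 8)
  b <- simulate_bws_dataset(cfg, bws_design(seed = 8))
  eff <- attr(b, "respondent_effects")
  ch <- b[b$stage == "best" & b$chosen == 1L, ]
  picks <- tapply(ch$domain == 1, ch$respondent, mean)
  # respondents with a high realized domain-1 coefficient pick it best often
  hi <- eff[, 1] > 1
  lo <- eff[, 1] < -1
  expect_gt(mean(picks[hi]), mean(picks[lo]) + 0.3)
})

test_that("noiseless TTO simulation reproduces the anchored latent scores", {
  an <- anchor_model(0.0305, -0.0695)
  cfg <- simulation_config(n_tto_respondents = 40, tto_noise_sd = 0,
                           anchor = an, true_params = fixed_params(),
                           seed = 10)
  td <- tto_design(seed = 10)
  tto <- simulate_tto_dataset(cfg, td)
  truth <- pmin(1, pmax(-1, predict(
    an, latent_score(tto$state, fixed_params()))))
  expect_equal(tto$value, round(truth / 0.05) * 0.05, tolerance = 1e-12)
  # branch / years / value are mutually consistent
  expect_equal(tto$value, tto_value(tto$branch, tto$years))
  expect_true(all(tto$value >= -1 & tto$value <= 1))
  expect_true(all(tto$value[tto$branch == "conventional"] >= 0))
  expect_true(all(tto$value[tto$branch == "lead_time"] < 0))
})

test_that("an anchor at the floor sends every state to the lead-time branch", {
  cfg <- simulation_config(n_tto_respondents = 8, tto_noise_sd = 0,
                           anchor = anchor_model(0, -1),
                           true_params = fixed_params(), seed = 11)
  tto <- simulate_tto_dataset(cfg, tto_design(seed = 11))
  expect_true(all(tto$branch == "lead_time"))
  expect_true(all(tto$years == 0))
  expect_true(all(tto$value == -1))
})

test_that("noisy per-state means converge to the anchored truth", {
  an <- anchor_model(0.0305, -0.0695)
  cfg <- simulation_config(n_tto_respondents = 50 * 4, tto_noise_sd = 0.3,
                           anchor = an, true_params = fixed_params(),
                           seed = 12)
  td <- tto_design(seed = 12)
  tto <- simulate_tto_dataset(cfg, td)
  ss <- summarize_states(tto)
  truth <- pmin(1, pmax(-1, predict(an, latent_score(ss$state,
                                                     fixed_params()))))
  # 50 responses per state, sd 0.3 => Monte-Carlo error ~ 0.04; clamping at
  # the top can shift means slightly further
  expect_true(all(abs(ss$mean - truth) < 0.15))
  expect_lt(mean(abs(ss$mean - truth)), 0.05)
})

test_that("response-time model hits its median, fraction and positivity", {
  expect_equal(simulate_response_times(5, median_minutes = 10, sdlog = 0),
               rep(10, 5))
  med <- response_time_median_for_fraction(0.2)
  t <- simulate_response_times(20000, median_minutes = med, seed = 13)
  expect_true(all(t > 0))
  expect_equal(mean(t < 4.5), 0.2, tolerance = 0.05)
  qc <- qc_filter(t)
  expect_equal(qc$n_excluded / length(t), 0.2, tolerance = 0.05)
})
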