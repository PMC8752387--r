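test_that("anchor fitting recovers exact linear relationships", {
  x <- c(1, 2, 5, 9, 12)
  y <- 0.03 * x - 0.07
  f_ols <- fit_anchor(x, y, method = "ols")
  expect_equal(f_ols$slope, 0.03, tolerance = 1e-12)
  expect_equal(f_ols$intercept, -0.07, tolerance = 1e-12)
  expect_equal(f_ols$r_squared, 1)
  expect_equal(f_ols$mse, 0, tolerance = 1e-20)
  f_anc <- fit_anchor(x, y, anchor_point = c(20, 0.03 * 20 - 0.07))
  expect_equal(f_anc$slope, 0.03, tolerance = 1e-12)
  expect_equal(predict(f_anc, c(0, 10)), c(-0.07, 0.23), tolerance = 1e-12)

  # constant response: zero slope, zero R2
  f0 <- fit_anchor(x, rep(0.4, 5), method = "ols")
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(f0$r_squared, 0)

  expect_error(fit_anchor(rep(1, 5), y[1:5]), "all equal")
  expect_error(fit_anchor(x[1:2], y[1:2]), "at least 3")
  expect_error(fit_anchor(x, y, method = "anchored"), "anchor_point")
})

test_that("the published line is reproduced from the published tables", {
  bws <- latent_score(fx$tto$state, fx$params)
  an <- fit_anchor(bws, fx$tto$mean,
                   anchor_point = c(latent_score("1111111", fx$params), 1))
  expect_equal(an$slope, 0.0305, tolerance = 2e-3)
  expect_equal(an$intercept, -0.0695, tolerance = 5e-3)
  # its root-mean-square error is the published 0.09 at printed precision
  expect_equal(round(an$rmse, 2), 0.09)
  # and the squared correlation matches the published correlation of 0.96
  expect_equal(round(sqrt(an$r_squared), 2), 0.96)
})

test_that("tariff construction maps item utilities through the anchor", {
  zero <- build_tariff(utility_params(rep(0, 7), rep(0, 20)),
                       anchor_model(0.0305, -0.0695))
  expect_true(all(zero$weights == 0))

  ta <- build_tariff(fx$params, anchor_model(0.0305, -0.0695))
  expect_equal(unname(ta$weights[1, 1]), 0.173) # 0.0305 * (0.908 + 4.764)
  expect_equal(unname(ta$weights[6, 4]), 0)     # reference item, any params
  expect_equal(ta$intercept, -0.07)             # rounded -0.0695
  # the unrounded anchored slope reproduces every published cell
  an <- fit_anchor(latent_score(fx$tto$state, fx$params), fx$tto$mean,
                   anchor_point = c(latent_score("1111111", fx$params), 1))
  ta2 <- build_tariff(fx$params, an)
  expect_equal(unname(ta2$weights), unname(fx$tariff$weights))
  expect_equal(ta2$intercept, fx$tariff$intercept)
  # unrounded mode keeps the pipeline values
  ta3 <- build_tariff(fx$params, an, rounding = NULL)
  expect_equal(unname(ta3$weights[1, 1]), an$slope * (0.908 + 4.764),
               tolerance = 1e-12)
})

test_that("state scoring reproduces the published worked examples", {
  expect_equal(unname(score_state("2234134", fx$tariff)), 0.486,
               tolerance = 1e-12)
  expect_equal(round(unname(score_state("4444444", fx$tariff)), 2), 0.02)
  expect_equal(unname(score_state("1111111", fx$tariff)), 1) # full-state rule
  # without the rule, the intercept applies everywhere
  free <- fx$tariff
  free$full_state_rule <- FALSE
  expect_equal(unname(score_state("1111111", free)),
               sum(fx$tariff$weights[, 1]) + fx$tariff$intercept)
})

test_that("tariff weights and scored utilities are monotone in severity", {
  for (ta in list(fx$tariff,
                  build_tariff(fx$params, anchor_model(0.0305, -0.0695)))) {
    expect_true(all(apply(ta$weights, 1, function(w) all(diff(w) <= 0))))
    set.seed(33)
    for (i in 1:25) {
      s <- sample(1:4, 7, replace = TRUE)
      p <- sample(7, 1)
      if (s[p] == 1) next
      better <- s; better[p] <- s[p] - 1L
      expect_gte(score_state(format_state(better), ta),
                 score_state(format_state(s), ta))
    }
  }
})

test_that("the value set spans [worst-state utility, 1] over all states", {
  u <- score_state(enumerate_states(inst), fx$tariff)
  expect_equal(max(u), 1)
  expect_equal(names(which.max(u)), "1111111")
  expect_equal(unname(min(u)), unname(score_state("4444444", fx$tariff)))
  expect_equal(names(which.min(u)), "4444444")
})

test_that("noiseless synthetic anchoring recovers the generating line", {
  truth <- anchor_model(0.028, -0.05)
  states <- fx$tto$state
  bws <- latent_score(states, fixed_params())
  tto <- predict(truth, bws)
  f <- fit_anchor(bws, tto, method = "ols")
  expect_equal(f$slope, truth$slope, tolerance = 1e-12)
  expect_equal(f$intercept, truth$intercept, tolerance = 1e-12)
})

test_that("batch scoring preserves order and collects malformed rows", {
  res <- score_dataset(c("2234134", "oops", "2234134", "1111119"), fx$tariff)
  expect_equal(nrow(res), 4)
  expect_equal(res$utility[c(1, 3)], rep(0.486, 2), tolerance = 1e-12)
  expect_equal(res$misery[1], 19L)
  expect_true(all(is.na(res$utility[c(2, 4)])))
  errs <- attr(res, "errors")
  expect_equal(errs$row, c(2L, 4L))
  expect_match(errs$message[2], "position 7")
  expect_equal(nrow(score_dataset(character(0), fx$tariff)), 0)
})
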