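test_that("design rows carry signed covariates and exact bookkeeping", {
  b <- small_bws(n = 10, seed = 21)
  rows <- build_design_rows(b)
  expect_equal(rows$n_rows, 10 * 8 * 22)
  expect_equal(rows$n_cases, 10 * 8 * 4)
  X <- design_matrix(rows)
  # a best-stage alternative (2,1) loads +1 on b2 and b21; worst-stage -1
  best21 <- which(b$stage == "best" & b$domain == 2 & b$level == 1)
  ord <- order(match(b$respondent, unique(b$respondent)))
  stopifnot(identical(ord, seq_len(nrow(b)))) # rows already respondent-sorted
  if (length(best21)) {
    r <- best21[1]
    expect_equal(unname(X[r, c("b2", "b21")]), c(1, 1))
    expect_equal(sum(X[r, ] != 0), 2)
  }
  worst21 <- which(b$sense == -1L & b$domain == 2 & b$level == 1)
  if (length(worst21))
    expect_equal(unname(X[worst21[1], c("b2", "b21")]), c(-1, -1))
  # reference-item rows are all zero regardless of stage
  ref <- which(b$domain == 6 & b$level == 4)
  if (length(ref)) expect_true(all(X[ref, ] == 0))

  expect_error(build_design_rows(b[, -match("sense", names(b))]),
               "missing column\\(s\\): sense")
  degen <- explode_profile("2234134", 1, 2, 3, 4)
  degen <- degen[degen$stage == "best", ][1, ]
  expect_error(build_design_rows(degen), "fewer than 2 alternatives")
})

test_that("MNL log-likelihood matches closed forms and a brute-force oracle", {
  b <- small_bws(n = 4, seed = 22)
  rows <- build_design_rows(b)
  # zero parameters: every case contributes log(1/k)
  expect_equal(mnl_loglik(numeric(27), rows),
               -4 * 8 * sum(log(7:4)), tolerance = 1e-12)
  # two identical alternatives: log(1/2)
  two <- data.frame(respondent = 1, state = "1111111", stage = "best",
                    domain = c(1, 1), level = c(1, 1), chosen = c(1, 0),
                    sense = 1)
  expect_equal(mnl_loglik(runif(27), build_design_rows(two)), log(0.5))
  # random parameter vectors against direct softmax enumeration
  set.seed(23)
  for (i in 1:10) {
    beta <- rnorm(27, sd = 0.7)
    expect_equal(mnl_loglik(beta, rows), brute_force_mnl(beta, rows),
                 tolerance = 1e-10)
  }
})

test_that("likelihood kernel gradient matches central differences", {
  b <- small_bws(n = 5, seed = 24)
  rows <- build_design_rows(b)
  eta <- halton_normal_draws(rows$n_respondents, 8, 7, seed = 1)
  theta <- c(rnorm(27, sd = 0.5), abs(rnorm(7, sd = 0.3)))
  ll <- function(th) mixl_loglik(params_of(th, inst), rows, eta = eta)
  res <- ascotcarer:::.exploded_loglik_cpp(
    theta, rows$dom, rows$lvl, rows$sgn, rows$case, rows$resp, rows$chosen,
    eta, rows$n_respondents, 8L, 7L, 20L, TRUE)
  num <- vapply(seq_along(theta), function(k) {
    h <- 1e-5
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (ll(tp) - ll(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(as.numeric(res$gradient), num, tolerance = 1e-5)
  expect_equal(res$loglik, ll(theta), tolerance = 1e-10)
})

test_that("simulated likelihood collapses to the MNL when scales are zero", {
  b <- small_bws(n = 6, seed = 25)
  rows <- build_design_rows(b)
  pr <- utility_params(fx$params$dom_mean, fx$params$lvl, rep(0, 7))
  for (nd in c(1, 7, 40))
    expect_equal(mixl_loglik(pr, rows, n_draws = nd, seed = 2),
                 mnl_loglik(pr, rows), tolerance = 1e-12)
  expect_error(mixl_loglik(pr, rows, n_draws = 0), "at least 1")
})

test_that("simulated likelihood agrees with direct quadrature on one case", {
  one <- explode_profile("1234321", 6, 4, 1, 2, respondent = 1)
  one <- one[one$stage == "best", ]
  rows <- build_design_rows(one)
  pr <- utility_params(fx$params$dom_mean, fx$params$lvl,
                       c(rep(0, 5), 1.2, 0)) # one random coefficient
  U <- item_utilities(utility_params(fx$params$dom_mean, fx$params$lvl), inst)
  lv <- unname(parse_state("1234321"))
  v <- U[cbind(1:7, lv)]
  # chosen = domain 6 at level 2: its utility shifts by 1.2 * eta
  prob <- function(e) {
    vv <- v
    vv[6] <- vv[6] + 1.2 * e
    1 / sum(exp(vv - vv[6])) # numerically stable softmax of the chosen item
  }
  oracle <- log(stats::integrate(function(e)
    vapply(e, prob, numeric(1)) * stats::dnorm(e), -Inf, Inf,
    rel.tol = 1e-10)$value)
  sim <- mixl_loglik(pr, rows, n_draws = 3000, seed = 3)
  expect_equal(sim, oracle, tolerance = 2e-3)
  # doubling draws barely moves the simulated value
  expect_lt(abs(mixl_loglik(pr, rows, n_draws = 2000, seed = 3) - sim), 5e-3)
})

test_that("per-case choice probabilities are a proper distribution", {
  b <- small_bws(n = 3, seed = 26)
  rows <- build_design_rows(b)
  X <- design_matrix(rows)
  set.seed(27)
  for (i in 1:5) {
    V <- drop(X %*% rnorm(27))
    pr <- unlist(lapply(split(V, rows$case), function(v) exp(v) / sum(exp(v))),
                 use.names = FALSE)
    expect_equal(unname(rowsum(pr, rows$case)[, 1]),
                 rep(1, rows$n_cases), tolerance = 1e-12)
    # adding a constant within each case leaves the likelihood unchanged
    shift <- stats::ave(numeric(rows$n_rows), rows$case,
                        FUN = function(z) rnorm(1))
    p2 <- unlist(lapply(split(V + shift, rows$case),
                        function(v) exp(v) / sum(exp(v))), use.names = FALSE)
    expect_equal(pr, p2, tolerance = 1e-12)
  }
})

test_that("MNL estimation recovers fixed-coefficient truth", {
  cfg <- simulation_config(n_respondents = 250, true_params = fixed_params(),
                           seed = 28)
  b <- simulate_bws_dataset(cfg, bws_design(seed = 28))
  fit <- fit_mnl(b)
  expect_true(fit$converged)
  truth <- c(fx$params$dom_mean, fx$params$lvl)
  est <- c(fit$params$dom_mean, fit$params$lvl)
  se <- c(fit$se$dom_mean, fit$se$lvl)
  expect_true(all(abs(est - truth) < 3 * se))
  expect_true(all(se > 0))
  # duplicating the dataset halves the variance: SE ratio ~ 1/sqrt(2)
  b2 <- b
  b2$respondent <- b2$respondent + max(b$respondent)
  fit2 <- fit_mnl(rbind(b, b2))
  expect_equal(max(abs(c(fit2$params$dom_mean, fit2$params$lvl) - est)), 0,
               tolerance = 1e-4)
  ratio <- c(fit2$se$dom_mean, fit2$se$lvl) / se
  expect_equal(unname(ratio), rep(1 / sqrt(2), 27), tolerance = 0.01)
})

test_that("uniform-random choices give near-zero estimates", {
  cfg <- simulation_config(n_respondents = 250,
                           true_params = utility_params(rep(0, 7), rep(0, 20)),
                           seed = 29)
  b <- simulate_bws_dataset(cfg, bws_design(seed = 29))
  fit <- fit_mnl(b)
  z <- c(fit$params$dom_mean, fit$params$lvl) /
    c(fit$se$dom_mean, fit$se$lvl)
  expect_true(all(abs(z) < 3.5))
  # estimates are noise around zero, on the scale of their standard errors
  expect_lt(mean(abs(c(fit$params$dom_mean, fit$params$lvl))),
            2 * mean(c(fit$se$dom_mean, fit$se$lvl)))
})

test_that("mixed-logit fitting is deterministic given seed and shrinks
           absent heterogeneity", {
  cfg <- simulation_config(n_respondents = 80, true_params = fixed_params(),
                           seed = 30)
  b <- simulate_bws_dataset(cfg, bws_design(seed = 30))
  f1 <- fit_mixl(b, n_draws = 25, seed = 4, se = FALSE)
  f2 <- fit_mixl(b, n_draws = 25, seed = 4, se = FALSE)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(all(f1$params$dom_sd >= 0))
  # truth has no heterogeneity: estimated scales stay small
  expect_lt(max(f1$params$dom_sd), 0.4)
  expect_gt(f1$loglik, fit_mnl(b)$loglik - 0.5)
})

test_that("scrambled Halton draws are low-discrepancy standard normals", {
  h <- halton_matrix(6, 2, skip = 0)
  expect_equal(h[, 1], c(1/2, 1/4, 3/4, 1/8, 5/8, 3/8))
  expect_equal(h[, 2], c(1/3, 2/3, 1/9, 4/9, 7/9, 2/9))
  z <- halton_normal_draws(10, 50, 7, seed = 5)
  expect_equal(dim(z), c(500, 7))
  expect_identical(z, halton_normal_draws(10, 50, 7, seed = 5))
  expect_false(identical(z, halton_normal_draws(10, 50, 7, seed = 6)))
  expect_true(all(abs(colMeans(z)) < 0.05))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 0.05))
})

test_that("QC filter applies a strict less-than threshold", {
  qc <- qc_filter(c(4.4, 4.5, 10.0))
  expect_equal(qc$excluded$minutes, 4.4)
  expect_equal(qc$included$minutes, c(4.5, 10.0))
  expect_equal(qc_filter(numeric(0))$n_included, 0)
  expect_equal(qc_filter(numeric(0))$n_excluded, 0)
  expect_equal(qc_filter(c(5, 6))$n_excluded, 0)
  qc2 <- qc_filter(data.frame(respondent = 1:3, minutes = c(NA, 2, 9)))
  expect_equal(qc2$excluded$reason, c("missing_time", "too_fast"))
  expect_equal(qc2$included$respondent, 3L)
})
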