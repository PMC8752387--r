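#' Build the signed design structure from exploded choice cases
#'
#' Each (case, alternative) row gets the item's covariate vector multiplied
#' by the case's sense (+1 best-type, -1 worst-type), the coding under which
#' best and worst selections are pooled in one conditional-logit likelihood.
#' Rows are sorted by respondent and case; every case must have one chosen
#' alternative and at least two alternatives.
#'
#' @param cases data.frame in the long format of [simulate_bws_dataset()] /
#'   [explode_profile()]: columns `respondent`, `state` (and optionally
#'   `profile`), `stage`, `domain`, `level`, `chosen`, `sense`.
#' @param instrument a `bws_instrument`.
#' @return An object of class `bws_rows` holding 0-based index vectors for
#'   the likelihood kernel plus bookkeeping counts (`n_rows`, `n_cases`,
#'   `n_respondents`).
#' @export
build_design_rows <- function(cases, instrument = ascot_carer()) {
  need <- c("respondent", "state", "stage", "domain", "level", "chosen",
            "sense")
  miss <- setdiff(need, names(cases))
  if (length(miss)) stop("cases table is missing column(s): ",
                         paste(miss, collapse = ", "))
  prof <- if ("profile" %in% names(cases)) cases$profile else cases$state
  key <- paste(cases$respondent, prof, cases$stage, sep = "\r")
  ord <- order(match(cases$respondent, unique(cases$respondent)),
               match(key, unique(key)))
  cases <- cases[ord, , drop = FALSE]
  key <- key[ord]
  case_id <- match(key, unique(key)) - 1L
  resp_f <- match(cases$respondent, unique(cases$respondent)) - 1L
  resp_of_case <- resp_f[!duplicated(case_id)]

  sizes <- tabulate(case_id + 1L)
  if (any(sizes < 2L))
    stop(sum(sizes < 2L), " case(s) have fewer than 2 alternatives")
  nch <- rowsum(as.integer(cases$chosen), case_id)
  if (any(nch != 1L))
    stop("every case must have exactly one chosen alternative")
  if (!all(cases$sense %in% c(-1L, 1L)))
    stop("sense must be +1 or -1")

  P <- instrument$n_domains
  dom <- as.integer(cases$domain)
  lvl <- as.integer(cases$level)
  if (any(dom < 1L | dom > P)) stop("domain index out of range")
  if (any(lvl < 1L | lvl > instrument$n_levels)) stop("level out of range")
  dom_idx <- dom - 1L
  is_ref <- dom == instrument$reference[1] & lvl == instrument$reference[2]
  dom_idx[is_ref] <- -1L
  li <- instrument$lvl_index[cbind(dom, lvl)]
  lvl_idx <- ifelse(is.na(li), -1L, li - 1L)

  structure(list(dom = dom_idx, lvl = as.integer(lvl_idx),
                 sgn = as.integer(cases$sense),
                 case = case_id, resp = resp_f,
                 chosen = as.integer(cases$chosen),
                 n_rows = nrow(cases),
                 n_cases = length(unique(case_id)),
                 n_respondents = length(unique(resp_f)),
                 resp_of_case = resp_of_case,
                 instrument = instrument),
            class = "bws_rows")
}

#' @export
print.bws_rows <- function(x, ...) {
  cat("exploded BWS data:", x$n_rows, "alternative rows,", x$n_cases,
      "cases,", x$n_respondents, "respondents\n")
  invisible(x)
}

#' Dense signed design matrix of exploded rows
#'
#' @param rows a `bws_rows`.
#' @return Numeric matrix, one row per alternative, one column per mean/fixed
#'   utility parameter (`param_names()` order); rows of worst-type cases are
#'   negated.
#' @export
design_matrix <- function(rows) {
  inst <- rows$instrument
  P <- inst$n_domains
  X <- matrix(0, rows$n_rows, inst$n_params,
              dimnames = list(NULL, param_names(inst)))
  hd <- rows$dom >= 0L
  X[cbind(which(hd), rows$dom[hd] + 1L)] <- rows$sgn[hd]
  hl <- rows$lvl >= 0L
  X[cbind(which(hl), P + rows$lvl[hl] + 1L)] <- rows$sgn[hl]
  X
}

theta_of <- function(params) c(params$dom_mean, params$lvl, params$dom_sd)

params_of <- function(theta, instrument) {
  P <- instrument$n_domains; K <- instrument$n_lvl_params
  utility_params(theta[seq_len(P)], theta[P + seq_len(K)],
                 theta[P + K + seq_len(P)], instrument)
}

zero_eta <- function(n_resp, P) matrix(0, n_resp, P)

#' Conditional-logit (MNL) log-likelihood of exploded cases
#'
#' Pure-R reference implementation: sum over cases of the chosen
#' alternative's log softmax probability, with per-case max subtraction so
#' the value is finite for any finite parameters. Heterogeneity scales in
#' `params` are ignored (the MNL treats all responses as independent).
#'
#' @param params a `utility_params` (or bare numeric vector of the
#'   mean/fixed parameters in `param_names()` order).
#' @param rows a `bws_rows`.
#' @return The log-likelihood (scalar).
#' @export
mnl_loglik <- function(params, rows) {
  inst <- rows$instrument
  beta <- if (inherits(params, "utility_params"))
    c(params$dom_mean, params$lvl) else as.numeric(params)
  stopifnot(length(beta) == inst$n_params)
  P <- inst$n_domains
  V <- numeric(rows$n_rows)
  hd <- rows$dom >= 0L
  V[hd] <- beta[rows$dom[hd] + 1L]
  hl <- rows$lvl >= 0L
  V[hl] <- V[hl] + beta[P + rows$lvl[hl] + 1L]
  V <- V * rows$sgn
  g <- rows$case + 1L
  cmax <- vapply(split(V, g), max, numeric(1))
  lse <- cmax + log(drop(rowsum(exp(V - cmax[g]), g)))
  sum(V[rows$chosen == 1L]) - sum(lse)
}

#' Panel mixed-logit simulated log-likelihood
#'
#' Averages, per respondent and over draws of the random domain
#' coefficients, the product of logit probabilities of all the respondent's
#' cases, and sums the log averages. The same draw sequence serves all of a
#' respondent's cases (panel structure). With all heterogeneity scales zero
#' this equals [mnl_loglik()] exactly, for any number of draws.
#'
#' @param params a `utility_params`.
#' @param rows a `bws_rows`.
#' @param n_draws number of scrambled Halton draws per respondent (>= 1).
#' @param seed seed for the draw scrambling.
#' @param eta optional pre-built draw matrix (`n_respondents * n_draws` rows,
#'   `n_domains` columns), overriding `n_draws`/`seed`.
#' @return The simulated log-likelihood (scalar).
#' @export
mixl_loglik <- function(params, rows, n_draws = 100L, seed = 1L, eta = NULL) {
  inst <- rows$instrument
  if (is.null(eta)) {
    if (n_draws < 1L) stop("n_draws must be at least 1")
    eta <- halton_normal_draws(rows$n_respondents, n_draws, inst$n_domains,
                               seed)
  }
  n_draws <- nrow(eta) / rows$n_respondents
  res <- .exploded_loglik_cpp(theta_of(params), rows$dom, rows$lvl, rows$sgn,
                              rows$case, rows$resp, rows$chosen, eta,
                              rows$n_respondents, as.integer(n_draws),
                              inst$n_domains, inst$n_lvl_params, FALSE)
  res$loglik
}

#' Scrambled Halton draws mapped to the standard normal
#'
#' Low-discrepancy Halton points (one prime base per dimension, the first
#' 100 points skipped) with a seeded random-shift scrambling, transformed by
#' the normal quantile function. Respondent `j` uses rows
#' `(j-1)*n_draws + 1 .. j*n_draws`.
#'
#' @param n_resp,n_draws respondents and draws per respondent.
#' @param n_dim dimensions (random coefficients).
#' @param seed integer seed for the scrambling shift.
#' @param skip leading Halton points to discard.
#' @return Numeric matrix `(n_resp * n_draws) x n_dim`.
#' @export
halton_normal_draws <- function(n_resp, n_draws, n_dim, seed = 1L,
                                skip = 100L) {
  u <- halton_matrix(n_resp * n_draws, n_dim, skip = skip)
  shift <- with_seed(seed, stats::runif(n_dim))
  u <- sweep(u, 2L, shift, function(a, b) (a + b) %% 1)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

halton_primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L,
                   41L, 43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L,
                   89L, 97L)

# radical-inverse (van der Corput) sequence in the given base, vectorised
radical_inverse <- function(i, base) {
  out <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0L)) {
    out <- out + (i %% base) * f
    i <- i %/% base
    f <- f / base
  }
  out
}

#' @rdname halton_normal_draws
#' @param n number of points.
#' @export
halton_matrix <- function(n, n_dim, skip = 100L) {
  if (n_dim > length(halton_primes))
    stop("at most ", length(halton_primes), " dimensions supported")
  idx <- skip + seq_len(n)
  vapply(halton_primes[seq_len(n_dim)],
         function(b) radical_inverse(idx, b), numeric(n))
}

new_bws_fit <- function(params, se, loglik, rows, method, n_draws = NA_integer_,
                        seed = NA_integer_, converged = TRUE, vcov = NULL) {
  structure(list(params = params, se = se, loglik = loglik,
                 n_cases = rows$n_cases, n_observations = rows$n_rows,
                 n_respondents = rows$n_respondents,
                 method = method, n_draws = n_draws, seed = seed,
                 converged = converged, vcov = vcov,
                 instrument = rows$instrument),
            class = "bws_fit")
}

as_rows <- function(x, instrument) {
  if (inherits(x, "bws_rows")) x else build_design_rows(x, instrument)
}

#' Fit the conditional-logit (MNL) model
#'
#' Maximises the exploded conditional-logit likelihood by BFGS with analytic
#' gradients; standard errors come from the inverse observed information.
#' The result is deterministic given the data.
#'
#' @param cases a long-format cases data.frame or a prebuilt `bws_rows`.
#' @param instrument a `bws_instrument`.
#' @param start optional numeric start vector (defaults to zero).
#' @return A `bws_fit` with mean/fixed estimates (`dom_sd` all zero).
#' @export
fit_mnl <- function(cases, instrument = ascot_carer(), start = NULL) {
  rows <- as_rows(cases, instrument)
  inst <- rows$instrument
  K <- inst$n_params
  if (rows$n_cases < K)
    stop("need at least ", K, " cases to identify ", K, " parameters")
  eta <- zero_eta(rows$n_respondents, inst$n_domains)
  obj <- function(beta) {
    th <- c(beta, numeric(inst$n_domains))
    .exploded_loglik_cpp(th, rows$dom, rows$lvl, rows$sgn, rows$case,
                         rows$resp, rows$chosen, eta, rows$n_respondents,
                         1L, inst$n_domains, inst$n_lvl_params, TRUE)
  }
  fn <- function(beta) obj(beta)$loglik
  gr <- function(beta) obj(beta)$gradient[seq_len(K)]
  if (is.null(start)) start <- numeric(K)
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = 500L,
                                     reltol = 1e-10))
  beta <- opt$par
  converged <- opt$convergence == 0L
  if (any(abs(beta) > 15))
    warning("some coefficients diverged; possible separation in the choices")
  # observed information: sum_c [ sum_r p x x' - xbar xbar' ]
  X <- design_matrix(rows)
  V <- drop(X %*% beta)
  g <- rows$case + 1L
  cmax <- vapply(split(V, g), max, numeric(1))
  e <- exp(V - cmax[g])
  p <- e / drop(rowsum(e, g))[g]
  E <- rowsum(p * X, g)
  info <- crossprod(X * sqrt(p)) - crossprod(E)
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, K) else sqrt(pmax(diag(vcov), 0))
  P <- inst$n_domains
  params <- utility_params(beta[seq_len(P)], beta[-seq_len(P)],
                           numeric(P), inst)
  se_p <- list(dom_mean = stats::setNames(se[seq_len(P)],
                                          inst$dom_param_names),
               lvl = stats::setNames(se[-seq_len(P)], inst$lvl_param_names),
               dom_sd = stats::setNames(rep(NA_real_, P),
                                        paste0("sd", seq_len(P))))
  new_bws_fit(params, se_p, opt$value, rows, "mnl", converged = converged,
              vcov = vcov)
}

#' Fit the panel mixed-logit (MIXL) model by maximum simulated likelihood
#'
#' Domain coefficients are independent normal random coefficients; level
#' increments are fixed. The simulated likelihood uses `n_draws` scrambled
#' Halton draws per respondent (same draws for all of a respondent's cases)
#' and is maximised by BFGS with analytic gradients, starting from the MNL
#' solution with all heterogeneity scales at 0.1. Scales are reported as
#' absolute values (the likelihood is symmetric in their sign); near-zero
#' scales are left at the boundary. Standard errors come from the inverse
#' negative Hessian of the simulated log-likelihood (finite differences of
#' the analytic gradient).
#'
#' @param cases a long-format cases data.frame or a prebuilt `bws_rows`.
#' @param instrument a `bws_instrument`.
#' @param n_draws Halton draws per respondent (default 100).
#' @param seed seed for the draw scrambling.
#' @param start optional `utility_params` or numeric start vector of length
#'   `n_params + n_domains`.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param max_iter BFGS iteration cap.
#' @param se compute standard errors (default TRUE).
#' @return A `bws_fit`.
#' @export
fit_mixl <- function(cases, instrument = ascot_carer(), n_draws = 100L,
                     seed = 1L, start = NULL, reltol = 1e-6,
                     max_iter = 500L, se = TRUE) {
  rows <- as_rows(cases, instrument)
  inst <- rows$instrument
  P <- inst$n_domains; K <- inst$n_lvl_params
  if (n_draws < 1L) stop("n_draws must be at least 1")
  eta <- halton_normal_draws(rows$n_respondents, n_draws, P, seed)
  if (is.null(start)) {
    mnl <- fit_mnl(rows, inst)
    start <- c(mnl$params$dom_mean, mnl$params$lvl, rep(0.1, P))
  } else if (inherits(start, "utility_params")) {
    start <- theta_of(start)
  }
  stopifnot(length(start) == P + K + P)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- .exploded_loglik_cpp(theta, rows$dom, rows$lvl, rows$sgn,
                                        rows$case, rows$resp, rows$chosen,
                                        eta, rows$n_respondents,
                                        as.integer(n_draws), P, K, TRUE)
      cache$key <- key
    }
    cache$res
  }
  fn <- function(theta) evaluate(theta)$loglik
  gr <- function(theta) evaluate(theta)$gradient
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = max_iter,
                                     reltol = reltol))
  theta <- opt$par
  theta[P + K + seq_len(P)] <- abs(theta[P + K + seq_len(P)])
  converged <- opt$convergence == 0L
  if (!converged)
    warning("mixed-logit optimisation did not converge (code ",
            opt$convergence, ")")

  se_vec <- rep(NA_real_, 2 * P + K)
  vcov <- NULL
  if (se) {
    h <- 1e-4 * (abs(theta) + 1e-3)
    H <- matrix(NA_real_, 2 * P + K, 2 * P + K)
    for (k in seq_along(theta)) {
      tp <- theta; tp[k] <- tp[k] + h[k]
      tm <- theta; tm[k] <- tm[k] - h[k]
      H[, k] <- (gr(tp) - gr(tm)) / (2 * h[k])
    }
    H <- (H + t(H)) / 2
    vcov <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vcov)) se_vec <- sqrt(pmax(diag(vcov), 0))
  }
  params <- params_of(theta, inst)
  se_p <- list(dom_mean = stats::setNames(se_vec[seq_len(P)],
                                          inst$dom_param_names),
               lvl = stats::setNames(se_vec[P + seq_len(K)],
                                     inst$lvl_param_names),
               dom_sd = stats::setNames(se_vec[P + K + seq_len(P)],
                                        paste0("sd", seq_len(P))))
  new_bws_fit(params, se_p, opt$value, rows, "mixl", n_draws = n_draws,
              seed = seed, converged = converged, vcov = vcov)
}

#' @export
print.bws_fit <- function(x, digits = 3, ...) {
  inst <- x$instrument
  cat(toupper(x$method), "fit:",
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- coef_table(x)
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  print(tab, row.names = FALSE)
  cat("Number of respondents =", x$n_respondents, "\n")
  cat("Number of observations =", x$n_observations, "\n")
  cat("Number of cases =", x$n_cases, "\n")
  cat(if (x$method == "mixl") "Log simulated-likelihood =" else
    "Log-likelihood =", format(x$loglik, nsmall = 3), "\n")
  if (!is.na(x$n_draws)) cat("Halton draws =", x$n_draws, "\n")
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param x a `bws_fit`.
#' @return data.frame `parameter`, `domain`, `estimate`, `se` with rows
#'   `b1, SD(b1), ..., b11, ...` mirroring the usual published layout.
#' @export
coef_table <- function(x) {
  inst <- x$instrument
  P <- inst$n_domains
  rows <- list()
  for (p in seq_len(P)) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("b", p), domain = inst$domain_names[p],
      estimate = unname(x$params$dom_mean[p]),
      se = unname(x$se$dom_mean[p]), stringsAsFactors = FALSE)
    if (x$method == "mixl")
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste0("SD(b", p, ")"), domain = "",
        estimate = unname(x$params$dom_sd[p]),
        se = unname(x$se$dom_sd[p]), stringsAsFactors = FALSE)
  }
  for (k in seq_len(inst$n_lvl_params))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = inst$lvl_param_names[k], domain = "",
      estimate = unname(x$params$lvl[k]), se = unname(x$se$lvl[k]),
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Exclude respondents who answered too fast
#'
#' Quality-control filter on total BWS response time: respondents strictly
#' under the threshold are excluded (a time of exactly the threshold is
#' retained); respondents with a missing time are excluded with reason
#' `"missing_time"`. Input order is preserved within each partition.
#'
#' @param times data.frame with columns `respondent` and `minutes`, or a
#'   bare numeric vector of minutes.
#' @param threshold_minutes exclusion threshold (default 4.5).
#' @return List with data.frames `included` and `excluded` (the latter with
#'   a `reason` column) and the two counts.
#' @export
qc_filter <- function(times, threshold_minutes = 4.5) {
  if (is.numeric(times) && is.null(dim(times)))
    times <- data.frame(respondent = seq_along(times), minutes = times)
  stopifnot(all(c("respondent", "minutes") %in% names(times)))
  missing_t <- is.na(times$minutes)
  too_fast <- !missing_t & times$minutes < threshold_minutes
  excl <- times[missing_t | too_fast, , drop = FALSE]
  excl$reason <- ifelse(is.na(excl$minutes), "missing_time", "too_fast")
  incl <- times[!(missing_t | too_fast), , drop = FALSE]
  rownames(incl) <- rownames(excl) <- NULL
  list(included = incl, excluded = excl,
       n_included = nrow(incl), n_excluded = nrow(excl))
}
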