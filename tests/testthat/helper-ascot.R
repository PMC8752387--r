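# shared fixtures and small builders for the test suite

fx <- load_fixtures()
inst <- ascot_carer()

toy_instrument <- function(P = 3L, L = 2L) {
  bws_instrument(paste0("dom", seq_len(P)), L, c(P, L))
}

# parameters with no heterogeneity, from the published means
fixed_params <- function() {
  utility_params(fx$params$dom_mean, fx$params$lvl, rep(0, 7))
}

# small simulated exploded dataset under the published truth
small_bws <- function(n = 40L, seed = 7L, params = fx$params) {
  cfg <- simulation_config(n_respondents = n, true_params = params,
                           seed = seed)
  simulate_bws_dataset(cfg, bws_design(seed = seed))
}

# brute-force conditional-logit log-likelihood: enumerate exp-utilities
# directly from the dense signed design matrix
brute_force_mnl <- function(beta, rows) {
  X <- design_matrix(rows)
  V <- drop(X %*% beta)
  ll <- 0
  for (cid in unique(rows$case)) {
    sel <- rows$case == cid
    pr <- exp(V[sel]) / sum(exp(V[sel]))
    ll <- ll + log(pr[rows$chosen[sel] == 1L])
  }
  ll
}
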