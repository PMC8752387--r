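#' Simulation settings for synthetic respondents
#'
#' Bundles everything the synthetic-data generator needs: the true utility
#' parameters (means, level increments and heterogeneity scales), the true
#' latent-to-TTO anchor, noise levels, sample sizes and the seed. Defaults
#' reproduce the conditions of the Japanese ASCOT-Carer valuation study:
#' 914 analysed BWS respondents each valuing one block of 8 profiles, 220
#' cTTO respondents each valuing one block of 8 states, the published
#' coefficient table as the true preference structure, and the published
#' anchor line (slope 0.0305, intercept -0.0695).
#'
#' @param n_respondents number of BWS respondents.
#' @param n_tto_respondents number of cTTO respondents.
#' @param true_params a `utility_params`; default: the packaged published
#'   coefficients (means, level increments and heterogeneity SDs).
#' @param anchor an `anchor_model` giving the true latent-to-TTO map.
#' @param tto_noise_sd additive normal noise on simulated TTO values, in
#'   utility units.
#' @param time_median_minutes,time_sdlog log-normal response-time model
#'   (median in minutes and log-scale SD); defaults calibrated to the
#'   reported BWS response-time distribution (median 8.5, mean 10.1 min).
#' @param seed integer seed governing every random draw.
#' @param instrument a `bws_instrument`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_respondents = 914L,
                              n_tto_respondents = 220L,
                              true_params = NULL,
                              anchor = anchor_model(0.0305, -0.0695),
                              tto_noise_sd = 0.3,
                              time_median_minutes = 8.5,
                              time_sdlog = 0.5866,
                              seed = 1L,
                              instrument = ascot_carer()) {
  if (is.null(true_params)) true_params <- load_fixtures(instrument)$params
  stopifnot(n_respondents >= 1L, tto_noise_sd >= 0,
            inherits(true_params, "utility_params"))
  structure(list(n_respondents = as.integer(n_respondents),
                 n_tto_respondents = as.integer(n_tto_respondents),
                 true_params = true_params, anchor = anchor,
                 tto_noise_sd = tto_noise_sd,
                 time_median_minutes = time_median_minutes,
                 time_sdlog = time_sdlog,
                 seed = as.integer(seed), instrument = instrument),
            class = "simulation_config")
}

# per-profile building blocks of realized item utility:
# u = lvl_part + dom_flag * beta_realized[domain]
profile_utility_parts <- function(states, params, instrument) {
  S <- as_state_matrix(states, instrument)
  P <- instrument$n_domains
  li <- instrument$lvl_index
  lvl_part <- matrix(0, nrow(S), P)
  dom_flag <- matrix(1, nrow(S), P)
  for (p in seq_len(P)) {
    ix <- li[p, S[, p]]
    lvl_part[, p] <- ifelse(is.na(ix), 0, params$lvl[ifelse(is.na(ix), 1L, ix)])
    if (p == instrument$reference[1])
      dom_flag[, p] <- as.numeric(S[, p] != instrument$reference[2])
  }
  list(S = S, lvl_part = lvl_part, dom_flag = dom_flag)
}

#' Simulate sequential best-worst responses
#'
#' Draws panel respondents under the random-utility model: each respondent's
#' domain coefficients are \eqn{\beta_p = \beta_p^m + \beta_p^s \eta} with
#' independent standard-normal \eqn{\eta} held fixed across all of the
#' respondent's choice cases, while every stage of every profile receives
#' fresh i.i.d. standard Gumbel shocks. Best-type stages select the
#' remaining item maximising \eqn{V + \epsilon}; worst-type stages maximise
#' \eqn{-V + \epsilon}; the selected item is removed before the next stage
#' (ties, possible only for degenerate parameters, go to the lowest domain
#' index). Each respondent is allocated one design block.
#'
#' @param config a `simulation_config`.
#' @param design a `bws_design`.
#' @return A data.frame of exploded choice cases in long format, one row per
#'   (case, alternative): `respondent`, `block`, `profile`, `state`, `stage`,
#'   `domain`, `level`, `chosen`, `sense`. The realized per-respondent domain
#'   coefficients are attached as attribute `"respondent_effects"`.
#' @export
simulate_bws_dataset <- function(config, design = bws_design(config$instrument,
                                                             seed = config$seed)) {
  inst <- config$instrument
  P <- inst$n_domains
  pr <- config$true_params
  with_seed(config$seed, {
    R <- config$n_respondents
    nb <- length(design$blocks)
    eta <- matrix(stats::rnorm(R * P), R, P)
    realized <- matrix(pr$dom_mean, R, P, byrow = TRUE) +
      matrix(pr$dom_sd, R, P, byrow = TRUE) * eta
    block_of <- sample(rep_len(seq_len(nb), R))
    # one row per respondent-profile valuation
    prof_idx <- unlist(design$blocks[block_of], use.names = FALSE)
    bsize <- lengths(design$blocks)[block_of]
    resp <- rep(seq_len(R), bsize)
    parts <- profile_utility_parts(design$profiles, pr, inst)
    nr <- length(prof_idx)
    V <- parts$lvl_part[prof_idx, , drop = FALSE] +
      parts$dom_flag[prof_idx, , drop = FALSE] * realized[resp, , drop = FALSE]
    lvmat <- parts$S[prof_idx, , drop = FALSE]
    avail <- matrix(TRUE, nr, P)
    n_stages <- n_stages_for(P)
    out <- vector("list", n_stages)
    for (s in seq_len(n_stages)) {
      sense <- stage_sense[[stage_levels[s]]]
      score <- sense * V + matrix(rgumbel(nr * P), nr, P)
      score[!avail] <- -Inf
      pick <- max.col(score, ties.method = "first")
      k <- P - s + 1L
      av_t <- t(avail)
      dom <- ((which(av_t) - 1L) %% P) + 1L
      row_idx <- rep(seq_len(nr), each = k)
      out[[s]] <- data.frame(
        respondent = resp[row_idx],
        block = block_of[resp[row_idx]],
        profile = prof_idx[row_idx],
        state = design$profiles[prof_idx[row_idx]],
        stage = stage_levels[s],
        domain = dom,
        level = lvmat[cbind(row_idx, dom)],
        chosen = as.integer(dom == pick[row_idx]),
        sense = sense,
        stringsAsFactors = FALSE)
      avail[cbind(seq_len(nr), pick)] <- FALSE
    }
    res <- do.call(rbind, out)
    ord <- order(res$respondent, res$profile,
                 match(res$stage, stage_levels), res$domain)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    # realized per-respondent domain coefficients (panel structure), for
    # diagnostics and tests
    attr(res, "respondent_effects") <- realized
    res
  })
}

# snap to the elicitation grid used by standard cTTO protocols
# (0.05 utility = half-year steps)
snap_tto <- function(v, grid = 0.05) round(v / grid) * grid

#' Simulate composite TTO indifference responses
#'
#' Each respondent is allocated one cTTO block and, for every state in it,
#' reports an indifference point: the true value is the anchor-mapped latent
#' score of the state plus normal noise, clamped to \[-1, 1\] and snapped to
#' the 0.05 utility grid (half-year steps). Non-negative values come from
#' the conventional branch (`years` = 10 v); negative values from the
#' lead-time branch (`years` = 10 (v + 1)).
#'
#' @param config a `simulation_config`.
#' @param design a `tto_design`.
#' @return A data.frame with columns `respondent`, `state`, `branch`,
#'   `years`, `value`.
#' @export
simulate_tto_dataset <- function(config, design = tto_design(
                                   instrument = config$instrument,
                                   seed = config$seed)) {
  inst <- config$instrument
  with_seed(config$seed + 1L, {
    R <- config$n_tto_respondents
    nb <- length(design$blocks)
    block_of <- ((seq_len(R) - 1L) %% nb) + 1L # round-robin: equal n per state
    states <- unlist(design$blocks[block_of], use.names = FALSE)
    resp <- rep(seq_len(R), lengths(design$blocks)[block_of])
    truth <- predict(config$anchor,
                     latent_score(design$unique_states, config$true_params,
                                  inst))
    v <- truth[match(states, design$unique_states)] +
      stats::rnorm(length(states), 0, config$tto_noise_sd)
    v <- snap_tto(pmin(1, pmax(-1, v)))
    branch <- ifelse(v >= 0, "conventional", "lead_time")
    years <- ifelse(v >= 0, 10 * v, 10 * (v + 1))
    data.frame(respondent = resp, state = states, branch = branch,
               years = years, value = v, stringsAsFactors = FALSE)
  })
}

#' Simulate BWS response times
#'
#' Log-normal total response times in minutes, used to exercise the
#' quality-control exclusion of too-fast respondents (see [qc_filter()]).
#'
#' @param n number of respondents.
#' @param median_minutes median total time in minutes.
#' @param sdlog log-scale standard deviation; 0 gives the median exactly for
#'   every respondent.
#' @param seed optional integer seed.
#' @return Numeric vector of positive times in minutes.
#' @export
simulate_response_times <- function(n, median_minutes = 8.5, sdlog = 0.5866,
                                    seed = NULL) {
  stopifnot(median_minutes > 0, sdlog >= 0)
  with_seed(seed, stats::rlnorm(n, meanlog = log(median_minutes), sdlog = sdlog))
}

#' Response-time median giving a target exclusion fraction
#'
#' Solves for the log-normal median such that a given fraction of simulated
#' respondents falls below the QC threshold.
#'
#' @param fraction target P(time < threshold).
#' @param threshold_minutes QC threshold (default 4.5 minutes).
#' @param sdlog log-scale standard deviation of the time model.
#' @return Median in minutes.
#' @export
response_time_median_for_fraction <- function(fraction,
                                              threshold_minutes = 4.5,
                                              sdlog = 0.5866) {
  stopifnot(fraction > 0, fraction < 1, sdlog > 0)
  exp(log(threshold_minutes) - stats::qnorm(fraction) * sdlog)
}
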