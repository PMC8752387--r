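#' Enumerate the full factorial of states
#'
#' @param instrument a `bws_instrument`.
#' @return Character vector of all `n_levels^n_domains` state strings in
#'   lexicographic order (`"1111111"` first, `"4444444"` last for the
#'   ASCOT-Carer).
#' @export
enumerate_states <- function(instrument = ascot_carer()) {
  P <- instrument$n_domains; L <- instrument$n_levels
  g <- expand.grid(rev(replicate(P, seq_len(L), simplify = FALSE)))[, P:1,
                                                                    drop = FALSE]
  format_state(as.matrix(g))
}

# two-way level co-occurrence counts for every ordered domain pair a < b,
# stored as a list of L x L matrices keyed "a:b"
cooccurrence_counts <- function(S, L) {
  P <- ncol(S)
  C <- list()
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P) {
    m <- matrix(0L, L, L)
    for (r in seq_len(nrow(S))) m[S[r, a], S[r, b]] <- m[S[r, a], S[r, b]] + 1L
    C[[paste(a, b, sep = ":")]] <- m
  }
  C
}

design_objective <- function(C, target) {
  sum(vapply(C, function(m) sum((m - target)^2), numeric(1)))
}

# objective change from swapping the column-p entries of rows r1 and r2,
# evaluated incrementally over the affected pairs only; applies the swap to
# (S, C) and returns the new state when apply = TRUE
swap_delta <- function(S, C, L, target, p, r1, r2) {
  v1 <- S[r1, p]; v2 <- S[r2, p]
  delta <- 0
  P <- ncol(S)
  for (b in seq_len(P)) {
    if (b == p) next
    a <- min(p, b); bb <- max(p, b)
    m <- C[[paste(a, bb, sep = ":")]]
    for (r in c(r1, r2)) {
      old_v <- S[r, p]; new_v <- if (r == r1) v2 else v1
      w <- S[r, b]
      io <- if (p < b) c(old_v, w) else c(w, old_v)
      im <- if (p < b) c(new_v, w) else c(w, new_v)
      co <- m[io[1], io[2]]; cm <- m[im[1], im[2]]
      delta <- delta - (co - target)^2 - (cm - target)^2 +
        (co - 1L - target)^2 + (cm + 1L - target)^2
      m[io[1], io[2]] <- co - 1L
      m[im[1], im[2]] <- cm + 1L
    }
    C[[paste(a, bb, sep = ":")]] <- m
  }
  S[c(r1, r2), p] <- c(v2, v1)
  list(delta = delta, S = S, C = C)
}

#' Select a balanced fractional-factorial profile set
#'
#' Draws `n` profiles with exact level balance (each level of each domain
#' appears exactly `n / n_levels` times) and near-orthogonal two-way
#' domain-level co-occurrence, by a seeded greedy exchange search: columns
#' start as random permutations of the balanced level multiset (so balance
#' holds by construction) and within-column swaps are accepted whenever they
#' reduce the summed squared deviation of all two-way co-occurrence tables
#' from proportionality.
#'
#' @param instrument a `bws_instrument`.
#' @param n number of profiles; must be divisible by `n_levels`.
#' @param seed integer seed; the search is deterministic given the seed.
#' @param max_sweeps maximum improvement sweeps.
#' @return Character vector of `n` distinct state strings.
#' @export
select_profiles <- function(instrument = ascot_carer(), n = 32L, seed = 1L,
                            max_sweeps = 30L) {
  P <- instrument$n_domains; L <- instrument$n_levels
  n <- as.integer(n)
  if (n %% L != 0L) stop("n must be divisible by the number of levels (", L, ")")
  if (n > L^P) stop("n exceeds the number of distinct states")
  with_seed(seed, {
    if (n == L^P) return(enumerate_states(instrument))
    target <- n / L^2
    S <- vapply(seq_len(P),
                function(p) sample(rep(seq_len(L), n / L)),
                integer(n))
    C <- cooccurrence_counts(S, L)
    optimize_once <- function(S, C) {
      for (sweep in seq_len(max_sweeps)) {
        improved <- FALSE
        for (p in seq_len(P)) {
          for (r1 in seq_len(n - 1L)) for (r2 in (r1 + 1L):n) {
            if (S[r1, p] == S[r2, p]) next
            sw <- swap_delta(S, C, L, target, p, r1, r2)
            if (sw$delta < -1e-9) {
              S <- sw$S; C <- sw$C; improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      list(S = S, C = C)
    }
    res <- optimize_once(S, C)
    S <- res$S; C <- res$C
    # rare: break up duplicated profiles with a random swap, then re-polish
    for (repair in seq_len(100L)) {
      dup <- which(duplicated(S))
      if (length(dup) == 0L) break
      r1 <- dup[1]
      p <- sample(P, 1L)
      r2 <- sample(which(S[, p] != S[r1, p]), 1L)
      # accept unconditionally: per-domain level balance is unaffected and
      # distinctness is the hard constraint here
      sw <- swap_delta(S, C, L, target, p, r1, r2)
      S <- sw$S; C <- sw$C
    }
    if (anyDuplicated(S))
      stop("profile search failed to produce distinct profiles; try another seed")
    format_state(S)
  })
}

#' Construct a blocked BWS design
#'
#' Selects `n_profiles` balanced profiles (see [select_profiles()]) and
#' partitions them into `n_blocks` blocks of equal size.
#'
#' @param instrument a `bws_instrument`.
#' @param n_profiles total number of profiles (default 32).
#' @param n_blocks number of blocks (default 4).
#' @param seed integer seed.
#' @return An object of class `bws_design` with elements `profiles`
#'   (character vector) and `blocks` (list of integer index vectors).
#' @export
bws_design <- function(instrument = ascot_carer(), n_profiles = 32L,
                       n_blocks = 4L, seed = 1L) {
  if (n_profiles %% n_blocks != 0L)
    stop("n_profiles must be divisible by n_blocks")
  profiles <- select_profiles(instrument, n_profiles, seed)
  blocks <- with_seed(seed + 1L, {
    idx <- sample(n_profiles)
    split(idx, rep(seq_len(n_blocks), each = n_profiles / n_blocks))
  })
  structure(list(profiles = profiles, blocks = unname(blocks),
                 instrument = instrument, seed = seed),
            class = "bws_design")
}

#' @export
print.bws_design <- function(x, ...) {
  cat("BWS design:", length(x$profiles), "profiles in",
      length(x$blocks), "blocks\n")
  invisible(x)
}

#' Construct the blocked cTTO design
#'
#' Allocates states to `n_blocks` blocks of `block_size`, with the worst
#' state (all domains at the worst level) appearing in exactly two blocks, so
#' that `n_blocks * block_size - 1` unique states are valued (31 for the
#' 4 x 8 layout).
#'
#' @param states character vector of `n_blocks * block_size - 1` distinct
#'   state strings that must include the worst state; if `NULL`, a balanced
#'   profile set is drawn with [select_profiles()] and the worst state is
#'   forced in.
#' @param instrument a `bws_instrument`.
#' @param seed integer seed for the block allocation.
#' @param n_blocks,block_size block layout (defaults 4 and 8).
#' @return An object of class `tto_design` with elements `blocks` (list of
#'   character vectors) and `unique_states`.
#' @export
tto_design <- function(states = NULL, instrument = ascot_carer(), seed = 1L,
                       n_blocks = 4L, block_size = 8L) {
  worst <- paste(rep(instrument$n_levels, instrument$n_domains), collapse = "")
  n_unique <- n_blocks * block_size - 1L
  if (is.null(states)) {
    cand <- select_profiles(instrument, n_unique + 1L, seed)
    if (!(worst %in% cand)) cand[length(cand)] <- worst
    states <- cand[cand != worst][seq_len(n_unique - 1L)]
    states <- c(states, worst)
  }
  states <- as.character(states)
  if (anyDuplicated(states)) stop("states must be distinct")
  if (length(states) != n_unique)
    stop("expected ", n_unique, " distinct states, got ", length(states))
  if (!(worst %in% states))
    stop("the worst state '", worst, "' must be among the TTO states")
  parse_states(states, instrument) # validates
  blocks <- with_seed(seed, {
    # the duplicated worst state goes into two distinct blocks
    worst_blocks <- sample(n_blocks, 2L)
    others <- sample(setdiff(states, worst))
    cap <- rep(block_size, n_blocks)
    cap[worst_blocks] <- cap[worst_blocks] - 1L
    alloc <- split(others, rep(seq_len(n_blocks), cap))
    lapply(seq_len(n_blocks), function(b)
      if (b %in% worst_blocks) c(alloc[[b]], worst) else alloc[[b]])
  })
  structure(list(blocks = blocks, unique_states = sort(unique(states)),
                 worst_state = worst, instrument = instrument),
            class = "tto_design")
}

#' @export
print.tto_design <- function(x, ...) {
  cat("cTTO design:", length(x$unique_states), "unique states in",
      length(x$blocks), "blocks (worst state duplicated)\n")
  invisible(x)
}

#' Explode one profile's sequential best-worst responses into choice cases
#'
#' A profile valuation is four sequential selections — best, worst, second
#' best, second worst — each over the domains not yet selected (the chosen
#' domain is removed before the next stage). Each selection becomes one
#' discrete-choice case; worst-type cases carry sense -1 so their covariate
#' rows are negated in estimation.
#'
#' @param state a state string or level vector.
#' @param best,worst,second_best,second_worst domain indices (1-based) of the
#'   selections; must be distinct. Instruments with fewer than five domains
#'   play fewer stages (a stage needs two remaining alternatives), in which
#'   case the later choices are omitted.
#' @param instrument a `bws_instrument`.
#' @param respondent,profile optional identifiers copied into the output.
#' @return A data.frame with one row per (case, alternative): columns
#'   `respondent`, `profile`, `state`, `stage`, `domain`, `level`, `chosen`,
#'   `sense`. For a 7-domain instrument the four cases contribute
#'   7 + 6 + 5 + 4 = 22 rows.
#' @export
explode_profile <- function(state, best, worst, second_best = NULL,
                            second_worst = NULL,
                            instrument = ascot_carer(),
                            respondent = NA_integer_, profile = NA_integer_) {
  lv <- drop(as_state_matrix(state, instrument))
  P <- instrument$n_domains
  choices <- c(best, worst, second_best, second_worst)
  n_stages <- n_stages_for(P)
  if (length(choices) != n_stages)
    stop("a ", P, "-domain profile needs ", n_stages, " stage choices")
  remaining <- seq_len(P)
  out <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    ch <- as.integer(choices[s])
    if (!(ch %in% remaining))
      stop("stage '", stage_levels[s], "': chosen domain ", ch,
           " is not among the remaining alternatives")
    out[[s]] <- data.frame(
      respondent = respondent, profile = profile,
      state = format_state(lv), stage = stage_levels[s],
      domain = remaining, level = lv[remaining],
      chosen = as.integer(remaining == ch),
      sense = stage_sense[[stage_levels[s]]],
      stringsAsFactors = FALSE, row.names = NULL)
    remaining <- setdiff(remaining, ch)
  }
  do.call(rbind, out)
}
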