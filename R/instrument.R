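#' Define a profile-case BWS instrument
#'
#' An instrument is a set of quality-of-life domains, each rated on an ordered
#' set of levels (level 1 best, the highest level worst). One item is the
#' global reference whose utility is fixed at zero for identification.
#'
#' The dummy-variable coding follows the usual convention for this class of
#' valuation models: every item (domain p, level q) has utility
#' \eqn{u(p,q) = \beta_p + \beta_{pq}}, where \eqn{\beta_p} is a domain main
#' effect and \eqn{\beta_{pq}} a level increment. Level dummies exist for
#' levels 1..L-1 of every domain (the worst level is absorbed into
#' \eqn{\beta_p}), except that the reference domain additionally drops the
#' dummy for level L-1, so that the reference item (reference domain, worst
#' level) has an all-zero covariate vector and utility exactly 0. For the
#' 7-domain, 4-level ASCOT-Carer this yields 7 + 20 = 27 mean/fixed
#' parameters.
#'
#' @param domain_names character vector of domain labels, in display order.
#' @param n_levels integer, number of response levels per domain (>= 2).
#' @param reference integer vector `c(domain, level)` identifying the
#'   reference item; the level must be the worst level `n_levels`.
#' @return An object of class `bws_instrument`.
#' @seealso [ascot_carer()] for the packaged 7-domain instrument.
#' @export
bws_instrument <- function(domain_names, n_levels = 4L,
                           reference = c(length(domain_names), n_levels)) {
  domain_names <- as.character(domain_names)
  P <- length(domain_names)
  L <- as.integer(n_levels)
  if (P < 2L) stop("an instrument needs at least 2 domains")
  if (L < 2L) stop("an instrument needs at least 2 levels per domain")
  if (anyDuplicated(domain_names)) stop("domain names must be unique")
  reference <- as.integer(reference)
  if (length(reference) != 2L || reference[1] < 1L || reference[1] > P)
    stop("reference must be c(domain, level) with a valid domain index")
  if (reference[2] != L)
    stop("the reference item must be the worst level (level ", L, ")")

  # level-dummy index per (domain, level); NA = no dummy for that cell
  lvl_index <- matrix(NA_integer_, nrow = P, ncol = L)
  k <- 0L
  lvl_names <- character(0)
  for (p in seq_len(P)) {
    q_max <- if (p == reference[1]) L - 2L else L - 1L
    for (q in seq_len(max(q_max, 0L))) {
      k <- k + 1L
      lvl_index[p, q] <- k
      lvl_names <- c(lvl_names, paste0("b", p, q))
    }
  }
  structure(
    list(
      domain_names = domain_names,
      n_domains = P,
      n_levels = L,
      reference = reference,
      n_lvl_params = k,
      n_params = P + k,
      lvl_index = lvl_index,
      dom_param_names = paste0("b", seq_len(P)),
      lvl_param_names = lvl_names
    ),
    class = "bws_instrument"
  )
}

#' The ASCOT-Carer instrument
#'
#' Seven social care-related quality-of-life domains for informal caregivers,
#' four levels each (level 1 best). The reference item is the fourth level of
#' "space and time to be yourself" (domain 6).
#'
#' @return A `bws_instrument` with 7 domains, 4 levels and 27 mean/fixed
#'   utility parameters.
#' @export
#' @examples
#' inst <- ascot_carer()
#' inst$n_params # 27
ascot_carer <- function() {
  bws_instrument(
    domain_names = c(
      "occupation",
      "control over daily life",
      "looking after yourself",
      "personal safety",
      "social participation and involvement",
      "space and time to be yourself",
      "feeling supported and encouraged"
    ),
    n_levels = 4L,
    reference = c(6L, 4L)
  )
}

#' @export
print.bws_instrument <- function(x, ...) {
  cat("BWS instrument:", x$n_domains, "domains x", x$n_levels, "levels\n")
  cat("  reference item: domain", x$reference[1],
      paste0("(", x$domain_names[x$reference[1]], "),"),
      "level", x$reference[2], "\n")
  cat("  mean/fixed utility parameters:", x$n_params, "\n")
  invisible(x)
}

#' Parameter names of an instrument's utility function
#'
#' @param instrument a `bws_instrument`.
#' @return Character vector: domain effects `b1..bP` followed by level
#'   increments `bpq` in the canonical order.
#' @export
param_names <- function(instrument) {
  c(instrument$dom_param_names, instrument$lvl_param_names)
}

#' Parse state strings
#'
#' A state is written as a string of level digits, one per domain in
#' instrument order, e.g. `"2234134"` for the 7-domain ASCOT-Carer.
#'
#' @param x character vector of state strings.
#' @param instrument a `bws_instrument`.
#' @return Integer matrix, one row per state, one column per domain; row
#'   names are the input strings.
#' @export
#' @examples
#' parse_states("2234134", ascot_carer())
parse_states <- function(x, instrument = ascot_carer()) {
  x <- as.character(x)
  P <- instrument$n_domains
  L <- instrument$n_levels
  bad_len <- nchar(x) != P
  if (any(bad_len))
    stop("state '", x[which(bad_len)[1]], "': expected ", P,
         " characters, got ", nchar(x[which(bad_len)[1]]))
  chars <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                  ncol = P, byrow = TRUE)
  digits <- suppressWarnings(matrix(as.integer(chars), ncol = P))
  bad <- is.na(digits) | digits < 1L | digits > L
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("state '", x[idx[1]], "': position ", idx[2], " has '",
         chars[idx[1], idx[2]], "', expected a digit in 1..", L)
  }
  rownames(digits) <- x
  digits
}

#' @rdname parse_states
#' @details `parse_state()` parses a single state and returns a bare integer
#'   vector of levels.
#' @export
parse_state <- function(x, instrument = ascot_carer()) {
  if (length(x) != 1L) stop("parse_state() takes a single state string")
  drop(parse_states(x, instrument))
}

#' Format level vectors as state strings
#'
#' Inverse of [parse_states()].
#'
#' @param levels integer vector (one state) or matrix (one row per state).
#' @return Character vector of digit strings.
#' @export
format_state <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1)
  apply(levels, 1, paste0, collapse = "")
}

# accept states as strings or a level matrix; always return a matrix
as_state_matrix <- function(states, instrument) {
  if (is.character(states)) return(parse_states(states, instrument))
  if (is.null(dim(states))) states <- matrix(as.integer(states), nrow = 1)
  storage.mode(states) <- "integer"
  if (ncol(states) != instrument$n_domains)
    stop("state matrix must have ", instrument$n_domains, " columns")
  if (any(states < 1L | states > instrument$n_levels))
    stop("state levels must lie in 1..", instrument$n_levels)
  states
}

#' Covariate vector of one item
#'
#' Encodes the identification constraints of the utility function: a domain
#' dummy for every item except the reference item, and a level dummy where
#' one exists (see [bws_instrument()]).
#'
#' @param domain,level integer item coordinates (1-based).
#' @param instrument a `bws_instrument`.
#' @return Named numeric vector of length `instrument$n_params`.
#' @export
#' @examples
#' v <- item_covariates(2, 1) # b2 = 1, b21 = 1, all else 0
#' v[v != 0]
item_covariates <- function(domain, level, instrument = ascot_carer()) {
  P <- instrument$n_domains
  L <- instrument$n_levels
  domain <- as.integer(domain); level <- as.integer(level)
  if (domain < 1L || domain > P) stop("invalid domain index: ", domain)
  if (level < 1L || level > L) stop("invalid level: ", level)
  v <- numeric(instrument$n_params)
  names(v) <- param_names(instrument)
  if (domain == instrument$reference[1] && level == L) return(v)
  v[domain] <- 1
  li <- instrument$lvl_index[domain, level]
  if (!is.na(li)) v[P + li] <- 1
  v
}

#' Covariate matrix over all items
#'
#' @param instrument a `bws_instrument`.
#' @return Numeric matrix with one row per item (domain-major order, row
#'   names `"d<p>l<q>"`) and one column per utility parameter.
#' @export
covariate_matrix <- function(instrument = ascot_carer()) {
  P <- instrument$n_domains; L <- instrument$n_levels
  rows <- lapply(seq_len(P), function(p)
    t(vapply(seq_len(L), function(q) item_covariates(p, q, instrument),
             numeric(instrument$n_params))))
  X <- do.call(rbind, rows)
  rownames(X) <- paste0("d", rep(seq_len(P), each = L), "l", rep(seq_len(L), P))
  X
}

#' Mean/fixed and heterogeneity parameters of the utility function
#'
#' @param dom_mean numeric vector of domain effects (`beta_p`, means of the
#'   random coefficients), length `n_domains`.
#' @param lvl numeric vector of fixed level increments (`beta_pq`) in the
#'   canonical order given by `param_names()`.
#' @param dom_sd numeric vector of heterogeneity scales (standard deviations
#'   of the random domain coefficients), non-negative; defaults to all zero
#'   (a fixed-coefficient model).
#' @param instrument a `bws_instrument`.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(dom_mean, lvl, dom_sd = NULL,
                           instrument = ascot_carer()) {
  P <- instrument$n_domains
  if (length(dom_mean) != P)
    stop("dom_mean must have length ", P)
  if (length(lvl) != instrument$n_lvl_params)
    stop("lvl must have length ", instrument$n_lvl_params)
  if (is.null(dom_sd)) dom_sd <- numeric(P)
  if (length(dom_sd) != P) stop("dom_sd must have length ", P)
  dom_sd <- abs(as.numeric(dom_sd))
  structure(
    list(dom_mean = stats::setNames(as.numeric(dom_mean),
                                    instrument$dom_param_names),
         lvl = stats::setNames(as.numeric(lvl), instrument$lvl_param_names),
         dom_sd = stats::setNames(dom_sd,
                                  paste0("sd", seq_len(P)))),
    class = "utility_params"
  )
}

#' @export
print.utility_params <- function(x, ...) {
  cat("utility parameters:", length(x$dom_mean), "domain effects,",
      length(x$lvl), "level increments\n")
  if (any(x$dom_sd > 0))
    cat("  random domain coefficients, sd range [",
        min(x$dom_sd), ", ", max(x$dom_sd), "]\n", sep = "")
  invisible(x)
}

#' Item utilities implied by a parameter set
#'
#' @param params a `utility_params`.
#' @param instrument a `bws_instrument`.
#' @return Numeric matrix `u[p, q]` of mean item utilities; the reference
#'   item is exactly 0.
#' @export
item_utilities <- function(params, instrument = ascot_carer()) {
  P <- instrument$n_domains; L <- instrument$n_levels
  U <- matrix(rep(params$dom_mean, L), nrow = P)
  li <- instrument$lvl_index
  add <- matrix(0, P, L)
  add[!is.na(li)] <- params$lvl[li[!is.na(li)]]
  U <- U + add
  U[instrument$reference[1], instrument$reference[2]] <- 0
  dimnames(U) <- list(instrument$domain_names,
                      paste0("level", seq_len(L)))
  U
}

#' Latent BWS score of states
#'
#' The sum over domains of mean item utilities \eqn{u(p, q_p)}; the quantity
#' that is later anchored onto the TTO scale.
#'
#' @param states character vector of state strings or an integer level matrix.
#' @param params a `utility_params`.
#' @param instrument a `bws_instrument`.
#' @return Numeric vector of latent scores, one per state.
#' @export
#' @examples
#' fx <- load_fixtures()
#' latent_score("4444444", fx$params) # 2.972
latent_score <- function(states, params, instrument = ascot_carer()) {
  S <- as_state_matrix(states, instrument)
  U <- item_utilities(params, instrument)
  P <- instrument$n_domains
  out <- numeric(nrow(S))
  for (p in seq_len(P)) out <- out + U[p, S[, p]]
  stats::setNames(out, rownames(S))
}

#' Misery score of states
#'
#' The sum of a state's level digits across domains: a crude severity index
#' (range 7..28 for the ASCOT-Carer).
#'
#' @inheritParams latent_score
#' @return Integer vector.
#' @export
misery_score <- function(states, instrument = ascot_carer()) {
  S <- as_state_matrix(states, instrument)
  stats::setNames(as.integer(rowSums(S)), rownames(S))
}
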