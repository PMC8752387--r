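#' Load the packaged published valuation tables
#'
#' The package ships, as plain-text fixtures, the published Japanese
#' ASCOT-Carer valuation results: the mixed-logit coefficient table (27
#' mean/fixed estimates plus 7 heterogeneity SDs, with standard errors),
#' the mean cTTO values of the 31 valued states, and the published tariff
#' (28 weights rounded to 3 decimals, intercept -0.069). Shape invariants
#' are validated at load time; a mismatch is a hard error because these
#' tables serve as test oracles.
#'
#' @param instrument a `bws_instrument`.
#' @return A list:
#' \describe{
#'   \item{params}{`utility_params` with the published means, level
#'     increments and heterogeneity SDs.}
#'   \item{se}{named list of standard errors in the same shapes.}
#'   \item{coefficients}{the raw coefficient data.frame.}
#'   \item{tto}{data.frame `state`, `n`, `mean` for the 31 valued states.}
#'   \item{tariff}{the published `ascot_tariff`.}
#'   \item{anchor}{the published anchor line (slope 0.0305, intercept
#'     -0.0695) as an `anchor_model`.}
#' }
#' @export
load_fixtures <- function(instrument = ascot_carer()) {
  path <- function(f) system.file("extdata", f, package = "ascotcarer",
                                  mustWork = TRUE)
  co <- utils::read.csv(path("japan_bws_coefficients.csv"),
                        stringsAsFactors = FALSE)
  tto <- utils::read.csv(path("japan_tto_values.csv"),
                         colClasses = c(state = "character"),
                         stringsAsFactors = FALSE)
  ta <- utils::read.csv(path("japan_tariff.csv"), stringsAsFactors = FALSE)

  P <- instrument$n_domains
  is_sd <- grepl("^sd", co$parameter)
  is_dom <- grepl("^b[0-9]$", co$parameter)
  is_lvl <- grepl("^b[0-9][0-9]$", co$parameter)
  if (sum(is_dom) != P || sum(is_lvl) != instrument$n_lvl_params)
    stop("coefficient fixture must hold ", instrument$n_params,
         " mean/fixed coefficients")
  if (sum(is_sd) != P)
    stop("coefficient fixture must hold ", P, " heterogeneity SDs")
  dm <- co$estimate[is_dom][order(co$domain[is_dom])]
  sd_ <- co$estimate[is_sd][order(co$domain[is_sd])]
  lv <- co[is_lvl, ]
  lv <- lv[order(lv$domain, lv$level), ]
  expect_names <- instrument$lvl_param_names
  if (!identical(paste0("b", lv$domain, lv$level), expect_names))
    stop("coefficient fixture level dummies do not match the instrument coding")
  params <- utility_params(dm, lv$estimate, sd_, instrument)
  se <- list(dom_mean = stats::setNames(co$se[is_dom][order(co$domain[is_dom])],
                                        instrument$dom_param_names),
             lvl = stats::setNames(lv$se, expect_names),
             dom_sd = stats::setNames(co$se[is_sd][order(co$domain[is_sd])],
                                      paste0("sd", seq_len(P))))

  worst <- paste(rep(instrument$n_levels, P), collapse = "")
  if (nrow(tto) != 31L) stop("TTO fixture must hold 31 states")
  if (anyDuplicated(tto$state)) stop("TTO fixture states must be unique")
  if (tto$n[tto$state == worst] != 110L)
    stop("TTO fixture worst state must pool n = 110")
  parse_states(tto$state, instrument)

  icpt_row <- ta$domain == "intercept"
  if (sum(icpt_row) != 1L) stop("tariff fixture needs exactly one intercept row")
  wrow <- ta[!icpt_row, ]
  if (nrow(wrow) != P * instrument$n_levels)
    stop("tariff fixture must hold ", P * instrument$n_levels, " weights")
  W <- matrix(NA_real_, P, instrument$n_levels)
  W[cbind(as.integer(wrow$domain), as.integer(wrow$level))] <- wrow$weight
  if (anyNA(W)) stop("tariff fixture is missing weight cells")
  if (W[instrument$reference[1], instrument$reference[2]] != 0)
    stop("tariff fixture reference-item weight must be 0")
  tariff <- new_tariff(W, ta$weight[icpt_row], instrument)

  list(params = params, se = se, coefficients = co, tto = tto,
       tariff = tariff, anchor = anchor_model(0.0305, -0.0695))
}

read_checked <- function(path, required, classes = NA, optional = character()) {
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = TRUE))
  if (!is.null(names(classes)))
    classes <- classes[names(classes) %in% hdr]
  if (length(classes) == 0L) classes <- NA
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra))
    warning("file '", path, "' has extra column(s), preserved: ",
            paste(extra, collapse = ", "))
  df
}

#' Read and write long-format BWS choice tables
#'
#' Comma-delimited UTF-8 CSV, "." decimal, one row per (case, alternative)
#' with the documented headers `respondent`, `state`, `stage`, `domain`,
#' `level`, `chosen`, `sense` (plus any extra columns, which are preserved
#' with a warning on read). Round-trips losslessly.
#'
#' @param cases a cases data.frame (see [simulate_bws_dataset()]).
#' @param path file path.
#' @return `read_bws_csv()` returns the data.frame; the writers return
#'   `path` invisibly.
#' @export
write_bws_csv <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bws_csv
#' @export
read_bws_csv <- function(path) {
  read_checked(path, c("respondent", "state", "stage", "domain", "level",
                       "chosen", "sense"),
               classes = c(state = "character"),
               optional = c("block", "profile"))
}

#' Read and write cTTO response tables
#'
#' Columns `respondent`, `state`, `branch`, `years`, `value`.
#'
#' @param responses a TTO data.frame (see [simulate_tto_dataset()]).
#' @param path file path.
#' @export
write_tto_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tto_csv
#' @export
read_tto_csv <- function(path) {
  read_checked(path, c("respondent", "state", "branch", "years", "value"),
               classes = c(state = "character"))
}

#' Read and write tariff CSV files
#'
#' One row per (domain, level) weight plus one `intercept` row — the layout
#' of the packaged published tariff.
#'
#' @param tariff an `ascot_tariff`.
#' @param path file path.
#' @param instrument a `bws_instrument` (for reading).
#' @export
write_tariff_csv <- function(tariff, path) {
  P <- nrow(tariff$weights); L <- ncol(tariff$weights)
  df <- data.frame(domain = as.character(rep(seq_len(P), each = L)),
                   level = rep(seq_len(L), P),
                   weight = as.vector(t(tariff$weights)))
  df <- rbind(df, data.frame(domain = "intercept", level = NA,
                             weight = tariff$intercept))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tariff_csv
#' @export
read_tariff_csv <- function(path, instrument = ascot_carer()) {
  df <- read_checked(path, c("domain", "level", "weight"))
  icpt <- df$domain == "intercept"
  if (sum(icpt) != 1L) stop("tariff file needs exactly one intercept row")
  w <- df[!icpt, ]
  W <- matrix(NA_real_, instrument$n_domains, instrument$n_levels)
  W[cbind(as.integer(w$domain), as.integer(w$level))] <- w$weight
  if (anyNA(W)) stop("tariff file is missing weight cells")
  new_tariff(W, df$weight[icpt], instrument)
}

#' Read and write blocked design CSVs
#'
#' One row per profile: `profile_index`, `state`, `block`.
#'
#' @param design a `bws_design`.
#' @param path file path.
#' @export
write_design_csv <- function(design, path) {
  blk <- integer(length(design$profiles))
  for (b in seq_along(design$blocks)) blk[design$blocks[[b]]] <- b
  df <- data.frame(profile_index = seq_along(design$profiles),
                   state = design$profiles, block = blk)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, instrument = ascot_carer()) {
  df <- read_checked(path, c("profile_index", "state", "block"),
                     classes = c(state = "character"))
  df <- df[order(df$profile_index), ]
  structure(list(profiles = df$state,
                 blocks = unname(split(df$profile_index, df$block)),
                 instrument = instrument, seed = NA_integer_),
            class = "bws_design")
}

#' Serialise an estimation result
#'
#' Writes the coefficient table (parameter, domain, estimate, SE) with the
#' fit metadata (counts, log-likelihood, draws, seed) as leading `#`
#' comment lines.
#'
#' @param fit a `bws_fit`.
#' @param path file path.
#' @export
write_fit_csv <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(method = fit$method, n_respondents = fit$n_respondents,
            n_cases = fit$n_cases, n_observations = fit$n_observations,
            loglik = format(fit$loglik, digits = 12),
            n_draws = fit$n_draws, seed = fit$seed,
            converged = fit$converged)
  writeLines(paste0("# ", names(meta), " = ", unname(meta)), con)
  utils::write.csv(coef_table(fit), con, row.names = FALSE)
  invisible(path)
}
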