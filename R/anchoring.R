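#' Linear latent-to-TTO anchor model
#'
#' Constructs an anchor model directly from a known slope and intercept
#' (e.g. the published line TTO = 0.0305 BWS - 0.0695), without fitting.
#'
#' @param slope,intercept coefficients of the line `TTO = slope * BWS +
#'   intercept`.
#' @return An object of class `anchor_model`.
#' @seealso [fit_anchor()] to estimate the line from data.
#' @export
anchor_model <- function(slope, intercept) {
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 r_squared = NA_real_, mse = NA_real_, rmse = NA_real_,
                 residuals = NULL, n = NA_integer_, method = "given"),
            class = "anchor_model")
}

#' Fit the linear map from latent BWS scores to TTO values
#'
#' Estimates `TTO_i = slope * BWS_i + intercept + e_i` over the valued
#' states. Two estimators are available:
#'
#' * `method = "anchored"` (default): least squares constrained so the line
#'   passes exactly through the full-health anchor point — by default the
#'   latent score of the best state mapping to utility 1. This is the
#'   convention under which the full-health state keeps utility 1 on the
#'   anchored scale, and it is the estimator that reproduces the published
#'   Japanese line (slope 0.0305, intercept -0.0695) from the published
#'   state values.
#' * `method = "ols"`: ordinary unconstrained least squares.
#'
#' Reported fit statistics: `r_squared` is the squared Pearson correlation
#' between observed and fitted values (identical to the OLS coefficient of
#' determination when `method = "ols"`), `mse` the mean squared residual and
#' `rmse` its square root.
#'
#' @param bws_scores numeric vector of latent BWS scores, one per state.
#' @param tto_values numeric vector of mean observed TTO values, same length.
#' @param method `"anchored"` or `"ols"`.
#' @param anchor_point length-2 numeric `c(bws, tto)` the anchored line must
#'   pass through; required for `method = "anchored"`.
#' @return An `anchor_model` with slope, intercept, fit statistics and
#'   residuals.
#' @export
#' @examples
#' fx <- load_fixtures()
#' an <- fit_anchor(latent_score(fx$tto$state, fx$params), fx$tto$mean,
#'                  anchor_point = c(latent_score("1111111", fx$params), 1))
#' round(c(an$slope, an$intercept), 4) # 0.0305, -0.0695
fit_anchor <- function(bws_scores, tto_values,
                       method = c("anchored", "ols"),
                       anchor_point = NULL) {
  method <- match.arg(method)
  x <- as.numeric(bws_scores); y <- as.numeric(tto_values)
  if (length(x) != length(y)) stop("score and value vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 states to fit the anchor")
  if (stats::sd(x) == 0) stop("latent scores are all equal; slope not identified")
  if (method == "anchored") {
    if (is.null(anchor_point) || length(anchor_point) != 2L)
      stop("method = 'anchored' needs anchor_point = c(bws, tto)")
    anchor_point <- unname(anchor_point)
    x0 <- anchor_point[1]; y0 <- anchor_point[2]
    slope <- sum((x - x0) * (y - y0)) / sum((x - x0)^2)
    intercept <- y0 - slope * x0
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  res <- y - (slope * x + intercept)
  fitted <- slope * x + intercept
  r2 <- if (stats::sd(fitted) == 0) 0 else stats::cor(y, fitted)^2
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, mse = mean(res^2), rmse = sqrt(mean(res^2)),
                 residuals = res, n = length(x), method = method,
                 anchor_point = anchor_point),
            class = "anchor_model")
}

#' @export
predict.anchor_model <- function(object, newdata, ...) {
  object$slope * as.numeric(newdata) + object$intercept
}

#' @export
print.anchor_model <- function(x, ...) {
  cat(sprintf("anchor: TTO = %.6f * BWS %+.6f  (%s", x$slope, x$intercept,
              x$method))
  if (!is.na(x$r_squared))
    cat(sprintf(", n = %d, R2 = %.3f, RMSE = %.3f", x$n, x$r_squared, x$rmse))
  cat(")\n")
  invisible(x)
}

#' Build a tariff (value set) from utility parameters and an anchor
#'
#' The tariff weight of item (p, q) is `slope * u(p, q)` with `u` the mean
#' item utility under the instrument coding, rounded to `rounding` decimals
#' for publication (`rounding = NULL` keeps the unrounded pipeline values);
#' the tariff intercept is the (equally rounded) anchor intercept.
#'
#' @param params a `utility_params`.
#' @param anchor an `anchor_model`.
#' @param instrument a `bws_instrument`.
#' @param rounding decimal places for published weights (default 3), or
#'   `NULL` for no rounding.
#' @param full_state_rule if `TRUE` (default), the all-level-1 state scores
#'   exactly 1 when the tariff is applied (the intercept is included for
#'   every other state).
#' @return An object of class `ascot_tariff`: a per-(domain, level) weight
#'   matrix plus intercept.
#' @export
build_tariff <- function(params, anchor, instrument = ascot_carer(),
                         rounding = 3L, full_state_rule = TRUE) {
  U <- item_utilities(params, instrument)
  W <- anchor$slope * U
  icpt <- anchor$intercept
  if (!is.null(rounding)) {
    W <- round(W, rounding)
    icpt <- round(icpt, rounding)
  }
  new_tariff(W, icpt, instrument, full_state_rule)
}

# internal constructor shared with the fixture loader
new_tariff <- function(weights, intercept, instrument, full_state_rule = TRUE) {
  stopifnot(nrow(weights) == instrument$n_domains,
            ncol(weights) == instrument$n_levels)
  dimnames(weights) <- list(instrument$domain_names,
                            paste0("level", seq_len(instrument$n_levels)))
  structure(list(weights = weights, intercept = as.numeric(intercept),
                 full_state_rule = isTRUE(full_state_rule),
                 instrument = instrument),
            class = "ascot_tariff")
}

#' @export
print.ascot_tariff <- function(x, digits = 3, ...) {
  cat("ASCOT-Carer tariff (intercept ", format(x$intercept, digits = digits),
      if (x$full_state_rule) "; full-health state pinned to 1", ")\n", sep = "")
  print(round(x$weights, digits))
  invisible(x)
}

#' Score states with a tariff
#'
#' The utility of a state is the sum of its seven per-domain weights plus
#' the tariff intercept; under the full-state rule the all-level-1 state
#' returns exactly 1 (the intercept applies to every other state).
#'
#' @param states character vector of state strings or a level matrix.
#' @param tariff an `ascot_tariff`.
#' @return Numeric vector of utilities.
#' @export
#' @examples
#' fx <- load_fixtures()
#' score_state("2234134", fx$tariff) # 0.486
score_state <- function(states, tariff) {
  inst <- tariff$instrument
  S <- as_state_matrix(states, inst)
  out <- numeric(nrow(S))
  for (p in seq_len(inst$n_domains)) out <- out + tariff$weights[p, S[, p]]
  out <- out + tariff$intercept
  if (tariff$full_state_rule) out[rowSums(S == 1L) == ncol(S)] <- 1
  stats::setNames(out, rownames(S))
}

#' Score a table of responses
#'
#' Vectorised [score_state()] over a column of state strings, preserving row
#' order and appending the misery score. Malformed states are not dropped
#' silently: their rows carry `NA` utility and the offending rows are
#' collected in the `"errors"` attribute.
#'
#' @param states character vector of state strings.
#' @param tariff an `ascot_tariff`.
#' @return A data.frame `state`, `utility`, `misery`, with attribute
#'   `"errors"` (a data.frame of row index, state and message; empty when
#'   all rows parsed).
#' @export
score_dataset <- function(states, tariff) {
  states <- as.character(states)
  n <- length(states)
  utility <- rep(NA_real_, n); misery <- rep(NA_integer_, n)
  errs <- list()
  for (i in seq_len(n)) {
    ok <- tryCatch({
      utility[i] <- score_state(states[i], tariff)
      misery[i] <- misery_score(states[i], tariff$instrument)
      TRUE
    }, error = function(e) {
      errs[[length(errs) + 1L]] <<- data.frame(
        row = i, state = states[i], message = conditionMessage(e),
        stringsAsFactors = FALSE)
      FALSE
    })
  }
  out <- data.frame(state = states, utility = utility, misery = misery,
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(), state = character(), message = character(),
               stringsAsFactors = FALSE)
  out
}
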