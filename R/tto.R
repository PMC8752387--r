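#' Composite TTO value of an indifference point
#'
#' Conventional branch (state considered better than dead): the respondent
#' equates 10 years in the state with `years` in full health, so the value
#' is `years / 10` in \[0, 1\]. Lead-time branch (worse than dead): `years`
#' of full health is equated with 10 years of full health followed by 10
#' years in the state, so the value is `years / 10 - 1` in \[-1, 1\].
#'
#' @param branch `"conventional"` or `"lead_time"` (vectorised).
#' @param years indifference years: 0..10 conventional, 0..20 lead-time.
#' @return Numeric vector of TTO values.
#' @export
#' @examples
#' tto_value("conventional", 8.7) # 0.87
#' tto_value("lead_time", 10)    # 0: the death-equivalent boundary
tto_value <- function(branch, years) {
  branch <- match.arg(as.character(branch), c("conventional", "lead_time"),
                      several.ok = TRUE)
  n <- max(length(branch), length(years))
  branch <- rep_len(branch, n); years <- rep_len(as.numeric(years), n)
  conv <- branch == "conventional"
  bad <- (conv & (years < 0 | years > 10)) | (!conv & (years < 0 | years > 20))
  if (any(bad))
    stop("years out of range for branch '", branch[which(bad)[1]], "': ",
         years[which(bad)[1]])
  ifelse(conv, years / 10, years / 10 - 1)
}

#' Per-state summaries of TTO responses
#'
#' Pools all responses to each state (the duplicated worst-state blocks pool
#' into a single row) and reports the count, mean and sample standard
#' deviation of the observed values, plus the misery score. States with a
#' single response get `sd = 0` and `degenerate = TRUE` rather than a
#' missing cell.
#'
#' @param responses data.frame with columns `state` and `value` (the layout
#'   written by [simulate_tto_dataset()] / [read_tto_csv()]).
#' @param instrument a `bws_instrument`.
#' @return A data.frame sorted by state string: `state`, `n`, `mean`, `sd`,
#'   `misery`, `degenerate`.
#' @export
summarize_states <- function(responses, instrument = ascot_carer()) {
  if (nrow(responses) == 0L)
    return(data.frame(state = character(), n = integer(), mean = numeric(),
                      sd = numeric(), misery = integer(),
                      degenerate = logical(), stringsAsFactors = FALSE))
  stopifnot(all(c("state", "value") %in% names(responses)))
  sp <- split(responses$value, responses$state)
  states <- sort(names(sp))
  n <- vapply(sp[states], length, integer(1))
  m <- vapply(sp[states], mean, numeric(1))
  s <- vapply(sp[states], function(v) if (length(v) > 1L) stats::sd(v) else 0,
              numeric(1))
  data.frame(state = states, n = unname(n), mean = unname(m), sd = unname(s),
             misery = unname(misery_score(states, instrument)),
             degenerate = unname(n == 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Misery-score summary of state values
#'
#' Groups state summaries by misery score (the sum of level digits) and
#' averages the state means within each group — the crude face-validity
#' check that observed values decrease as states worsen.
#'
#' @param summaries output of [summarize_states()].
#' @return A data.frame `misery`, `n_states`, `mean`, `sd` (SD across state
#'   means within the group; 0 for singleton groups).
#' @export
misery_summary <- function(summaries) {
  stopifnot(nrow(summaries) > 0, all(c("misery", "mean") %in% names(summaries)))
  sp <- split(summaries$mean, summaries$misery)
  data.frame(
    misery = as.integer(names(sp)),
    n_states = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
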