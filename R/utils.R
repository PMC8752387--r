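# evaluate `code` under a local RNG state seeded with `seed`;
# NULL seed = use (and advance) the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# standard Gumbel (type-I extreme value) shocks
rgumbel <- function(n) -log(-log(stats::runif(n)))

stage_levels <- c("best", "worst", "second_best", "second_worst")
stage_sense <- c(best = 1L, worst = -1L, second_best = 1L, second_worst = -1L)

# stages played for a P-domain profile: best/worst/second-best/second-worst,
# but a stage needs at least 2 remaining alternatives
n_stages_for <- function(P) min(4L, P - 1L)
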