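# Deterministic substreams: every stochastic operation takes one integer
# seed; stage streams are derived from a master seed by a stable label so a
# change in one stage does not shift another stage's draws.

derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483563
  as.integer((abs(as.numeric(seed)) %% 2147483563 * 31 + h) %% 2147483563)
}

# A self-contained RNG stream that saves/restores the global RNG state so
# package draws never disturb (nor depend on) the caller's RNG.
seeded_rng <- function(seed, label = "stream") {
  sub <- derive_seed(seed, label)
  state <- NULL
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(sub)
    else assign(".Random.seed", state, globalenv())
    out <- fn()
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    sample_int = function(n, size = n, replace = FALSE)
      with_state(function() sample.int(n, size, replace))
  )
}
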