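# Internal deterministic RNG streams.
#
# Generator code draws from private RNG streams so that corpus generation
# is reproducible from a single integer seed and never perturbs (nor is
# perturbed by) the caller's global RNG state.

get_rand_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

set_rand_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  outer_state <- get_rand_state()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get_rand_state()
  set_rand_state(outer_state)

  with_state <- function(f) {
    outer_state <- get_rand_state()
    set_rand_state(env$state)
    on.exit({
      env$state <- get_rand_state()
      set_rand_state(outer_state)
    })
    f()
  }
  env$sample_int <- function(n, k = 1L, replace = FALSE) {
    with_state(function() sample.int(n, k, replace = replace))
  }
  env$runif <- function(n = 1L) with_state(function() stats::runif(n))
  env$rpois <- function(n, lambda) {
    with_state(function() stats::rpois(n, lambda))
  }
  env$pick <- function(x) x[[env$sample_int(length(x), 1L)]]
  env$derive <- function(offset) {
    # spawn a child stream deterministically from this one
    local_rng(with_state(function() {
      sample.int(.Machine$integer.max - 1L, 1L)
    }) + as.integer(offset) %% 1000003L)
  }
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a
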