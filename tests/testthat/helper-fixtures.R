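# Shared fixtures, built in code at test time.

fixture_pset <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache) || attr(cache, "seed") != seed) {
      p <- synthetic_parameter_set(seed)
      attr(p, "seed") <- seed
      cache <<- p
    }
    cache
  }
})

fixture_space <- function() build_state_space()

# A tiny hand-built strategy list for quick runs.
fast_menu <- function() strategy_menu()[c("no_screening", "every_2y")]

# Occupancy vector with all mass in one state.
unit_occ <- function(space, state, mass = 1) {
  occ <- stats::setNames(numeric(nrow(space)), space$id)
  occ[[state]] <- mass
  occ
}
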