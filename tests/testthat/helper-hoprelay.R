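# Small-scale parameter sets for desk-scale simulator tests.  Regime
# structure is robust down to a few tens of dimers, so tests use reduced
# dimer counts and shortened runs where only qualitative behaviour matters.
small_params <- function(preset = "fig4", nA = 50, ...) {
  par_preset(preset, nA = nA, ...)
}

# A state with a single nucleoid-bound dimer and no event dynamics
# (ka = kd = kh = 0, Dh = 0): isolates the elastic fluctuation propagator.
single_dimer_state <- function(p) {
  st <- init_state(p, seed = 11)
  st$state <- rep(1L, p$nA)
  st$x <- st$hx <- rep(p$L / 2, p$nA)
  st$y <- st$hy <- rep(p$W / 2, p$nA)
  st
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
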