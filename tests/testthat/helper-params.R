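# Shared fixtures: coarse but adequate grids keep the suite fast.

small_params <- function(...) {
  args <- list(...)
  if (!"n_grid" %in% names(args)) args$n_grid <- 200
  do.call(model_params, args)
}

# the two reference supply regimes (supply rate = delta * R_s_max)
low_supply_params <- function(...) small_params(R_s_max = 0.25, ...)
high_supply_params <- function(...) small_params(R_s_max = 2, ...)

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), rel_tol)
}
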