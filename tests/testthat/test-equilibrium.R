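test_that("the consumer-free equilibrium sits exactly at carrying capacity", {
  p <- small_params()
  eq <- solve_equilibrium(numeric(0), p)
  expect_identical(unname(eq$env), unname(p$R_max))
  expect_true(eq$converged)
  # resource balance vanishes there and only there
  r0 <- resource_balance_residual(list(traits = numeric(0), b = numeric(0)),
                                  p$R_max, p)
  expect_equal(unname(r0), rep(0, 7))
  r1 <- resource_balance_residual(list(traits = numeric(0), b = numeric(0)),
                                  0.9 * p$R_max, p)
  expect_true(all(r1 > 0))
})

test_that("the resource-balance residual is linear in the birth rates", {
  p <- small_params()
  env <- 0.8 * p$R_max
  co1 <- list(traits = c(1, 3.5), b = c(2e-3, 1e-3))
  co2 <- list(traits = c(1, 3.5), b = 2 * co1$b)
  r1 <- resource_balance_residual(co1, env, p)
  r2 <- resource_balance_residual(co2, env, p)
  supply <- p$delta * (p$R_max - env)
  # depletion term (supply - residual) doubles when all b double
  expect_equal(unname(supply - r2), 2 * unname(supply - r1),
               tolerance = 1e-10)
})

test_that("a resident that cannot sustain itself is reported extinct", {
  # shared supply far below the juvenile critical density
  p <- small_params(R_s_max = 0.05)
  eq <- solve_equilibrium(1, p)
  expect_true(eq$converged)
  expect_length(eq$traits, 0)
  expect_equal(eq$extinct, 1)
  expect_identical(unname(eq$env), unname(p$R_max))
})

test_that("equilibria satisfy R0 = 1 and resource balance at both supply regimes", {
  for (p in list(low_supply_params(), high_supply_params())) {
    eq <- solve_equilibrium(1, p)
    expect_true(eq$converged)
    expect_lt(max(abs(eq$R0 - 1)), 1e-6)
    res <- resource_balance_residual(list(traits = eq$traits, b = eq$b),
                                     eq$env, p)
    expect_lt(max(abs(res)), 1e-8)
    expect_true(all(eq$env > 0 & eq$env <= p$R_max + 1e-12))
    expect_true(all(eq$b > 0))
  }
})

test_that("randomized parameter draws solve to valid equilibria", {
  for (seed in c(21, 22, 23, 24)) {
    p <- build_fixture("random-params", seed = seed)
    eq <- solve_equilibrium(p$theta[2], p)
    expect_true(eq$converged)
    if (length(eq$traits)) {
      expect_lt(max(abs(eq$R0 - 1)), 1e-6)
      expect_true(all(eq$env > 0 & eq$env <= p$R_max + 1e-12))
    }
  }
})

test_that("supply regimes produce the documented size-structure contrast", {
  # low supply: few large consumers, specific resources barely depleted;
  # high supply: many large consumers, strong specific-resource depletion
  eq_lo <- solve_equilibrium(1, low_supply_params())
  eq_hi <- solve_equilibrium(1, high_supply_params())
  expect_gt(eq_lo$env["R_1"], 0.85)
  expect_lt(eq_hi$env["R_1"], 0.25)
  bio_lo <- standing_biomass(eq_lo)
  bio_hi <- standing_biomass(eq_hi)
  expect_gt(bio_hi["large"], 10 * bio_lo["large"])
})

test_that("the high-supply reference equilibrium is dynamically stable", {
  p <- high_supply_params(n_grid = 300)
  eq <- solve_equilibrium(1, p)
  expect_identical(as.character(classify_stability(eq, p)), "stable")
})
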