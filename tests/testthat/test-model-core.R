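test_that("attack coefficient is Gaussian in the trait with the documented limits", {
  p <- small_params()
  # at the optimum the coefficient equals A_max
  expect_equal(attack_coefficient(p$theta[2], 2, p), p$A_max)
  # infinite niche width (shared resource): A_max for every trait value
  for (x in c(-3, 0, 7.3, 40)) {
    expect_equal(attack_coefficient(x, 1, p), p$A_max)
  }
  # one niche width away: A_max * exp(-1/2)
  expect_equal(attack_coefficient(p$theta[3] + p$tau[3], 3, p),
               p$A_max * exp(-0.5))
  # symmetry about the optimum, and strictly below A_max away from it
  for (d in c(0.1, 0.7, 2.4)) {
    expect_equal(attack_coefficient(p$theta[4] + d, 4, p),
                 attack_coefficient(p$theta[4] - d, 4, p))
    expect_lt(attack_coefficient(p$theta[4] + d, 4, p), p$A_max)
  }
  expect_error(attack_coefficient(1, 9, p), "resource index")
  expect_error(attack_coefficient(1, 0, p), "resource index")
})

test_that("diet weights implement the discrete shift and its relaxations", {
  p <- small_params()
  # discrete: shared only below m_shift, specific only from m_shift on
  expect_equal(diet_weight(p$m_shift / 2, 1, p), 1)
  expect_equal(diet_weight(p$m_shift / 2, 3, p), 0)
  expect_equal(diet_weight(2 * p$m_shift, 1, p), 0)
  expect_equal(diet_weight(2 * p$m_shift, 3, p), 1)
  expect_equal(diet_weight(p$m_shift, 1, p), 0)  # shift mass itself is 'post'
  # broadening: the shared resource stays available at every size
  pb <- small_params(shift_mode = "broadening")
  expect_equal(diet_weight(2 * pb$m_shift, 1, pb), 1)
  expect_equal(diet_weight(2 * pb$m_shift, 4, pb), 1)
  expect_equal(diet_weight(pb$m_shift / 2, 4, pb), 0)
  # gradual: smooth, complementary, and steepness recovers the discrete case
  pg <- small_params(shift_mode = "gradual", shift_steep = 8)
  m <- c(1, 4, 5, 6, 20)
  ws <- diet_weight(m, 1, pg)
  wc <- diet_weight(m, 2, pg)
  expect_true(all(ws >= 0 & ws <= 1))
  expect_equal(ws + wc, rep(1, length(m)))
  expect_true(all(diff(ws) < 0))
  pg2 <- small_params(shift_mode = "gradual", shift_steep = 500)
  expect_equal(diet_weight(4.9, 1, pg2), 1, tolerance = 1e-4)
  expect_equal(diet_weight(5.1, 1, pg2), 0, tolerance = 1e-4)
})

test_that("encounter rate sums accessible resources with m^q allometry", {
  p <- small_params()
  env0 <- resource_env(0, rep(0, 6))
  expect_equal(encounter_rate(c(0.1, 1, 30), 1, env0, p), rep(0, 3))
  # a juvenile encounters only the shared resource
  env <- resource_env(1.3, rep(0.7, 6))
  m <- 0.8
  expect_equal(encounter_rate(m, 1, env, p), p$A_max * m^p$q * 1.3)
  # doubling mass multiplies the rate by 2^q (within one diet phase)
  expect_equal(encounter_rate(2 * m, 1, env, p) /
                 encounter_rate(m, 1, env, p), 2^p$q)
  # an adult on a single stocked specific resource: A(x, theta_j) m^q R_j
  env1 <- resource_env(0, c(0, 0.9, 0, 0, 0, 0))
  x <- 3.1
  expect_equal(encounter_rate(20, x, env1, p),
               attack_coefficient(x, 3, p) * 20^p$q * 0.9)
  expect_error(encounter_rate(1, 1, c(-0.1, rep(1, 6)), p), "non-negative")
})

test_that("feeding level saturates between 0 and 1 and ignores inaccessible resources", {
  p <- small_params()
  expect_equal(feeding_level(1, 1, resource_env(0, rep(0, 6)), p), 0)
  # half saturation when encounter equals maximum intake
  m <- 2
  Rhalf <- p$h * m^p$n_intake / (p$A_max * m^p$q)
  expect_equal(feeding_level(m, 1, resource_env(Rhalf, rep(0, 6)), p), 0.5)
  # saturation toward 1
  expect_gt(feeding_level(m, 1, resource_env(1e6, rep(0, 6)), p), 0.999)
  # monotone in every accessible resource; flat in inaccessible ones
  f0 <- feeding_level(30, 1, resource_env(1, rep(0.5, 6)), p)
  f_up <- feeding_level(30, 1, resource_env(1, c(0.9, rep(0.5, 5))), p)
  expect_gt(f_up, f0)
  f_shared_up <- feeding_level(30, 1, resource_env(2, rep(0.5, 6)), p)
  expect_equal(f_shared_up, f0)  # adults do not see the shared resource
  fj <- feeding_level(1, 1, resource_env(1, rep(0.5, 6)), p)
  fj2 <- feeding_level(1, 1, resource_env(1, rep(0.9, 6)), p)
  expect_equal(fj, fj2)          # juveniles do not see the specific ones
})

test_that("growth, fecundity and mortality follow the energy budget", {
  p <- small_params()
  # the critical feeding level balances intake and maintenance exactly
  # (n_intake = p_met so it is mass independent)
  f_c <- p$k_met / (p$alpha * p$h)
  m <- 1.5
  R_crit <- f_c / (1 - f_c) * p$h * m^p$n_intake / (p$A_max * m^p$q)
  env_c <- resource_env(R_crit, rep(0, 6))
  expect_equal(growth_rate(m, 1, env_c, p), 0, tolerance = 1e-12)
  # mortality at the critical level is exactly background
  expect_equal(mortality_rate(m, 1, env_c, p), p$mu_0 * m^p$mort_exp,
               tolerance = 1e-12)
  # a starving individual dies faster than background
  env_low <- resource_env(R_crit / 2, rep(0, 6))
  expect_gt(mortality_rate(m, 1, env_low, p), p$mu_0 * m^p$mort_exp)
  expect_equal(growth_rate(m, 1, env_low, p), 0)  # floored, never negative
  # juveniles do not reproduce; adults at the critical level do not either
  env <- consumer_free_env(p)
  expect_equal(fecundity_rate(m, 1, env, p), 0)
  madult <- p$m_mat * 1.5
  expect_gt(fecundity_rate(madult, 1, env, p), 0)
  R_crit_a <- f_c / (1 - f_c) * p$h / (p$A_max * madult^(p$q - p$n_intake))
  expect_equal(fecundity_rate(madult, 1,
                              resource_env(0, c(R_crit_a, rep(0, 5))), p), 0,
               tolerance = 1e-12)
  # halving egg mass doubles the offspring rate at a fixed energy flux
  p2 <- update_params(p, m_b = p$m_b / 2)
  expect_equal(fecundity_rate(madult, 1, env, p2) /
                 fecundity_rate(madult, 1, env, p), 2, tolerance = 1e-10)
})

test_that("rates are non-decreasing in the feeding level and jump only at m_shift", {
  p <- small_params()
  env <- consumer_free_env(p)
  # growth increases with resource density at fixed mass
  gr <- vapply(c(0.2, 0.5, 1, 2), function(R)
    growth_rate(1, 1, resource_env(R, rep(0, 6)), p), numeric(1))
  expect_true(all(diff(gr) > 0))
  fec <- vapply(c(0.3, 0.6, 1), function(R)
    fecundity_rate(80, 1, resource_env(0, rep(R, 6)), p), numeric(1))
  expect_true(all(diff(fec) > 0))
  # piecewise smooth in mass with a single discontinuity at m_shift
  m_lo <- p$m_shift * (1 - 1e-9)
  m_hi <- p$m_shift * (1 + 1e-9)
  g_lo <- growth_rate(m_lo, 1, env, p)
  g_hi <- growth_rate(m_hi, 1, env, p)
  expect_gt(abs(g_hi - g_lo), 1e-6)     # the diet shift is discontinuous
  ms <- seq(p$m_b, p$m_shift * 0.999, length.out = 40)
  expect_true(all(abs(diff(growth_rate(ms, 1, env, p))) < 0.05))
})
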