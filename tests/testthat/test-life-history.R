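test_that("growth matches the closed form when the feeding level is constant", {
  fx <- build_fixture("growth-env", seed = 11, f_level = 0.6)
  p <- fx$params
  lh <- integrate_life_history(1, fx$env, p, n_grid = 800)
  traj <- lh$trajectory
  juv <- traj$mass < p$m_mat * 0.999
  expect_gt(sum(juv), 100)
  pred <- fx$mass_at_age(traj$age[juv])
  expect_lt(max(abs(traj$mass[juv] - pred) / pred), 1e-6)
  # at the critical feeding level growth is exactly zero
  f_c <- p$k_met / (p$alpha * p$h)
  fx_c <- build_fixture("growth-env", seed = 11, f_level = f_c)
  expect_equal(growth_rate(1, 1, fx_c$env, fx_c$params), 0,
               tolerance = 1e-14)
})

test_that("quadrature agrees with an adaptive age-based integration of the same rates", {
  # independent oracle: lsoda on d(m, S, B)/dt with the exported rate
  # functions, restarted exactly at the diet-shift crossing
  p <- small_params(n_grid = 2000)
  eq <- solve_equilibrium(1, p)
  env <- eq$env
  for (x in c(1, 2.2)) {
    rhs <- function(t, y, parms) {
      m <- y[1]
      list(c(growth_rate(m, x, env, p),
             -mortality_rate(m, x, env, p) * y[2],
             fecundity_rate(m, x, env, p) * y[2]))
    }
    # restart exactly at the diet-shift and maturation discontinuities
    o1 <- deSolve::lsoda(c(m = p$m_b, S = 1, B = 0),
                         times = c(0, 1e6), func = rhs,
                         rootfunc = function(t, y, parms) y[1] - p$m_shift,
                         rtol = 1e-11, atol = 1e-14)
    y1 <- o1[nrow(o1), -1]
    y1[1] <- p$m_shift * (1 + 1e-12)
    o2 <- deSolve::lsoda(y1, times = c(o1[nrow(o1), 1], 1e6), func = rhs,
                         rootfunc = function(t, y, parms) y[1] - p$m_mat,
                         rtol = 1e-11, atol = 1e-14)
    y2 <- o2[nrow(o2), -1]
    y2[1] <- p$m_mat * (1 + 1e-12)
    o3 <- deSolve::lsoda(y2, times = c(o2[nrow(o2), 1], 3e5), func = rhs,
                         rtol = 1e-11, atol = 1e-16, maxsteps = 50000)
    R0_ode <- o3[nrow(o3), "B"]
    lh <- integrate_life_history(x, env, p)
    expect_rel_equal(lh$R0, R0_ode, 1e-6)
  }
})

test_that("life-history solutions satisfy their structural invariants", {
  p <- small_params()
  for (seed in c(3, 4)) {
    pr <- build_fixture("random-params", seed = seed)
    lh <- integrate_life_history(pr$theta[2] + 0.3, consumer_free_env(pr), pr)
    traj <- lh$trajectory
    expect_equal(traj$S[1], 1)
    expect_true(all(diff(traj$S) <= 1e-12))       # survival non-increasing
    expect_true(all(diff(traj$mass) >= -1e-12))   # mass non-decreasing
    expect_true(all(diff(traj$B) >= -1e-9))       # reproduction cumulative
    expect_rel_equal(max(traj$B), lh$R0, 1e-6)
    expect_true(all(lh$C >= 0))
  }
  # an empty environment: growth stalls at birth and R0 = 0
  lh0 <- integrate_life_history(1, resource_env(0, rep(0, 6)), p)
  expect_equal(lh0$R0, 0)
  expect_true(lh0$stalled)
  expect_equal(lh0$m_stall, p$m_b)
})

test_that("juveniles reach the diet shift earlier under high shared supply", {
  p_hi <- high_supply_params()
  p_lo <- low_supply_params()
  eq_hi <- solve_equilibrium(1, p_hi)
  eq_lo <- solve_equilibrium(1, p_lo)
  g_hi <- growth_curve(1, eq_hi$env, p_hi)
  g_lo <- growth_curve(1, eq_lo$env, p_lo)
  expect_lt(attr(g_hi, "age_shift"), attr(g_lo, "age_shift") / 5)
  # the consumer-free environment is the fastest possible growth curve
  g_free <- growth_curve(1, consumer_free_env(p_hi), p_hi)
  expect_lt(attr(g_free, "age_shift"), attr(g_hi, "age_shift"))
})
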