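test_that("residents are selectively neutral at their own equilibrium", {
  for (seed in c(31, 32, 33)) {
    p <- build_fixture("random-params", seed = seed)
    eq <- solve_equilibrium(p$theta[2], p)
    if (!length(eq$traits)) next
    expect_lt(abs(invasion_fitness(eq$traits[1], eq)), 1e-6)
  }
  # and in a dimorphic coalition
  p <- high_supply_params()
  eq2 <- solve_equilibrium(c(1.2, 4.5), p)
  expect_true(eq2$converged)
  expect_lt(max(abs(invasion_fitness(eq2$traits, eq2))), 1e-6)
})

test_that("the selection gradient matches a higher-order stencil", {
  p <- low_supply_params()
  eq <- solve_equilibrium(0.7, p)
  g2 <- selection_gradient(eq, step = 1e-3)
  # five-point stencil oracle at a larger step
  h <- 2e-3
  s <- invasion_fitness(0.7 + c(-2, -1, 1, 2) * h, eq)
  g5 <- (s[1] - 8 * s[2] + 8 * s[3] - s[4]) / (12 * h)
  expect_rel_equal(g2, g5, 1e-4)
  # at low shared supply, selection pushes the resident toward theta_1
  expect_gt(g2, 0)
})

test_that("the central singular strategy exists by symmetry and classifies as branching", {
  p <- small_params(m_shift = 0, tau = 1, peak_spacing = 2.5)
  ctr <- mean(p$theta[-1])
  cs <- classify_singularity(ctr, p)
  expect_lt(abs(cs$gradient), 1e-4)
  expect_identical(cs$classification, "branching")
  expect_gt(cs$curvature, 0)
  # classification is invariant under translating the whole resource array
  p2 <- small_params(m_shift = 0, tau = 1, peak_spacing = 2.5,
                     theta_1 = 4, theta_s = 3)
  cs2 <- classify_singularity(mean(p2$theta[-1]), p2)
  expect_identical(cs2$classification, cs$classification)
  expect_rel_equal(cs2$curvature, cs$curvature, 0.02)
})

test_that("find_singular_points brackets and classifies interior roots", {
  p <- small_params(m_shift = 0, tau = 1, peak_spacing = 2.5)
  ctr <- mean(p$theta[-1])
  pts <- find_singular_points(p, ctr + c(-1, 1), n_pts = 9)
  expect_gte(length(pts), 1)
  xs <- vapply(pts, `[[`, numeric(1), "x_star")
  expect_lt(min(abs(xs - ctr)), 0.02)
})

test_that("trait substitution is deterministic and finds the low-supply ESS", {
  p <- low_supply_params()
  ctl <- list(max_steps = 120)
  tr1 <- evolve_traits(0.3, p, control = ctl)
  tr2 <- evolve_traits(0.3, p, control = ctl)
  expect_identical(tr1$history, tr2$history)   # no RNG in the AD engine
  expect_identical(tr1$status, "ess")
  expect_length(tr1$traits, 1)
  expect_lt(abs(tr1$traits - p$theta[2]), 0.25)
  expect_equal(species_count(tr1), 1L)
})

test_that("trajectories mirror when the trait axis is reflected about the array centre", {
  p <- small_params()                    # tau_s = Inf: no trait role below m_shift
  ctr <- mean(p$theta[-1])
  ctl <- list(max_steps = 50)
  up <- evolve_traits(ctr + 1.4, p, control = ctl)
  dn <- evolve_traits(ctr - 1.4, p, control = ctl)
  # compare the coalition as a set per step: branching may reorder rows
  steps <- intersect(unique(up$history$step), unique(dn$history$step))
  expect_gt(length(steps), 20)
  for (s in steps) {
    xu <- sort(up$history$x[up$history$step == s]) - ctr
    xd <- rev(ctr - sort(dn$history$x[dn$history$step == s]))
    expect_equal(xu, xd, tolerance = 1e-8)
  }
})

test_that("the species-count grid runs cell-wise with bistability flags", {
  p <- small_params()
  gr <- species_count_grid(
    p,
    axis1 = list(name = "rel_productivity", values = c(0.25, 2)),
    axis2 = list(name = "m_shift", values = 5),
    control = list(max_steps = 60))
  expect_identical(nrow(gr), 2L)
  expect_true(all(is.na(gr$error)))
  expect_true(all(gr$count_small >= 0 & gr$count_large >= 0))
  # large-dominated starts never yield fewer species than small-dominated
  expect_true(all(gr$count_large >= gr$count_small))
  expect_identical(gr$bistable, gr$count_small != gr$count_large)
})
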