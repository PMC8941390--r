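test_that("supply-rate continuation traces the fold structure with stability labels", {
  p <- small_params(n_grid = 250)
  ct <- continue_in_parameter(1, p, "R_s_max", c(0.25, 1.2), h0 = 0.05,
                              classify = TRUE, n_bins = 40)
  df <- as.data.frame(ct)
  expect_gt(nrow(df), 10)
  folds <- attr(ct, "folds")
  expect_length(folds, 2)
  win <- attr(ct, "bistable_window")
  expect_false(is.null(win))
  expect_lt(win[1], win[2])
  # the reference supplies lie outside the bistable window on either side
  expect_gt(win[1], 0.25)
  expect_lt(win[2], 2)
  # between the folds the middle segment is unstable, the outer ones stable
  segs <- split(df, df$segment)
  expect_identical(length(segs), 3L)
  expect_true(segs[[1]]$stable[1])
  expect_false(segs[[2]]$stable[1])
  expect_true(segs[[3]]$stable[1])
  # small-consumer biomass dominates the first branch at low supply,
  # large-consumer biomass the third branch
  expect_gt(mean(segs[[3]]$biomass_large), mean(segs[[1]]$biomass_large))
})

test_that("continuation points are re-found by direct solves from perturbed guesses", {
  p <- small_params(n_grid = 250)
  ct <- continue_in_parameter(1, p, "R_s_max", c(0.3, 0.9), h0 = 0.06,
                              classify = FALSE, max_points = 60)
  df <- as.data.frame(ct)
  for (i in unique(round(seq(2, nrow(df), length.out = 4)))) {
    pv <- update_params(p, R_s_max = df$par[i])
    env_i <- as.numeric(df[i, c("R_s", paste0("R_", 1:6))])
    eq <- solve_equilibrium(1, pv,
                            guess = list(env = env_i * 1.02,
                                         b = df$b_1[i] * 0.97))
    expect_true(eq$converged)
    expect_lt(abs(log(eq$env[1] / df$R_s[i])), 1e-5)
  }
})

test_that("hysteresis: sweeps from opposite ends land on different branches in the window", {
  p <- small_params(n_grid = 250)
  win <- c(0.5, 0.62)  # generous bracket around the fold window
  probe <- mean(win)
  up <- NULL
  for (v in seq(0.3, probe, length.out = 8)) {
    eq <- solve_equilibrium(1, update_params(p, R_s_max = v), guess = up)
    if (eq$converged) up <- list(env = eq$env, b = eq$b)
  }
  dn <- NULL
  for (v in seq(1.4, probe, length.out = 8)) {
    eq <- solve_equilibrium(1, update_params(p, R_s_max = v), guess = dn)
    if (eq$converged) dn <- list(env = eq$env, b = eq$b)
  }
  expect_false(is.null(up)); expect_false(is.null(dn))
  # forward sweep: shared resource depleted to near the juvenile critical
  # density; backward sweep: large-consumer branch with higher R_s
  expect_gt(dn$env[1] / up$env[1], 1.3)
})

test_that("the consumer-free branch is flat at carrying capacity", {
  p <- small_params()
  for (v in c(0.3, 0.7, 1.5)) {
    pv <- update_params(p, R_s_max = v)
    eq <- solve_equilibrium(numeric(0), pv)
    expect_identical(unname(eq$env), unname(pv$R_max))
  }
})
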