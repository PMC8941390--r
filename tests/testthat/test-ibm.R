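test_that("phenotypes are additive sums and bounded means of allelic values", {
  g <- genetic_params(F_x = 5, F_a = 3)
  geno <- list(x_alleles = rep(0, 10), a_alleles = rep(0, 6))
  expect_equal(unname(phenotype_from_genotype(geno)), c(0, 0))
  geno2 <- list(x_alleles = rep(0.3, 10), a_alleles = rep(1, 6))
  ph <- phenotype_from_genotype(geno2)
  expect_equal(unname(ph["x"]), 10 * 0.3)   # 2 F_x alleles of value c sum to 2 F_x c
  expect_equal(unname(ph["a"]), 1)          # the bound is attained
  geno3 <- list(x_alleles = rnorm(10), a_alleles = runif(6, -1, 1))
  expect_equal(unname(phenotype_from_genotype(geno3)),
               c(sum(geno3$x_alleles), mean(geno3$a_alleles)))
})

test_that("offspring inherit one allele per parent per locus, mutating at rate nu", {
  g0 <- genetic_params(F_x = 4, F_a = 4, nu = 0)
  mom <- list(x_alleles = rep(c(1, 2), 4), a_alleles = rep(c(-0.5, 0.5), 4))
  dad <- list(x_alleles = rep(c(10, 20), 4), a_alleles = rep(c(-0.1, 0.1), 4))
  set.seed(1)
  for (i in 1:20) {
    off <- make_offspring(mom, dad, g0)
    # without mutation every allele is an exact parental copy
    expect_true(all(off$x_alleles %in% c(1, 2, 10, 20)))
    expect_true(all(off$a_alleles %in% c(-0.5, 0.5, -0.1, 0.1)))
  }
  # expected offspring x equals the mid-parent value under nu = 0
  set.seed(2)
  xs <- replicate(4000, sum(make_offspring(mom, dad, g0)$x_alleles))
  midparent <- (sum(mom$x_alleles) + sum(dad$x_alleles)) / 2
  se <- sd(xs) / sqrt(length(xs))
  expect_lt(abs(mean(xs) - midparent), 4 * se)
  # realized mutation fraction matches nu within binomial error
  g1 <- genetic_params(F_x = 25, F_a = 1, nu = 0.1)
  mom1 <- list(x_alleles = rep(0, 50), a_alleles = rep(0, 2))
  set.seed(3)
  n_rep <- 2000
  mut <- replicate(n_rep,
    sum(make_offspring(mom1, mom1, g1)$x_alleles != 0))
  n_alleles <- n_rep * 50
  phat <- sum(mut) / n_alleles
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / n_alleles))
})

test_that("mate choice samples candidates in proportion to the analytic weights", {
  g <- genetic_params(sigma_m = 1)
  # a = 0: uniform over candidates
  expect_equal(mate_weights(0, c(0, 1, 3), 1), rep(1, 3))
  # self-matching maximum at zero distance
  w <- mate_weights(1, c(0, 0.5, 2), 1)
  expect_identical(which.max(w), 1L)
  expect_equal(w, exp(-(c(0, 0.5, 2))^2 / 2))
  # disassortative mothers avoid identical partners
  wd <- mate_weights(-1, c(0, 2), 1)
  expect_lt(wd[1], wd[2])
  # empirical sampling frequencies match the weights (binomial error)
  xc <- c(0, 0.8, 1.6, 3.0)
  wts <- mate_weights(0.8, 0 - xc, 1)
  probs <- wts / sum(wts)
  set.seed(42)
  n <- 2e4
  draws <- tabulate(vapply(seq_len(n), function(i)
    choose_mate(0, 0.8, xc, g), integer(1)), nbins = 4)
  for (k in 1:4) {
    se <- sqrt(probs[k] * (1 - probs[k]) / n)
    expect_lt(abs(draws[k] / n - probs[k]), 4 * se)
  }
})

test_that("an empty population leaves resources relaxing to carrying capacity", {
  p <- small_params()
  g <- genetic_params(F_x = 2, F_a = 2, V = 100)
  st <- init_ibm_state(1, 1, p, g)
  st$m <- st$m[0]; st$buffer <- st$buffer[0]; st$id <- st$id[0]
  st$x_alleles <- st$x_alleles[0, , drop = FALSE]
  st$a_alleles <- st$a_alleles[0, , drop = FALSE]
  st$resources <- 0.3 * unname(p$R_max)
  set.seed(1)
  r_prev <- st$resources
  for (i in 1:5) {
    st <- ibm_step(st, p, g, dt = 1, n_steps = 20)
    expect_true(all(st$resources >= r_prev - 1e-12))
    r_prev <- st$resources
  }
  expect_true(all(abs(st$resources - p$R_max) < 0.01 * p$R_max))
})

test_that("one step conserves resource mass given the realized grazing", {
  p <- small_params()
  g <- genetic_params(F_x = 2, F_a = 2, V = 50)
  set.seed(9)
  st <- init_ibm_state(40, 1, p, g, profile = "spread")
  st$resources <- 0.6 * unname(p$R_max)
  # independent computation of the grazing of step one from the same state
  vr <- vital_rates(st$m, 1, st$resources, p)
  uptake <- colSums(vr$cons)
  pred <- st$resources + 1 * (p$delta * (p$R_max - st$resources) - uptake / g$V)
  st1 <- ibm_step(st, p, g, dt = 1, n_steps = 1)
  expect_equal(unname(st1$resources), unname(pred), tolerance = 1e-10)
})

test_that("without mutation a monomorphic population stays monomorphic", {
  p <- small_params()
  g <- genetic_params(F_x = 3, F_a = 3, nu = 0, V = 300)
  res <- run_ibm(p, g, seed = 5, t_max = 3000, n0 = 200, x1 = 1,
                 record_every = 500)
  expect_false(res$extinct)
  expect_true(all(abs(res$final_state$x - 1) < 1e-12))
  expect_true(all(res$final_state$a == 0))
})

test_that("runs are bit-reproducible and resumable through the RNG stream", {
  p <- small_params()
  g <- genetic_params(F_x = 3, F_a = 3, V = 200)
  r1 <- run_ibm(p, g, seed = 11, t_max = 1500, n0 = 150, x1 = 1,
                record_every = 300)
  r2 <- run_ibm(p, g, seed = 11, t_max = 1500, n0 = 150, x1 = 1,
                record_every = 300)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$final_state, r2$final_state)
  expect_identical(r1$matings, r2$matings)
  # split run: one leg of 300 steps equals 150 + 150 on the same RNG stream
  set.seed(4); st0 <- init_ibm_state(100, 1, p, g)
  a <- ibm_step(st0, p, g, n_steps = 300)
  set.seed(4); st0b <- init_ibm_state(100, 1, p, g)
  b1 <- ibm_step(st0b, p, g, n_steps = 150)
  b1 <- unserialize(serialize(b1, NULL))   # state round-trips losslessly
  b2 <- ibm_step(b1, p, g, n_steps = 150)
  expect_identical(a, b2)
})

test_that("with trait-blind attack rates the niche trait drifts without bias", {
  p <- small_params(tau = Inf, tau_s = Inf)  # fitness independent of x
  g <- genetic_params(F_x = 3, F_a = 3, sigma = 0.05, V = 150)
  drift <- vapply(1:6, function(s) {
    res <- run_ibm(p, g, seed = 100 + s, t_max = 4000, n0 = 120, x1 = 1,
                   record_every = 4000)
    mean(res$final_state$x) - 1
  }, numeric(1))
  se <- sd(drift) / sqrt(length(drift))
  expect_lt(abs(mean(drift)), 4 * se + 0.02)
})

test_that("gap clustering counts well separated trait groups", {
  expect_equal(cluster_species(rep(2.5, 10))$k, 1L)
  set.seed(8)
  x <- c(rnorm(40, 1, 0.1), rnorm(40, 3.5, 0.1), rnorm(40, 6, 0.1))
  for (gs in c(0.3, 0.5, 0.8)) {
    cl <- cluster_species(x, g_split = gs)
    expect_equal(cl$k, 3L)
  }
  cl <- cluster_species(x)
  expect_equal(cl$means, c(1, 3.5, 6), tolerance = 0.1)
  expect_true(all(cl$assign[1:40] == 1L))
})

test_that("the isolation index is 0 for random mating, 1 for none, 1/2 for half", {
  fx0 <- build_fixture("mating-log", seed = 51, between_frac = 0.5)
  ri0 <- reproductive_isolation(
    data.frame(x_mother = fx0$x_mother, x_father = fx0$x_father),
    breaks = attr(fx0, "breaks"), freqs = c(0.5, 0.5))
  expect_lt(abs(ri0), 0.1)                  # half between = random expectation
  fx1 <- build_fixture("mating-log", seed = 52, between_frac = 0)
  ri1 <- reproductive_isolation(
    data.frame(x_mother = fx1$x_mother, x_father = fx1$x_father),
    breaks = attr(fx1, "breaks"), freqs = c(0.5, 0.5))
  expect_equal(ri1, 1)
  fx5 <- build_fixture("mating-log", seed = 53, between_frac = 0.25)
  ri5 <- reproductive_isolation(
    data.frame(x_mother = fx5$x_mother, x_father = fx5$x_father),
    breaks = attr(fx5, "breaks"), freqs = c(0.5, 0.5))
  expect_equal(ri5, attr(fx5, "ri_truth"), tolerance = 1e-12)
  expect_lt(abs(ri5 - 0.5), 0.1)
  # undefined cases are reported as missing
  expect_true(is.na(reproductive_isolation(
    data.frame(x_mother = numeric(0), x_father = numeric(0)), breaks = 2.5)))
})

test_that("at large volume the IBM tracks the deterministic equilibrium", {
  p <- small_params(n_grid = 300)
  g <- genetic_params(F_x = 3, F_a = 3, nu = 0, V = 1500)
  res <- run_ibm(p, g, seed = 21, t_max = 5000, n0 = 500, x1 = 1,
                 record_every = 100)
  eq <- solve_equilibrium(1, p)
  s <- res$series[res$series$time > 2500, ]
  expect_lt(abs(log(mean(s$R_s) / eq$env["R_s"])), 0.15)
  expect_lt(abs(log(mean(s$R_1) / eq$env["R_1"])), 0.15)
})
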