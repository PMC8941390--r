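# Synthetic fixtures: randomized-but-valid parameter draws for property
# tests, small canned IBM states, mating logs with known ground-truth
# isolation, and growth environments with closed-form growth curves.

#' Build a synthetic test fixture
#'
#' Deterministic (seeded) generators for the objects the test-suite and
#' examples need:
#' \describe{
#'   \item{`random-params`}{a valid [model_params()] draw within documented
#'     ranges (masses, supply rates, niche geometry, both trade-off
#'     settings).}
#'   \item{`small-ibm-state`}{a small founding IBM state plus matching
#'     parameter objects.}
#'   \item{`mating-log`}{a two-cluster mating log with a prescribed
#'     between-cluster mating fraction; the implied ground-truth
#'     reproductive isolation is attached (`ri_truth`, with cluster
#'     frequencies 1/2 each so the random-mating expectation is 1/2).}
#'   \item{`growth-env`}{parameters with `q = n_intake` (so the feeding
#'     level is mass-independent), no mortality and a fixed environment:
#'     the growth curve has the closed form
#'     `m(t) = (m_b^(1/4) + (1 - n) c t)^4` with
#'     `c = (alpha f h - k)` and `f` the (constant) feeding level, exact
#'     while `m < m_mat`.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed (required; generation is deterministic).
#' @param ... kind-specific overrides: `n_matings` and `between_frac`
#'   (mating-log), `n0` (small-ibm-state), `f_level` (growth-env).
#' @return the fixture object; see details per kind.
#' @export
build_fixture <- function(kind = c("random-params", "small-ibm-state",
                                   "mating-log", "growth-env"),
                          seed, ...) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  opts <- list(...)
  switch(kind,
    "random-params" = {
      m_b <- exp(runif(1, log(5e-4), log(0.1)))
      m_shift <- exp(runif(1, log(1), log(10)))
      m_mat <- m_shift * exp(runif(1, log(3), log(20)))
      model_params(
        m_b = m_b, m_shift = m_shift, m_mat = m_mat,
        R_s_max = exp(runif(1, log(0.3), log(3))),
        R_c_max = exp(runif(1, log(0.5), log(2))),
        peak_spacing = runif(1, 2.2, 3.0),
        tau_s = sample(c(Inf, 20), 1),
        theta_1 = runif(1, 0.5, 1.5),
        n_grid = 300
      )
    },
    "small-ibm-state" = {
      n0 <- opts$n0 %||% 50L
      p <- model_params(n_grid = 300)
      g <- genetic_params(F_x = 4L, F_a = 4L, V = 200)
      list(params = p, genetics = g,
           state = init_ibm_state(n0, x1 = 1, p, g, profile = "spread"))
    },
    "mating-log" = {
      n <- opts$n_matings %||% 400L
      between <- opts$between_frac %||% 0
      x_lo <- rnorm(ceiling(n / 2), 1, 0.05)
      x_hi <- rnorm(n - length(x_lo), 4, 0.05)
      mothers <- c(x_lo, x_hi)[sample.int(n)]
      is_between <- runif(n) < between
      fathers <- ifelse(
        xor(mothers < 2.5, is_between),
        rnorm(n, 1, 0.05), rnorm(n, 4, 0.05)
      )
      log <- data.frame(time = seq_len(n), x_mother = mothers,
                        x_father = fathers)
      attr(log, "breaks") <- 2.5
      # two equal clusters: expected between-fraction 1/2 under random mating
      attr(log, "ri_truth") <- 1 - mean(xor(log$x_mother < 2.5,
                                            log$x_father < 2.5)) / 0.5
      log
    },
    "growth-env" = {
      f <- opts$f_level %||% 0.6
      p <- model_params(q = 0.75, m_shift = Inf, tau_s = Inf,
                        mu_0 = 0, xi_starv = 0, n_grid = 300)
      # with q = n the feeding level is constant in m: solve R_s for f
      R_s <- f / (1 - f) * p$h / p$A_max
      env <- resource_env(R_s, rep(0, p$n_resources))
      cgrow <- (p$alpha * f * p$h - p$k_met)
      list(params = p, env = env, f_level = f,
           mass_at_age = function(t)
             (p$m_b^(1 - p$n_intake) +
                (1 - p$n_intake) * cgrow * t)^(1 / (1 - p$n_intake)))
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
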