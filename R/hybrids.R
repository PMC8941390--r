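#' Dimorphic equilibrium loaded with a hybrid swarm
#'
#' Just after evolutionary branching, mating is still random, so roughly half
#' of all offspring are intermediate hybrids. The hybrid cohort does not
#' sustain itself (hybrids rarely mature) but it grazes the intermediate
#' resource and thereby shapes its own fitness. This solver computes the
#' quasi-equilibrium of two parental morphs plus that hybrid load: morphs
#' must achieve R0 = 2 (half their offspring are hybrids), the hybrid
#' newborn flux equals the total cross-mating flux `b_1 + b_2`, and the
#' resource balance includes hybrid consumption.
#'
#' @param x_pair trait values of the two parental morphs.
#' @param x_h hybrid trait value (default: midpoint).
#' @param p a [model_params()] object.
#' @param guess optional list(env, b) starting point; defaults to the plain
#'   dimorphic equilibrium.
#' @return list with `env`, `b` (morph birth rates), `b_hybrid`, `converged`,
#'   and the three [integrate_life_history()] solutions (`lh_pair`,
#'   `lh_hybrid`) evaluated in the loaded environment.
#' @export
hybrid_swarm_equilibrium <- function(x_pair, x_h = mean(x_pair), p,
                                     guess = NULL) {
  stopifnot(length(x_pair) == 2L)
  nR <- p$n_resources + 1L
  resid_fun <- function(v) {
    env <- exp(v[1:nR]); b <- v[nR + 1:2]
    lh1 <- integrate_life_history(x_pair[1], env, p)
    lh2 <- integrate_life_history(x_pair[2], env, p)
    lhh <- integrate_life_history(x_h, env, p)
    rR <- p$delta * (p$R_max - env) -
      b[1] * lh1$C - b[2] * lh2$C - (b[1] + b[2]) * lhh$C
    c(rR, log(max(lh1$R0, 1e-300) / 2), log(max(lh2$R0, 1e-300) / 2))
  }
  if (is.null(guess)) {
    eq0 <- solve_equilibrium(x_pair, p)
    if (!eq0$converged || length(eq0$traits) != 2L)
      stop("no dimorphic starting equilibrium for the hybrid-swarm solve")
    guess <- list(env = eq0$env, b = eq0$b)
  }
  v <- c(log(pmax(guess$env, 1e-12)), pmax(guess$b, 1e-8))
  converged <- FALSE
  for (it in 1:60) {
    r <- resid_fun(v)
    fn <- sum(r^2)
    if (max(abs(r)) < 1e-10) { converged <- TRUE; break }
    J <- matrix(0, nR + 2L, nR + 2L)
    for (j in seq_len(nR + 2L)) {
      vj <- v; vj[j] <- vj[j] + 1e-6
      J[, j] <- (resid_fun(vj) - r) / 1e-6
    }
    st <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(st)) break
    st[1:nR] <- pmin(pmax(st[1:nR], -1), 1)
    lam <- 1; ok <- FALSE
    for (h in 1:14) {
      vn <- v + lam * st
      rn <- resid_fun(vn)
      if (all(is.finite(rn)) && sum(rn^2) < fn) { v <- vn; ok <- TRUE; break }
      lam <- lam / 2
    }
    if (!ok) break
  }
  env <- exp(v[1:nR])
  names(env) <- c("R_s", paste0("R_", seq_len(p$n_resources)))
  b <- v[nR + 1:2]
  list(env = env, b = b, b_hybrid = sum(b), converged = converged,
       lh_pair = lapply(x_pair, integrate_life_history, env = env, p = p),
       lh_hybrid = integrate_life_history(x_h, env, p),
       x_pair = x_pair, x_h = x_h)
}
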