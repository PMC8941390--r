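# Ecological equilibrium of a resident coalition.
#
# Unknowns are the 7 resource densities (log-transformed, which keeps them
# positive) and the population birth rates b_i of the residents. Equations:
# semi-chemostat resource balance for every resource and log R0_i = 0 for
# every resident. The residual is linear in b and R0 is independent of b,
# so the b-block of the Jacobian is analytic (-C_ij and 0); only the
# log-resource block is computed by finite differences.

coalition_rates <- function(traits, env, p, n_grid = p$n_grid) {
  lhs <- lapply(traits, integrate_life_history, env = env, p = p,
                n_grid = n_grid)
  list(
    R0 = vapply(lhs, `[[`, numeric(1), "R0"),
    C = do.call(rbind, lapply(lhs, `[[`, "C")),  # N x 7
    lh = lhs
  )
}

#' Resource-balance residual of a resident coalition
#'
#' For each resource, the semi-chemostat supply `delta * (R_max - R_j)` minus
#' the total depletion `sum_i b_i * C_ij`, where `C_ij` is the lifetime
#' survival-discounted consumption of resource `j` by one newborn of resident
#' `i` in the environment `env`. Zero at an ecological equilibrium.
#'
#' @param coalition list with elements `traits` (niche trait values) and `b`
#'   (population birth rates, newborns m^-3 day^-1).
#' @param env resource-density vector.
#' @param p a [model_params()] object.
#' @return named residual vector (g m^-3 day^-1), one entry per resource.
#' @export
resource_balance_residual <- function(coalition, env, p) {
  r <- p$delta * (p$R_max - env)
  if (length(coalition$traits)) {
    cr <- coalition_rates(coalition$traits, env, p)
    r <- r - drop(crossprod(cr$C, coalition$b))
  }
  names(r) <- c("R_s", paste0("R_", seq_len(p$n_resources)))
  r
}

eq_residual <- function(logR, b, traits, p, n_grid) {
  env <- exp(logR)
  cr <- coalition_rates(traits, env, p, n_grid)
  res_R <- p$delta * (p$R_max - env) - drop(crossprod(cr$C, b))
  c(res_R, log(pmax(cr$R0, 1e-300)))
}

# Damped Newton on v = (log R, b). Analytic b-block of the Jacobian,
# finite differences for the log-resource block. Starts whose environment
# puts some resident in the starvation dead zone (R0 = 0, flat residual)
# are nudged toward carrying capacity first.
newton_eq <- function(traits, p, v0, ctl) {
  nR <- p$n_resources + 1L
  N <- length(traits)
  env0 <- exp(v0[1:nR])
  for (try in 1:10) {
    cr0 <- coalition_rates(traits, env0, p, ctl$n_grid)
    if (all(cr0$R0 > 1e-8)) break
    env0 <- (env0 + p$R_max) / 2
  }
  v <- c(log(env0), v0[-(1:nR)])
  resid <- eq_residual(v[1:nR], v[-(1:nR)], traits, p, ctl$n_grid)
  fnorm <- sum(resid^2)
  converged <- FALSE
  hh <- 1e-6
  for (it in seq_len(ctl$max_iter)) {
    env <- exp(v[1:nR])
    cr <- coalition_rates(traits, env, p, ctl$n_grid)
    JR <- matrix(0, nR + N, nR)
    for (k in seq_len(nR)) {
      vk <- v[1:nR]; vk[k] <- vk[k] + hh
      rk <- eq_residual(vk, v[-(1:nR)], traits, p, ctl$n_grid)
      JR[, k] <- (rk - resid) / hh
    }
    J <- cbind(JR, rbind(-t(cr$C), matrix(0, N, N)))
    step <- tryCatch(solve(J, -resid), error = function(e) NULL)
    if (is.null(step)) {
      ridge <- 1e-8 * max(abs(J))
      step <- tryCatch(
        solve(crossprod(J) + diag(ridge, ncol(J)), -crossprod(J, resid)),
        error = function(e) NULL)
      if (is.null(step)) break
      step <- drop(step)
    }
    step[1:nR] <- pmin(pmax(step[1:nR], -2), 2)  # keep exp() sane
    lam <- 1
    improved <- FALSE
    for (half in 1:15) {
      vn <- v + lam * step
      rn <- eq_residual(vn[1:nR], vn[-(1:nR)], traits, p, ctl$n_grid)
      if (all(is.finite(rn)) && sum(rn^2) < fnorm) {
        v <- vn; resid <- rn; fnorm <- sum(rn^2); improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
    if (max(abs(resid[-(1:nR)])) < ctl$tol_R0 &&
        max(abs(resid[1:nR])) < ctl$tol_res) {
      converged <- TRUE
      break
    }
  }
  list(v = v, converged = converged, fnorm = fnorm)
}

# Robust cold start for a single resident: for a trial birth rate b the
# resource balance R_j = R_max,j - b C_j(R) / delta is solved by a damped
# fixed-point iteration, and b is then bisected on log R0(R(b)) = 0
# (R0 falls with b through resource depletion). Returns a (env, b) guess
# for the Newton polish.
single_resident_guess <- function(x, p, env_seed = NULL, n_grid = p$n_grid) {
  nR <- p$n_resources + 1L
  seed <- if (!is.null(env_seed)) pmax(env_seed, 1e-10) else p$R_max
  env_last <- seed
  env_of_b <- function(b) {
    env <- env_last
    gam <- 0.4; prev_res <- Inf
    for (it in 1:400) {
      C <- integrate_life_history(x, env, p, n_grid = n_grid)$C
      target <- pmax(p$R_max - b * C / p$delta, 1e-10)
      res <- max(abs(target - env))
      if (res < 1e-9) break
      # damp harder whenever the map overshoots (residual not shrinking)
      gam <- if (res > prev_res * 0.999) max(gam * 0.6, 0.02)
             else min(gam * 1.05, 0.7)
      prev_res <- res
      env <- (1 - gam) * env + gam * target
    }
    env_last <<- env
    env
  }
  f <- function(b) {
    log(max(lifetime_R0(x, env_of_b(b), p, n_grid = n_grid), 1e-300))
  }
  if (f(0) <= 0) return(list(env = p$R_max, b = 0))
  b_lo <- 0; b_hi <- 1e-6
  for (i in 1:40) {
    if (f(b_hi) < 0) break
    b_lo <- b_hi
    b_hi <- b_hi * 2
  }
  # plain bisection: robust to the mild history dependence of the
  # warm-started inner iteration
  for (i in 1:45) {
    mid <- (b_lo + b_hi) / 2
    if (f(mid) > 0) b_lo <- mid else b_hi <- mid
    if ((b_hi - b_lo) < 1e-7 * b_hi) break
  }
  b <- (b_lo + b_hi) / 2
  list(env = env_of_b(b), b = b)
}

#' Solve for the ecological equilibrium of a resident coalition
#'
#' Damped Newton solve for the resource densities and resident birth rates
#' satisfying `R0_i = 1` for every persisting resident together with the
#' resource balance. Residents for which no positive birth rate exists are
#' removed and reported as extinct; an empty coalition returns the exact
#' consumer-free equilibrium with every resource at carrying capacity.
#'
#' @param traits niche trait values of the residents (may be empty).
#' @param p a [model_params()] object.
#' @param guess optional list with elements `env` (length 7) and `b`
#'   (length `length(traits)`) used as the starting point; defaults to a
#'   mildly depleted environment with small positive birth rates.
#' @param control list; `tol_R0` (default 1e-9) and `tol_res` (1e-10) are
#'   the convergence tolerances on `|R0 - 1|` and the resource residual,
#'   `max_iter` the Newton iteration cap.
#' @return An `equilibrium_state` object: traits, `b`, `env`, per-resident
#'   `R0`, consumption matrix `C`, cached life histories, residual norm,
#'   extinct traits, and a stability flag (`NA` until
#'   [classify_stability()] is called).
#' @export
solve_equilibrium <- function(traits, p, guess = NULL, control = list()) {
  ctl <- modifyList(list(tol_R0 = 1e-9, tol_res = 1e-10, max_iter = 80,
                         n_grid = p$n_grid), control)
  traits <- as.numeric(traits)
  extinct <- numeric(0)

  if (length(traits)) {
    # a resident not viable even at carrying capacity can never persist
    viable <- vapply(traits, function(x)
      lifetime_R0(x, p$R_max, p, n_grid = ctl$n_grid) > 1, logical(1))
    extinct <- traits[!viable]
    keep <- viable
    if (!is.null(guess) && length(guess$b) == length(traits))
      guess$b <- guess$b[keep]
    traits <- traits[keep]
  }

  if (!length(traits)) {
    env <- p$R_max
    names(env) <- c("R_s", paste0("R_", seq_len(p$n_resources)))
    return(structure(list(
      traits = numeric(0), b = numeric(0), env = env,
      R0 = numeric(0), C = matrix(0, 0, p$n_resources + 1L),
      lh = list(), resid_norm = 0, converged = TRUE,
      extinct = extinct, stability = "stable", params = p
    ), class = "equilibrium_state"))
  }

  N <- length(traits)
  if (is.null(guess)) guess <- list()
  if (is.null(guess$env) || length(guess$b) != N) {
    # cold start: build the coalition up one resident at a time, each time
    # initializing from the robust nested single-resident solve
    g1 <- single_resident_guess(traits[1], p,
                                env_seed = guess$env, n_grid = ctl$n_grid)
    env0 <- g1$env; b0 <- g1$b
    if (N > 1) {
      for (i in 2:N) {
        b0 <- c(b0 * 0.8, max(mean(b0) * 0.5, 1e-6))
        vi <- newton_eq(traits[1:i], p, c(log(pmax(env0, 1e-12)), b0), ctl)
        env0 <- exp(vi$v[1:(p$n_resources + 1L)])
        b0 <- vi$v[-(1:(p$n_resources + 1L))]
        b0 <- pmax(b0, 1e-8)
      }
    }
  } else {
    env0 <- pmax(guess$env, 1e-12)
    b0 <- pmax(guess$b, 1e-8)
  }
  nR <- p$n_resources + 1L
  sol <- newton_eq(traits, p, c(log(env0), b0), ctl)
  if (!sol$converged && N > 1) {
    # fallback: overlay the single-resident equilibria (each resource at
    # its most-depleted value) and re-solve
    singles <- lapply(traits, single_resident_guess, p = p,
                      n_grid = ctl$n_grid)
    envc <- do.call(pmin, lapply(singles, `[[`, "env"))
    bc <- vapply(singles, `[[`, numeric(1), "b") * 0.7
    sol2 <- newton_eq(traits, p, c(log(pmax(envc, 1e-12)), pmax(bc, 1e-8)),
                      ctl)
    if (sol2$converged || sol2$fnorm < sol$fnorm) sol <- sol2
  }
  v <- sol$v; converged <- sol$converged; fnorm <- sol$fnorm

  b <- v[-(1:nR)]
  if (converged && any(b < 0)) {
    # no positive-birth-rate solution for some resident: drop and re-solve
    drop_i <- which.min(b)
    sub <- solve_equilibrium(traits[-drop_i], p,
                             guess = list(env = exp(v[1:nR]), b = b[-drop_i]),
                             control = control)
    sub$extinct <- c(extinct, traits[drop_i], sub$extinct)
    return(sub)
  }

  env <- exp(v[1:nR])
  names(env) <- c("R_s", paste0("R_", seq_len(p$n_resources)))
  cr <- coalition_rates(traits, env, p, ctl$n_grid)
  structure(list(
    traits = traits, b = b, env = env, R0 = cr$R0, C = cr$C, lh = cr$lh,
    resid_norm = sqrt(fnorm), converged = converged,
    extinct = extinct, stability = NA_character_, params = p
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Ecological equilibrium\n")
  if (!length(x$traits)) {
    cat("  consumer-free: all resources at carrying capacity\n")
  } else {
    for (i in seq_along(x$traits))
      cat(sprintf("  resident x = %8.4f  b = %.5g  R0 = %.8f\n",
                  x$traits[i], x$b[i], x$R0[i]))
  }
  cat(sprintf("  R_s = %.5g; specific R = %s\n", x$env[1],
              paste(format(x$env[-1], digits = 4), collapse = ", ")))
  cat(sprintf("  converged: %s (residual %.3g); stability: %s\n",
              x$converged, x$resid_norm, x$stability))
  if (length(x$extinct))
    cat("  extinct traits:", paste(format(x$extinct, digits = 4),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Locate all equilibria of a coalition from a deterministic multi-start
#'
#' Runs [solve_equilibrium()] from a fixed list of starting points designed
#' to land in the small-consumer-dominated basin (shared resource depleted),
#' the large-consumer-dominated basin (specific resources depleted) and the
#' intermediate unstable state, and returns the distinct converged solutions.
#'
#' @inheritParams solve_equilibrium
#' @return list of distinct `equilibrium_state` objects.
#' @export
find_equilibria <- function(traits, p, control = list()) {
  N <- length(traits)
  shared_frac <- c(0.9, 0.5, 0.1, 0.02, 0.9, 0.5)
  spec_frac <- c(0.9, 0.5, 0.9, 0.9, 0.1, 0.15)
  bs <- c(1e-4, 1e-3, 1e-2, 0.1, 1e-3, 1e-2)
  sols <- list()
  for (s in seq_along(shared_frac)) {
    g <- list(env = c(shared_frac[s] * p$R_s_max, spec_frac[s] * p$R_c_max),
              b = rep(bs[s], N))
    eq <- solve_equilibrium(traits, p, guess = g, control = control)
    if (!eq$converged) next
    dup <- any(vapply(sols, function(z)
      length(z$b) == length(eq$b) &&
        max(abs(log(pmax(z$env, 1e-12)) - log(pmax(eq$env, 1e-12)))) < 1e-5,
      logical(1)))
    if (!dup) sols[[length(sols) + 1L]] <- eq
  }
  sols
}

#' Standing consumer biomass below and above the diet-shift mass
#'
#' Biomass density (g m^-3) of small (`m < m_shift`) and large
#' (`m >= m_shift`) consumers implied by an equilibrium state: birth rates
#' times the per-newborn standing-biomass integrals of the life histories.
#'
#' @param eq an `equilibrium_state`.
#' @return named numeric `c(small =, large =)`.
#' @export
standing_biomass <- function(eq) {
  if (!length(eq$traits)) return(c(small = 0, large = 0))
  sm <- sum(eq$b * vapply(eq$lh, `[[`, numeric(1), "biomass_small"))
  lg <- sum(eq$b * vapply(eq$lh, `[[`, numeric(1), "biomass_large"))
  c(small = sm, large = lg)
}
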