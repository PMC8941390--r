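# Life-history integration in a fixed resource environment.
#
# At an ecological equilibrium a (mutant or resident) individual experiences
# a constant environment, so the age-structured system
#   dm/dt = g(m), dS/dt = -mu(m) S, dB/dt = fec(m) S, dC_j/dt = cons_j(m) S
# can be rewritten as quadratures over mass wherever growth is positive
# (dt = dm/g(m)) with a closed-form tail once growth stops (determinate
# growth at m_mat, or a starvation stall). Integrals are evaluated by
# cumulative Simpson quadrature on a log-mass grid split exactly at the
# diet-shift and maturation masses, so the discrete diet shift never falls
# inside a quadrature panel.

# Cumulative Simpson integral on an evenly spaced grid (odd node count).
# Returns the running integral at every node; O(h^4).
cumsimp <- function(y, h) {
  n <- length(y)
  stopifnot(n >= 3L, n %% 2L == 1L)
  I <- numeric(n)
  idx <- seq(1L, n - 2L, by = 2L)
  panel <- (h / 3) * (y[idx] + 4 * y[idx + 1L] + y[idx + 2L])
  Iodd <- c(0, cumsum(panel))
  I[seq(1L, n, by = 2L)] <- Iodd
  I[idx + 1L] <- Iodd[-length(Iodd)] +
    (h / 12) * (5 * y[idx] + 8 * y[idx + 1L] - y[idx + 2L])
  I
}

# odd number of nodes >= 5 for a mass segment
odd_nodes <- function(n_grid) {
  n <- max(5L, as.integer(n_grid))
  if (n %% 2L == 0L) n + 1L else n
}

#' Integrate the life history of one phenotype in a fixed environment
#'
#' Computes the full life-history solution of an individual with niche trait
#' `x` born at mass `m_b` into the constant resource environment `env`:
#' growth trajectory, survival, cumulative reproduction, the lifetime
#' reproductive number R0, and the lifetime (survival-discounted) consumption
#' of every resource, which closes the population-level resource balance.
#'
#' Growth is integrated exactly through the diet-shift discontinuity by
#' splitting the mass axis at `m_shift` and `m_mat`. If net energy is
#' non-positive at some mass (starvation stall) the individual stops growing
#' there, keeps consuming, and dies at the (starvation-elevated) mortality
#' rate; an individual that stalls below `m_mat` has R0 = 0. Under the
#' default smooth allocation adults are integrated on a grid geometric in
#' distance to the asymptotic mass and the terminal pile-up near the
#' asymptote contributes in closed form (`fec * S / mu` at the final mass);
#' under `allocation = "fixed"` with `kappa_repro = 1` the whole adult phase
#' is that closed form at `m_mat`.
#'
#' @param x niche trait value.
#' @param env resource-density vector (`R_s` first, see [resource_env()]).
#' @param p a [model_params()] object.
#' @param n_grid quadrature nodes per mass segment (defaults to `p$n_grid`).
#' @return A `life_history` object: list with elements `R0`, `S_mat`
#'   (survival to maturation), `C` (lifetime consumption per resource, g per
#'   newborn), `age_shift`, `age_mat`, `N_small`/`N_large` and
#'   `biomass_small`/`biomass_large` (standing number and biomass per unit
#'   newborn flux, split at `m_shift`), `stalled`, `m_stall`, and a
#'   `trajectory` data frame (age, mass, S, B).
#' @export
integrate_life_history <- function(x, env, p, n_grid = p$n_grid) {
  nres <- p$n_resources + 1L
  # juvenile mass segments, split at the diet shift
  cuts <- c(p$m_b, p$m_shift, p$m_mat)
  cuts <- sort(unique(pmin(pmax(cuts, p$m_b), p$m_mat)))
  nn <- odd_nodes(n_grid)

  t0 <- 0; L0 <- 0
  C <- numeric(nres); B <- 0
  N_small <- N_large <- bio_small <- bio_large <- 0
  ages <- c(0); masses <- c(p$m_b); Ss <- c(1); Bs <- c(0)
  stalled <- FALSE; m_T <- p$m_mat
  age_shift <- if (p$m_b >= p$m_shift) 0 else NA_real_
  age_mat <- NA_real_

  for (s in seq_len(length(cuts) - 1L)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    if (b <= a) next
    phase <- if (p$shift_mode == "gradual") "auto"
             else if (b <= p$m_shift) "pre" else "post"
    u <- seq(log(a), log(b), length.out = nn)
    hu <- u[2L] - u[1L]
    m <- exp(u); m[1L] <- a; m[nn] <- b
    vr <- vital_rates(m, x, env, p, stage = "juvenile", phase = phase)
    g <- vr$growth
    k <- which(g <= 0)[1L]
    if (!is.na(k) && k == 1L) {       # stalls at the segment start
      stalled <- TRUE; m_T <- a
      break
    }
    if (!is.na(k)) {                  # stalls inside the segment
      keep <- k - 1L
      if (keep %% 2L == 0L) keep <- keep - 1L
      if (keep < 3L) { stalled <- TRUE; m_T <- a; break }
      u <- u[seq_len(keep)]; m <- m[seq_len(keep)]
      vr <- lapply(vr, function(z) if (is.matrix(z)) z[seq_len(keep), , drop = FALSE] else z[seq_len(keep)])
      g <- vr$growth
      stalled <- TRUE
    }
    w <- m / g                         # dt/du on the log-mass grid
    tt <- t0 + cumsimp(w, hu)
    Lam <- L0 + cumsimp(vr$mortality * w, hu)
    S <- exp(-Lam)
    C <- C + colSums_simp(vr$cons * (S * w), hu)
    nseg <- cumsimp(S * w, hu)[length(m)]
    bseg <- cumsimp(m * S * w, hu)[length(m)]
    if (b <= p$m_shift) { N_small <- N_small + nseg; bio_small <- bio_small + bseg }
    else { N_large <- N_large + nseg; bio_large <- bio_large + bseg }
    ages <- c(ages, tt[-1L]); masses <- c(masses, m[-1L])
    Ss <- c(Ss, S[-1L]); Bs <- c(Bs, rep(B, length(m) - 1L))
    t0 <- tt[length(m)]; L0 <- Lam[length(m)]
    if (stalled) { m_T <- m[length(m)]; break }
    if (abs(b - p$m_shift) < 1e-12) age_shift <- t0
  }

  S_T <- exp(-L0)
  # adult growth toward the asymptotic mass (smooth allocation): grids are
  # geometric in (m_asym - m) so the slow approach to the asymptote is
  # resolved; the pile-up at the asymptote itself is the closed-form tail
  if (!stalled && p$allocation == "smooth") {
    M <- p$m_asym
    m_stop <- M * (1 - 1e-5)
    acuts <- sort(unique(c(p$m_mat,
                           if (p$m_shift > p$m_mat && p$m_shift < m_stop) p$m_shift,
                           m_stop)))
    for (s in seq_len(length(acuts) - 1L)) {
      a <- acuts[s]; bb <- acuts[s + 1L]
      if (bb <= a) next
      phase <- if (p$shift_mode == "gradual") "auto"
               else if (bb <= p$m_shift) "pre" else "post"
      u <- seq(log(M - a), log(M - bb), length.out = nn)
      hu <- u[1L] - u[2L]
      m <- M - exp(u); m[1L] <- a; m[nn] <- bb
      vr <- vital_rates(m, x, env, p, stage = "adult", phase = phase)
      g <- vr$growth
      k <- which(g <= 0)[1L]
      if (!is.na(k) && k <= 3L) { stalled <- TRUE; m_T <- a; break }
      if (!is.na(k)) {
        keep <- k - 1L; if (keep %% 2L == 0L) keep <- keep - 1L
        u <- u[seq_len(keep)]; m <- m[seq_len(keep)]
        vr <- lapply(vr, function(z) if (is.matrix(z)) z[seq_len(keep), , drop = FALSE] else z[seq_len(keep)])
        g <- vr$growth
        stalled <- TRUE
      }
      w <- (M - m) / g                 # dm/d(-u) on the tip-geometric grid
      tt <- t0 + cumsimp(w, hu)
      Lam <- L0 + cumsimp(vr$mortality * w, hu)
      S <- exp(-Lam)
      Bcum <- B + cumsimp(vr$fecundity * S * w, hu)
      C <- C + colSums_simp(vr$cons * (S * w), hu)
      nseg <- cumsimp(S * w, hu)[length(m)]
      bseg <- cumsimp(m * S * w, hu)[length(m)]
      if (bb <= p$m_shift) { N_small <- N_small + nseg; bio_small <- bio_small + bseg }
      else { N_large <- N_large + nseg; bio_large <- bio_large + bseg }
      ages <- c(ages, tt[-1L]); masses <- c(masses, m[-1L])
      Ss <- c(Ss, S[-1L]); Bs <- c(Bs, Bcum[-1L])
      t0 <- tt[length(m)]; L0 <- Lam[length(m)]; B <- Bcum[length(m)]
      m_T <- m[length(m)]
      if (stalled) break
    }
    S_T <- exp(-L0)
  }
  # fixed allocation with kappa < 1: open-ended adult growth, doubling
  # mass segments until the survival floor
  if (!stalled && p$allocation == "fixed" && p$kappa_repro < 1) {
    lo <- p$m_mat
    for (dbl in 1:30) {
      hi <- lo * 2
      u <- seq(log(lo), log(hi), length.out = nn); hu <- u[2L] - u[1L]
      m <- exp(u)
      vr <- vital_rates(m, x, env, p, stage = "adult")
      g <- vr$growth
      k <- which(g <= 0)[1L]
      if (!is.na(k) && k <= 3L) { stalled <- TRUE; m_T <- lo; break }
      if (!is.na(k)) {
        keep <- k - 1L; if (keep %% 2L == 0L) keep <- keep - 1L
        u <- u[seq_len(keep)]; m <- m[seq_len(keep)]
        vr <- lapply(vr, function(z) if (is.matrix(z)) z[seq_len(keep), , drop = FALSE] else z[seq_len(keep)])
        g <- vr$growth
        stalled <- TRUE
      }
      w <- m / g
      tt <- t0 + cumsimp(w, hu)
      Lam <- L0 + cumsimp(vr$mortality * w, hu)
      S <- exp(-Lam)
      Bcum <- B + cumsimp(vr$fecundity * S * w, hu)
      C <- C + colSums_simp(vr$cons * (S * w), hu)
      N_large <- N_large + cumsimp(S * w, hu)[length(m)]
      bio_large <- bio_large + cumsimp(m * S * w, hu)[length(m)]
      ages <- c(ages, tt[-1L]); masses <- c(masses, m[-1L])
      Ss <- c(Ss, S[-1L]); Bs <- c(Bs, Bcum[-1L])
      t0 <- tt[length(m)]; L0 <- Lam[length(m)]; B <- Bcum[length(m)]
      m_T <- m[length(m)]
      if (stalled || exp(-L0) < p$S_min) break
      lo <- hi
    }
    S_T <- exp(-L0)
  }

  # closed-form tail: the individual sits at m_T until death
  vrT <- vital_rates(m_T, x, env, p)
  muT <- vrT$mortality
  life_T <- if (muT > 0) S_T / muT else if (S_T > 0) Inf else 0
  B <- B + (if (vrT$fecundity > 0) life_T * vrT$fecundity else 0)
  C <- C + as.numeric(vrT$cons) * (if (is.finite(life_T)) life_T else 0)
  if (m_T >= p$m_shift) {
    N_large <- N_large + life_T; bio_large <- bio_large + m_T * life_T
  } else {
    N_small <- N_small + life_T; bio_small <- bio_small + m_T * life_T
  }

  # with determinate growth the final juvenile node is exactly m_mat
  i_mat <- which(masses >= p$m_mat - 1e-12)[1L]
  S_mat <- 0
  if (!is.na(i_mat)) {
    S_mat <- Ss[i_mat]
    age_mat <- ages[i_mat]
  }
  if (is.na(age_shift) && any(masses >= p$m_shift)) {
    age_shift <- ages[which(masses >= p$m_shift)[1L]]
  }

  # a short reported tail at constant mass down to the survival floor
  t_end <- if (muT > 0) t0 + log(max(S_T, p$S_min) / p$S_min) / muT else t0
  if (t_end > t0) {
    tt_tail <- seq(t0, t_end, length.out = 12L)[-1L]
    S_tail <- S_T * exp(-muT * (tt_tail - t0))
    B_tail <- B - S_tail * vrT$fecundity / muT
    ages <- c(ages, tt_tail); masses <- c(masses, rep(m_T, length(tt_tail)))
    Ss <- c(Ss, S_tail); Bs <- c(Bs, B_tail)
  }

  names(C) <- c("R_s", paste0("R_", seq_len(p$n_resources)))
  structure(list(
    x = x, env = env, R0 = B, S_mat = S_mat, C = C,
    age_shift = age_shift, age_mat = age_mat,
    N_small = N_small, N_large = N_large,
    biomass_small = bio_small, biomass_large = bio_large,
    stalled = stalled, m_stall = if (stalled) m_T else NA_real_,
    trajectory = data.frame(age = ages, mass = masses, S = Ss, B = Bs)
  ), class = "life_history")
}

# Simpson integral of every column of a matrix of integrand values
colSums_simp <- function(M, h) {
  n <- nrow(M)
  idx <- seq(1L, n - 2L, by = 2L)
  (h / 3) * colSums(M[idx, , drop = FALSE] + 4 * M[idx + 1L, , drop = FALSE] +
                      M[idx + 2L, , drop = FALSE])
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("Life history of phenotype x = %.4g\n", x$x))
  cat(sprintf("  R0 = %.6g, survival to maturation = %.4g\n", x$R0, x$S_mat))
  if (x$stalled) cat(sprintf("  growth stalls at m = %.4g g\n", x$m_stall))
  if (!is.na(x$age_mat))
    cat(sprintf("  age at shift = %.4g d, age at maturation = %.4g d\n",
                x$age_shift, x$age_mat))
  invisible(x)
}

#' Lifetime reproductive number of a phenotype in a fixed environment
#'
#' Convenience wrapper around [integrate_life_history()] returning only R0,
#' the expected lifetime offspring production of an individual born into the
#' constant environment `env`.
#'
#' @inheritParams integrate_life_history
#' @return R0 (dimensionless).
#' @export
lifetime_R0 <- function(x, env, p, n_grid = p$n_grid) {
  integrate_life_history(x, env, p, n_grid = n_grid)$R0
}

#' Individual growth curve in a fixed environment
#'
#' Age-mass trajectory of a phenotype, with the ages at which the diet-shift
#' and maturation masses are crossed attached as attributes. A projection of
#' [integrate_life_history()].
#'
#' @inheritParams integrate_life_history
#' @return data frame with columns `age`, `mass`, `S` (survival); attributes
#'   `age_shift` and `age_mat`.
#' @export
growth_curve <- function(x, env, p, n_grid = p$n_grid) {
  lh <- integrate_life_history(x, env, p, n_grid = n_grid)
  out <- lh$trajectory[, c("age", "mass", "S")]
  attr(out, "age_shift") <- lh$age_shift
  attr(out, "age_mat") <- lh$age_mat
  attr(out, "stalled") <- lh$stalled
  out
}
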