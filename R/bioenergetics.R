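#' Trait-dependent attack-rate coefficient
#'
#' The attack-rate coefficient on resource `j` declines in a Gaussian manner
#' as the niche trait moves away from the resource's optimum:
#' `A_max * exp(-(x - theta_j)^2 / (2 tau_j^2))`. An infinite niche width
#' (`tau_j = Inf`, the default for the shared resource) makes the coefficient
#' equal to `A_max` for every trait value.
#'
#' @param x niche trait value (scalar or vector).
#' @param j resource index: 1 is the shared resource, `2 .. n_resources + 1`
#'   the species-specific resources.
#' @param p a [model_params()] object.
#' @return attack coefficient(s), same units as `A_max`.
#' @export
attack_coefficient <- function(x, j, p) {
  if (any(j < 1L) || any(j > p$n_resources + 1L) || any(j != floor(j)))
    stop("invalid resource index")
  th <- p$theta[j]
  tw <- p$tau[j]
  # finite^2 / Inf == 0, so tau = Inf yields exp(0) = A_max automatically
  p$A_max * exp(-((x - th)^2) / (2 * tw^2))
}

# All attack coefficients of one phenotype, length n_resources + 1.
attack_vector <- function(x, p) {
  tw2 <- 2 * p$tau^2
  a <- p$A_max * exp(-((x - p$theta)^2) / tw2)
  a[is.infinite(p$tau)] <- p$A_max
  a
}

#' Ontogenetic diet weight
#'
#' Access mask of an individual of mass `m` on resource `j` (1 = shared). In
#' the default discrete mode individuals feed exclusively on the shared
#' resource below `m_shift` and exclusively on the species-specific resources
#' from `m_shift` on. In gradual mode the shared weight declines logistically
#' in log mass around `m_shift` (complementary weight on the specific
#' resources); in broadening mode the shared resource remains fully
#' accessible at all sizes while specific-resource access still opens at
#' `m_shift`. Weights are an access mask, not a preference distribution, so
#' they need not sum to one.
#'
#' @param m body mass (g), vectorized.
#' @param j resource index (1 = shared).
#' @param p a [model_params()] object.
#' @return weight(s) in `[0, 1]`.
#' @export
diet_weight <- function(m, j, p) {
  if (any(j < 1L) || any(j > p$n_resources + 1L)) stop("invalid resource index")
  if (any(m < p$m_b)) stop("mass below mass at birth")
  w <- diet_weight_matrix(m, p)
  unname(w[, j])
}

# length(m) x (n_resources + 1) access-weight matrix; phase = "pre"/"post"
# pins the discrete rule on one side of m_shift for quadrature endpoints.
diet_weight_matrix <- function(m, p, phase = c("auto", "pre", "post")) {
  phase <- match.arg(phase)
  nm <- length(m)
  nr <- p$n_resources
  if (p$shift_mode == "gradual" && is.finite(p$m_shift) && p$m_shift > 0) {
    ws <- 1 / (1 + (m / p$m_shift)^p$shift_steep)
    wc <- 1 - ws
  } else {
    post <- switch(phase,
      auto = m >= p$m_shift,
      pre = rep(FALSE, nm),
      post = rep(TRUE, nm)
    )
    wc <- as.numeric(post)
    ws <- if (p$shift_mode == "broadening") rep(1, nm) else 1 - wc
    if (p$shift_mode == "gradual") ws <- 1 - wc  # m_shift 0 or Inf: degenerate
  }
  cbind(ws, matrix(wc, nm, nr))
}

#' Rate of food encounter
#'
#' Mass flux of food encountered by an individual: the sum over accessible
#' resources of `diet_weight * attack_coefficient * m^q * R_j` (g day^-1).
#'
#' @param m body mass (g), vectorized.
#' @param x niche trait value.
#' @param env resource-density vector (see [resource_env()]).
#' @param p a [model_params()] object.
#' @return encountered food mass flux (g day^-1).
#' @export
encounter_rate <- function(m, x, env, p) {
  if (any(env < 0)) stop("resource densities must be non-negative")
  w <- diet_weight_matrix(m, p)
  a <- attack_vector(x, p)
  drop(w %*% (a * env)) * m^p$q
}

#' Feeding level
#'
#' Realized intake as a fraction of the maximum intake `h * m^n_intake`
#' (type-II functional response): `f = E / (E + h m^n)` with `E` the
#' encounter rate. Dimensionless, in `[0, 1]`.
#'
#' @inheritParams encounter_rate
#' @return feeding level(s) in `[0, 1]`.
#' @export
feeding_level <- function(m, x, env, p) {
  E <- encounter_rate(m, x, env, p)
  E / (E + p$h * m^p$n_intake)
}

# Fraction of adult net energy routed to reproduction. Under the smooth
# rule this rises from ~ (eta_mat)^(1-n) at maturation to 1 at the
# asymptotic mass m_asym, so growth slows smoothly toward m_asym; the gate
# to zero below m_mat is applied by the caller (juveniles never reproduce).
reproductive_fraction <- function(m, p) {
  if (p$allocation == "fixed") return(rep(p$kappa_repro, length(m)))
  pmin(1, (m / p$m_asym)^(1 - p$n_intake) / (1 + (m / p$m_mat)^(-p$psi_exp)))
}

# Core bioenergetic closure evaluated on a mass vector in a fixed
# environment. Returns all individual-level rates at once; `stage` pins the
# allocation rule on one side of m_mat for quadrature endpoints and `phase`
# pins the diet on one side of m_shift.
vital_rates <- function(m, x, env, p,
                        stage = c("auto", "juvenile", "adult"),
                        phase = c("auto", "pre", "post")) {
  stage <- match.arg(stage)
  w <- diet_weight_matrix(m, p, phase = match.arg(phase))
  a <- attack_vector(x, p)
  Ej <- w * rep(a * env, each = length(m)) * m^p$q   # per-resource encounter
  E <- rowSums(Ej)
  h_m <- p$h * m^p$n_intake
  f <- ifelse(E > 0, E / (E + h_m), 0)
  E_net <- p$alpha * f * h_m - p$k_met * m^p$p_met
  surplus <- pmax(E_net, 0)
  deficit <- pmax(-E_net, 0)
  adult <- switch(stage,
    auto = m >= p$m_mat,
    juvenile = rep(FALSE, length(m)),
    adult = rep(TRUE, length(m))
  )
  psi <- reproductive_fraction(m, p)
  growth <- ifelse(adult, (1 - psi) * surplus, surplus)
  repro_flux <- ifelse(adult, psi * surplus, 0)
  fecundity <- p$eps_egg * repro_flux / p$m_b
  mortality <- p$mu_0 * m^p$mort_exp + p$xi_starv * deficit / m
  cons <- Ej * (1 - f)   # realized per-resource consumption (g day^-1)
  list(f = f, E = E, E_net = E_net, growth = growth,
       fecundity = fecundity, mortality = mortality, cons = cons)
}

#' Somatic growth rate
#'
#' Net energy (assimilated intake minus maintenance) routed to growth.
#' Juveniles (`m < m_mat`) invest all net energy in growth; adults invest the
#' fraction `1 - kappa_repro` (zero under the default determinate-growth
#' rule). Growth is floored at zero: energy deficits do not shrink the body
#' but raise mortality instead (see [mortality_rate()]).
#'
#' @inheritParams encounter_rate
#' @return growth rate dm/dt (g day^-1).
#' @export
growth_rate <- function(m, x, env, p) {
  vital_rates(m, x, env, p)$growth
}

#' Fecundity rate
#'
#' Offspring production rate of an adult: the reproductive energy flux
#' (`kappa_repro` times net energy, zero for juveniles and for starving
#' adults) converted to eggs of mass `m_b` with efficiency `eps_egg`.
#'
#' @inheritParams encounter_rate
#' @return offspring day^-1.
#' @export
fecundity_rate <- function(m, x, env, p) {
  vital_rates(m, x, env, p)$fecundity
}

#' Mortality rate
#'
#' Background mortality `mu_0 * m^mort_exp` plus starvation mortality: when
#' assimilated intake falls short of maintenance the per-capita death rate
#' increases by `xi_starv` times the relative energy deficit (deficit per
#' unit body mass).
#'
#' @inheritParams encounter_rate
#' @return per-capita mortality rate (day^-1).
#' @export
mortality_rate <- function(m, x, env, p) {
  vital_rates(m, x, env, p)$mortality
}
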