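#' Ecological and bioenergetic model parameters
#'
#' Builds the parameter set for the size-structured consumer-resource model.
#' Consumers are born at mass `m_b`, feed on a shared resource until they reach
#' the diet-shift mass `m_shift`, from which point they have access to
#' `n_resources` species-specific resources, and mature at `m_mat`, after which
#' net energy is routed to reproduction. Resource use is governed by a
#' Gaussian trait-matching attack-rate coefficient around per-resource optima
#' `theta` with widths `tau`; resources renew with semi-chemostat dynamics.
#'
#' The bioenergetic closure follows the size-spectrum framework of
#' Hartvig, Andersen & Beyer (2011, J. Theor. Biol. 272:113-122): type-II
#' (saturating) intake with maximum intake `h * m^n_intake`, assimilation
#' efficiency `alpha`, maintenance `k_met * m^p_met`, a hard allocation switch
#' at maturation routing the fraction `kappa_repro` of net energy to
#' reproduction (the default 1 gives determinate growth), egg-production
#' efficiency `eps_egg`, and background mortality `mu_0 * m^mort_exp`.
#' Published fish-community values, converted to day units, are the defaults.
#' `A_max` is calibrated so that a 1 g individual at its optimal resource held
#' at 1 g m-3 realizes a feeding level of 0.6 (the same reference-feeding-level
#' calibration used in that framework).
#'
#' @param m_b body mass at birth (g).
#' @param m_mat body mass at maturation (g).
#' @param m_shift body mass at the ontogenetic diet shift (g). `0` gives
#'   lifelong access to the species-specific resources; `Inf` confines the
#'   consumer to the shared resource.
#' @param q allometric exponent of the mass-dependent attack rate.
#' @param A_max maximum attack-rate coefficient (m^3 g^-q day^-1).
#' @param n_resources number of species-specific resources.
#' @param theta_s optimal niche trait for the shared resource (only relevant
#'   for finite `tau_s`).
#' @param theta_1 optimal niche trait for the first species-specific resource.
#' @param peak_spacing distance between adjacent resource optima.
#' @param tau niche width of the species-specific feeding curves.
#' @param tau_s niche width for the shared resource; `Inf` (default) removes
#'   any juvenile trade-off, `20` gives the weak developmental trade-off.
#' @param delta resource turnover rate (day^-1), shared by all resources.
#' @param R_s_max carrying density of the shared resource (g m^-3). The supply
#'   rate quoted in scenario descriptions is `delta * R_s_max`.
#' @param R_c_max carrying density of the species-specific resources (g m^-3);
#'   scalar or one value per resource.
#' @param shift_mode `"discrete"` (default), `"gradual"` (logistic transition
#'   in log mass centred on `m_shift`) or `"broadening"` (the shared resource
#'   stays accessible for life).
#' @param shift_steep steepness of the logistic transition in gradual mode;
#'   larger values approach the discrete shift.
#' @param h,n_intake maximum-intake coefficient (g^(1-n_intake) day^-1) and exponent.
#' @param alpha assimilation efficiency.
#' @param k_met,p_met maintenance coefficient (g^(1-p_met) day^-1) and exponent.
#' @param allocation adult energy-allocation rule. `"smooth"` (default) uses
#'   the mass-dependent reproductive fraction
#'   `psi(m) = min(1, [1 + (m/m_mat)^-psi_exp]^-1 (m/M)^(1-n_intake))` with
#'   asymptotic mass `M = m_mat / eta_mat`, gated to zero below `m_mat`;
#'   growth then slows smoothly toward `M` and adults spread over sizes.
#'   `"fixed"` routes the constant fraction `kappa_repro` to reproduction
#'   from `m_mat` on (determinate growth at `m_mat` when `kappa_repro = 1`).
#' @param eta_mat ratio of maturation to asymptotic mass (smooth allocation).
#' @param psi_exp sharpness of the allocation switch around `m_mat`.
#' @param kappa_repro adult reproductive fraction for `allocation = "fixed"`.
#' @param eps_egg efficiency of converting reproductive energy into egg mass.
#' @param mu_0,mort_exp background mortality coefficient (g^-mort_exp day^-1)
#'   and mass exponent.
#' @param xi_starv starvation mortality per unit relative energy deficit.
#' @param S_min survival probability below which life-history integration is
#'   truncated.
#' @param n_grid quadrature nodes per life-history phase.
#'
#' @return An object of class `model_params`: a validated list with the above
#'   fields plus the assembled vectors `theta` and `tau` (length
#'   `n_resources + 1`; element 1 is the shared resource) and `R_max`.
#' @examples
#' p <- model_params()
#' p$theta
#' attack_coefficient(1, 2, p)  # consumer at the first optimum
#' @export
model_params <- function(m_b = 0.05,
                         m_mat = 50,
                         m_shift = 5,
                         q = 0.8,
                         A_max = 0.35,
                         n_resources = 6,
                         theta_s = 0,
                         theta_1 = 1,
                         peak_spacing = 2.5,
                         tau = 1,
                         tau_s = Inf,
                         delta = 0.1,
                         R_s_max = 2,
                         R_c_max = 1,
                         shift_mode = c("discrete", "gradual", "broadening"),
                         shift_steep = 10,
                         h = 85 / 365,
                         n_intake = 0.75,
                         alpha = 0.6,
                         k_met = 10 / 365,
                         p_met = 0.75,
                         allocation = c("smooth", "fixed"),
                         eta_mat = 0.25,
                         psi_exp = 10,
                         kappa_repro = 1,
                         eps_egg = 0.1,
                         mu_0 = 1.68 / 365,
                         mort_exp = -0.25,
                         xi_starv = 1,
                         S_min = 1e-12,
                         n_grid = 400) {
  shift_mode <- match.arg(shift_mode)
  allocation <- match.arg(allocation)
  if (length(R_c_max) == 1L) R_c_max <- rep(R_c_max, n_resources)
  theta <- c(theta_s, theta_1 + peak_spacing * (seq_len(n_resources) - 1))
  tauv <- c(tau_s, rep(tau, n_resources))
  p <- list(
    m_b = m_b, m_mat = m_mat, m_shift = m_shift,
    q = q, A_max = A_max,
    n_resources = n_resources,
    theta = theta, tau = tauv,
    theta_s = theta_s, theta_1 = theta_1, peak_spacing = peak_spacing,
    tau_width = tau, tau_s = tau_s,
    delta = delta, R_s_max = R_s_max, R_c_max = R_c_max,
    R_max = c(R_s_max, R_c_max),
    shift_mode = shift_mode, shift_steep = shift_steep,
    h = h, n_intake = n_intake, alpha = alpha,
    k_met = k_met, p_met = p_met,
    allocation = allocation, eta_mat = eta_mat, psi_exp = psi_exp,
    m_asym = m_mat / eta_mat,
    kappa_repro = kappa_repro, eps_egg = eps_egg,
    mu_0 = mu_0, mort_exp = mort_exp, xi_starv = xi_starv,
    S_min = S_min, n_grid = n_grid
  )
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

#' Validate a model parameter object
#'
#' Checks the structural invariants of a [model_params()] object: positive
#' masses, positive turnover and carrying densities, positive (or infinite)
#' niche widths and strictly increasing species-specific optima. Note that no
#' ordering between `m_shift` and `m_mat` is imposed: the diet shift may
#' precede or follow maturation.
#'
#' @param p a `model_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!(p$m_b > 0 && p$m_mat > 0)) stop("masses must be positive")
  if (p$m_shift < 0) stop("m_shift must be >= 0")
  if (p$m_b >= p$m_mat) stop("m_b must be smaller than m_mat")
  if (!(p$delta > 0)) stop("resource turnover delta must be positive")
  if (any(p$R_max <= 0)) stop("carrying densities must be positive")
  if (any(!(p$tau > 0))) stop("niche widths must be positive (Inf allowed)")
  if (length(p$theta) != p$n_resources + 1L)
    stop("theta must have one entry per resource plus the shared resource")
  if (any(diff(p$theta[-1L]) <= 0))
    stop("species-specific optima must be strictly increasing")
  if (p$kappa_repro < 0 || p$kappa_repro > 1)
    stop("kappa_repro must lie in [0, 1]")
  if (p$allocation == "smooth" && !(p$eta_mat > 0 && p$eta_mat < 1))
    stop("eta_mat must lie in (0, 1)")
  if (p$eps_egg <= 0 || p$alpha <= 0) stop("efficiencies must be positive")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Size-structured consumer-resource model parameters\n")
  cat(sprintf("  masses (g): m_b = %g, m_shift = %g, m_mat = %g  [%s shift]\n",
              x$m_b, x$m_shift, x$m_mat, x$shift_mode))
  cat(sprintf("  resources: shared (tau_s = %g) + %d specific at theta = %s\n",
              x$tau_s, x$n_resources,
              paste(format(x$theta[-1L]), collapse = ", ")))
  cat(sprintf("  supply: delta = %g /day, R_s_max = %g, R_c_max = %s g/m^3\n",
              x$delta, x$R_s_max, paste(format(x$R_c_max), collapse = ", ")))
  cat(sprintf("  intake: A_max = %g, q = %g, h = %.4g, n = %g, alpha = %g\n",
              x$A_max, x$q, x$h, x$n_intake, x$alpha))
  cat(sprintf("  maintenance: k = %.4g m^%g; mortality: %.4g m^%g (+starvation)\n",
              x$k_met, x$p_met, x$mu_0, x$mort_exp))
  if (x$allocation == "smooth") {
    cat(sprintf("  reproduction: smooth allocation, m_asym = %g g, eps_egg = %g\n",
                x$m_asym, x$eps_egg))
  } else {
    cat(sprintf("  reproduction: fixed fraction kappa = %g, eps_egg = %g\n",
                x$kappa_repro, x$eps_egg))
  }
  invisible(x)
}

#' Update model parameters by name
#'
#' Returns a copy of `p` with the named fields replaced and all derived
#' vectors (`theta`, `tau`, `R_max`) rebuilt. Used by parameter continuation
#' and the scenario grids.
#'
#' @param p a `model_params` object.
#' @param ... named scalar fields accepted by [model_params()], e.g.
#'   `R_s_max = 0.25`, `m_shift = 1`.
#' @return an updated, validated `model_params` object.
#' @export
update_params <- function(p, ...) {
  upd <- list(...)
  args <- list(
    m_b = p$m_b, m_mat = p$m_mat, m_shift = p$m_shift, q = p$q,
    A_max = p$A_max, n_resources = p$n_resources, theta_s = p$theta_s,
    theta_1 = p$theta_1, peak_spacing = p$peak_spacing, tau = p$tau_width,
    tau_s = p$tau_s, delta = p$delta, R_s_max = p$R_s_max,
    R_c_max = p$R_c_max, shift_mode = p$shift_mode,
    shift_steep = p$shift_steep, h = p$h, n_intake = p$n_intake,
    alpha = p$alpha, k_met = p$k_met, p_met = p$p_met,
    allocation = p$allocation, eta_mat = p$eta_mat, psi_exp = p$psi_exp,
    kappa_repro = p$kappa_repro, eps_egg = p$eps_egg, mu_0 = p$mu_0,
    mort_exp = p$mort_exp, xi_starv = p$xi_starv, S_min = p$S_min,
    n_grid = p$n_grid
  )
  bad <- setdiff(names(upd), names(args))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  args[names(upd)] <- upd
  do.call(model_params, args)
}

#' Resource environment vector
#'
#' The environment experienced by an individual is the vector of resource
#' densities `(R_s, R_1, ..., R_n)`. This helper builds a named vector and
#' checks non-negativity.
#'
#' @param R_s shared-resource density (g m^-3).
#' @param R species-specific resource densities (g m^-3).
#' @return named numeric vector of length `length(R) + 1`.
#' @export
resource_env <- function(R_s, R) {
  env <- c(R_s, R)
  if (any(env < 0)) stop("resource densities must be non-negative")
  names(env) <- c("R_s", paste0("R_", seq_along(R)))
  env
}

#' Consumer-free resource environment
#'
#' At the consumer-free equilibrium of the semi-chemostat dynamics every
#' resource sits exactly at its carrying density.
#'
#' @param p a `model_params` object.
#' @return named resource-density vector at carrying capacity.
#' @export
consumer_free_env <- function(p) {
  resource_env(p$R_s_max, p$R_c_max)
}
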