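# Scenario orchestration: canonical parameterizations of the package's
# reference analyses, serializable to YAML, runnable at test or full
# resolution through one dispatcher that writes CSV tables plus a JSON
# manifest.

# Test-resolution genetics: fewer loci, coarser mutational steps (wider for
# the bounded mating trait) and a sharper mate-choice function compress the
# directional, branching and assortment phases into a desk-scale horizon.
# Full-resolution scenarios keep the reference mutation parameters.
scaled_ibm_genetics <- function(V) {
  genetic_params(F_x = 4, F_a = 4, sigma = 0.075, sigma_a = 0.15,
                 sigma_m = 0.3, V = V)
}

#' Canonical analysis scenarios
#'
#' Returns the named scenario configuration. Engines: `equilibrium`,
#' `continuation` (supply-rate sweep with stability, the bistability
#' diagram), `ad-evolve` (adaptive-dynamics trait evolution), `ad-grid`
#' (two-parameter species counts), `ibm` (stochastic eco-genetic runs),
#' `hybrid` (growth of two morphs and their hybrid in the swarm-loaded
#' dimorphic state). The `scale` knob switches between the full
#' parameterization and a coarser test resolution (shorter horizons,
#' smaller volumes and grids) from the same template.
#'
#' Scenario names follow the regimes studied: `radiation-low-supply`
#' (supply 0.025 g m-3 day-1, no radiation), `radiation-high-supply`
#' (supply 0.2, full radiation), their IBM counterparts `ibm-low-supply`
#' and `ibm-high-supply`, `bistability` (supply sweep at x = 1),
#' `hybrid-growth` (morphs 1.57/4.87, hybrid 3.29),
#' `grid-mshift` / `grid-mb` (supply ratio crossed with m_shift or m_b,
#' without and with the juvenile trade-off via `tau_s`), and
#' `initial-composition` (supply 0.6, m_b 0.5 mg, tau_s 20, small- vs
#' large-dominated IBM starts).
#'
#' @param name scenario name (see Details).
#' @param scale `"test"` or `"full"`.
#' @param tau_s override of the juvenile trade-off width for the grids.
#' @return a `scenario` list: name, engine, params, genetics (IBM only),
#'   init, seeds, control.
#' @export
scenario <- function(name = c("radiation-low-supply", "radiation-high-supply",
                              "ibm-low-supply", "ibm-high-supply",
                              "bistability", "hybrid-growth",
                              "grid-mshift", "grid-mb",
                              "initial-composition"),
                     scale = c("test", "full"), tau_s = Inf) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  test <- scale == "test"
  base <- model_params(n_grid = if (test) 300 else 600)
  low <- update_params(base, R_s_max = 0.25)   # supply 0.025
  high <- base                                  # supply 0.2

  sc <- switch(name,
    "radiation-low-supply" = list(
      engine = "ad-evolve", params = low, init = list(x1 = 0),
      control = list(max_steps = if (test) 400 else 2000)),
    "radiation-high-supply" = list(
      engine = "ad-evolve", params = high, init = list(x1 = 0),
      control = list(max_steps = if (test) 800 else 3000)),
    "ibm-low-supply" = list(
      engine = "ibm", params = low,
      genetics = if (test) scaled_ibm_genetics(V = 2000)
                 else genetic_params(V = 1e4),
      init = list(x1 = 0, n0 = 500, profile = "spread"),
      control = list(t_max = if (test) 6e4 else 1e6, record_every = 1000)),
    "ibm-high-supply" = list(
      engine = "ibm", params = high,
      genetics = if (test) scaled_ibm_genetics(V = 2000)
                 else genetic_params(V = 1e4),
      init = list(x1 = 0, n0 = 500, profile = "spread"),
      control = list(t_max = if (test) 3e5 else 2e6,
                     record_every = 2500)),
    "bistability" = list(
      engine = "continuation", params = update_params(base, R_s_max = 0.25),
      init = list(x1 = 1),
      control = list(range = c(0.25, 2.2), h0 = 0.05, classify = TRUE,
                     max_points = if (test) 150 else 400)),
    "hybrid-growth" = list(
      engine = "hybrid", params = high,
      init = list(x_pair = c(1.57, 4.87), x_h = 3.29), control = list()),
    "grid-mshift" = list(
      engine = "ad-grid", params = update_params(base, tau_s = tau_s),
      init = list(x1 = 1),
      control = list(
        axis1 = list(name = "rel_productivity",
                     values = if (test) c(0.5, 2) else seq(0.25, 4, by = 0.25)),
        axis2 = list(name = "m_shift",
                     values = if (test) c(1, 5) else c(0.5, 1, 2, 5, 10)),
        evolve = list(max_steps = if (test) 250 else 2000))),
    "grid-mb" = list(
      engine = "ad-grid", params = update_params(base, tau_s = tau_s),
      init = list(x1 = 1),
      control = list(
        axis1 = list(name = "rel_productivity",
                     values = if (test) c(0.5, 2) else seq(0.25, 4, by = 0.25)),
        axis2 = list(name = "m_b",
                     values = if (test) c(0.005, 0.05) else
                       c(5e-4, 5e-3, 5e-2, 0.5)),
        evolve = list(max_steps = if (test) 250 else 2000))),
    "initial-composition" = list(
      engine = "ibm",
      params = update_params(base, R_s_max = 6, m_b = 5e-4, tau_s = 20),
      genetics = if (test) scaled_ibm_genetics(V = 300)
                 else genetic_params(V = 1e3),
      init = list(x1 = 3, n0 = 500, profile = "newborn",
                  profiles = c("newborn", "large")),
      control = list(t_max = if (test) 4e4 else 1e6, record_every = 1000))
  )
  sc$name <- name
  sc$scale <- scale
  sc$seeds <- 1L
  class(sc) <- "scenario"
  sc
}

#' Serialize or restore a scenario configuration
#'
#' Scenario configurations round-trip exactly through YAML (infinite niche
#' widths included), so every run is re-runnable from its manifest.
#'
#' @param sc a `scenario` object.
#' @param path file to write (`scenario_to_yaml`) or read
#'   (`scenario_from_yaml`).
#' @return `scenario_to_yaml`: the YAML string, invisibly (written to
#'   `path` if given); `scenario_from_yaml`: the restored `scenario`.
#' @export
scenario_to_yaml <- function(sc, path = NULL) {
  strip <- function(x) {
    if (inherits(x, "model_params") || inherits(x, "genetic_params"))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  obj <- strip(unclass(sc))
  obj$params$theta <- NULL; obj$params$tau <- NULL  # derived, rebuilt
  obj$params$R_max <- NULL; obj$params$m_asym <- NULL
  obj$params$R_c_max <- obj$params$R_c_max[1]
  txt <- yaml::as.yaml(obj, precision = 15)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @rdname scenario_to_yaml
#' @param text YAML string (alternative to `path`).
#' @export
scenario_from_yaml <- function(path = NULL, text = NULL) {
  obj <- if (!is.null(text)) yaml::yaml.load(text)
         else yaml::read_yaml(path)
  pf <- obj$params
  obj$params <- model_params(
    m_b = pf$m_b, m_mat = pf$m_mat, m_shift = pf$m_shift, q = pf$q,
    A_max = pf$A_max, n_resources = pf$n_resources, theta_s = pf$theta_s,
    theta_1 = pf$theta_1, peak_spacing = pf$peak_spacing,
    tau = pf$tau_width, tau_s = pf$tau_s, delta = pf$delta,
    R_s_max = pf$R_s_max, R_c_max = pf$R_c_max, shift_mode = pf$shift_mode,
    shift_steep = pf$shift_steep, h = pf$h, n_intake = pf$n_intake,
    alpha = pf$alpha, k_met = pf$k_met, p_met = pf$p_met,
    allocation = pf$allocation, eta_mat = pf$eta_mat, psi_exp = pf$psi_exp,
    kappa_repro = pf$kappa_repro, eps_egg = pf$eps_egg, mu_0 = pf$mu_0,
    mort_exp = pf$mort_exp, xi_starv = pf$xi_starv, S_min = pf$S_min,
    n_grid = pf$n_grid)
  if (!is.null(obj$genetics))
    obj$genetics <- do.call(genetic_params, obj$genetics)
  class(obj) <- "scenario"
  obj
}

#' Run a scenario end to end
#'
#' Dispatches a [scenario()] to its engine and collects the result tables.
#' When `out_dir` is given, tables are written as CSV together with a JSON
#' manifest (scenario YAML, its MD5 hash, seed, package and R versions)
#' sufficient for an exact re-run.
#'
#' @param sc a `scenario` object.
#' @param seed integer seed for stochastic engines (default: the
#'   scenario's first packaged seed).
#' @param out_dir optional output directory.
#' @param verbose print progress.
#' @return list with `tables` (named data frames), `objects`
#'   (engine-native results) and `manifest`.
#' @export
run_scenario <- function(sc, seed = sc$seeds[1], out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  p <- sc$params
  tables <- list(); objects <- list()
  say("running scenario '%s' (%s scale, engine %s)", sc$name, sc$scale,
      sc$engine)
  if (sc$engine == "equilibrium") {
    eq <- solve_equilibrium(sc$init$x1, p)
    tables$equilibrium <- data.frame(
      trait = eq$traits, b = eq$b, t(as.matrix(eq$env)))
    objects$equilibrium <- eq
  } else if (sc$engine == "continuation") {
    ct <- continue_in_parameter(sc$init$x1, p, "R_s_max",
                                sc$control$range, h0 = sc$control$h0,
                                classify = isTRUE(sc$control$classify),
                                max_points = sc$control$max_points)
    tables$continuation <- as.data.frame(ct)
    objects$continuation <- ct
  } else if (sc$engine == "ad-evolve") {
    tr <- evolve_traits(sc$init$x1, p, control = sc$control)
    tables$trajectory <- tr$history
    tables$events <- tr$events
    objects$trajectory <- tr
  } else if (sc$engine == "ad-grid") {
    gr <- species_count_grid(p, sc$control$axis1, sc$control$axis2,
                             x1 = sc$init$x1, control = sc$control$evolve)
    tables$grid <- gr
  } else if (sc$engine == "hybrid") {
    hs <- hybrid_swarm_equilibrium(sc$init$x_pair, sc$init$x_h, p)
    gc_rows <- do.call(rbind, lapply(
      c(sc$init$x_pair, sc$init$x_h), function(x) {
        g <- growth_curve(x, hs$env, p)
        data.frame(x = x, age = g$age, mass = g$mass, S = g$S)
      }))
    tables$growth_curves <- gc_rows
    tables$hybrid_summary <- data.frame(
      x = c(sc$init$x_pair, sc$init$x_h),
      S_mat = c(vapply(hs$lh_pair, `[[`, numeric(1), "S_mat"),
                hs$lh_hybrid$S_mat),
      R0 = c(vapply(hs$lh_pair, `[[`, numeric(1), "R0"),
             hs$lh_hybrid$R0))
    objects$hybrid <- hs
  } else if (sc$engine == "ibm") {
    profiles <- sc$init$profiles %||% sc$init$profile
    for (prof in profiles) {
      res <- run_ibm(p, sc$genetics, seed = seed,
                     t_max = sc$control$t_max, n0 = sc$init$n0,
                     x1 = sc$init$x1, profile = prof,
                     record_every = sc$control$record_every)
      key <- if (length(profiles) > 1) paste0("ibm_", prof) else "ibm"
      tables[[paste0(key, "_snapshots")]] <- res$snapshots
      tables[[paste0(key, "_series")]] <- res$series
      tables[[paste0(key, "_matings")]] <- res$matings
      objects[[key]] <- res
    }
  } else stop("unknown engine: ", sc$engine)

  cfg <- scenario_to_yaml(sc)
  tf <- tempfile(); writeLines(cfg, tf)
  manifest <- list(
    scenario = sc$name, scale = sc$scale, engine = sc$engine,
    seed = seed, config_yaml = cfg,
    config_md5 = unname(tools::md5sum(tf)),
    package_version = as.character(utils::packageVersion("ontoradiate")),
    r_version = R.version.string)
  unlink(tf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      write.csv(tables[[nm]],
                file.path(out_dir, paste0(sc$name, "_", nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(sc$name, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tables = tables, objects = objects, manifest = manifest)
}
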