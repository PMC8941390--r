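#' Genetic and mating parameters for the individual-based model
#'
#' @param F_x diploid locus count for the niche trait x.
#' @param F_a diploid locus count for the assortative-mating trait a.
#' @param nu per-allele mutation probability at birth.
#' @param sigma standard deviation of the Gaussian mutation kernel
#'   (allelic scale) for the niche-trait loci.
#' @param sigma_a mutation kernel width for the mating-trait loci
#'   (defaults to `sigma`).
#' @param sigma_m width of the self-matching mate-choice function
#'   (niche-trait units).
#' @param V system volume (m^3); demographic stochasticity scales with 1/V.
#' @return a validated `genetic_params` list.
#' @export
genetic_params <- function(F_x = 10L, F_a = 10L, nu = 0.1, sigma = 0.01,
                           sigma_a = sigma, sigma_m = 1, V = 1000) {
  g <- list(F_x = as.integer(F_x), F_a = as.integer(F_a), nu = nu,
            sigma = sigma, sigma_a = sigma_a, sigma_m = sigma_m, V = V)
  stopifnot(g$F_x >= 1L, g$F_a >= 1L, nu >= 0, nu <= 1, sigma > 0,
            sigma_a > 0, sigma_m > 0, V > 0)
  class(g) <- "genetic_params"
  g
}

#' Phenotype determined by an additive diploid genotype
#'
#' The niche trait is the sum of the x-allele values (unbounded); the
#' assortative-mating trait is the mean of the a-allele values, each bounded
#' in `[-1, 1]`, so `a` lies in `[-1, 1]` automatically.
#'
#' @param genotype list with `x_alleles` (length `2 F_x`) and `a_alleles`
#'   (length `2 F_a`).
#' @return named numeric `c(x =, a =)`.
#' @export
phenotype_from_genotype <- function(genotype) {
  c(x = sum(genotype$x_alleles), a = mean(genotype$a_alleles))
}

#' Sample a father by self-matching mate choice
#'
#' The spawning individual weighs mature candidates by the distance between
#' its own niche trait and theirs: `w = exp(-a^2 d^2 / (2 sigma_m^2))` for
#' assortative mothers (`a > 0`), uniform for `a = 0`, and the complementary
#' disassortative weighting (with a small uniform floor) for `a < 0`. Only
#' the mother's `a` is used (female-limited choosiness).
#'
#' @param x_mother,a_mother phenotype of the spawning individual.
#' @param x_candidates niche traits of the candidate fathers.
#' @param g a [genetic_params()] object.
#' @return index of the sampled candidate (or `NA_integer_` if none).
#' @export
choose_mate <- function(x_mother, a_mother, x_candidates, g) {
  if (!length(x_candidates)) return(NA_integer_)
  w <- cpp_mate_weights(a_mother, x_mother - x_candidates, g$sigma_m)
  sample.int(length(x_candidates), 1L, prob = w)
}

#' Mate-choice weights
#'
#' The unnormalized sampling weights used by [choose_mate()] and the IBM
#' spawning loop; exposed for testing sampling frequencies against the
#' analytic form.
#'
#' @param a assortative-mating trait of the chooser.
#' @param dx trait differences mother minus candidate.
#' @param sigma_m mate-choice width.
#' @return numeric weights.
#' @export
mate_weights <- function(a, dx, sigma_m) {
  cpp_mate_weights(a, dx, sigma_m)
}

#' Create an offspring genotype by free recombination and mutation
#'
#' Per locus, one allele is drawn uniformly from each parent's two (free
#' recombination, loci independent); each inherited allele mutates with
#' probability `nu` by adding a Gaussian deviate with standard deviation
#' `sigma`; a-alleles are clamped to `[-1, 1]`.
#'
#' @param mother,father genotype lists (`x_alleles`, `a_alleles`).
#' @param g a [genetic_params()] object.
#' @return offspring genotype list.
#' @export
make_offspring <- function(mother, father, g) {
  cpp_make_offspring(mother$x_alleles, father$x_alleles,
                     mother$a_alleles, father$a_alleles,
                     g$F_x, g$F_a, g$nu, g$sigma, g$sigma_a)
}

#' Initial IBM population state
#'
#' Builds a monomorphic founding population: every individual carries
#' x-alleles `x1 / (2 F_x)` (so the phenotype is exactly `x1`) and a-alleles
#' 0 (random mating). Body masses follow the named profile: `"newborn"`
#' (all at `m_b`), `"spread"` (log-uniform between `m_b` and `m_mat`), or
#' `"large"` (log-uniform between `m_shift` and `m_mat`; a population
#' dominated by large individuals).
#'
#' @param n0 founding population size.
#' @param x1 ancestral niche trait value.
#' @param p a [model_params()] object.
#' @param g a [genetic_params()] object.
#' @param profile initial mass profile.
#' @return state list (`m`, `buffer`, `x_alleles`, `a_alleles`, `id`,
#'   `resources`, `time`, `next_id`) consumable by [run_ibm()] / [ibm_step()].
#' @export
init_ibm_state <- function(n0, x1, p, g,
                           profile = c("spread", "newborn", "large")) {
  profile <- match.arg(profile)
  m <- switch(profile,
    newborn = rep(p$m_b, n0),
    spread = exp(runif(n0, log(p$m_b), log(p$m_mat))),
    large = exp(runif(n0, log(max(p$m_shift, p$m_b)), log(p$m_mat)))
  )
  list(
    m = m,
    buffer = rep(0, n0),
    x_alleles = matrix(x1 / (2 * g$F_x), n0, 2 * g$F_x),
    a_alleles = matrix(0, n0, 2 * g$F_a),
    id = seq_len(n0),
    resources = unname(consumer_free_env(p)),
    time = 0,
    next_id = n0 + 1L
  )
}

#' Advance the IBM by one (or more) time steps
#'
#' Executes the fixed event order: (1) feeding and growth (juveniles) or
#' reproductive-buffer filling (adults), (2) semi-chemostat resource update
#' with realized grazing scaled by 1/V, (3) stochastic mortality with
#' probability `1 - exp(-mu dt)`, (4) spawning: each adult whose buffer
#' holds at least one egg cost `m_b / eps_egg` chooses a father among the
#' mature individuals and produces offspring at `m_b`.
#'
#' @param state an IBM state list (see [init_ibm_state()]).
#' @param p a [model_params()] object.
#' @param g a [genetic_params()] object.
#' @param dt time step (days).
#' @param n_steps number of steps to advance.
#' @return the advanced state list.
#' @export
ibm_step <- function(state, p, g, dt = 1, n_steps = 1L) {
  out <- cpp_run_ibm(p, unclass(g), state, t_max = dt * n_steps, dt = dt,
                     record_every = -1, snapshot_mature_only = TRUE,
                     candidate_cap = 0L, mating_log = 0L)
  out$final_state
}

#' Run the individual-based eco-genetic simulation
#'
#' Simulates the stochastic size-structured population with explicit
#' multi-locus genetics in a finite volume, recording mature-individual
#' phenotype snapshots, population/resource series and the mating log.
#' Requires an explicit seed: identical (config, seed) pairs give
#' bit-identical output.
#'
#' @param p a [model_params()] object.
#' @param g a [genetic_params()] object.
#' @param seed integer RNG seed (required).
#' @param t_max simulated time (days).
#' @param n0,x1,profile founding population passed to [init_ibm_state()]
#'   (ignored when `state` is given).
#' @param state optional explicit initial state (exact resume).
#' @param dt time step (days).
#' @param record_every snapshot/series interval (days).
#' @param snapshot_mature_only record only mature individuals in snapshots.
#' @param candidate_cap cap on the candidate-father pool per spawning (0 =
#'   all mature individuals; a positive cap subsamples for speed and is a
#'   documented deviation from the all-candidates default).
#' @return An `ibm_result` list: `snapshots`, `series`, `matings` data
#'   frames, `final_state`, `extinct`, and the call configuration.
#' @export
run_ibm <- function(p, g, seed, t_max, n0 = 500, x1 = 0,
                    profile = "spread", state = NULL, dt = 1,
                    record_every = 200, snapshot_mature_only = TRUE,
                    candidate_cap = 0L) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (is.null(state)) state <- init_ibm_state(n0, x1, p, g, profile)
  out <- cpp_run_ibm(p, unclass(g), state, t_max = t_max, dt = dt,
                     record_every = record_every,
                     snapshot_mature_only = snapshot_mature_only,
                     candidate_cap = as.integer(candidate_cap),
                     mating_log = 1L)
  nmR <- c("R_s", paste0("R_", seq_len(p$n_resources)))
  series <- data.frame(time = out$series_t, n = out$series_n,
                       n_mature = out$series_nmat,
                       mean_a = out$series_mean_a,
                       mean_x = out$series_mean_x)
  series <- cbind(series, as.data.frame(out$series_R) |>
                    stats::setNames(nmR))
  res <- list(
    snapshots = data.frame(time = out$snap_t, id = out$snap_id,
                           mass = out$snap_m, x = out$snap_x,
                           a = out$snap_a),
    series = series,
    matings = data.frame(time = out$mate_t, mother = out$mate_mother,
                         father = out$mate_father,
                         x_mother = out$mate_x_mother,
                         x_father = out$mate_x_father,
                         n_off = out$mate_n_off),
    final_state = out$final_state,
    extinct = out$extinct,
    seed = seed, t_max = t_max, dt = dt, params = p, genetics = g
  )
  class(res) <- "ibm_result"
  res
}

#' @export
print.ibm_result <- function(x, ...) {
  fs <- x$final_state
  cat(sprintf("IBM run: t = %g d, %d individuals%s\n", fs$time,
              length(fs$m), if (x$extinct) " (EXTINCT)" else ""))
  if (length(fs$m)) {
    cl <- cluster_species(fs$x[fs$m >= x$params$m_mat])
    cat(sprintf("  mature clusters: %d; mean a = %.3f\n", cl$k,
                mean(fs$a)))
  }
  invisible(x)
}

#' Gap clustering of a niche-trait sample into species
#'
#' One-dimensional clustering: the sorted traits are split wherever the gap
#' between neighbours exceeds `g_split`. Operationalizes counting
#' "ecologically different species" in IBM output.
#'
#' @param x trait sample (at least one value).
#' @param g_split gap threshold (default half the specific niche width).
#' @return list with `assign` (cluster index per input, in input order),
#'   `k` (cluster count), `means` (cluster mean traits, ascending), and
#'   `breaks` (split points, useful to classify other individuals).
#' @export
cluster_species <- function(x, g_split = 0.5) {
  stopifnot(length(x) >= 1L)
  o <- order(x)
  xs <- x[o]
  new_cluster <- c(TRUE, diff(xs) > g_split)
  cl_sorted <- cumsum(new_cluster)
  assign <- integer(length(x))
  assign[o] <- cl_sorted
  breaks <- if (max(cl_sorted) > 1L) {
    i <- which(new_cluster[-1L])
    (xs[i] + xs[i + 1L]) / 2
  } else numeric(0)
  list(assign = assign, k = max(cl_sorted),
       means = as.numeric(tapply(xs, cl_sorted, mean)), breaks = breaks)
}

#' Reproductive isolation index from a mating log
#'
#' Compares the observed fraction of between-cluster matings with the
#' fraction expected under random mating given the cluster frequencies:
#' `RI = 1 - observed / expected`, clipped to `[0, 1]`. A value of 0
#' indicates random mating across clusters and 1 complete isolation.
#' Undefined (NA) with fewer than two clusters or an empty window.
#'
#' @param matings data frame with `x_mother`, `x_father` (a window of a
#'   [run_ibm()] mating log).
#' @param breaks cluster split points (from [cluster_species()]).
#' @param freqs optional cluster frequencies for the random-mating
#'   expectation; defaults to the frequencies among mating participants.
#' @return RI in `[0, 1]`, or `NA` if undefined.
#' @export
reproductive_isolation <- function(matings, breaks, freqs = NULL) {
  if (!nrow(matings) || !length(breaks)) return(NA_real_)
  cl_m <- findInterval(matings$x_mother, breaks)
  cl_f <- findInterval(matings$x_father, breaks)
  if (is.null(freqs)) {
    part <- c(cl_m, cl_f)
    freqs <- as.numeric(table(factor(part, levels = 0:length(breaks))))
    freqs <- freqs / sum(freqs)
  }
  expected <- 1 - sum(freqs^2)
  if (expected <= 0) return(NA_real_)
  observed <- mean(cl_m != cl_f)
  min(max(1 - observed / expected, 0), 1)
}

#' Reproductive-isolation time series of an IBM run
#'
#' For every snapshot time with at least two mature clusters, clusters the
#' mature niche traits and computes [reproductive_isolation()] over the
#' mating log of the trailing window.
#'
#' @param res an `ibm_result`.
#' @param window trailing window length (days).
#' @param g_split gap threshold for [cluster_species()].
#' @return data frame: `time`, `k` (cluster count), `RI`.
#' @export
ri_series <- function(res, window = 2000, g_split = 0.5) {
  ts <- unique(res$snapshots$time)
  out <- data.frame(time = ts, k = NA_integer_, RI = NA_real_)
  for (i in seq_along(ts)) {
    xs <- res$snapshots$x[res$snapshots$time == ts[i]]
    if (!length(xs)) next
    cl <- cluster_species(xs, g_split)
    out$k[i] <- cl$k
    if (cl$k < 2L) next
    mw <- res$matings[res$matings$time > ts[i] - window &
                        res$matings$time <= ts[i], ]
    out$RI[i] <- reproductive_isolation(mw, cl$breaks)
  }
  out
}
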