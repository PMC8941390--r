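# Pseudo-arclength continuation of ecological equilibria in one parameter.
#
# The augmented unknown is w = (log R, b, parameter). A secant tangent
# predicts the next point; the corrector solves the equilibrium system plus
# the arclength constraint t . (w - w_pred) = 0 by damped Newton. Folds are
# detected as sign changes of the parameter component of the tangent.

cont_residual <- function(logR, b, par_val, traits, par_name, p, n_grid) {
  pp <- tryCatch(
    do.call(update_params, c(list(p), setNames(list(par_val), par_name))),
    error = function(e) NULL)
  # invalid trial parameter (e.g. a negative carrying density during a
  # Newton overshoot): return a huge residual so the corrector backs off
  if (is.null(pp)) return(rep(1e8, p$n_resources + 1L + length(traits)))
  eq_residual(logR, b, traits, pp, n_grid)
}

#' Continue an ecological equilibrium in one model parameter
#'
#' Tracks the equilibrium branch of a resident coalition as one parameter
#' varies, through fold bifurcations, using pseudo-arclength continuation.
#' Each branch segment between folds is classified as dynamically stable or
#' unstable with [classify_stability()] applied at the segment midpoint (the
#' classification is constant between folds). The returned table exposes,
#' per continuation point, the resource densities, birth rates, and standing
#' biomass of small (`m < m_shift`) and large (`m >= m_shift`) consumers, so
#' a supply-rate sweep reproduces the classic bistability diagram.
#'
#' @param traits resident niche trait values.
#' @param p a [model_params()] object (the starting parameterization).
#' @param par_name name of the continued parameter (e.g. `"R_s_max"`).
#' @param range length-2 numeric: parameter interval to cover.
#' @param guess optional starting guess passed to [solve_equilibrium()] at
#'   `range[1]`.
#' @param h0 initial arclength step; steps adapt between `h_min` and `h_max`.
#' @param h_min,h_max arclength step bounds.
#' @param max_points cap on continuation points.
#' @param classify logical: classify stability per segment (default TRUE).
#' @param n_bins passed to [classify_stability()].
#' @return An object of class `continuation`: a data frame with columns
#'   `par` (parameter value), `supply` (`delta * par` when the parameter is
#'   a carrying density, else `NA`), `R_s`, `R_1..`, `b_1..`,
#'   `biomass_small`, `biomass_large`, `segment`, `stable`; attributes
#'   `folds` (parameter values of detected folds), `bistable_window`
#'   (parameter interval with at least two stable segments), and `par_name`.
#' @export
continue_in_parameter <- function(traits, p, par_name, range,
                                  guess = NULL, h0 = 0.05,
                                  h_min = 1e-4, h_max = 0.25,
                                  max_points = 400, classify = TRUE,
                                  n_bins = 40) {
  stopifnot(length(range) == 2L, range[2] > range[1])
  N <- length(traits)
  nR <- p$n_resources + 1L
  set_p <- function(val)
    do.call(update_params, c(list(p), setNames(list(val), par_name)))

  p1 <- set_p(range[1])
  eq <- solve_equilibrium(traits, p1, guess = guess)
  if (!eq$converged || length(eq$traits) != N)
    stop("no converged starting equilibrium at range[1]")

  # scale for the parameter in the arclength metric
  psc <- diff(range)
  wrap <- function(eq, val) c(log(eq$env), eq$b, val / psc)
  w <- wrap(eq, range[1])

  rows <- list(); eqs <- list()
  push <- function(w) {
    rows[[length(rows) + 1L]] <<- w
  }
  push(w)
  eqs[[1]] <- eq

  # second point by a small natural-parameter step
  val2 <- range[1] + h0 * psc * 0.5
  eq2 <- solve_equilibrium(traits, set_p(val2),
                           guess = list(env = eq$env, b = eq$b))
  if (!eq2$converged || length(eq2$traits) != N)
    stop("continuation failed on the first natural step")
  w2 <- wrap(eq2, val2)
  push(w2); eqs[[2]] <- eq2

  h <- h0
  w_prev <- w; w_cur <- w2
  for (k in 3:max_points) {
    tg <- w_cur - w_prev
    tg <- tg / sqrt(sum(tg^2))
    ok <- FALSE
    while (!ok) {
      w_pred <- w_cur + h * tg
      # corrector: damped Newton on the augmented system
      wn <- w_pred
      good <- FALSE
      for (it in 1:25) {
        val <- wn[nR + N + 1L] * psc
        r1 <- cont_residual(wn[1:nR], wn[nR + seq_len(N)], val, traits,
                            par_name, p, p$n_grid)
        r <- c(r1, sum(tg * (wn - w_pred)))
        if (!all(is.finite(r))) break
        if (max(abs(r1[-(1:nR)])) < 1e-9 && max(abs(r1[1:nR])) < 1e-10 &&
            abs(r[nR + N + 1L]) < 1e-10) { good <- TRUE; break }
        J <- matrix(0, nR + N + 1L, nR + N + 1L)
        hh <- 1e-6
        for (c1 in 1:nR) {
          wv <- wn[1:nR]; wv[c1] <- wv[c1] + hh
          J[1:(nR + N), c1] <-
            (cont_residual(wv, wn[nR + seq_len(N)], val, traits, par_name,
                           p, p$n_grid) - r1) / hh
        }
        ppv <- tryCatch(set_p(val), error = function(e) NULL)
        if (is.null(ppv)) break   # trial parameter out of its domain
        crv <- coalition_rates(traits, exp(wn[1:nR]), ppv, p$n_grid)
        J[1:nR, nR + seq_len(N)] <- -t(crv$C)
        rp <- cont_residual(wn[1:nR], wn[nR + seq_len(N)], val + hh * psc,
                            traits, par_name, p, p$n_grid)
        J[1:(nR + N), nR + N + 1L] <- (rp - r1) / hh
        J[nR + N + 1L, ] <- tg
        step <- tryCatch(solve(J, -r), error = function(e) NULL)
        if (is.null(step)) break
        step[1:nR] <- pmin(pmax(step[1:nR], -1.5), 1.5)
        wn <- wn + step
      }
      if (good) {
        ok <- TRUE
        if (it <= 4 && h < h_max) h <- min(h * 1.4, h_max)
      } else {
        h <- h / 2
        if (h < h_min) break
      }
    }
    if (!ok) break
    w_prev <- w_cur; w_cur <- wn
    push(w_cur)
    val <- w_cur[nR + N + 1L] * psc
    # stop when leaving the requested range or a resident dies out
    if (val > range[2] + 1e-9 || val < range[1] - 1e-9) break
    if (any(w_cur[nR + seq_len(N)] < 0)) break
  }

  W <- do.call(rbind, rows)
  par_vals <- W[, nR + N + 1L] * psc
  # folds: sign changes in the parameter direction of travel
  dp <- diff(par_vals)
  fold_idx <- which(sign(dp[-1]) * sign(dp[-length(dp)]) < 0) + 1L
  folds <- par_vals[fold_idx]
  segment <- cumsum(c(1, as.integer(seq_along(par_vals)[-1] %in% (fold_idx + 1L))))

  dens <- c("m_shift", "m_b", "m_mat")
  supply <- if (par_name %in% c("R_s_max", "R_c_max")) p$delta * par_vals
            else rep(NA_real_, length(par_vals))

  # standing biomass and stability per point / segment
  bio <- matrix(NA_real_, length(par_vals), 2)
  stable <- rep(NA, length(par_vals))
  seg_ids <- unique(segment)
  seg_stab <- setNames(rep(NA, length(seg_ids)), seg_ids)
  for (i in seq_along(par_vals)) {
    ppv <- set_p(par_vals[i])
    eqi <- list(traits = traits, b = W[i, nR + seq_len(N)],
                env = exp(W[i, 1:nR]), params = ppv)
    cri <- coalition_rates(traits, eqi$env, ppv, p$n_grid)
    eqi$lh <- cri$lh
    bio[i, ] <- standing_biomass(eqi)
  }
  if (classify) {
    dyn_classify <- function(s) {
      idx <- which(segment == s)
      mid <- idx[ceiling(length(idx) / 2)]
      ppv <- set_p(par_vals[mid])
      eqm <- solve_equilibrium(traits, ppv,
                               guess = list(env = exp(W[mid, 1:nR]),
                                            b = W[mid, nR + seq_len(N)]))
      eqm$converged &&
        as.character(classify_stability(eqm, ppv, n_bins = n_bins)) == "stable"
    }
    # dynamic classification of the outer segments; a fold exchanges the
    # sign of one real eigenvalue, so labels alternate across folds. The
    # discretized dynamics cannot classify the saddle segment directly
    # (its own fold window is slightly shifted, so the saddle may not
    # exist there at the same parameter value). Parity is anchored on the
    # final segment and cross-checked against the first.
    ns <- length(seg_ids)
    last_stable <- dyn_classify(seg_ids[ns])
    alt <- last_stable == ((ns - seq_along(seg_ids)) %% 2L == 0L)
    if (ns > 1L) {
      first_stable <- dyn_classify(seg_ids[1])
      if (first_stable != alt[1]) {
        warning("fold-parity and dynamic classification disagree; ",
                "using per-segment dynamic labels")
        alt <- vapply(seg_ids, dyn_classify, logical(1))
      }
    }
    seg_stab[as.character(seg_ids)] <- alt
    stable <- unname(seg_stab[as.character(segment)])
  }

  out <- data.frame(par = par_vals, supply = supply)
  env_cols <- exp(W[, 1:nR, drop = FALSE])
  colnames(env_cols) <- c("R_s", paste0("R_", seq_len(p$n_resources)))
  b_cols <- W[, nR + seq_len(N), drop = FALSE]
  colnames(b_cols) <- paste0("b_", seq_len(N))
  out <- cbind(out, env_cols, b_cols,
               biomass_small = bio[, 1], biomass_large = bio[, 2],
               segment = segment, stable = stable)

  # bistable window: parameter interval covered by >= 2 stable segments
  win <- NULL
  if (classify) {
    stabsegs <- seg_ids[seg_stab[as.character(seg_ids)] %in% TRUE]
    if (length(stabsegs) >= 2) {
      ivs <- lapply(stabsegs, function(s) range(par_vals[segment == s]))
      for (a in seq_along(ivs)) for (b in seq_along(ivs)) {
        if (a < b) {
          lo <- max(ivs[[a]][1], ivs[[b]][1])
          hi <- min(ivs[[a]][2], ivs[[b]][2])
          if (hi > lo) win <- if (is.null(win)) c(lo, hi)
                              else c(min(win[1], lo), max(win[2], hi))
        }
      }
    }
  }
  structure(out, folds = folds, bistable_window = win, par_name = par_name,
            class = c("continuation", "data.frame"))
}

#' @export
print.continuation <- function(x, ...) {
  cat(sprintf("Equilibrium continuation in %s: %d points, %d fold(s)\n",
              attr(x, "par_name"), nrow(x), length(attr(x, "folds"))))
  if (length(attr(x, "folds")))
    cat("  folds at", paste(format(attr(x, "folds"), digits = 5),
                            collapse = ", "), "\n")
  w <- attr(x, "bistable_window")
  if (!is.null(w))
    cat(sprintf("  bistable window: [%.5g, %.5g]\n", w[1], w[2]))
  NextMethod()
}
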