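#' Reversible two-pool priming models
#'
#' Both models describe a primed vesicle pool PP fed from a large upstream
#' depot pool (DP) through a reversible priming step and drained by fusion:
#'
#' * **Model I** (no release-site limit, the chromaffin-cell case):
#'   \deqn{dPP/dt = k_1 DP - (k_{-1} + k_f)\,PP}
#'   The forward rate is the lumped product `k1dp` = k1 * DP (fF/s); DP is
#'   assumed not to change size during the experiment.
#' * **Model II** (release-site model, the 'neuronal' case): priming is
#'   limited by a release-site capacity `pp_max`, with sites recycling
#'   immediately after use:
#'   \deqn{dPP/dt = k_1 DP\,(PP_{max} - PP) - (k_{-1} + k_f)\,PP}
#'   Here `k1dp` has unit s^-1 (per release site).
#'
#' `k_f` is the fusion rate constant, taken as 0 between stimuli.
#'
#' @param k1dp forward priming rate: fF/s (Model I) or s^-1 (Model II).
#' @param k_minus1 depriming rate constant, s^-1.
#' @param k_f fusion rate constant, s^-1 (default 0).
#' @param pp_max release-site capacity, fF (Model II only).
#' @return Parameter objects of class `model1_params` / `model2_params`.
#' @export
model1_params <- function(k1dp, k_minus1, k_f = 0) {
  stopifnot(k1dp >= 0, k_minus1 >= 0, k_f >= 0, k_minus1 + k_f > 0)
  structure(list(k1dp = k1dp, k_minus1 = k_minus1, k_f = k_f),
            class = "model1_params")
}

#' @rdname model1_params
#' @export
model2_params <- function(k1dp, pp_max, k_minus1, k_f = 0) {
  stopifnot(k1dp >= 0, pp_max > 0, k_minus1 >= 0, k_f >= 0)
  stopifnot(k_minus1 + k_f + k1dp > 0)
  structure(list(k1dp = k1dp, pp_max = pp_max, k_minus1 = k_minus1, k_f = k_f),
            class = "model2_params")
}

#' Closed-form primed-pool trajectories
#'
#' Model I: \eqn{PP(t) = PP(\infty) - (PP(\infty) - PP_0) e^{-(k_{-1}+k_f) t}}
#' with steady state \eqn{PP(\infty) = k_1 DP / (k_{-1} + k_f)}.
#' Model II: same form with relaxation rate \eqn{k_{-1} + k_f + k_1 DP}
#' (recovery is sped up by the forward rate) and steady state
#' \eqn{k_1 DP \cdot PP_{max} / (k_{-1} + k_f + k_1 DP)}.
#'
#' @param t time since the pool was emptied, s (>= 0).
#' @param p a [model1_params()] / [model2_params()] object.
#' @param pp0 initial pool size, fF (0 for a recovery experiment).
#' @return Pool size PP(t), fF.
#' @export
model1_pool <- function(t, p, pp0 = 0) {
  stopifnot(inherits(p, "model1_params"), all(t >= 0))
  lam <- p$k_minus1 + p$k_f
  ss <- p$k1dp / lam
  ss - (ss - pp0) * exp(-lam * t)
}

#' @rdname model1_pool
#' @export
model2_pool <- function(t, p, pp0 = 0) {
  stopifnot(inherits(p, "model2_params"), all(t >= 0))
  lam <- p$k_minus1 + p$k_f + p$k1dp
  ss <- p$k1dp * p$pp_max / lam
  ss - (ss - pp0) * exp(-lam * t)
}

#' Steady-state primed pool size
#' @param p a model parameter object.
#' @return PP at equilibrium, fF.
#' @export
steady_state_pool <- function(p) {
  if (inherits(p, "model1_params")) p$k1dp / (p$k_minus1 + p$k_f)
  else p$k1dp * p$pp_max / (p$k_minus1 + p$k_f + p$k1dp)
}

#' Numerical ODE reference for the priming models
#'
#' Integrates the Model I / Model II differential equation with a
#' stiff-capable solver (`deSolve::ode`, "lsoda"). This is an independent
#' check on the closed forms and is used only in tests.
#'
#' @param p a [model1_params()] or [model2_params()] object.
#' @param t_end end time, s.
#' @param pp0 initial pool size, fF.
#' @param n number of output points.
#' @return Data frame with columns `t` and `pp`.
#' @export
ode_oracle <- function(p, t_end, pp0 = 0, n = 201) {
  stopifnot(t_end > 0)
  times <- seq(0, t_end, length.out = n)
  rhs <- if (inherits(p, "model1_params")) {
    function(t, y, parms) list(p$k1dp - (p$k_minus1 + p$k_f) * y)
  } else {
    function(t, y, parms)
      list(p$k1dp * (p$pp_max - y) - (p$k_minus1 + p$k_f) * y)
  }
  sol <- deSolve::ode(y = c(pp = pp0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-11)
  data.frame(t = sol[, "time"], pp = sol[, "pp"])
}

#' Recovery-curve container
#'
#' Per-cell paired-flash ratios Stim2/Stim1 grouped by inter-stimulus
#' interval. Stim1/Stim2 are the secretion amplitudes at a fixed readout
#' time (60 ms ~ RRP, 600 ms ~ RRP + SRP) after the first and second flash.
#'
#' @param intervals inter-stimulus intervals, s (one per ratio, > 0).
#' @param ratios dimensionless Stim2/Stim1 values (>= 0).
#' @param readout readout time the amplitudes refer to, s.
#' @param cell optional cell identifiers.
#' @return Data frame of class `recovery_curve`.
#' @export
recovery_curve <- function(intervals, ratios, readout = 0.06, cell = NULL) {
  stopifnot(length(intervals) == length(ratios), all(intervals > 0),
            all(is.finite(ratios)))
  df <- data.frame(interval = intervals, ratio = ratios)
  if (!is.null(cell)) df$cell <- cell
  structure(df, readout = readout, class = c("recovery_curve", "data.frame"))
}

#' Simulate a noiseless paired-flash recovery curve
#'
#' The first flash empties the primed pool from its steady state; the pool
#' then refills for the inter-stimulus interval with the forward priming
#' rate switched to `k1dp_after` at the first flash (the depriming rate is
#' unchanged). Ratios are Stim2/Stim1 = PP(interval; after-rates) / PP(Inf;
#' before-rates).
#'
#' @param p model parameters before stimulation.
#' @param k1dp_after forward priming rate after stimulation (same unit as
#'   `p$k1dp`); defaults to no change.
#' @param intervals inter-stimulus intervals, s.
#' @param readout readout label, s.
#' @return A [recovery_curve()].
#' @export
simulate_recovery <- function(p, k1dp_after = p$k1dp, intervals,
                              readout = 0.06) {
  stopifnot(all(intervals > 0), k1dp_after >= 0)
  stim1 <- steady_state_pool(p)
  p_after <- p; p_after$k1dp <- k1dp_after
  pool_fn <- if (inherits(p, "model1_params")) model1_pool else model2_pool
  stim2 <- pool_fn(intervals, p_after, pp0 = 0)
  recovery_curve(intervals, stim2 / stim1, readout = readout)
}

#' Fit a mono-exponential recovery curve
#'
#' Fits `ratio(dt) = plateau * (1 - exp(-rate * dt))` to per-cell ratio
#' points by least squares. Under Model I with `k_f = 0` the fitted rate
#' estimates the depriming rate constant `k_minus1`; under Model II it
#' estimates `k_minus1 + k1dp`. A plateau above 1 reflects post-stimulation
#' overfilling, below 1 incomplete recovery.
#'
#' @param curve a [recovery_curve()].
#' @param mode `"points"` fits all per-cell points (default); `"means"` fits
#'   interval means.
#' @return List of class `recovery_fit`: `plateau`, `rate` (s^-1), `rss`,
#'   `converged`, `degenerate`.
#' @export
fit_recovery <- function(curve, mode = c("points", "means")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "recovery_curve"))
  if (length(unique(curve$interval)) < 3)
    stop("recovery fit needs at least 3 distinct intervals")
  if (mode == "means") {
    agg <- stats::aggregate(ratio ~ interval, data = curve, FUN = mean)
    x <- agg$interval; y <- agg$ratio
  } else {
    x <- curve$interval; y <- curve$ratio
  }
  if (stats::sd(y) == 0)
    return(structure(list(plateau = y[1], rate = NA_real_, rss = 0,
                          converged = FALSE, degenerate = TRUE),
                     class = "recovery_fit"))
  resid_fn <- function(p) y - p[1] * (1 - exp(-p[2] * x))
  best <- NULL
  for (r0 in c(0.005, 0.02, 0.08, 0.3, 1)) {
    p0 <- c(max(mean(y[x >= stats::median(x)]), 0.1), r0)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = c(0, 1e-6), upper = c(Inf, 100),
                         resid_fn, control = .lm_ctrl()),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("recovery fit did not converge")
  structure(list(plateau = unname(best$par[1]), rate = unname(best$par[2]),
                 rss = best$deviance, converged = .lm_ok(best, y),
                 degenerate = FALSE),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> plateau = %.4g, rate = %.4g s^-1\n",
              x$plateau, x$rate))
  invisible(x)
}

#' Derive priming/depriming rates from a recovery fit
#'
#' Under Model I with `k_f = 0` during recovery, the fitted recovery rate is
#' the depriming rate constant `k_minus1`, and the steady-state relation
#' PP(Inf) = k1dp / k_minus1 gives the forward priming rate before
#' stimulation, `k1dp_before = k_minus1 * pool_size`. Post-stimulation
#' overfilling (plateau != 1) is attributed to a changed forward rate:
#' `k1dp_after = k1dp_before * plateau`.
#'
#' @param pool_size steady-state pool size from the first stimulation, fF.
#' @param fit a [fit_recovery()] result.
#' @return List of class `derived_rates`: `k_minus1` (s^-1), `k1dp_before`,
#'   `k1dp_after` (fF/s), `pool_size` (fF).
#' @export
derive_rates <- function(pool_size, fit) {
  stopifnot(inherits(fit, "recovery_fit"), fit$rate > 0)
  if (pool_size < 0) stop("pool_size must be non-negative")
  structure(list(k_minus1 = fit$rate,
                 k1dp_before = fit$rate * pool_size,
                 k1dp_after = fit$rate * pool_size * fit$plateau,
                 pool_size = pool_size),
            class = "derived_rates")
}

#' Translate Model I estimates into release-site (Model II) parameters
#'
#' Finds the Model II parameter set whose recovery curve is identical (same
#' relaxation rate and steady state) to the Model I fit, assuming the
#' release sites are at fraction `occupancy` of capacity at rest and
#' `k_f = 0` during recovery. Solving
#' \deqn{k_{-1} + k_1 DP = rate, \qquad
#'       k_1 DP \cdot PP_{max} / (k_{-1} + k_1 DP) = pool}
#' with \eqn{PP_{max} = pool / occupancy} gives
#' `k1dp = rate * occupancy` and `k_minus1 = rate * (1 - occupancy)`.
#'
#' @param pool_size steady-state pool size, fF.
#' @param recovery_rate fitted recovery rate constant, s^-1.
#' @param occupancy resting occupancy of release sites, in (0, 1]
#'   (default 0.9).
#' @return A [model2_params()] object.
#' @export
translate_to_release_site <- function(pool_size, recovery_rate,
                                      occupancy = 0.9) {
  stopifnot(pool_size > 0, recovery_rate > 0)
  if (occupancy <= 0 || occupancy > 1)
    stop("occupancy must be in (0, 1]")
  model2_params(k1dp = recovery_rate * occupancy,
                pp_max = pool_size / occupancy,
                k_minus1 = recovery_rate * (1 - occupancy),
                k_f = 0)
}
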