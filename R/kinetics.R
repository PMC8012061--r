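#' Kinetic parameter sets for flash-evoked secretion
#'
#' `flash_kinetics()` describes the standard response: two exponential burst
#' components (amplitudes are pool sizes, time constants are fusion time
#' constants) plus a linear sustained component,
#' \deqn{\Delta C_m(t) = A_1(1 - e^{-t/\tau_1}) + A_2(1 - e^{-t/\tau_2}) + A_3 t.}
#'
#' `delayed_srp_kinetics()` replaces the slow exponential by an SRP that
#' fuses after a delay. When the delay is long, the fusion rate of the SRP
#' grows approximately linearly in time and the SRP term becomes
#' \deqn{\Delta C_m(t) = SRP\,(1 - e^{-t^2/\tau_{slow,delay}}),}
#' where `tau_slow_delay` (s^2) is the product of the delay and fusion time
#' constants — the two cannot be determined separately. The optional full-model
#' fields `kslow` (s^-1) and `tau_delay` (s) store the un-approximated pair
#' when it is known (e.g. for a generator ground truth).
#'
#' @param A1,A2 burst amplitudes (pool sizes), fF; must be >= 0.
#' @param tau1,tau2 fusion time constants, s; must be > 0.
#' @param A3 sustained rate, fF/s (may be negative).
#' @param SRP delayed-SRP amplitude, fF.
#' @param tau_slow_delay product of delay and slow fusion time constants, s^2.
#' @param kslow,tau_delay optional full-model fields (see Details).
#' @return An object of class `flash_kinetics` or `delayed_srp_kinetics`.
#' @export
flash_kinetics <- function(A1, tau1, A2, tau2, A3 = 0) {
  p <- list(A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2, A3 = A3)
  stop_if_not_finite(p, "flash kinetics parameters")
  stopifnot(A1 >= 0, A2 >= 0, tau1 > 0, tau2 > 0)
  structure(p, class = "flash_kinetics")
}

#' @rdname flash_kinetics
#' @export
delayed_srp_kinetics <- function(A1, tau1, SRP, tau_slow_delay, A3 = 0,
                                 kslow = NULL, tau_delay = NULL) {
  p <- list(A1 = A1, tau1 = tau1, SRP = SRP,
            tau_slow_delay = tau_slow_delay, A3 = A3)
  stop_if_not_finite(p, "delayed SRP kinetics parameters")
  stopifnot(A1 >= 0, SRP >= 0, tau1 > 0, tau_slow_delay > 0)
  if (!is.null(kslow)) stopifnot(kslow > 0)
  if (!is.null(tau_delay)) stopifnot(tau_delay > 0)
  p$kslow <- kslow
  p$tau_delay <- tau_delay
  structure(p, class = "delayed_srp_kinetics")
}

#' Evaluate a flash-response model function
#'
#' Returns the noiseless capacitance increase at times `t` (0 for t < 0).
#'
#' @param kin a [flash_kinetics()] or [delayed_srp_kinetics()] object.
#' @param t times, s (flash at 0).
#' @return numeric vector of capacitance, fF.
#' @export
eval_kinetics <- function(kin, t) UseMethod("eval_kinetics")

#' @export
eval_kinetics.flash_kinetics <- function(kin, t) {
  ifelse(t < 0, 0,
         kin$A1 * (1 - exp(-t / kin$tau1)) +
           kin$A2 * (1 - exp(-t / kin$tau2)) + kin$A3 * t)
}

#' @export
eval_kinetics.delayed_srp_kinetics <- function(kin, t) {
  ifelse(t < 0, 0,
         kin$A1 * (1 - exp(-t / kin$tau1)) +
           kin$SRP * (1 - exp(-t^2 / kin$tau_slow_delay)) + kin$A3 * t)
}

#' Capacitance trace container
#'
#' @param t sample times, s (strictly increasing; flash at 0).
#' @param cm membrane capacitance, fF, baseline-subtracted or raw.
#' @param meta named list of free-form labels (genotype, prestimulation
#'   calcium in uM, ...).
#' @return A data frame of class `capacitance_trace` with columns `t`, `cm`.
#' @export
capacitance_trace <- function(t, cm, meta = list()) {
  stopifnot(length(t) == length(cm), all(is.finite(t)), all(is.finite(cm)))
  if (any(diff(t) <= 0)) stop("time vector must be strictly increasing")
  if (sum(t >= 0) < 100)
    stop("capacitance trace needs at least 100 post-flash samples")
  structure(data.frame(t = t, cm = cm),
            meta = meta, class = c("capacitance_trace", "data.frame"))
}

# baseline = mean of pre-flash samples (t < 0); 0 if there are none
.cm_baseline <- function(trace) {
  pre <- trace$cm[trace$t < 0]
  if (length(pre)) mean(pre) else 0
}

# post-flash samples inside the fit window, baseline-subtracted
.fit_samples <- function(trace, window = NULL) {
  t_end <- if (is.null(window)) 5 else window$t_end
  keep <- trace$t >= 0 & trace$t <= t_end
  if (sum(keep) < 10) stop("trace does not cover the fit window")
  list(t = trace$t[keep], y = trace$cm[keep] - .cm_baseline(trace))
}

# Solve for the amplitudes given the time-constant basis by linear least
# squares (variable projection); used to build good multi-start points.
.vp_amplitudes <- function(t, y, basis, clip_nonneg) {
  X <- cbind(basis, t)
  a <- tryCatch(qr.solve(X, y), error = function(e) rep(1, ncol(X)))
  a[clip_nonneg] <- pmax(a[clip_nonneg], 0)
  a
}

.lm_ctrl <- function() minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                                  ptol = 1e-12)

# Levenberg-Marquardt termination codes 1-4 indicate convergence; code 5
# (iteration cap) still counts when the fit is numerically exact
.lm_ok <- function(fit, y) {
  fit$info %in% 1:4 ||
    (fit$info == 5 && fit$deviance <= 1e-16 * max(sum(y^2), 1))
}

#' Fit the standard two-exponential-plus-line model
#'
#' Bounded nonlinear least squares over the post-flash window, with 8
#' multi-starts from log-spaced time-constant initializations (amplitudes are
#' initialised by linear least squares at each start). Time constants are
#' bounded to (1e-4, 10] s, amplitudes to \[0, Inf), and the sustained rate
#' is unbounded. The returned components are ordered so `tau1 <= tau2`.
#'
#' @param trace a [capacitance_trace()].
#' @param window a [time_grid()] whose `t_end` sets the fit window (default
#'   0–5 s post-flash).
#' @return An object of class `flash_fit` with elements `model_id`
#'   (`"standard"`), `params` ([flash_kinetics()]), `rss` (fF^2), `converged`,
#'   `n` and `assignment` (filled by [classify_components()]).
#' @export
fit_standard <- function(trace, window = NULL) {
  s <- .fit_samples(trace, window)
  t <- s$t; y <- s$y
  resid_fn <- function(p) {
    y - (p[1] * (1 - exp(-t / p[2])) + p[3] * (1 - exp(-t / p[4])) + p[5] * t)
  }
  lower <- c(0, 1e-4, 0, 1e-4, -Inf)
  upper <- c(Inf, 10, Inf, 10, Inf)
  starts <- expand.grid(tau1 = c(0.005, 0.03), tau2 = c(0.1, 0.3, 0.8, 2))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    tt <- c(starts$tau1[k], starts$tau2[k])
    a <- .vp_amplitudes(t, y, cbind(1 - exp(-t / tt[1]), 1 - exp(-t / tt[2])),
                        clip_nonneg = c(TRUE, TRUE, FALSE))
    p0 <- c(a[1], tt[1], a[2], tt[2], a[3])
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower, upper, resid_fn, control = .lm_ctrl()),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(.flash_fit("standard", NULL, NA_real_, length(t), converged = FALSE))
  p <- unname(best$par)
  if (p[2] > p[4]) p <- p[c(3, 4, 1, 2, 5)]  # order fast component first
  kin <- flash_kinetics(p[1], p[2], p[3], p[4], p[5])
  .flash_fit("standard", kin, best$deviance, length(t),
             converged = .lm_ok(best, y))
}

#' Fit the delayed-SRP model
#'
#' As [fit_standard()], but the slow burst is replaced by the delayed-SRP
#' term `SRP * (1 - exp(-t^2 / tau_slow_delay))`. The sustained rate may come
#' out negative for strongly convex traces.
#'
#' @inheritParams fit_standard
#' @return A `flash_fit` with `model_id = "delayed_srp"` and
#'   [delayed_srp_kinetics()] parameters.
#' @export
fit_delayed_srp <- function(trace, window = NULL) {
  s <- .fit_samples(trace, window)
  t <- s$t; y <- s$y
  resid_fn <- function(p) {
    y - (p[1] * (1 - exp(-t / p[2])) + p[3] * (1 - exp(-t^2 / p[4])) + p[5] * t)
  }
  lower <- c(0, 1e-4, 0, 1e-6, -Inf)
  upper <- c(Inf, 10, Inf, 100, Inf)
  starts <- expand.grid(tau1 = c(0.008, 0.04), tausd = c(0.05, 0.25, 1, 4))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    tt <- c(starts$tau1[k], starts$tausd[k])
    a <- .vp_amplitudes(t, y,
                        cbind(1 - exp(-t / tt[1]), 1 - exp(-t^2 / tt[2])),
                        clip_nonneg = c(TRUE, TRUE, FALSE))
    p0 <- c(a[1], tt[1], a[2], tt[2], a[3])
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower, upper, resid_fn, control = .lm_ctrl()),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(.flash_fit("delayed_srp", NULL, NA_real_, length(t),
                      converged = FALSE))
  p <- unname(best$par)
  kin <- delayed_srp_kinetics(p[1], p[2], p[3], p[4], p[5])
  .flash_fit("delayed_srp", kin, best$deviance, length(t),
             converged = .lm_ok(best, y))
}

.flash_fit <- function(model_id, params, rss, n, converged,
                       assignment = NULL, diagnostics = list()) {
  structure(list(model_id = model_id, params = params, rss = rss, n = n,
                 converged = converged, assignment = assignment,
                 diagnostics = diagnostics),
            class = "flash_fit")
}

#' @export
print.flash_fit <- function(x, ...) {
  cat("<flash_fit> model:", x$model_id,
      if (!x$converged) "(NOT converged)", "\n")
  if (!is.null(x$params))
    cat("  params:", paste(sprintf("%s=%.4g", names(unclass(x$params))[
      vapply(x$params, is.numeric, TRUE)],
      unlist(x$params[vapply(x$params, is.numeric, TRUE)])), collapse = ", "),
      "\n")
  cat(sprintf("  rss: %.4g fF^2 over %d samples\n", x$rss, x$n))
  if (!is.null(x$assignment)) print(x$assignment)
  invisible(x)
}

#' Select between the standard and delayed-SRP models
#'
#' Both model families are fitted and the one with the lower goodness-of-fit
#' statistic is returned. Both families have 5 free parameters, so raw
#' residual sum of squares is a valid comparison; optionally the statistic is
#' normalized by a baseline noise variance estimate (a chi-square), which
#' does not change the ranking for a single trace. Ties go to the standard
#' model.
#'
#' @inheritParams fit_standard
#' @param normalize if `TRUE`, divide rss by the variance of the pre-flash
#'   baseline before comparison (reported in `diagnostics$chisq`).
#' @return The winning `flash_fit`; `diagnostics` carries both models' rss.
#' @export
select_model <- function(trace, window = NULL, normalize = FALSE) {
  f_std <- fit_standard(trace, window)
  f_del <- fit_delayed_srp(trace, window)
  if (!f_std$converged && !f_del$converged)
    stop("neither model fit converged")
  if (!f_std$converged) return(f_del)
  if (!f_del$converged) return(f_std)
  stat_std <- f_std$rss; stat_del <- f_del$rss
  if (normalize) {
    v <- stats::var(trace$cm[trace$t < 0])
    if (is.finite(v) && v > 0) { stat_std <- stat_std / v; stat_del <- stat_del / v }
  }
  win <- if (stat_del < stat_std) f_del else f_std
  win$diagnostics$rss_standard <- f_std$rss
  win$diagnostics$rss_delayed <- f_del$rss
  if (normalize) win$diagnostics$chisq <- min(stat_std, stat_del)
  win
}

#' Classify fitted components into RRP, SRP and sustained release
#'
#' Exponential components are assigned to the readily releasable pool when
#' their time constant is at most `rrp_cutoff` (60 ms) and to the slowly
#' releasable pool when it lies between `rrp_cutoff` and `srp_upper`
#' (1 s by default; 1.6 s is the convention for delayed-SRP data sets).
#' A component slower than `srp_upper` is dropped from the pools and
#' reported in the `dropped` field. If both exponentials fall in the same
#' class, `refit_needed` is set and the trace should be refitted with
#' [refit_single_exponential()]. For a delayed-SRP fit the SRP amplitude is
#' assigned directly; its effective time constant is
#' `sqrt(tau_slow_delay)`.
#'
#' @param fit a `flash_fit`.
#' @param rrp_cutoff RRP/SRP boundary, s.
#' @param srp_upper upper limit for SRP assignment, s.
#' @return A `pool_assignment` list: `rrp_size`, `rrp_tau`, `srp_size`,
#'   `srp_tau`, `sustained_rate`, plus `refit_needed` and `dropped`.
#'   A pool of size 0 has `NA` time constant.
#' @export
classify_components <- function(fit, rrp_cutoff = 0.060, srp_upper = 1.000) {
  stopifnot(inherits(fit, "flash_fit"), fit$converged)
  p <- fit$params
  asn <- list(rrp_size = 0, rrp_tau = NA_real_,
              srp_size = 0, srp_tau = NA_real_,
              sustained_rate = p$A3, refit_needed = FALSE, dropped = list())
  place <- function(asn, A, tau, eff_tau = tau) {
    if (eff_tau <= rrp_cutoff) {
      if (asn$rrp_size > 0) asn$refit_needed <- TRUE
      asn$rrp_size <- asn$rrp_size + A
      asn$rrp_tau <- if (asn$refit_needed) NA_real_ else tau
    } else if (eff_tau <= srp_upper) {
      if (asn$srp_size > 0) asn$refit_needed <- TRUE
      asn$srp_size <- asn$srp_size + A
      asn$srp_tau <- if (asn$refit_needed) NA_real_ else tau
    } else {
      asn$dropped <- c(asn$dropped, list(list(size = A, tau = tau)))
    }
    asn
  }
  if (fit$model_id == "delayed_srp") {
    if (p$A1 > 0) asn <- place(asn, p$A1, p$tau1)
    eff <- sqrt(p$tau_slow_delay)
    if (p$SRP > 0) asn <- place(asn, p$SRP, eff)
  } else if (fit$model_id == "single_exp") {
    if (p$A1 > 0) asn <- place(asn, p$A1, p$tau1)
  } else {
    if (p$A1 > 0) asn <- place(asn, p$A1, p$tau1)
    if (p$A2 > 0) asn <- place(asn, p$A2, p$tau2)
  }
  if (asn$rrp_size == 0) asn$rrp_tau <- NA_real_
  if (asn$srp_size == 0) asn$srp_tau <- NA_real_
  structure(asn, class = "pool_assignment")
}

#' @export
print.pool_assignment <- function(x, ...) {
  cat(sprintf("  RRP: %.3g fF (tau %.4g s)  SRP: %.3g fF (tau %.4g s)  sustained: %.3g fF/s\n",
              x$rrp_size, x$rrp_tau, x$srp_size, x$srp_tau, x$sustained_rate))
  if (isTRUE(x$refit_needed))
    cat("  [two components in one class: refit with a single exponential]\n")
  invisible(x)
}

#' Refit with a single exponential plus line
#'
#' Used when the two-exponential fit places both time constants in the same
#' pool class: the trace is refitted with one exponential and a line, and the
#' resulting component is assigned to the requested pool.
#'
#' @inheritParams fit_standard
#' @param component `"rrp"` or `"srp"` — the pool the component belongs to.
#' @return A `flash_fit` with `model_id = "single_exp"` and an `assignment`.
#' @export
refit_single_exponential <- function(trace, component = c("rrp", "srp"),
                                     window = NULL) {
  component <- match.arg(component)
  s <- .fit_samples(trace, window)
  t <- s$t; y <- s$y
  resid_fn <- function(p) y - (p[1] * (1 - exp(-t / p[2])) + p[3] * t)
  lower <- c(0, 1e-4, -Inf); upper <- c(Inf, 10, Inf)
  taus <- exp(seq(log(0.002), log(2), length.out = 8))
  best <- NULL
  for (tau in taus) {
    a <- .vp_amplitudes(t, y, cbind(1 - exp(-t / tau)),
                        clip_nonneg = c(TRUE, FALSE))
    fit <- tryCatch(
      minpack.lm::nls.lm(c(a[1], tau, a[2]), lower, upper, resid_fn,
                         control = .lm_ctrl()),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(.flash_fit("single_exp", NULL, NA_real_, length(t),
                      converged = FALSE))
  p <- unname(best$par)
  kin <- flash_kinetics(p[1], p[2], 0, 1, p[3])  # A2 = 0 placeholder
  kin$A2 <- NULL; kin$tau2 <- NULL
  class(kin) <- "flash_kinetics"
  asn <- structure(list(
    rrp_size = if (component == "rrp") p[1] else 0,
    rrp_tau = if (component == "rrp" && p[1] > 0) p[2] else NA_real_,
    srp_size = if (component == "srp") p[1] else 0,
    srp_tau = if (component == "srp" && p[1] > 0) p[2] else NA_real_,
    sustained_rate = p[3], refit_needed = FALSE,
    dropped = list()), class = "pool_assignment")
  out <- .flash_fit("single_exp", kin, best$deviance, length(t),
                    converged = .lm_ok(best, y), assignment = asn)
  if (p[1] == 0) out$diagnostics$flat <- TRUE
  out
}

#' Model-free capacitance readouts
#'
#' Capacitance increase relative to the pre-flash baseline (mean of pre-flash
#' samples) at fixed times after the flash, linearly interpolated between
#' samples. 60 ms approximately corresponds to fusion of the RRP, 600 ms to
#' RRP + SRP; the 0.5 s readout is labelled `"burst"` and the 5 s readout
#' `"total"`.
#'
#' @param trace a [capacitance_trace()].
#' @param times readout times, s.
#' @return Named numeric vector (names are the times, with a `labels`
#'   attribute marking burst/total). Times outside the trace range are `NA`
#'   with a warning.
#' @export
readouts <- function(trace, times = c(0.06, 0.6, 0.5, 5.0)) {
  base <- .cm_baseline(trace)
  out <- rep(NA_real_, length(times))
  inside <- times >= min(trace$t) & times <= max(trace$t)
  if (any(!inside))
    warning("readout time(s) outside trace range: ",
            paste(times[!inside], collapse = ", "))
  if (any(inside))
    out[inside] <- approx(trace$t, trace$cm, xout = times[inside])$y - base
  names(out) <- as.character(times)
  labels <- rep("", length(times))
  labels[times == 0.5] <- "burst"
  labels[times == 5.0] <- "total"
  attr(out, "labels") <- labels
  out
}
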