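#' Generate a synthetic flash-evoked capacitance trace
#'
#' Evaluates the chosen kinetic model on the grid (0 before the flash) and
#' adds i.i.d. Gaussian noise of SD `noise$sigma_cm`. With a seed the output
#' is reproducible bit-for-bit; the session RNG is left untouched.
#'
#' @param kin a [flash_kinetics()] or [delayed_srp_kinetics()] ground truth.
#' @param grid a [time_grid()].
#' @param noise a [noise_spec()].
#' @param meta free-form labels attached to the trace.
#' @return A [capacitance_trace()] with the ground-truth parameters stored
#'   in `attr(, "truth")`.
#' @export
generate_flash_trace <- function(kin, grid = time_grid(),
                                 noise = noise_spec(), meta = list()) {
  stopifnot(inherits(kin, c("flash_kinetics", "delayed_srp_kinetics")),
            inherits(grid, "time_grid"), inherits(noise, "noise_spec"))
  cm <- eval_kinetics(kin, grid$t)
  if (noise$sigma_cm > 0)
    cm <- cm + with_seed(noise$seed,
                         rnorm(length(cm), sd = noise$sigma_cm))
  tr <- capacitance_trace(grid$t, cm, meta = meta)
  attr(tr, "truth") <- kin
  tr
}

#' Generate a synthetic paired-flash recovery experiment
#'
#' For each inter-stimulus interval, `n_cells_per_interval` cells are
#' simulated. Stim1 is the steady-state primed pool of the model (plus
#' Gaussian amplitude noise of SD `noise$sigma_cm`); the first flash empties
#' the pool and switches the forward priming rate to `k1dp_after`; Stim2 is
#' the pool recovered after the interval (plus noise). Returned ratios are
#' per-cell Stim2/Stim1.
#'
#' @param params a [model1_params()] or [model2_params()] object
#'   (pre-stimulation rates).
#' @param intervals inter-stimulus intervals, s (> 0).
#' @param k1dp_after post-stimulation forward priming rate (same unit as
#'   `params$k1dp`); defaults to no change.
#' @param n_cells_per_interval simulated cells per interval (>= 1).
#' @param noise a [noise_spec()]; `sigma_cm` is applied to the stimulus
#'   amplitudes in fF.
#' @param readout readout label, s.
#' @return A [recovery_curve()] with per-cell rows.
#' @export
generate_recovery_experiment <- function(params, intervals,
                                         k1dp_after = params$k1dp,
                                         n_cells_per_interval = 5,
                                         noise = noise_spec(),
                                         readout = 0.06) {
  if (any(intervals <= 0)) stop("intervals must be strictly positive")
  stopifnot(n_cells_per_interval >= 1)
  pool_fn <- if (inherits(params, "model1_params")) model1_pool
             else model2_pool
  p_after <- params; p_after$k1dp <- k1dp_after
  dt <- rep(intervals, each = n_cells_per_interval)
  with_seed(noise$seed, {
    stim1 <- steady_state_pool(params) +
      rnorm(length(dt), sd = noise$sigma_cm)
    stim2 <- pool_fn(dt, p_after, pp0 = 0) +
      rnorm(length(dt), sd = noise$sigma_cm)
    recovery_curve(dt, stim2 / stim1, readout = readout,
                   cell = seq_along(dt))
  })
}

#' Amperometric spike template
#'
#' A single-vesicle release event: an optional foot plateau (fusion-pore
#' leak) of `foot_duration` s at `foot_amplitude` pA, a linear rise to
#' `i_max` over `rise_time` s, and an exponential decay with time constant
#' `decay_tau` s.
#'
#' @param i_max peak current, pA.
#' @param rise_time foot-to-peak rise time, s.
#' @param decay_tau decay time constant, s.
#' @param foot_amplitude foot plateau current, pA (0 = no foot).
#' @param foot_duration foot plateau duration, s.
#' @return An object of class `spike_shape`.
#' @export
spike_shape <- function(i_max = 40, rise_time = 0.001, decay_tau = 0.003,
                        foot_amplitude = 0, foot_duration = 0) {
  stopifnot(i_max > 0, rise_time > 0, decay_tau > 0,
            foot_amplitude >= 0, foot_duration >= 0)
  structure(list(i_max = i_max, rise_time = rise_time,
                 decay_tau = decay_tau, foot_amplitude = foot_amplitude,
                 foot_duration = foot_duration), class = "spike_shape")
}

# render the template at times `t` relative to event onset
.render_spike <- function(shape, t) {
  f <- shape$foot_duration
  out <- numeric(length(t))
  inf <- t >= 0 & t < f
  out[inf] <- shape$foot_amplitude
  ris <- t >= f & t < f + shape$rise_time
  out[ris] <- shape$foot_amplitude +
    (shape$i_max - shape$foot_amplitude) * (t[ris] - f) / shape$rise_time
  dec <- t >= f + shape$rise_time
  out[dec] <- shape$i_max * exp(-(t[dec] - f - shape$rise_time) /
                                  shape$decay_tau)
  out
}

#' Generate a synthetic amperometric spike train
#'
#' Spikes are placed by a Poisson process with the given rate, thinned by a
#' refractory gap (default 50 ms) so single spikes stay resolvable, each
#' rendered from the template, plus Gaussian noise of SD `noise$sigma_amp`.
#'
#' @param rate mean spike rate, spikes/s (>= 0).
#' @param shape a [spike_shape()].
#' @param duration trace duration, s (> 0).
#' @param noise a [noise_spec()].
#' @param fs sampling rate, Hz (default 25000, decimate for speed in tests).
#' @param refractory minimum gap between spike onsets, s.
#' @return An [amperometry_trace()]; event onset times in
#'   `attr(, "spike_times")`.
#' @export
generate_spike_train <- function(rate, shape = spike_shape(), duration,
                                 noise = noise_spec(), fs = 25000,
                                 refractory = 0.05) {
  if (duration <= 0) stop("duration must be positive")
  stopifnot(rate >= 0, inherits(shape, "spike_shape"), fs > 0)
  t <- seq(0, duration, by = 1 / fs)
  with_seed(noise$seed, {
    times <- numeric(0)
    if (rate > 0) {
      tt <- 0
      repeat {
        tt <- tt + rexp(1, rate)
        if (tt > duration) break
        if (!length(times) || tt - times[length(times)] >= refractory)
          times <- c(times, tt)
      }
    }
    i <- numeric(length(t))
    for (tk in times) {
      span <- shape$foot_duration + shape$rise_time + 8 * shape$decay_tau
      idx <- which(t >= tk & t <= tk + span)
      i[idx] <- i[idx] + .render_spike(shape, t[idx] - tk)
    }
    if (noise$sigma_amp > 0)
      i <- i + rnorm(length(i), sd = noise$sigma_amp)
    tr <- amperometry_trace(t, i, fs)
    attr(tr, "spike_times") <- times
    attr(tr, "truth") <- shape
    tr
  })
}

#' Perturb a stereology input for robustness testing
#'
#' Returns a copy of `truth` with Gaussian jitter (relative SD
#' `noise$sigma_cm / 100`, i.e. sigma_cm read as a percent coefficient of
#' variation here) applied to density, diameter and linear density; all
#' fields are clipped to stay strictly positive and the docked fraction to
#' \[0, 1\]. Zero noise returns the input unchanged.
#'
#' @param truth a [stereology_input()].
#' @param noise a [noise_spec()]; `sigma_cm` doubles as the percent CV.
#' @return A [stereology_input()].
#' @export
generate_stereology_sample <- function(truth, noise = noise_spec()) {
  stopifnot(inherits(truth, "stereology_input"))
  cv <- noise$sigma_cm / 100
  if (cv == 0) return(truth)
  with_seed(noise$seed, {
    jit <- function(x) max(x * (1 + rnorm(1, sd = cv)), x * 1e-3)
    stereology_input(
      delta_v = jit(truth$delta_v), d_v = jit(truth$d_v), h = truth$h,
      c_rest = jit(truth$c_rest), spec_cap = truth$spec_cap, f = truth$f,
      n_l = if (truth$n_l > 0) jit(truth$n_l) else 0,
      docked_fraction = min(max(truth$docked_fraction *
                                  (1 + rnorm(1, sd = cv)), 0), 1))
  })
}
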