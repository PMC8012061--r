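#' Amperometry trace container
#'
#' @param t sample times, s (uniform at 1/fs).
#' @param i amperometric current, pA.
#' @param fs sampling rate, Hz.
#' @return Data frame of class `amperometry_trace`.
#' @export
amperometry_trace <- function(t, i, fs) {
  stopifnot(fs > 0, length(t) == length(i), all(is.finite(i)))
  if (length(t) > 1 &&
      max(abs(diff(t) - 1 / fs)) > 1e-6 / fs)
    stop("amperometry trace must be uniformly sampled at 1/fs")
  structure(data.frame(t = t, i = i), fs = fs,
            class = c("amperometry_trace", "data.frame"))
}

# Gaussian low-pass filter; fc is the -3 dB cut-off. The equivalent
# time-domain SD is 0.1325/fc (standard Gaussian filter relation). Edges are
# handled by renormalizing the truncated kernel.
.gaussian_lowpass <- function(x, fs, fc) {
  sigma <- 0.1325 / fc * fs            # SD in samples
  if (sigma < 0.3) return(x)           # cut-off above Nyquist-ish: no-op
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' Preprocess an amperometric recording
#'
#' Subtracts the cell's 'empty' flash artifact trace sample-wise (recorded
#' without catecholamines, to remove the photoelectric response of the
#' fiber) and applies a Gaussian low-pass filter with 500 Hz cut-off.
#'
#' @param trace an [amperometry_trace()].
#' @param artifact optional artifact trace on the identical grid.
#' @param fc filter cut-off, Hz (default 500).
#' @return The filtered [amperometry_trace()].
#' @export
preprocess_amperometry <- function(trace, artifact = NULL, fc = 500) {
  stopifnot(inherits(trace, "amperometry_trace"))
  i <- trace$i
  if (!is.null(artifact)) {
    if (nrow(artifact) != nrow(trace) ||
        max(abs(artifact$t - trace$t)) > 1e-9)
      stop("artifact trace must share the recording's time grid")
    i <- i - artifact$i
  }
  amperometry_trace(trace$t, .gaussian_lowpass(i, attr(trace, "fs"), fc),
                    attr(trace, "fs"))
}

#' Detect amperometric spikes
#'
#' Finds maximal contiguous excursions above `threshold` pA over baseline
#' (baseline = overall median current), extends each to the surrounding
#' baseline crossings, and flags compound events — a second supra-threshold
#' peak occurring before the current has returned to 25% of the first
#' peak — which are excluded from shape analysis.
#'
#' @param trace a preprocessed [amperometry_trace()].
#' @param threshold detection threshold above baseline, pA (default 5).
#' @return Data frame of class `spike_windows` with columns `start`, `end`,
#'   `peak` (sample indices), `t_peak` (s), `i_peak` (pA above baseline),
#'   `compound` (logical); attribute `baseline` (pA).
#' @export
detect_spikes <- function(trace, threshold = 5) {
  stopifnot(inherits(trace, "amperometry_trace"), threshold > 0)
  base <- stats::median(trace$i)
  x <- trace$i - base
  above <- x > threshold
  if (!any(above)) {
    out <- data.frame(start = integer(), end = integer(), peak = integer(),
                      t_peak = numeric(), i_peak = numeric(),
                      compound = logical())
    return(structure(out, baseline = base,
                     class = c("spike_windows", "data.frame")))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  n <- length(x)
  # extend each run to the surrounding baseline (<= 0) crossings
  for (j in seq_len(nrow(runs))) {
    s <- runs$start[j]
    while (s > 1 && x[s - 1] > 0) s <- s - 1L
    e <- runs$end[j]
    while (e < n && x[e + 1] > 0) e <- e + 1L
    runs$start[j] <- s; runs$end[j] <- e
  }
  # merge runs that now overlap (they share one supra-baseline excursion)
  keep <- !logical(nrow(runs))
  merged <- runs[1, , drop = FALSE]
  for (j in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    if (runs$start[j] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], runs$end[j])
    } else merged <- rbind(merged, runs[j, ])
  }
  runs <- merged
  runs$peak <- vapply(seq_len(nrow(runs)), function(j) {
    idx <- runs$start[j]:runs$end[j]
    idx[which.max(x[idx])]
  }, integer(1))
  runs$t_peak <- trace$t[runs$peak]
  runs$i_peak <- x[runs$peak]
  # compound: another supra-threshold local maximum inside the window that
  # is separated from the main peak by a trough above 25% of the main peak
  runs$compound <- vapply(seq_len(nrow(runs)), function(j) {
    idx <- runs$start[j]:runs$end[j]
    xi <- x[idx]
    if (length(xi) < 5) return(FALSE)
    loc <- which(diff(sign(diff(xi))) == -2) + 1L
    loc <- loc[xi[loc] > threshold]
    if (length(loc) < 2) return(FALSE)
    main <- which.max(xi)
    for (l in loc) {
      if (l == main) next
      trough <- min(xi[min(l, main):max(l, main)])
      if (trough > 0.25 * max(xi)) return(TRUE)
    }
    FALSE
  }, logical(1))
  rownames(runs) <- NULL
  structure(runs, baseline = base,
            class = c("spike_windows", "data.frame"))
}

# linearly interpolated crossing time of level `lev` between samples k, k+1
.cross_time <- function(t, x, k, lev) {
  if (x[k + 1] == x[k]) return(t[k])
  t[k] + (lev - x[k]) / (x[k + 1] - x[k]) * (t[k + 1] - t[k])
}

# first upward crossing of `lev` in x[idx] scanning left from `from`
.last_rise_below <- function(x, from, lev) {
  k <- from
  while (k > 1 && x[k - 1] > lev) k <- k - 1L
  k
}

#' Extract shape parameters of a single spike
#'
#' Computes, for one non-compound spike window: peak current above baseline
#' (`i_max`, pA), integrated charge of foot plus spike (`q`, pC; trapezoidal
#' rule over the window), duration at half maximum (`t_half`, ms),
#' baseline-to-baseline duration (`duration`, ms), 50–90% rise time and
#' 75–25% decay time (ms; linear interpolation between samples), and the
#' foot signal. Foot onset is the first sustained crossing of
#' `foot_threshold` pA before the main upstroke; foot end is where the
#' extrapolated maximal-slope line of the upstroke meets the foot level.
#' If no foot is found the foot fields are `NA` (absent), not zero.
#'
#' @param trace the preprocessed [amperometry_trace()].
#' @param window one row of [detect_spikes()] output.
#' @param baseline baseline current, pA. Default: median of the 50 ms
#'   preceding the window (falling back to the detection baseline).
#' @param foot_threshold foot detection level above baseline, pA (default 2).
#' @return List of class `spike_features`.
#' @export
spike_features <- function(trace, window, baseline = NULL,
                           foot_threshold = 2) {
  stopifnot(inherits(trace, "amperometry_trace"))
  if (isTRUE(window$compound))
    stop("compound spikes are excluded from shape analysis")
  fs <- attr(trace, "fs")
  s <- window$start; e <- window$end
  if (is.null(baseline)) {
    pre <- max(1L, s - round(0.05 * fs)):max(1L, s - 1L)
    baseline <- if (length(pre) && pre[1] < s) stats::median(trace$i[pre])
                else attr(window, "baseline") %||% stats::median(trace$i)
  }
  idx <- s:e
  t <- trace$t[idx]
  x <- trace$i[idx] - baseline
  pk <- which.max(x)
  i_max <- x[pk]
  q <- sum(diff(t) * (head(x, -1) + tail(x, -1)) / 2)  # pA*s = pC
  width_at <- function(lev) {
    up <- .cross_time(t, x, max(1L, .last_rise_below(x, pk, lev) - 1L), lev)
    k <- pk
    while (k < length(x) && x[k + 1] > lev) k <- k + 1L
    dn <- if (k < length(x)) .cross_time(t, x, k, lev) else t[length(x)]
    c(up = up, down = dn)
  }
  h <- width_at(i_max / 2)
  t_half <- (h["down"] - h["up"]) * 1000
  duration <- (t[length(t)] - t[1]) * 1000
  r50 <- width_at(0.50 * i_max)["up"]
  r90 <- width_at(0.90 * i_max)["up"]
  d75 <- width_at(0.75 * i_max)["down"]
  d25 <- width_at(0.25 * i_max)["down"]
  rise_50_90 <- (r90 - r50) * 1000
  decay_75_25 <- (d25 - d75) * 1000
  # foot: maximal upstroke slope, extrapolated back to the foot level
  foot <- list(foot_duration = NA_real_, foot_amplitude = NA_real_,
               foot_charge = NA_real_)
  if (pk > 2) {
    slopes <- diff(x[1:pk]) * fs
    m <- which.max(slopes)
    slope <- slopes[m]
    if (is.finite(slope) && slope > 0 && i_max > foot_threshold) {
      # upstroke line through the max-slope segment midpoint, extrapolated
      # back to the pre-foot baseline: its intercept marks the foot end
      tm <- (t[m] + t[m + 1]) / 2
      xm <- (x[m] + x[m + 1]) / 2
      t_end <- tm - xm / slope
      k_on <- .last_rise_below(x, m, foot_threshold)
      t_on <- if (k_on > 1) .cross_time(t, x, k_on - 1L, foot_threshold)
              else t[1]
      # a genuine foot must precede the upstroke by more than one sample
      if (t_end - t_on > 1.5 / fs) {
        seg <- t >= t_on & t <= t_end
        if (sum(seg) >= 2) {
          foot$foot_duration <- (t_end - t_on) * 1000
          foot$foot_amplitude <- mean(x[seg])
          ts <- t[seg]; xs <- x[seg]
          foot$foot_charge <-
            sum(diff(ts) * (head(xs, -1) + tail(xs, -1)) / 2)
        }
      }
    }
  }
  structure(c(list(i_max = i_max, q = q,
                   t_half = unname(t_half), duration = duration,
                   rise_50_90 = unname(rise_50_90),
                   decay_75_25 = unname(decay_75_25),
                   t_peak = t[pk]),
              foot),
            class = "spike_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a spike train
#'
#' The interspike interval is the **median** time between consecutive
#' spikes. Per-feature means and medians are reported across spikes.
#'
#' @param features list of [spike_features()] (each carrying `t_peak`).
#' @return List with `n_spikes`, `interspike_interval` (s; `NA` with fewer
#'   than 2 spikes) and a `features` data frame of mean/median per metric.
#' @export
train_summary <- function(features) {
  stopifnot(is.list(features))
  n <- length(features)
  isi <- if (n >= 2) {
    tp <- sort(vapply(features, function(f) f$t_peak, numeric(1)))
    stats::median(diff(tp))
  } else NA_real_
  metrics <- c("i_max", "q", "t_half", "duration", "rise_50_90",
               "decay_75_25", "foot_duration", "foot_amplitude",
               "foot_charge")
  tab <- if (n > 0) {
    vals <- sapply(metrics, function(m)
      vapply(features, function(f) f[[m]] %||% NA_real_, numeric(1)))
    vals <- matrix(vals, nrow = n)
    data.frame(metric = metrics,
               mean = apply(vals, 2, mean, na.rm = TRUE),
               median = apply(vals, 2, median, na.rm = TRUE),
               n = apply(vals, 2, function(v) sum(!is.na(v))))
  } else data.frame(metric = character(), mean = numeric(),
                    median = numeric(), n = integer())
  list(n_spikes = n, interspike_interval = isi, features = tab)
}
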