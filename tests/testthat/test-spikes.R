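# a clean rectangular pulse trace: analytic feature values
rect_trace <- function(amp = 20, width = 0.004, fs = 10000, pad = 0.1) {
  t <- seq(0, 2 * pad + width, by = 1 / fs)
  i <- ifelse(t >= pad & t < pad + width, amp, 0)
  amperometry_trace(t, i, fs)
}

test_that("preprocessing subtracts the artifact and low-passes the signal", {
  tr <- generate_spike_train(2, duration = 2,
                             noise = noise_spec(sigma_amp = 1, seed = 3),
                             fs = 10000)
  zero <- preprocess_amperometry(tr, artifact = tr)
  expect_lt(max(abs(zero$i)), 1e-12)
  # low-pass property on white noise
  wn <- amperometry_trace(seq(0, 1, 1 / 10000),
                          rnorm(10001), fs = 10000)
  expect_lt(sd(preprocess_amperometry(wn)$i), sd(wn$i))
  # grid mismatch rejected
  short <- amperometry_trace(tr$t[-1], tr$i[-1], attr(tr, "fs"))
  expect_error(preprocess_amperometry(tr, artifact = short), "grid")
})

test_that("detection finds well-separated spikes and none in a flat trace", {
  flat <- amperometry_trace(seq(0, 1, 1e-4), rep(0, 10001), 10000)
  expect_equal(nrow(detect_spikes(flat)), 0)

  sh <- spike_shape(i_max = 30, rise_time = 0.001, decay_tau = 0.003)
  tr <- generate_spike_train(2, sh, duration = 6,
                             noise = noise_spec(sigma_amp = 0.5, seed = 21),
                             fs = 10000)
  w <- detect_spikes(preprocess_amperometry(tr))
  expect_equal(nrow(w), length(attr(tr, "spike_times")))
  # detection count is non-increasing in threshold
  counts <- vapply(c(2, 5, 10, 20), function(th)
    nrow(detect_spikes(preprocess_amperometry(tr), threshold = th)),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("generator round trip: detected count tracks the injected count", {
  n_inj <- n_det <- 0
  for (s in 1:5) {
    tr <- generate_spike_train(3, duration = 4,
                               noise = noise_spec(sigma_amp = 0.5,
                                                  seed = 40 + s),
                               fs = 10000)
    n_inj <- n_inj + length(attr(tr, "spike_times"))
    n_det <- n_det + nrow(detect_spikes(preprocess_amperometry(tr)))
  }
  expect_lt(abs(n_det - n_inj), 3 * sqrt(n_inj))  # Poisson-scale agreement
})

test_that("rectangular pulse yields analytic shape features", {
  amp <- 20; width <- 0.004
  tr <- rect_trace(amp, width)
  w <- detect_spikes(tr, threshold = 5)
  expect_equal(nrow(w), 1)
  f <- spike_features(tr, w[1, ], baseline = 0)
  expect_equal(f$i_max, amp)
  expect_equal(f$q, amp * width, tolerance = 0.05)
  expect_equal(f$t_half, width * 1000, tolerance = 0.1)
  # vertical flanks: rise and decay intervals are below one sample
  expect_lt(f$rise_50_90, 1000 / attr(tr, "fs"))
  expect_lt(f$decay_75_25, 1000 / attr(tr, "fs"))
})

test_that("amplitude features are homogeneous and time features scale-invariant", {
  sh <- spike_shape(i_max = 40, rise_time = 0.001, decay_tau = 0.003,
                    foot_amplitude = 3, foot_duration = 0.002)
  tr <- generate_spike_train(1, sh, duration = 1.2,
                             noise = noise_spec(sigma_amp = 0, seed = 9),
                             fs = 25000)
  if (nrow(detect_spikes(tr)) == 0)
    tr <- generate_spike_train(2, sh, duration = 2,
                               noise = noise_spec(sigma_amp = 0, seed = 10),
                               fs = 25000)
  w <- detect_spikes(tr)
  f1 <- spike_features(tr, w[1, ], baseline = 0)
  tr2 <- amperometry_trace(tr$t, tr$i * 2, attr(tr, "fs"))
  f2 <- spike_features(tr2, detect_spikes(tr2)[1, ], baseline = 0)
  expect_equal(f2$i_max, 2 * f1$i_max, tolerance = 1e-9)
  expect_equal(f2$q, 2 * f1$q, tolerance = 1e-9)
  expect_equal(f2$foot_amplitude, 2 * f1$foot_amplitude, tolerance = 1e-6)
  for (m in c("t_half", "duration", "rise_50_90", "decay_75_25"))
    expect_equal(f2[[m]], f1[[m]], tolerance = 1e-6)
})

test_that("foot metrics are recovered from the generation template", {
  sh <- spike_shape(i_max = 40, rise_time = 0.0005, decay_tau = 0.003,
                    foot_amplitude = 3, foot_duration = 0.001)
  tr <- generate_spike_train(2, sh, duration = 4,
                             noise = noise_spec(sigma_amp = 0, seed = 14),
                             fs = 25000)
  w <- detect_spikes(tr)
  f <- spike_features(tr, w[1, ], baseline = 0)
  expect_equal(f$foot_amplitude, 3, tolerance = 0.5)
  expect_equal(f$foot_duration, 1, tolerance = 0.35)
  expect_equal(f$i_max, 40, tolerance = 0.02)
  # a footless template reports absent foot fields, not zero
  sh0 <- spike_shape(i_max = 40, rise_time = 0.0005, decay_tau = 0.003)
  tr0 <- generate_spike_train(2, sh0, duration = 4,
                              noise = noise_spec(sigma_amp = 0, seed = 14),
                              fs = 25000)
  f0 <- spike_features(tr0, detect_spikes(tr0)[1, ], baseline = 0)
  expect_true(is.na(f0$foot_duration))
})

test_that("charge is additive over a partition of the window", {
  tr <- rect_trace(15, 0.006)
  w <- detect_spikes(tr, threshold = 5)
  f_all <- spike_features(tr, w[1, ], baseline = 0)
  mid <- floor((w$start[1] + w$end[1]) / 2)
  q_left <- sum(diff(tr$t[w$start[1]:mid]) *
                  (head(tr$i[w$start[1]:mid], -1) +
                     tail(tr$i[w$start[1]:mid], -1)) / 2)
  q_right <- sum(diff(tr$t[mid:w$end[1]]) *
                   (head(tr$i[mid:w$end[1]], -1) +
                      tail(tr$i[mid:w$end[1]], -1)) / 2)
  expect_equal(q_left + q_right, f_all$q, tolerance = 1e-12)
})

test_that("train summary reports the median interspike interval", {
  mk <- function(tp) list(i_max = 10, q = 0.1, t_half = 2, duration = 5,
                          rise_50_90 = 0.3, decay_75_25 = 2,
                          foot_duration = NA_real_,
                          foot_amplitude = NA_real_,
                          foot_charge = NA_real_, t_peak = tp)
  s <- train_summary(lapply(c(0, 1, 2, 3), mk))
  expect_equal(s$interspike_interval, 1)
  one <- train_summary(list(mk(0.5)))
  expect_true(is.na(one$interspike_interval))
  expect_equal(one$features$mean[one$features$metric == "i_max"], 10)
  # Poisson train: median interval ~ ln 2 / rate over many spikes
  set.seed(31)
  tp <- cumsum(rexp(4000, 5))
  s2 <- train_summary(lapply(tp, mk))
  expect_equal(s2$interspike_interval, log(2) / 5, tolerance = 0.1)
})

test_that("compound events are flagged and excluded from shape analysis", {
  fs <- 10000
  t <- seq(0, 0.2, 1 / fs)
  tpl <- function(tc) 30 * exp(-((t - tc) / 0.004)^2)
  tr <- amperometry_trace(t, tpl(0.08) + tpl(0.088), fs)  # overlapping pair
  w <- detect_spikes(tr)
  expect_true(any(w$compound))
  expect_error(spike_features(tr, w[which(w$compound)[1], ]), "compound")
})
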