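# shared fixtures, built in code

# WT-like flash kinetics at raised prestimulation calcium (large RRP, slow
# burst, modest sustained rate)
wt_like_kinetics <- function() flash_kinetics(A1 = 74, tau1 = 0.0134,
                                              A2 = 48, tau2 = 0.5, A3 = 15)

# strong-delay kinetics typical of ubMunc13-2 overexpression without Syt-7
delayed_like_kinetics <- function() delayed_srp_kinetics(
  A1 = 200, tau1 = 0.02, SRP = 800, tau_slow_delay = 1.0, A3 = 20)

# pre-stimulation Model I parameter sets from the paired-flash analysis
# (60 ms readout): pool size and depriming rate per genotype
wt_model1 <- function() model1_params(k1dp = 0.043 * 74.2, k_minus1 = 0.043)
ko_model1 <- function() model1_params(k1dp = 0.091 * 33.6, k_minus1 = 0.091)

# inter-stimulus intervals used throughout the recovery simulations
recovery_intervals <- function() c(2, 5, 10, 22, 60, 120)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

expect_rel <- function(est, truth, tol) {
  expect_lt(max(rel_err(est, truth)), tol)
}

# brute-force two-sided Fisher p: enumerate the hypergeometric support with
# dhyper (independent of the package's log-factorial route)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  pk <- stats::dhyper(k, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  min(sum(pk[pk <= p_obs * (1 + 1e-7)]), 1)
}
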