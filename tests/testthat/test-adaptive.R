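stationary_cc <- function(seed, rate = c(105, 115)) {
  p <- cc_gen_params(rate_range = rate, cycle_jitter_cv = 0,
                     harmonic_mod_sd = 0)
  generate_cc_artifact(4, p, seed = seed)
}

test_that("instantaneous frequency follows cycle lengths", {
  ref <- compression_reference(seq(0, 3, by = 0.5))
  f0 <- instantaneous_frequency(ref, 1000, 250)
  expect_equal(unique(f0), 2)

  ref2 <- compression_reference(c(0, 0.6, 1.0))
  f02 <- instantaneous_frequency(ref2, 500, 250)
  expect_equal(f02[1], 1 / 0.6)
  expect_equal(f02[round(0.6 * 250) + 2], 2.5)
  # step change exactly at the onset sample
  expect_equal(unique(f02[1:150]), 1 / 0.6)
  expect_equal(unique(f02[152:500]), 2.5)

  expect_error(instantaneous_frequency(list(onset_times = 0), 100, 250),
               "compression_reference")
})

test_that("mu = 0 leaves the input untouched", {
  g <- stationary_cc(1)
  vf <- generate_vf(4, seed = 2)
  mixed <- mix_at_snr(vf, g$segment, 0)
  f0 <- instantaneous_frequency(g$reference, 1000, 250)
  out <- lms_cancel(mixed, f0, lms_config(mu = 0))
  expect_identical(out$estimated_vf$samples, mixed$samples)
  expect_true(all(out$artifact_estimate$samples == 0))
})

test_that("canceller suppresses a stationary harmonic artifact by >= 15 dB", {
  supp <- vapply(1:5, function(seed) {
    g <- stationary_cc(seed)
    f0 <- instantaneous_frequency(g$reference, 1000, 250)
    res <- lms_cancel(g$segment, f0, lms_config())
    late <- 501:1000
    10 * log10(mean(g$segment$samples[late]^2) /
                 mean(res$estimated_vf$samples[late]^2))
  }, 0)
  expect_true(all(supp >= 15))
})

test_that("canceller improves SNR by >= 6 dB at 0 dB mixing", {
  # mean over enough seeded trials that the Monte-Carlo error of the
  # mean (sd ~1.6 dB between trials) is well below the margin tested
  impr <- vapply(1:300, function(seed) {
    vf <- generate_vf(4, seed = 300 + seed)
    g <- stationary_cc(600 + seed, rate = c(80, 130))
    mixed <- mix_at_snr(vf, g$segment, 0)
    f0 <- instantaneous_frequency(g$reference, 1000, 250)
    res <- lms_cancel(mixed, f0, lms_config())
    ss <- 251:1000 # steady state after the 1-s adaptation transient
    snr <- function(est) {
      10 * log10(mean(vf$samples[ss]^2) /
                   mean((est[ss] - vf$samples[ss])^2))
    }
    snr(res$estimated_vf$samples) - snr(mixed$samples)
  }, 0)
  expect_gte(mean(impr), 6)
})

test_that("amsa_adf passes through clean VF and suppresses pure artifact", {
  vf <- generate_vf(4, seed = 30)
  ref <- compression_reference(seq(0, 3.6, by = 0.55))
  expect_equal(amsa_adf(vf, ref, lms_config(mu = 0)), amsa_fft(vf))

  # converged suppression: run over 8 s of stationary artifact and take
  # AMSA of the trailing 4-s window of residual vs input (the 4-s direct
  # ratio is dominated by the adaptation transient, not by leakage)
  p <- cc_gen_params(rate_range = c(105, 115), cycle_jitter_cv = 0,
                     harmonic_mod_sd = 0)
  g8 <- generate_cc_artifact(8, p, seed = 31)
  f0 <- instantaneous_frequency(g8$reference, 2000, 250)
  res <- lms_cancel(g8$segment, f0)
  tail4 <- function(x) ecg_segment(x$samples[1001:2000], fs = 250)
  expect_lt(amsa_fft(tail4(res$estimated_vf)),
            0.2 * amsa_fft(tail4(g8$segment)))
  # and the 4-s direct ratio still shows clear suppression
  g <- stationary_cc(31)
  expect_lt(amsa_adf(g$segment, g$reference), 0.5 * amsa_fft(g$segment))
})

test_that("adaptive filtering beats the naive FFT on 0 dB mixtures", {
  wins <- vapply(1:200, function(seed) {
    vf <- generate_vf(4, seed = 1000 + seed)
    g <- generate_cc_artifact(4, seed = 3000 + seed)
    mixed <- mix_at_snr(vf, g$segment, 0)
    truth <- amsa_fft(vf)
    abs(amsa_adf(mixed, g$reference) - truth) <
      abs(amsa_fft(mixed) - truth)
  }, NA)
  expect_gte(mean(wins), 0.8)
})

test_that("filter is stable and continuous in the step size", {
  vf <- generate_vf(4, seed = 50)
  g <- stationary_cc(51)
  mixed <- mix_at_snr(vf, g$segment, -3)
  f0 <- instantaneous_frequency(g$reference, 1000, 250)
  # Widrow-form update w += 2*mu*e*u/||u||^2: the classical normalized-LMS
  # stability range (step < 2) maps to mu < 1
  for (mu in c(0.1, 0.5, 0.9)) {
    res <- lms_cancel(mixed, f0, lms_config(mu = mu))
    expect_true(all(is.finite(res$a)) && all(is.finite(res$b)))
    expect_lt(max(abs(res$a), abs(res$b)), 100)
  }
  tiny <- lms_cancel(mixed, f0, lms_config(mu = 1e-8))
  expect_lt(max(abs(tiny$estimated_vf$samples - mixed$samples)), 1e-4)
  expect_error(lms_cancel(mixed, rep(30, 1000), lms_config()), "aliasing")
})
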