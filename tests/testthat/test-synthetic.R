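test_that("generated VF is band-limited, amplitude-calibrated and seeded", {
  vf <- generate_vf(4, seed = 1)
  hp <- highpass(vf)
  X <- Mod(stats::fft(hp$samples))^2
  f <- (seq_along(X) - 1) * vf$fs / length(X)
  half <- f <= vf$fs / 2
  expect_gt(sum(X[half & f < 18]) / sum(X[half]), 0.9)
  expect_true(is_vf(vf))

  pinned <- vf_gen_params(amplitude_pp_range = c(0.5, 0.5))
  v2 <- generate_vf(4, pinned, seed = 2)
  sec_pp <- vapply(split(v2$samples, ceiling(seq_along(v2$samples) / 250)),
                   function(s) diff(range(s)), 0)
  expect_gt(median(sec_pp), 0.4)
  expect_lt(median(sec_pp), 0.6)

  a <- generate_vf(4, seed = 3)
  b <- generate_vf(4, seed = 3)
  expect_identical(a$samples, b$samples)
  c_ <- generate_vf(4, seed = 4)
  expect_lt(abs(cor(a$samples, c_$samples)), 0.5)
})

test_that("vf parameter invariants are enforced", {
  expect_error(vf_gen_params(dominant_freq_range = c(1, 7)), "\\[2, 18\\]")
  expect_error(vf_gen_params(amplitude_pp_range = c(0.05, 1)), "0.1 mV")
  expect_error(generate_vf(2), "at least 4")
})

test_that("compression artifact has the prescribed harmonic structure", {
  p <- cc_gen_params(rate_range = c(100, 100), cycle_jitter_cv = 0,
                     harmonic_mod_sd = 0)
  g <- generate_cc_artifact(4, p, seed = 1)
  X <- Mod(stats::fft(g$segment$samples))
  f <- (seq_along(X) - 1) * 250 / length(X)
  half <- which(f <= 125)
  f0 <- 100 / 60
  for (k in 1:3) {
    # a spectral peak within one 0.25 Hz bin of each harmonic
    sel <- which(abs(f[half] - k * f0) <= 0.25 + 1e-9)
    nearby <- which(abs(f[half] - k * f0) <= 1)
    expect_equal(max(X[half][sel]), max(X[half][nearby]))
  }
  expect_s3_class(g$reference, "compression_reference")

  # 4 s at fixed 120/min -> 8 complete cycles
  p120 <- cc_gen_params(rate_range = c(120, 120), cycle_jitter_cv = 0)
  g120 <- generate_cc_artifact(4, p120, seed = 2)
  on <- g120$reference$onset_times
  expect_equal(sum(on < 4 - 1e-9), 8)

  expect_error(cc_gen_params(rate_range = c(40, 100)), "\\[50, 200\\]")
})

test_that("single-harmonic jitter-free artifact is a pure tone", {
  p <- cc_gen_params(rate_range = c(110, 110), cycle_jitter_cv = 0,
                     n_harmonics = 1, harmonic_mod_sd = 0)
  g <- generate_cc_artifact(4, p, seed = 3)
  x <- g$segment$samples
  # fit amplitude/phase at the fundamental; residual = harmonic distortion
  f0 <- 110 / 60
  t <- (seq_along(x) - 1) / 250
  fit <- lm(x ~ cos(2 * pi * f0 * t) + sin(2 * pi * f0 * t))
  thd <- sqrt(mean(residuals(fit)^2) / mean(x^2))
  expect_lt(thd, 0.01)
})

test_that("mix_at_snr achieves the requested level exactly", {
  vf <- generate_vf(4, seed = 10)
  art <- generate_cc_artifact(4, seed = 11)$segment
  for (snr in c(3, 0, -3, -6)) {
    mixed <- mix_at_snr(vf, art, snr)
    g <- attr(mixed, "gain")
    measured <- 10 * log10(mean(vf$samples^2) /
                             mean((g * art$samples)^2))
    expect_equal(measured, snr, tolerance = 1e-12)
    expect_equal(mixed$samples, vf$samples + g * art$samples)
  }
  # 0 dB equalizes powers
  m0 <- mix_at_snr(vf, art, 0)
  g0 <- attr(m0, "gain")
  expect_equal(mean((g0 * art$samples)^2) / mean(vf$samples^2), 1,
               tolerance = 1e-9)
  # closed-form gain for unit-power inputs at 3 dB
  u1 <- ecg_segment(rep(c(1, -1), 500))
  u2 <- ecg_segment(rep(c(1, 1, -1, -1), 250))
  expect_equal(attr(mix_at_snr(u1, u2, 3), "gain"), 10^(-3 / 20),
               tolerance = 1e-9)
  expect_error(mix_at_snr(vf, ecg_segment(rep(0, 1000))), "zero power")
})

test_that("amplitude-based rhythm rules behave at the 0.1 mV boundary", {
  zero <- ecg_segment(rep(0, 1000))
  expect_true(is_asystole(zero))
  expect_false(is_vf(zero))
  expect_true(is_vf(generate_vf(4, seed = 20)))
  low <- sinusoid_segment(6, amp = 0.099 / 2)
  high <- sinusoid_segment(6, amp = 0.101 / 2)
  expect_true(is_asystole(low))
  expect_false(is_asystole(high))
  # a strongly periodic organized-looking rhythm fails the VF rule even
  # when large
  org <- sinusoid_segment(1.5, amp = 1)
  expect_false(is_vf(org))
})

test_that("simulated shock outcomes follow the logistic link", {
  amsa <- exp(runif(4000, 0, 3.2))
  # beta1 = 0: success rate equals plogis(beta0) within a binomial CI
  y0 <- simulate_shock_outcomes(amsa, outcome_model(-1, 0), seed = 1)
  p0 <- plogis(-1)
  expect_lt(abs(mean(y0) - p0), 3 * sqrt(p0 * (1 - p0) / 4000))
  # large beta1: near-perfect separation
  y1 <- simulate_shock_outcomes(amsa, outcome_model(-15, 10), seed = 2)
  expect_gt(roc_auc(amsa, y1)$auc, 0.95)
  expect_error(simulate_shock_outcomes(c(1, -2), outcome_model()),
               "positive")
})

test_that("empirical AUC matches the integration oracle", {
  set.seed(7)
  amsa <- exp(rnorm(5000, 2, 0.7))
  model <- outcome_model(-3, 1.5)
  y <- simulate_shock_outcomes(amsa, model, seed = 7)
  emp <- roc_auc(amsa, y)$auc
  # oracle: expected concordance of the label-generating process over the
  # empirical AMSA distribution, computed by cumulative sums over the
  # sorted scores
  p <- plogis(model$beta0 + model$beta1 * log(amsa))
  o <- order(amsa)
  ps <- p[o]
  qs <- 1 - ps
  # sum over j of q_j * (sum of p_i for scores above j)
  above <- rev(cumsum(rev(ps))) - ps
  oracle <- sum(qs * above) / (sum(ps) * sum(qs))
  expect_lt(abs(emp - oracle), 0.03)
})

test_that("dataset builds are subject-disjoint, SNR-balanced, seeded", {
  ds <- tiny_dataset()
  by_split <- split(ds$subject_id, ds$split)
  expect_length(intersect(by_split$train, by_split$test), 0)
  expect_length(intersect(by_split$train, by_split$validation), 0)
  expect_length(intersect(by_split$validation, by_split$test), 0)
  tab <- table(ds$snr_db)
  expect_true(max(tab) - min(tab) <= 1)
  ds2 <- tiny_dataset()
  expect_identical(
    lapply(ds$corrupted, function(s) s$samples),
    lapply(ds2$corrupted, function(s) s$samples)
  )
  expect_identical(ds$amsa_true, ds2$amsa_true)
  expect_error(
    build_dataset(experiment_config(split = c(train = 0.5,
                                              validation = 0.2,
                                              test = 0.2))),
    "summing to 1")
})
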