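test_that("resampling rescales length and preserves band content", {
  s125 <- sinusoid_segment(5, duration = 4, fs = 125)
  up <- resample_to(s125, 250)
  expect_equal(length(up), 1000)
  expect_equal(up$fs, 250)

  s <- sinusoid_segment(5, duration = 4, fs = 250)
  expect_identical(resample_to(s, 250), s)

  down_up <- resample_to(resample_to(s, 125), 250)
  edge <- round(0.1 * 250)
  interior <- (edge + 1):(length(s) - edge)
  t <- seq_len(1000) / 250
  expect_lt(max(abs(down_up$samples[interior] - sin(2 * pi * 5 * t)[interior])),
            0.01)
  expect_error(resample_to(s, -1), "positive")
})

test_that("round-trip resampling has small relative RMS error", {
  # band-limited multitone (all content below the 62.5 Hz lower Nyquist)
  set.seed(5)
  t <- seq_len(1000) / 250
  x <- rowSums(vapply(1:10, function(k) {
    runif(1, 0.1, 1) * sin(2 * pi * runif(1, 2, 30) * t + runif(1, 0, 6))
  }, t))
  s <- ecg_segment(x)
  rt <- resample_to(resample_to(s, 125), 250)
  edge <- round(0.1 * 250)
  interior <- (edge + 1):(length(s) - edge)
  err <- rt$samples[interior] - s$samples[interior]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(s$samples[interior]^2)), 0.01)
})

test_that("segment pairs are found for the clean/corrupt adjacency layouts", {
  fs <- 250
  set.seed(9)
  mk <- function(n) ecg_segment(rnorm(n, sd = 0.2), fs = fs,
                                subject_id = "S1")
  # 8 s, CC on in the first 4 s only -> one pair
  e8 <- mk(8 * fs)
  mask8 <- rep(c(TRUE, FALSE), each = 4 * fs)
  p <- extract_segment_pairs(e8, mask8)
  expect_equal(nrow(p), 1)
  expect_equal(p$t_corrupt, 0)
  expect_equal(p$t_clean, 4)
  expect_equal(p$amsa_true[1], amsa_fft(p$uncorrupted[[1]]))

  # CC throughout -> no pairs
  expect_equal(nrow(extract_segment_pairs(e8, rep(TRUE, 8 * fs))), 0)

  # 12 s with CC only in the middle 4 s -> two pairs sharing the corrupted
  # window
  e12 <- mk(12 * fs)
  mask12 <- rep(c(FALSE, TRUE, FALSE), each = 4 * fs)
  p2 <- extract_segment_pairs(e12, mask12)
  expect_equal(nrow(p2), 2)
  expect_setequal(p2$t_clean, c(0, 8))
  expect_equal(unique(p2$t_corrupt), 4)
})

test_that("pair windows never straddle a compression-state transition", {
  fs <- 250
  set.seed(10)
  for (rep in 1:5) {
    n <- 20 * fs
    e <- ecg_segment(rnorm(n, sd = 0.2), fs = fs, subject_id = "S1")
    # random alternating mask with segment lengths of 2-6 s
    mask <- logical(0)
    state <- runif(1) > 0.5
    while (length(mask) < n) {
      mask <- c(mask, rep(state, round(runif(1, 2, 6) * fs)))
      state <- !state
    }
    mask <- mask[seq_len(n)]
    p <- extract_segment_pairs(e, mask)
    if (nrow(p) == 0) next
    w <- 4 * fs
    for (i in seq_len(nrow(p))) {
      i_clean <- round(p$t_clean[i] * fs) + 1
      i_corr <- round(p$t_corrupt[i] * fs) + 1
      expect_true(all(!mask[i_clean:(i_clean + w - 1)]))
      expect_true(all(mask[i_corr:(i_corr + w - 1)]))
    }
  }
})
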