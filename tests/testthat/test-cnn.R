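test_that("architecture configuration is validated", {
  expect_error(cnn_config(kernel_width = 4), "odd")
  expect_error(cnn_config(n_pooled_blocks = 9), "1..7")
  expect_error(cnn_config(channels = 12), "4, 8, 16, 32, 64")
  expect_error(build_cnn(cnn_config(n_pooled_blocks = 7), 100), "too short")
})

test_that("feature lengths halve with ceiling and the output is scalar", {
  mdl <- build_cnn(cnn_config(), 499, seed = 1)
  expect_equal(mdl$lengths, c(499, 250, 125, 63, 32, 16))
  seg <- generate_vf(4, seed = 1)
  out <- predict_amsa(mdl, seg)
  expect_length(out, 1)
  expect_true(is.finite(out))
  expect_gte(out, 0)
})

test_that("builds are deterministic under a fixed seed", {
  m1 <- build_cnn(cnn_config(), 499, seed = 5)
  m2 <- build_cnn(cnn_config(), 499, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_equal(amsacc:::n_parameters(m1), amsacc:::n_parameters(m2))
})

test_that("backpropagation matches finite differences", {
  cfg <- cnn_config(kernel_width = 3, n_pooled_blocks = 2, channels = 4,
                    dropout = 0, fc_sizes = c(5, 1))
  mdl <- build_cnn(cfg, 13, seed = 3)
  set.seed(42)
  B <- 3
  X <- matrix(rnorm(2 * 13 * B), 2)
  y <- rnorm(B)
  lossfun <- function(params) {
    m2 <- mdl
    m2$params <- params
    fwd <- amsacc:::cnn_forward(m2, X, B, train = TRUE)
    mean((fwd$pred - y)^2)
  }
  fwd <- amsacc:::cnn_forward(mdl, X, B, train = TRUE)
  grads <- amsacc:::cnn_backward(mdl, fwd, 2 * (fwd$pred - y) / B, B)
  eps <- 1e-6
  for (nm in names(mdl$params)) {
    idx <- seq_along(mdl$params[[nm]])
    if (length(idx) > 12) idx <- sample(idx, 12)
    for (i in idx) {
      p1 <- mdl$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- mdl$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      gn <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      expect_equal(grads[[nm]][i], gn, tolerance = 1e-4)
    }
  }
})

test_that("a small network memorizes a small training set", {
  ds <- tiny_dataset(n_subjects = 8, pairs_per_snr = 1, seed = 21)
  tr <- ds[seq_len(16), ]
  tcfg <- train_config(batch_size = 32, epochs = 400, seed = 2)
  mdl <- build_cnn(tiny_cnn(), 499, seed = 2)
  mdl <- train_cnn(mdl, tr, tcfg)
  expect_lt(tail(mdl$history$loss, 1), 0.05)
  expect_lt(tail(mdl$history$loss, 1), mdl$history$loss[1])
})

test_that("training is deterministic and the loss trend decreases", {
  ds <- tiny_dataset(n_subjects = 6, pairs_per_snr = 1, seed = 22)
  tcfg <- tiny_train(epochs = 6, seed = 9)
  m1 <- train_cnn(build_cnn(tiny_cnn(), 499, seed = 9), ds, tcfg)
  m2 <- train_cnn(build_cnn(tiny_cnn(), 499, seed = 9), ds, tcfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])

  seg <- ds$corrupted[[1]]
  expect_identical(predict_amsa(m1, seg), predict_amsa(m1, seg))
  expect_error(train_cnn(m1, ds[0, ], tcfg), "empty")
})

test_that("predictions ignore a constant offset of the raw segment", {
  ds <- tiny_dataset(n_subjects = 6, pairs_per_snr = 1, seed = 23)
  mdl <- train_cnn(build_cnn(tiny_cnn(), 499, seed = 4), ds,
                   tiny_train(epochs = 2, seed = 4))
  seg <- ds$corrupted[[1]]
  shifted <- ecg_segment(seg$samples + 0.8, fs = seg$fs)
  # differencing removes DC exactly; the causal high-pass adds only a
  # decaying transient
  x1 <- difference_transform(seg, hp = FALSE)
  x2 <- difference_transform(shifted, hp = FALSE)
  expect_equal(x1$ch1, x2$ch1, tolerance = 1e-12)
  expect_equal(x1$ch2, x2$ch2, tolerance = 1e-12)
  p1 <- predict_amsa(mdl, x1)
  p2 <- predict_amsa(mdl, x2)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("length mismatches are rejected at prediction time", {
  mdl <- build_cnn(tiny_cnn(), 499, seed = 1)
  short <- generate_vf(4, seed = 1, fs = 125)
  expect_error(predict_amsa(mdl, short), "does not match")
})

test_that("glance and tidy expose architecture and history", {
  mdl <- build_cnn(cnn_config(), 499, seed = 1)
  g <- glance(mdl)
  expect_equal(g$kernel_width, 11)
  expect_false(g$trained)
  expect_s3_class(tidy(mdl), "tbl_df")
})
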