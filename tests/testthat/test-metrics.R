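test_that("error metrics match hand-worked values", {
  m <- compute_metrics(c(2, 2, 2), c(1, 2, 3))
  expect_equal(m$mae, 2 / 3, tolerance = 1e-4)
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(m$prd, 100 * sqrt(2 / 14), tolerance = 1e-3)

  ident <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$prd, 0)

  dbl <- compute_metrics(2 * (1:10), 1:10)
  expect_equal(dbl$spearman_r, 1)
  expect_equal(dbl$prd, 100)

  expect_error(compute_metrics(1:3, 1:4), "equal")
  expect_error(compute_metrics(1:3, c(0, 0, 0)), "PRD")
})

test_that("MAE <= RMSE and PRD is scale invariant", {
  set.seed(6)
  for (i in 1:20) {
    y <- runif(50, 1, 20)
    yh <- y + rnorm(50, sd = 3)
    m <- compute_metrics(yh, y)
    expect_lte(m$mae, m$rmse + 1e-12)
    m2 <- compute_metrics(7 * yh, 7 * y)
    expect_equal(m2$prd, m$prd, tolerance = 1e-9)
  }
})

test_that("Bland-Altman bias and limits are correct", {
  ba <- bland_altman(c(2, 3, 4) + 1, c(2, 3, 4))
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_low, 1)
  expect_equal(ba$loa_high, 1)

  ba2 <- bland_altman(c(0, 2, 4), c(1, 2, 3))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_high, 1.96)
  expect_equal(ba2$loa_low, -1.96)

  ba3 <- bland_altman(c(1, 2, 3), c(0, 2, 4))
  expect_equal(ba3$bias, -ba2$bias)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("AUC matches worked examples and the brute-force count", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)

  brute_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(12)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    s <- round(rnorm(n), 1) # coarse scores force ties
    l <- rbinom(n, 1, 0.4)
    if (sum(l) == 0 || sum(l) == n) next
    expect_equal(roc_auc(s, l)$auc, brute_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both")
})

test_that("AUC is invariant under monotone transforms of the scores", {
  set.seed(13)
  s <- rexp(100)
  l <- rbinom(100, 1, plogis(s - 1))
  a0 <- roc_auc(s, l)$auc
  expect_equal(roc_auc(log(s), l)$auc, a0)
  expect_equal(roc_auc(s^3, l)$auc, a0)
})

test_that("paired AUC comparison agrees with the reference implementation", {
  set.seed(14)
  n <- 150
  x <- rnorm(n)
  l <- rbinom(n, 1, plogis(1.5 * x))
  s1 <- x + rnorm(n, sd = 0.5)
  s2 <- x + rnorm(n, sd = 1.5)
  r1 <- roc_auc(s1, l)
  r2 <- roc_auc(s2, l)
  cmp <- compare_auc(r1, r2)
  ref <- pROC::roc.test(pROC::roc(l, s1, quiet = TRUE),
                        pROC::roc(l, s2, quiet = TRUE), method = "delong",
                        paired = TRUE)
  expect_equal(cmp$p_value, as.numeric(ref$p.value), tolerance = 1e-6)
  expect_equal(r1$auc, as.numeric(pROC::auc(pROC::roc(l, s1, quiet = TRUE))),
               tolerance = 1e-12)

  self <- compare_auc(r1, r1)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)

  hm <- compare_auc(r1, r2, method = "hanley_mcneil")
  expect_true(hm$p_value >= 0 && hm$p_value <= 1)
})
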