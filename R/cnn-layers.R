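# Internal layer mechanics of the 1-D CNN regressor.
#
# Feature maps are channel-major matrices: C x (L*B), columns running
# position-fastest within each sample. Convolutions execute in compiled
# code (src/conv1d.cpp) as one BLAS GEMM per kernel shift; batch norm,
# pooling, dropout and the fully connected head are vectorized R.

bn_eps <- 1e-5

bn_forward <- function(Y, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1) {
  if (train) {
    f <- bn_fwd(Y, gamma, beta, bn_eps)
    run_mean <- (1 - momentum) * run_mean + momentum * as.numeric(f$mean)
    run_var <- (1 - momentum) * run_var + momentum * as.numeric(f$var)
    list(out = f$out, xhat = f$xhat, inv = as.numeric(f$inv),
         run_mean = run_mean, run_var = run_var)
  } else {
    inv <- 1 / sqrt(run_var + bn_eps)
    xhat <- (Y - run_mean) * inv
    list(out = gamma * xhat + beta, xhat = xhat, inv = inv,
         run_mean = run_mean, run_var = run_var)
  }
}

bn_backward <- function(dout, cache, gamma) {
  bn_bwd(dout, cache$xhat, cache$inv, gamma)
}

lrelu_forward <- function(Y, slope) {
  list(out = lrelu_fwd(Y, slope))
}

lrelu_backward <- function(dout, cache, slope) {
  lrelu_bwd(dout, cache$out, slope)
}

maxpool2_forward <- function(X, L, B) {
  out <- maxpool2_fwd(X, L, B)
  out$Lout <- ceiling(L / 2)
  out$L <- L
  out$B <- B
  out$C <- nrow(X)
  out
}

maxpool2_backward <- function(dout, cache) {
  maxpool2_bwd(dout, cache$arg, cache$C, cache$L, cache$B)
}

gmaxpool_forward <- function(X, L, B) {
  C <- nrow(X)
  Z <- matrix(0, C, B)
  arg <- matrix(0L, C, B)
  for (b in seq_len(B)) {
    block <- X[, ((b - 1) * L + 1):(b * L), drop = FALSE]
    j <- max.col(block, ties.method = "first")
    Z[, b] <- block[cbind(seq_len(C), j)]
    arg[, b] <- j + (b - 1L) * L
  }
  list(out = Z, arg = arg, L = L, B = B, C = C)
}

gmaxpool_backward <- function(dZ, cache) {
  dX <- matrix(0, cache$C, cache$L * cache$B)
  lin <- (as.vector(cache$arg) - 1) * cache$C +
    rep(seq_len(cache$C), cache$B)
  dX[lin] <- as.vector(dZ)
  dX
}

# lengths of the feature maps entering each of the N+1 conv blocks
block_lengths <- function(input_length, n_pooled) {
  Ls <- integer(n_pooled + 1)
  Ls[1] <- input_length
  for (j in seq_len(n_pooled)) Ls[j + 1] <- ceiling(Ls[j] / 2)
  Ls
}

init_cnn_params <- function(cfg, input_length) {
  W <- cfg$kernel_width
  N <- cfg$n_pooled_blocks
  C <- cfg$channels
  cins <- c(2, rep(C, N))
  p <- list()
  for (j in seq_len(N + 1)) {
    cin <- cins[j]
    # Xavier-normal fan based on the receptive field
    sd <- sqrt(2 / (cin * W + C * W))
    p[[paste0("K", j)]] <- array(stats::rnorm(cin * C * W, 0, sd),
                                 dim = c(cin, C, W))
    p[[paste0("g", j)]] <- rep(1, C)
    p[[paste0("be", j)]] <- rep(0, C)
  }
  sizes <- c(C, cfg$fc_sizes)
  lo <- cfg$init_range[1]
  hi <- cfg$init_range[2]
  for (m in seq_along(cfg$fc_sizes)) {
    p[[paste0("W", m)]] <- matrix(stats::runif(sizes[m + 1] * sizes[m],
                                               lo, hi),
                                  sizes[m + 1], sizes[m])
    p[[paste0("b", m)]] <- rep(0, sizes[m + 1])
  }
  p
}

cnn_forward <- function(model, X, B, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  run <- model$running
  N <- cfg$n_pooled_blocks
  W <- cfg$kernel_width
  C <- cfg$channels
  slope <- cfg$leaky_slope
  Ls <- model$lengths
  caches <- list()
  cins <- c(2, rep(C, N))
  for (j in seq_len(N + 1)) {
    L <- Ls[j]
    conv <- conv1d_forward(X, p[[paste0("K", j)]], cins[j], C, W, L, B)
    bn <- bn_forward(conv, p[[paste0("g", j)]], p[[paste0("be", j)]],
                     run[[paste0("m", j)]], run[[paste0("v", j)]], train)
    run[[paste0("m", j)]] <- bn$run_mean
    run[[paste0("v", j)]] <- bn$run_var
    act <- lrelu_forward(bn$out, slope)
    if (j <= N) {
      pool <- maxpool2_forward(act$out, L, B)
    } else {
      pool <- gmaxpool_forward(act$out, L, B)
    }
    caches[[j]] <- list(Xin = X, bn = bn, act = act, pool = pool, L = L)
    X <- pool$out
  }
  Z <- X # C x B pooled features
  drop_mask <- NULL
  if (train && cfg$dropout > 0) {
    drop_mask <- matrix(
      (stats::runif(length(Z)) >= cfg$dropout) / (1 - cfg$dropout),
      nrow(Z), ncol(Z))
    Z <- Z * drop_mask
  }
  fc_caches <- list()
  A <- Z
  nf <- length(cfg$fc_sizes)
  for (m in seq_len(nf)) {
    pre <- p[[paste0("W", m)]] %*% A + p[[paste0("b", m)]]
    if (m < nf) {
      aout <- lrelu_fwd(pre, slope)
      fc_caches[[m]] <- list(Ain = A, Aout = aout)
      A <- aout
    } else {
      fc_caches[[m]] <- list(Ain = A, Aout = NULL)
      A <- pre
    }
  }
  list(pred = as.numeric(A), caches = caches, fc_caches = fc_caches,
       drop_mask = drop_mask, running = run, Z = Z)
}

cnn_backward <- function(model, fwd, dpred, B) {
  cfg <- model$cfg
  p <- model$params
  N <- cfg$n_pooled_blocks
  W <- cfg$kernel_width
  C <- cfg$channels
  slope <- cfg$leaky_slope
  cins <- c(2, rep(C, N))
  g <- list()
  nf <- length(cfg$fc_sizes)
  dA <- matrix(dpred, 1, B)
  for (m in rev(seq_len(nf))) {
    cache <- fwd$fc_caches[[m]]
    if (m < nf) dA <- lrelu_bwd(dA, cache$Aout, slope)
    g[[paste0("W", m)]] <- dA %*% t(cache$Ain)
    g[[paste0("b", m)]] <- rowSums(dA)
    dA <- t(p[[paste0("W", m)]]) %*% dA
  }
  dZ <- dA
  if (!is.null(fwd$drop_mask)) dZ <- dZ * fwd$drop_mask
  dX <- dZ
  for (j in rev(seq_len(N + 1))) {
    cache <- fwd$caches[[j]]
    dact <- if (j <= N) maxpool2_backward(dX, cache$pool) else
      gmaxpool_backward(dX, cache$pool)
    dbn_out <- lrelu_backward(dact, cache$act, slope)
    bb <- bn_backward(dbn_out, cache$bn, p[[paste0("g", j)]])
    g[[paste0("g", j)]] <- bb$dgamma
    g[[paste0("be", j)]] <- bb$dbeta
    cv <- conv1d_backward(cache$Xin, p[[paste0("K", j)]], bb$dY, cins[j],
                          C, W, cache$L, B)
    g[[paste0("K", j)]] <- cv$dK
    dX <- cv$dX
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gI <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gI
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gI^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
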