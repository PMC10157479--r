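#' CNN architecture configuration
#'
#' The regressor stacks `N` feature-extraction blocks of
#' convolution (width `W`, `C` channels, stride 1, same padding) -> batch
#' norm -> leaky ReLU -> max-pool (kernel 2, stride 2), one further block
#' whose pooling is a global max-pool followed by dropout, and a fully
#' connected head ending in a single linear regression output. The feature
#' length after pooled block `n` is `ceiling(len / 2^n)`.
#'
#' @param kernel_width Convolution kernel width `W` (odd, 3-11; default 11).
#' @param n_pooled_blocks Number of pooled blocks `N` (1-7; default 5).
#' @param channels Channels `C` per block (4, 8, 16, 32 or 64; default 32).
#' @param leaky_slope Negative-side slope of the leaky ReLU (default 0.01).
#' @param dropout Dropout probability after the global pool (default 0.2;
#'   with only `C` pooled features feeding a nonlinear regression head,
#'   heavier dropout leaves a train/eval calibration gap that compresses
#'   the predicted AMSA scale).
#' @param fc_sizes Fully connected layer widths (default `c(64, 32, 1)`;
#'   the final width must be 1).
#' @param init_range Uniform initialization range of the fully connected
#'   weights (default `c(-0.1, 0.1)`); convolution kernels use
#'   Xavier-normal initialization.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(kernel_width = 11, n_pooled_blocks = 5,
                       channels = 32, leaky_slope = 0.01, dropout = 0.2,
                       fc_sizes = c(64, 32, 1),
                       init_range = c(-0.1, 0.1)) {
  if (kernel_width %% 2 != 1 || kernel_width < 3 || kernel_width > 11) {
    stop("`kernel_width` must be odd and within 3..11", call. = FALSE)
  }
  if (n_pooled_blocks < 1 || n_pooled_blocks > 7) {
    stop("`n_pooled_blocks` must lie in 1..7", call. = FALSE)
  }
  if (!channels %in% c(4, 8, 16, 32, 64)) {
    stop("`channels` must be one of 4, 8, 16, 32, 64", call. = FALSE)
  }
  if (utils::tail(fc_sizes, 1) != 1) {
    stop("the last fully connected layer must have width 1", call. = FALSE)
  }
  structure(list(kernel_width = kernel_width,
                 n_pooled_blocks = n_pooled_blocks, channels = channels,
                 leaky_slope = leaky_slope, dropout = dropout,
                 fc_sizes = fc_sizes, init_range = init_range),
            class = "cnn_config")
}

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: Adam with default moments and a
#' learning rate of 1e-3, mean squared error loss, mini-batches of 1024,
#' 50 epochs, Xavier-normal convolution kernels and fully connected weights
#' drawn uniformly from \[-0.1, 0.1\]. For desk-scale experiments (unit
#' tests, small synthetic studies) a batch of 256 and 30 epochs are the
#' package's reduced protocol; pass them explicitly.
#'
#' @param lr Learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 1024).
#' @param epochs Training epochs (default 50).
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout (default 1).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, batch_size = 1024, epochs = 50,
                         seed = 1) {
  if (lr <= 0 || batch_size < 1 || epochs < 1) {
    stop("lr, batch_size and epochs must be positive", call. = FALSE)
  }
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = "adam",
                 loss = "mse", seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) CNN AMSA regressor
#'
#' @param cfg A [cnn_config()].
#' @param input_length Length of each input channel (499 for 4-s segments
#'   at 250 Hz after [difference_transform()]); must be at least
#'   `2^n_pooled_blocks`.
#' @param seed Integer seed for weight initialization.
#' @return An `amsa_cnn` model object.
#' @export
build_cnn <- function(cfg = cnn_config(), input_length = 499, seed = 1) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (input_length < 2^cfg$n_pooled_blocks) {
    stop(sprintf("input length %d too short for %d pooled blocks",
                 input_length, cfg$n_pooled_blocks), call. = FALSE)
  }
  set.seed(seed)
  params <- init_cnn_params(cfg, input_length)
  C <- cfg$channels
  running <- list()
  for (j in seq_len(cfg$n_pooled_blocks + 1)) {
    running[[paste0("m", j)]] <- rep(0, C)
    running[[paste0("v", j)]] <- rep(1, C)
  }
  structure(list(cfg = cfg, input_length = input_length, params = params,
                 running = running,
                 lengths = block_lengths(input_length,
                                         cfg$n_pooled_blocks),
                 history = tibble::tibble(epoch = integer(0),
                                          loss = numeric(0)),
                 trained = FALSE),
            class = "amsa_cnn")
}

#' @export
print.amsa_cnn <- function(x, ...) {
  cat(sprintf(
    "<amsa_cnn> W=%d N=%d C=%d, input %d, %s (%d parameters)\n",
    x$cfg$kernel_width, x$cfg$n_pooled_blocks, x$cfg$channels,
    x$input_length, if (x$trained) "trained" else "untrained",
    n_parameters(x)))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# stack segment pairs into the channel-major input matrix + labels
assemble_training_matrix <- function(pairs, augment, spectral_cfg) {
  inputs <- list()
  labels <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    lab <- pairs$amsa_true[i]
    for (seg in list(pairs$corrupted[[i]], pairs$uncorrupted[[i]])) {
      x <- difference_transform(seg, hp = TRUE, cfg = spectral_cfg)
      inputs[[length(inputs) + 1]] <- x
      labels <- c(labels, lab)
      if (augment) {
        for (v in augment_variants(x)) {
          inputs[[length(inputs) + 1]] <- v
          labels <- c(labels, lab)
        }
      }
    }
  }
  Lc <- length(inputs[[1]])
  X <- matrix(0, 2, Lc * length(inputs))
  for (s in seq_along(inputs)) {
    X[1, ((s - 1) * Lc + 1):(s * Lc)] <- inputs[[s]]$ch1
    X[2, ((s - 1) * Lc + 1):(s * Lc)] <- inputs[[s]]$ch2
  }
  list(X = X, y = labels, Lc = Lc)
}

#' Train the CNN regressor on segment pairs
#'
#' Both members of every pair enter training with the pair's shared label
#' (the FFT AMSA of the uncorrupted member). Optimization is mini-batch
#' Adam on the mean squared error; with `augment = TRUE` the seven
#' symmetry variants of each input are added up front, multiplying the
#' training data by eight.
#'
#' @param model An `amsa_cnn` from [build_cnn()], or `NULL` to build one
#'   with default architecture for the data's input length.
#' @param pairs Tibble of segment pairs (columns `corrupted`,
#'   `uncorrupted`, `amsa_true`), e.g. from [build_dataset()].
#' @param tcfg A [train_config()].
#' @param augment Add the 7 augmentation variants (default `FALSE`).
#' @param spectral_cfg A [spectral_config()] for the input transform.
#' @param quiet Suppress per-epoch progress (default `TRUE`).
#' @return The trained `amsa_cnn`, with per-epoch loss in `$history`.
#' @export
train_cnn <- function(model = NULL, pairs, tcfg = train_config(),
                      augment = FALSE, spectral_cfg = spectral_config(),
                      quiet = TRUE) {
  if (nrow(pairs) == 0) stop("empty training set", call. = FALSE)
  dat <- assemble_training_matrix(pairs, augment, spectral_cfg)
  if (is.null(model)) model <- build_cnn(cnn_config(), dat$Lc,
                                         seed = tcfg$seed)
  stopifnot(inherits(model, "amsa_cnn"))
  if (dat$Lc != model$input_length) {
    stop(sprintf("pairs produce inputs of length %d but the model expects %d",
                 dat$Lc, model$input_length), call. = FALSE)
  }
  set.seed(tcfg$seed + 1L)
  n <- length(dat$y)
  Lc <- dat$Lc
  state <- adam_init(model$params)
  hist <- numeric(tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1, n)]
      B <- length(idx)
      cols <- as.vector(outer(seq_len(Lc), (idx - 1) * Lc, "+"))
      Xb <- dat$X[, cols, drop = FALSE]
      yb <- dat$y[idx]
      fwd <- cnn_forward(model, Xb, B, train = TRUE)
      model$running <- fwd$running
      err <- fwd$pred - yb
      losses <- c(losses, mean(err^2))
      grads <- cnn_backward(model, fwd, 2 * err / B, B)
      upd <- adam_step(model$params, grads, state, tcfg$lr)
      model$params <- upd$params
      state <- upd$state
    }
    hist[ep] <- mean(losses)
    if (!quiet) message(sprintf("epoch %3d  mse %.4f", ep, hist[ep]))
  }
  model$history <- tibble::tibble(epoch = seq_len(tcfg$epochs),
                                  loss = hist)
  model$trained <- TRUE
  model$train_cfg <- tcfg
  model
}

#' Predict AMSA for segments
#'
#' Applies the input transform and a forward pass in evaluation mode
#' (batch-norm running statistics, no dropout); outputs are clipped at 0.
#'
#' @param model A trained `amsa_cnn`.
#' @param segments An [ecg_segment], a `two_channel_input`, or a list of
#'   either.
#' @param spectral_cfg A [spectral_config()] for the input transform.
#' @param batch_size Forward-pass batch size (default 512).
#' @return Numeric vector of AMSA estimates in mV Hz.
#' @export
predict_amsa <- function(model, segments,
                         spectral_cfg = spectral_config(),
                         batch_size = 512) {
  stopifnot(inherits(model, "amsa_cnn"))
  if (is_ecg_segment(segments) || inherits(segments, "two_channel_input")) {
    segments <- list(segments)
  }
  inputs <- lapply(segments, function(s) {
    if (is_ecg_segment(s)) s <- difference_transform(s, hp = TRUE,
                                                     cfg = spectral_cfg)
    if (!inherits(s, "two_channel_input")) {
      stop("inputs must be ecg_segment or two_channel_input", call. = FALSE)
    }
    if (length(s) != model$input_length) {
      stop(sprintf("input of length %d does not match model input %d",
                   length(s), model$input_length), call. = FALSE)
    }
    s
  })
  Lc <- model$input_length
  n <- length(inputs)
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    B <- length(idx)
    Xb <- matrix(0, 2, Lc * B)
    for (k in seq_along(idx)) {
      s <- inputs[[idx[k]]]
      Xb[1, ((k - 1) * Lc + 1):(k * Lc)] <- s$ch1
      Xb[2, ((k - 1) * Lc + 1):(k * Lc)] <- s$ch2
    }
    fwd <- cnn_forward(model, Xb, B, train = FALSE)
    out[idx] <- pmax(fwd$pred, 0)
  }
  out
}

#' @export
predict.amsa_cnn <- function(object, newdata, ...) {
  predict_amsa(object, newdata, ...)
}

#' Subject-grouped k-fold cross-validation
#'
#' Partitions subjects (never individual pairs) into `k` folds, trains on
#' `k - 1` folds and evaluates on the held-out fold, returning the
#' per-fold metric bundle; overall performance is the fold average.
#'
#' @param pairs Segment-pair tibble with a `subject_id` column.
#' @param cfg A [cnn_config()].
#' @param tcfg A [train_config()].
#' @param k Number of folds (default 5).
#' @param augment Forwarded to [train_cnn()].
#' @param spectral_cfg A [spectral_config()].
#' @return Tibble with one row per fold: `fold`, `n_subjects`, `mae`,
#'   `rmse`, `prd`, `spearman_r`, `n`.
#' @export
cross_validate <- function(pairs, cfg = cnn_config(),
                           tcfg = train_config(), k = 5, augment = FALSE,
                           spectral_cfg = spectral_config()) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  subjects <- unique(pairs$subject_id)
  if (length(subjects) < k) {
    stop(sprintf("need at least %d subjects for %d folds", k, k),
         call. = FALSE)
  }
  set.seed(tcfg$seed)
  fold_of <- sample(rep(seq_len(k), length.out = length(subjects)))
  names(fold_of) <- subjects
  out <- vector("list", k)
  for (f in seq_len(k)) {
    va_subj <- subjects[fold_of == f]
    tr <- pairs[!pairs$subject_id %in% va_subj, ]
    va <- pairs[pairs$subject_id %in% va_subj, ]
    mdl <- build_cnn(cfg, segment_input_length(va), seed = tcfg$seed + f)
    mdl <- train_cnn(mdl, tr, tcfg, augment = augment,
                     spectral_cfg = spectral_cfg)
    est <- predict_amsa(mdl, va$corrupted, spectral_cfg = spectral_cfg)
    met <- compute_metrics(est, va$amsa_true)
    out[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_subjects = length(va_subj)), met)
  }
  dplyr::bind_rows(out)
}

segment_input_length <- function(pairs) {
  floor(length(pairs$corrupted[[1]]$samples) / 2) - 1
}

#' Hyperparameter grid search
#'
#' Exhaustively evaluates architecture combinations on a subject-grouped
#' 80/20 holdout (or full cross-validation), ranks by validation MAE and
#' breaks ties toward the smaller parameter count. Combinations invalid
#' for the input length are skipped with a warning.
#'
#' @param pairs Segment-pair tibble.
#' @param grid Data frame with columns `W`, `N`, `C` (defaults to the full
#'   reference grid: W in 3..11 step 2, N in 1..7, C in 4..64 powers of 2).
#' @param tcfg A [train_config()].
#' @param method `"holdout"` (default) or `"cv"`.
#' @param k Folds for `method = "cv"`.
#' @param spectral_cfg A [spectral_config()].
#' @return List with `best` (a [cnn_config()]) and `table` (tibble of all
#'   evaluated combinations with `mae` and `n_parameters`).
#' @export
grid_search <- function(pairs,
                        grid = expand.grid(W = seq(3, 11, 2), N = 1:7,
                                           C = c(4, 8, 16, 32, 64)),
                        tcfg = train_config(), method = c("holdout", "cv"),
                        k = 5, spectral_cfg = spectral_config()) {
  method <- match.arg(method)
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  input_len <- segment_input_length(pairs)
  subjects <- unique(pairs$subject_id)
  set.seed(tcfg$seed)
  va_subj <- sample(subjects, max(1, round(0.2 * length(subjects))))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    W <- grid$W[i]; N <- grid$N[i]; C <- grid$C[i]
    cfg <- tryCatch(cnn_config(kernel_width = W, n_pooled_blocks = N,
                               channels = C),
                    error = function(e) NULL)
    if (is.null(cfg) || input_len < 2^N) {
      warning(sprintf("skipping invalid combination W=%d N=%d C=%d", W, N,
                      C), call. = FALSE)
      rows[[i]] <- tibble::tibble(W = W, N = N, C = C, mae = NA_real_,
                                  n_parameters = NA_integer_)
      next
    }
    if (method == "cv") {
      cvt <- cross_validate(pairs, cfg, tcfg, k = k,
                            spectral_cfg = spectral_cfg)
      mae <- mean(cvt$mae)
      mdl <- build_cnn(cfg, input_len)
    } else {
      tr <- pairs[!pairs$subject_id %in% va_subj, ]
      va <- pairs[pairs$subject_id %in% va_subj, ]
      mdl <- build_cnn(cfg, input_len, seed = tcfg$seed)
      mdl <- train_cnn(mdl, tr, tcfg, spectral_cfg = spectral_cfg)
      est <- predict_amsa(mdl, va$corrupted, spectral_cfg = spectral_cfg)
      mae <- compute_metrics(est, va$amsa_true)$mae
    }
    rows[[i]] <- tibble::tibble(W = W, N = N, C = C, mae = mae,
                                n_parameters = n_parameters(mdl))
  }
  table <- dplyr::bind_rows(rows)
  ok <- table[!is.na(table$mae), ]
  ok <- ok[order(ok$mae, ok$n_parameters), ]
  best <- cnn_config(kernel_width = ok$W[1], n_pooled_blocks = ok$N[1],
                     channels = ok$C[1])
  list(best = best, table = table)
}

#' @export
tidy.amsa_cnn <- function(x, ...) x$history

#' @export
glance.amsa_cnn <- function(x, ...) {
  tibble::tibble(
    kernel_width = x$cfg$kernel_width,
    n_pooled_blocks = x$cfg$n_pooled_blocks,
    channels = x$cfg$channels,
    n_parameters = n_parameters(x),
    trained = x$trained,
    final_loss = if (nrow(x$history)) utils::tail(x$history$loss, 1)
                 else NA_real_
  )
}
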