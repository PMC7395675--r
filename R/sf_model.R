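# The 768 -> 52 regression models: a small 1D convolutional network
# (conv 32 -> conv 64, kernel 3, valid padding, stride 1, no pooling; dense
# 54 -> 52; ReLU on hidden layers, linear output) trained with Adam on mean
# squared error, and an ordinary-least-squares baseline on the same inputs
# and outputs.
#
# The network is implemented directly on BLAS matrix products via an im2col
# formulation: a batch of profiles (n x 768) becomes, for each conv layer, a
# (n*L_out) x (k*C_in) patch matrix multiplied by a (k*C_in) x C_out kernel
# matrix. Row index of every intermediate is (sample, position) in
# column-major order, which makes the flatten before the dense layers a free
# `dim<-` reshape (flattened feature q = position + (channel-1)*L_out).

#' CNN architecture description
#'
#' @param conv_channels Kernels per convolutional layer (default `c(32, 64)`).
#' @param kernel_size Convolution kernel length (odd; default 3).
#' @param fc_sizes Fully connected layer sizes (default `c(54, 52)`; the last
#'   is the output and uses a linear activation).
#' @param input_len Profile length (default 768).
#' @param input_scale Profiles are divided by this before entering the
#'   network (µm -> ~[0, 2.5]); stored with the model so predictions are
#'   scaling-aware.
#' @return Object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(conv_channels = c(32L, 64L), kernel_size = 3L,
                             fc_sizes = c(54L, 52L), input_len = 768L,
                             input_scale = 100) {
  stop_if_not(all(conv_channels > 0) && all(fc_sizes > 0) && input_len > 0,
              "layer sizes must be positive")
  stop_if_not(kernel_size %% 2 == 1, "kernel size must be odd")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 fc_sizes = as.integer(fc_sizes),
                 input_len = as.integer(input_len),
                 input_scale = input_scale),
            class = "cnn_architecture")
}

# Output length of each conv layer under valid padding, stride 1.
conv_out_lens <- function(arch) {
  l <- arch$input_len
  vapply(seq_along(arch$conv_channels), function(i) {
    l <<- l - arch$kernel_size + 1L
    l
  }, integer(1))
}

#' Build an untrained CNN with seeded Glorot-uniform weights
#'
#' Layer stack for the default architecture: conv(32, k=3) -> ReLU ->
#' conv(64, k=3) -> ReLU -> flatten -> dense(54) -> ReLU -> dense(52, linear).
#' Valid padding, stride 1, no pooling. Kernels are stored as
#' `(kernel_size * in_channels) x out_channels` matrices.
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `oct2vf_cnn` with elements `arch`, `weights`
#'   (list `W1`,`b1`,...), `history` (`NULL` until trained) and
#'   `selected_epoch`.
#' @export
build_cnn <- function(arch = cnn_architecture(), seed = 1L) {
  stop_if_not(inherits(arch, "cnn_architecture"), "arch must be a cnn_architecture")
  set.seed(seed)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  k <- arch$kernel_size
  ch <- c(1L, arch$conv_channels)
  w <- list()
  for (i in seq_along(arch$conv_channels)) {
    w[[paste0("W", i)]] <- glorot(k * ch[i], ch[i + 1])
    w[[paste0("b", i)]] <- rep(0, ch[i + 1])
  }
  lens <- conv_out_lens(arch)
  flat <- lens[length(lens)] * arch$conv_channels[length(arch$conv_channels)]
  sizes <- c(flat, arch$fc_sizes)
  off <- length(arch$conv_channels)
  for (j in seq_along(arch$fc_sizes)) {
    w[[paste0("W", off + j)]] <- glorot(sizes[j], sizes[j + 1])
    w[[paste0("b", off + j)]] <- rep(0, sizes[j + 1])
  }
  structure(list(arch = arch, weights = w, history = NULL,
                 selected_epoch = NA_integer_),
            class = "oct2vf_cnn")
}

#' Number of trainable parameters
#' @param model An `oct2vf_cnn`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, numeric(1)))
}

#' @export
print.oct2vf_cnn <- function(x, ...) {
  a <- x$arch
  cat(sprintf("1D CNN %d -> conv(%s, k=%d) -> dense(%s): %s parameters%s\n",
              a$input_len, paste(a$conv_channels, collapse = ","),
              a$kernel_size, paste(a$fc_sizes, collapse = ","),
              format(n_parameters(x), big.mark = ","),
              if (is.na(x$selected_epoch)) " (untrained)"
              else sprintf(", best epoch %d", x$selected_epoch)))
  invisible(x)
}

# Forward pass on an already-scaled batch x (n x input_len). keep = TRUE
# retains the intermediates needed by the backward pass. Conv biases are
# folded into the kernel matrix through the ones column of im2col_ones;
# ReLU is applied in place on unshared matmul results.
cnn_forward <- function(model, x, keep = FALSE) {
  w <- model$weights
  arch <- model$arch
  n <- nrow(x)
  k <- arch$kernel_size
  nconv <- length(arch$conv_channels)
  lens <- c(arch$input_len, conv_out_lens(arch))
  a <- x + 0  # unshare: reshaped and mutated below
  dim(a) <- c(n * arch$input_len, 1L)
  cache <- list(n = n)
  for (i in seq_len(nconv)) {
    m <- im2col_ones(a, n, lens[i], k)
    a <- relu_inplace(m %*% rbind(w[[paste0("b", i)]], w[[paste0("W", i)]]))
    if (keep) {
      cache[[paste0("M", i)]] <- m
      # the last conv activation is cached once, reshaped, as F1 below
      if (i < nconv) cache[[paste0("A", i)]] <- a
    }
  }
  flat <- lens[nconv + 1L] * arch$conv_channels[nconv]
  dim(a) <- c(n, flat)  # free reshape: feature q = position + (channel-1)*l
  nfc <- length(arch$fc_sizes)
  for (j in seq_len(nfc)) {
    if (keep) cache[[paste0("F", j)]] <- a
    z <- a %*% w[[paste0("W", nconv + j)]]
    z <- z + rep(w[[paste0("b", nconv + j)]], each = n)
    a <- if (j < nfc) relu_inplace(z) else z
    if (keep && j < nfc) cache[[paste0("H", j)]] <- a
  }
  if (keep) list(pred = a, cache = cache) else a
}

# Gradient of the batch MSE wrt every weight array; returns a list matching
# model$weights. The ones column of the cached patch matrices yields the conv
# bias gradients as the first row of crossprod.
cnn_backward <- function(model, cache, pred, y) {
  w <- model$weights
  arch <- model$arch
  n <- cache$n
  k <- arch$kernel_size
  nconv <- length(arch$conv_channels)
  nfc <- length(arch$fc_sizes)
  lens <- c(arch$input_len, conv_out_lens(arch))
  g <- list()
  d <- (pred - y) * (2 / length(y))
  for (j in rev(seq_len(nfc))) {
    if (j < nfc) d <- relu_backward_inplace(d, cache[[paste0("H", j)]])
    wi <- paste0("W", nconv + j)
    g[[wi]] <- crossprod(cache[[paste0("F", j)]], d)
    g[[paste0("b", nconv + j)]] <- colSums(d)
    d <- d %*% t(w[[wi]])
  }
  # d is n x flat == elementwise view of the last conv activation
  dim(d) <- c(n * lens[nconv + 1L], arch$conv_channels[nconv])
  for (i in rev(seq_len(nconv))) {
    # the last conv activation lives in the cache as F1 (reshaped view)
    mask <- if (i == nconv) cache$F1 else cache[[paste0("A", i)]]
    d <- relu_backward_inplace(d, mask)
    gb <- crossprod(cache[[paste0("M", i)]], d)
    g[[paste0("b", i)]] <- gb[1L, ]
    g[[paste0("W", i)]] <- gb[-1L, , drop = FALSE]
    if (i > 1L) {
      dm <- d %*% t(w[[paste0("W", i)]])         # (n*l_out) x (k*c_in)
      d <- conv_input_grad(dm, n, lens[i], k, arch$conv_channels[i - 1L])
    }
  }
  g
}

#' Training protocol configuration
#'
#' Mirrors the development protocol: minibatch gradient descent with the Adam
#' optimizer (beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7), learning rate
#' 1e-3, mean-squared-error loss, and checkpointing of the epoch with the
#' lowest validation MSE.
#'
#' @param epochs Number of epochs (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 128).
#' @param seed Seed for shuffling.
#' @export
training_config <- function(epochs = 100L, learning_rate = 1e-3,
                            batch_size = 128L, seed = 1L) {
  stop_if_not(epochs >= 1, "epochs must be >= 1")
  stop_if_not(learning_rate > 0, "learning rate must be positive")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_config")
}

as_xy <- function(data) {
  if (inherits(data, "paired_cohort")) {
    list(x = data$rnfl, y = data$vf, patient_id = data$exams$patient_id)
  } else {
    stop_if_not(is.list(data) && !is.null(data$x) && !is.null(data$y),
                "data must be a paired_cohort or list(x, y, patient_id)")
    data
  }
}

#' Train the CNN
#'
#' Runs the full protocol: every epoch shuffles the training exams, sweeps
#' minibatches with Adam on the MSE loss, then records train and validation
#' MSE; after the final epoch the weights of the epoch with the lowest
#' validation MSE are restored. The full 768-point profile feeds every output
#' — no topographic priors are imposed, so any structure-function
#' correspondence in the trained weights is learned from the data alone.
#'
#' @param model An untrained (or previously trained) `oct2vf_cnn`.
#' @param train,val `paired_cohort` objects or lists `x` (n x 768 µm), `y`
#'   (n x 52 dB), `patient_id`. Patient ids, when present in both, must be
#'   disjoint.
#' @param config A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return The model with `weights` from the best epoch, `history` (data frame
#'   `epoch`, `train_mse`, `val_mse`) and `selected_epoch`.
#' @export
train_cnn <- function(model, train, val, config = training_config(),
                      verbose = FALSE) {
  stop_if_not(inherits(model, "oct2vf_cnn"), "model must be an oct2vf_cnn")
  tr <- as_xy(train); va <- as_xy(val)
  stop_if_not(nrow(tr$x) > 0 && nrow(va$x) > 0,
              "train and validation sets must be non-empty")
  if (!is.null(tr$patient_id) && !is.null(va$patient_id)) {
    stop_if_not(length(intersect(tr$patient_id, va$patient_id)) == 0,
                "train and validation sets share patients")
  }
  sc <- model$arch$input_scale
  x <- tr$x / sc; y <- tr$y
  xv <- va$x / sc; yv <- va$y
  n <- nrow(x)
  set.seed(config$seed)

  # deep copies: the Adam step mutates in place and must never touch the
  # caller's model or a recorded checkpoint
  deep_copy <- function(ws) lapply(ws, function(p) p + 0)
  w <- deep_copy(model$weights)
  m_t <- lapply(w, function(p) p * 0)
  v_t <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  step <- 0L
  best <- list(mse = Inf, weights = model$weights, epoch = NA_integer_)
  hist <- data.frame(epoch = integer(), train_mse = numeric(),
                     val_mse = numeric())
  mdl <- model
  mdl$weights <- w

  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    sse <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n)]
      fw <- cnn_forward(mdl, x[bi, , drop = FALSE], keep = TRUE)
      err <- fw$pred - y[bi, , drop = FALSE]
      sse <- sse + sum(err * err)
      g <- cnn_backward(mdl, fw$cache, fw$pred, y[bi, , drop = FALSE])
      step <- step + 1L
      lr_t <- config$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(w)) {
        adam_step_inplace(w[[nm]], m_t[[nm]], v_t[[nm]], g[[nm]],
                          lr_t, b1, b2, eps)
      }
    }
    train_mse <- sse / (n * ncol(y))
    val_mse <- chunked_mse(mdl, xv, yv)
    hist <- rbind(hist, data.frame(epoch = ep, train_mse = train_mse,
                                   val_mse = val_mse))
    if (val_mse < best$mse)
      best <- list(mse = val_mse, weights = deep_copy(w), epoch = ep)
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %.4f%s", ep,
                      train_mse, val_mse,
                      if (best$epoch == ep) "  *" else ""))
    }
  }
  mdl$weights <- best$weights
  mdl$history <- hist
  mdl$selected_epoch <- best$epoch
  mdl
}

chunked_mse <- function(model, x_scaled, y, chunk = 256L) {
  sse <- 0
  for (s in seq(1L, nrow(x_scaled), by = chunk)) {
    i <- s:min(s + chunk - 1L, nrow(x_scaled))
    p <- cnn_forward(model, x_scaled[i, , drop = FALSE])
    sse <- sse + sum((p - y[i, , drop = FALSE])^2)
  }
  sse / length(y)
}

#' Predict visual-field thresholds from RNFL profiles
#'
#' Applies the model's stored input scaling and runs the forward pass in
#' chunks. Raw outputs are returned unclamped; report rendering clamps for
#' display.
#'
#' @param object An `oct2vf_cnn`.
#' @param newdata A 768-vector or n x 768 matrix of thickness (µm).
#' @param ... Unused.
#' @return n x 52 matrix (or 52-vector) of predicted thresholds in dB.
#' @export
predict.oct2vf_cnn <- function(object, newdata, ...) {
  one <- !is.matrix(newdata)
  x <- if (one) matrix(newdata, nrow = 1) else newdata
  stop_if_not(ncol(x) == object$arch$input_len,
              "profiles must have %d samples", object$arch$input_len)
  x <- x / object$arch$input_scale
  out <- do.call(rbind, lapply(seq(1L, nrow(x), by = 256L), function(s) {
    i <- s:min(s + 255L, nrow(x))
    cnn_forward(object, x[i, , drop = FALSE])
  }))
  if (one) drop(out) else out
}

# ---- Model serialization ----------------------------------------------------

#' Save / load a trained CNN as plain text
#'
#' The architecture, training history and selected epoch go to a JSON sidecar;
#' the weight arrays to one CSV per array.
#'
#' @param model An `oct2vf_cnn`.
#' @param dir Directory.
#' @export
write_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(arch = unclass(model$arch), selected_epoch = model$selected_epoch,
         weight_names = names(model$weights)),
    file.path(dir, "architecture.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(model$history))
    write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  for (nm in names(model$weights)) {
    p <- model$weights[[nm]]
    if (!is.matrix(p)) p <- matrix(p, nrow = 1)
    write.csv(p, file.path(dir, paste0("weights_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  arch <- do.call(cnn_architecture, meta$arch[c("conv_channels", "kernel_size",
                                                "fc_sizes", "input_len",
                                                "input_scale")])
  w <- list()
  for (nm in meta$weight_names) {
    p <- as.matrix(read.csv(file.path(dir, paste0("weights_", nm, ".csv"))))
    dimnames(p) <- NULL
    if (startsWith(nm, "b")) p <- drop(p)
    w[[nm]] <- p
  }
  hist_path <- file.path(dir, "history.csv")
  structure(list(arch = arch, weights = w,
                 history = if (file.exists(hist_path)) read.csv(hist_path),
                 selected_epoch = meta$selected_epoch %||% NA_integer_),
            class = "oct2vf_cnn")
}

# ---- Linear baseline --------------------------------------------------------

#' Ordinary-least-squares baseline on the same inputs and outputs
#'
#' One least-squares fit per visual-field point, all 768 thickness samples as
#' predictors plus an intercept. With fewer training exams than predictors the
#' fit falls back to ridge regression (small penalty) with a warning;
#' rank-deficient (e.g. constant) columns get zero coefficients, logged.
#'
#' @param train A `paired_cohort` or list `x`, `y`.
#' @param ridge_lambda Penalty used only by the low-rank fallback.
#' @return Object of class `oct2vf_ols` with `coef` (768 x 52) and
#'   `intercept` (52).
#' @export
fit_linear_baseline <- function(train, ridge_lambda = 1e-3) {
  tr <- as_xy(train)
  x <- tr$x; y <- tr$y
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  p <- ncol(x)
  if (nrow(x) > p) {
    fit <- lm.fit(cbind(1, x), y)
    cf <- fit$coefficients
    if (anyNA(cf)) {
      warning(sprintf("%d degenerate coefficient(s) set to zero",
                      sum(is.na(cf))))
      cf[is.na(cf)] <- 0
    }
  } else {
    warning("fewer exams than predictors; using ridge fallback")
    xs <- cbind(1, x)
    xtx <- crossprod(xs)
    # penalty scaled to the predictor magnitude so the solve is conditioned
    pen <- diag(rep(ridge_lambda * mean(diag(xtx)), p + 1))
    cf <- solve(xtx + pen, crossprod(xs, y))
  }
  structure(list(coef = cf[-1, , drop = FALSE], intercept = cf[1, ]),
            class = "oct2vf_ols")
}

#' @export
print.oct2vf_ols <- function(x, ...) {
  cat(sprintf("OLS baseline: %d predictors -> %d outputs\n",
              nrow(x$coef), ncol(x$coef)))
  invisible(x)
}

#' @rdname fit_linear_baseline
#' @param object An `oct2vf_ols`.
#' @param newdata 768-vector or n x 768 matrix (µm).
#' @param ... Unused.
#' @export
predict.oct2vf_ols <- function(object, newdata, ...) {
  one <- !is.matrix(newdata)
  x <- if (one) matrix(newdata, nrow = 1) else newdata
  out <- x %*% object$coef + rep(object$intercept, each = nrow(x))
  if (one) drop(out) else out
}

#' Wrap the generator's forward model as a predictor
#'
#' Useful as an oracle: the generator's own noiseless structure-function map
#' packaged with the same `predict()` interface as the trained models.
#'
#' @param cfg A [generator_config()].
#' @param sectors A [assign_gh_sectors()] result.
#' @param age Age at which predictions are evaluated (years).
#' @export
forward_model_predictor <- function(cfg = generator_config(),
                                    sectors = assign_gh_sectors(build_grid_24_2("right")),
                                    age = 63) {
  structure(list(cfg = cfg, sectors = sectors, age = age),
            class = "oct2vf_oracle")
}

#' @export
predict.oct2vf_oracle <- function(object, newdata, ...) {
  forward_sf_model(newdata, object$age, object$cfg, object$sectors,
                   noisy = FALSE)
}
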