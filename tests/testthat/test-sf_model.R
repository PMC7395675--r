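test_that("architecture is validated and the parameter count matches layer arithmetic", {
  expect_error(cnn_architecture(kernel_size = 4), "odd")
  expect_error(cnn_architecture(fc_sizes = c(0, 52)), "positive")
  m <- build_cnn(seed = 1)
  # per-layer arithmetic oracle: conv1, conv2, dense on 764*64 flatten, output
  expected <- (3 * 1 * 32 + 32) + (3 * 32 * 64 + 64) +
    ((764 * 64) * 54 + 54) + (54 * 52 + 52)
  expect_equal(n_parameters(m), expected)
})

test_that("weight initialization is seeded and deterministic", {
  a <- build_cnn(seed = 5); b <- build_cnn(seed = 5); c <- build_cnn(seed = 6)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, c$weights))
})

test_that("any 768-length input yields a 52-length output and bad input is rejected", {
  m <- build_cnn(seed = 2)
  expect_length(predict(m, runif(768, 40, 140)), 52)
  expect_equal(dim(predict(m, matrix(runif(768 * 3, 40, 140), 3))), c(3, 52))
  expect_error(predict(m, runif(100)), "768")
})

test_that("forward pass matches the brute-force conv/dense oracle on a tiny fixture", {
  arch <- cnn_architecture(conv_channels = c(2L, 3L), kernel_size = 3L,
                           fc_sizes = c(4L, 3L), input_len = 8L,
                           input_scale = 1)
  m <- build_cnn(arch, seed = 11)
  # hand-set, structured weights so the check does not depend on init
  m$weights$W1 <- matrix(seq(-0.3, 0.2, length.out = 6), 3, 2)
  m$weights$b1 <- c(0.1, -0.05)
  m$weights$W2 <- matrix(sin(1:18), 6, 3)
  m$weights$b2 <- c(0, 0.2, -0.1)
  m$weights$W3 <- matrix(cos(1:48) * 0.3, 12, 4)
  m$weights$b3 <- c(0.05, 0, -0.05, 0.1)
  m$weights$W4 <- matrix(seq(0.1, 1.2, length.out = 12), 4, 3)
  m$weights$b4 <- c(1, 2, 3)
  set.seed(8)
  for (i in 1:4) {
    x <- rnorm(8)
    expect_equal(drop(predict(m, matrix(x, 1))), brute_force_cnn(m, x),
                 tolerance = 1e-6)
  }
})

test_that("predictions are stateless: duplicates and batch partitioning do not matter", {
  m <- build_cnn(seed = 3)
  x <- matrix(runif(768 * 4, 40, 140), 4)
  x[2, ] <- x[1, ]
  p <- predict(m, x)
  expect_equal(p[1, ], p[2, ])
  one_by_one <- t(vapply(1:4, function(i) predict(m, x[i, ]), numeric(52)))
  expect_equal(p, one_by_one, tolerance = 1e-12)
})

# small training problem reused below: noiseless affine map of the profile;
# patient ids carry the seed so sets from different draws are disjoint
linear_problem <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 768, 40, 140), n)
  w <- matrix(rnorm(768 * 52, sd = 0.02), 768, 52)
  y <- x %*% w + rep(rnorm(52, 25, 2), each = n)
  list(x = x, y = y, patient_id = sprintf("S%d_P%d", seed, seq_len(n)))
}

test_that("training runs the protocol: history, checkpointing, reproducibility", {
  tr <- linear_problem(120, 21)
  va <- linear_problem(40, 22)
  m1 <- train_cnn(build_cnn(seed = 4), tr, va, training_config(epochs = 1, seed = 4))
  expect_equal(m1$selected_epoch, 1)

  m5 <- train_cnn(build_cnn(seed = 4), tr, va, training_config(epochs = 5, seed = 4))
  h <- m5$history
  expect_equal(nrow(h), 5)
  # selected epoch is the argmin of validation MSE
  expect_equal(m5$selected_epoch, which.min(h$val_mse))
  expect_lte(min(h$val_mse), h$val_mse[5])
  # training reduces the loss on a learnable problem
  expect_lt(h$train_mse[5], h$train_mse[1])
  # restored weights reproduce the recorded best validation MSE
  pv <- predict(m5, va$x)
  expect_equal(mean((pv - va$y)^2), min(h$val_mse), tolerance = 1e-10)
  # bit-for-bit reproducibility under a fixed seed
  m5b <- train_cnn(build_cnn(seed = 4), tr, va, training_config(epochs = 5, seed = 4))
  expect_identical(m5$weights, m5b$weights)
  # the caller's untrained model is not mutated by in-place optimizer steps
  m0 <- build_cnn(seed = 4)
  w_before <- m0$weights$W4 + 0
  invisible(train_cnn(m0, tr, va, training_config(epochs = 1, seed = 4)))
  expect_identical(m0$weights$W4, w_before)
})

test_that("training rejects shared patients and empty sets", {
  tr <- linear_problem(30, 1)
  va <- linear_problem(10, 2)
  va$patient_id <- tr$patient_id[1:10]
  expect_error(train_cnn(build_cnn(seed = 1), tr, va, training_config(epochs = 1)),
               "share patients")
  expect_error(train_cnn(build_cnn(seed = 1), list(x = tr$x[0, , drop = FALSE],
                                                   y = tr$y[0, , drop = FALSE]),
                         va, training_config(epochs = 1)),
               "non-empty")
})

test_that("a trained model round-trips through its text serialization", {
  tr <- linear_problem(60, 31)
  va <- linear_problem(20, 32)
  m <- train_cnn(build_cnn(seed = 9), tr, va, training_config(epochs = 2, seed = 9))
  dir <- withr::local_tempdir()
  write_cnn(m, dir)
  back <- read_cnn(dir)
  x <- matrix(runif(768 * 3, 40, 140), 3)
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
  expect_equal(back$selected_epoch, m$selected_epoch)
})

test_that("OLS baseline recovers an exact affine map and shifts with the targets", {
  pr <- linear_problem(900, 41)
  fit <- fit_linear_baseline(pr)
  expect_equal(predict(fit, pr$x), pr$y, tolerance = 1e-6)
  # residual orthogonality on the training data
  res <- pr$y - predict(fit, pr$x)
  expect_lt(max(abs(crossprod(pr$x, res))) / nrow(pr$x), 1e-6)
  # adding a constant to one output moves only that intercept
  y2 <- pr$y; y2[, 7] <- y2[, 7] + 5
  fit2 <- fit_linear_baseline(list(x = pr$x, y = y2))
  expect_equal(fit2$intercept[7] - fit$intercept[7], 5, tolerance = 1e-6)
  expect_equal(fit2$coef[, 7], fit$coef[, 7], tolerance = 1e-7)
  expect_equal(fit2$coef[, -7], fit$coef[, -7], tolerance = 1e-9)
})

test_that("underdetermined OLS falls back to ridge with a warning", {
  pr <- linear_problem(50, 51)
  expect_warning(fit <- fit_linear_baseline(pr), "ridge")
  expect_equal(dim(fit$coef), c(768, 52))
})
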