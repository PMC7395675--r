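test_that("pointwise metrics reproduce hand arithmetic and affine identities", {
  pred <- matrix(c(30, 28), 2, 1)
  meas <- matrix(c(32, 31), 2, 1)
  pm <- pointwise_metrics(pred, meas)
  expect_equal(pm$mae, 2.5)

  set.seed(1)
  meas52 <- matrix(runif(10 * 52, 10, 35), 10)
  pm0 <- pointwise_metrics(meas52, meas52)
  expect_equal(pm0$mae, rep(0, 52))
  pm5 <- pointwise_metrics(meas52 + 5, meas52)
  expect_equal(pm5$mae, rep(5, 52))
  expect_equal(pm5$r, rep(1, 52))
  expect_equal(attr(pm5, "avg_mae"), 5)
  # average over points equals the overall mean absolute error
  set.seed(2)
  pr <- meas52 + matrix(rnorm(10 * 52), 10)
  pm2 <- pointwise_metrics(pr, meas52)
  expect_equal(attr(pm2, "avg_mae"), mean(abs(pr - meas52)))
  # exam order does not matter
  perm <- sample(10)
  pm3 <- pointwise_metrics(pr[perm, ], meas52[perm, ])
  expect_equal(pm3$mae, pm2$mae)
  expect_equal(pm3$r, pm2$r)
})

test_that("zero-variance points yield NA correlations with a warning", {
  pred <- matrix(5, 4, 2); pred[, 2] <- 1:4
  meas <- matrix(rnorm(8), 4, 2)
  expect_warning(pm <- pointwise_metrics(pred, meas), "zero variance")
  expect_true(is.na(pm$r[1]))
  expect_equal(attr(pm, "avg_r"), pm$r[2])
})

test_that("cluster bootstrap is seeded, degenerate on constants, and needs clusters", {
  x <- rnorm(40)
  cl <- rep(1:10, each = 4)
  ci_const <- bootstrap_cis(function(i) c(k = 1), cl, B = 200, seed = 1)
  expect_equal(ci_const$lo, 1)
  expect_equal(ci_const$hi, 1)
  a <- bootstrap_cis(function(i) c(m = mean(x[i])), cl, B = 200, seed = 3)
  b <- bootstrap_cis(function(i) c(m = mean(x[i])), cl, B = 200, seed = 3)
  expect_identical(a, b)
  expect_lt(a$lo, a$est); expect_gt(a$hi, a$est)
  expect_error(bootstrap_cis(function(i) 1, rep(1, 5), B = 200), "clusters")
  expect_error(bootstrap_cis(function(i) 1, cl, B = 50), "B must")
})

test_that("sector averages and metrics match a hand-computed fixture", {
  co <- small_cohort()
  sectors <- assign_gh_sectors(build_grid_24_2("right"))
  idx <- sector_indices(sectors)
  set.seed(4)
  meas <- matrix(runif(3 * 52, 15, 35), 3)
  pred <- meas + matrix(rnorm(3 * 52), 3)
  sm <- sector_metrics(pred, meas, sectors)
  expect_equal(nrow(sm), 6)
  # hand computation for one sector
  s <- "superior"
  pa <- rowMeans(pred[, idx[[s]]]); ma <- rowMeans(meas[, idx[[s]]])
  expect_equal(sm$mae[sm$sector == s], mean(abs(pa - ma)))
  expect_equal(sm$r[sm$sector == s], cor(pa, ma))
  # identical inputs give zero MAE everywhere
  expect_equal(sector_metrics(meas, meas, sectors)$mae, rep(0, 6))
  # constant-valued sector: the average equals that value
  meas2 <- meas; meas2[, idx[[s]]] <- 27
  pa2 <- vapply(seq_len(3), function(i) mean(meas2[i, idx[[s]]]), numeric(1))
  expect_equal(pa2, rep(27, 3))
})

test_that("correlation comparison is null on identical models and detects separation", {
  set.seed(5)
  n <- 300
  meas <- matrix(runif(n * 52, 10, 35), n)
  cl <- rep(seq_len(n / 3), each = 3)
  pa <- meas + matrix(rnorm(n * 52, sd = 1), n)
  same <- compare_models_correlation(pa, pa, meas, cl, B = 200, seed = 6)
  expect_equal(same$diff_r, 0)
  expect_gt(same$p_value, 0.9)
  # model B: predictions shuffled across exams -> correlation destroyed
  pb <- pa[sample(n), ]
  sep <- compare_models_correlation(pa, pb, meas, cl, B = 200, seed = 6)
  expect_gt(sep$diff_r, 0.5)
  expect_lt(sep$p_value, 0.05)
  expect_true(sep$ci[1] > 0)
  # CI excluding zero and p < .05 agree by construction
  expect_equal(unname(sep$ci[1] > 0 || sep$ci[2] < 0), sep$p_value < 0.05)
})

test_that("mixed-model comparison reproduces exact shifts", {
  set.seed(7)
  participants <- rep(sprintf("P%02d", 1:30), each = 3)
  err_a <- abs(rnorm(90, 3, 1)) + rep(rnorm(30, 0, 0.8), each = 3)
  same <- suppressMessages(compare_models_abs_error(err_a, err_a, participants))
  expect_equal(same$estimate, 0, tolerance = 1e-10)
  shift <- suppressMessages(compare_models_abs_error(err_a, err_a + 1, participants))
  expect_equal(shift$estimate, 1, tolerance = 1e-8)
  expect_lt(shift$p_value, 0.001)
  expect_error(compare_models_abs_error(err_a, err_a, rep("P1", 90)),
               "participants")
})

test_that("threshold-binned MAE isolates bins and degenerates to the global MAE", {
  set.seed(8)
  meas <- matrix(runif(5 * 52, 20, 21.9), 5)  # all in [20, 22)
  pred <- meas + matrix(rnorm(5 * 52), 5)
  b <- mae_by_threshold_bins(pred, meas)
  filled <- which(!is.na(b$mae))
  expect_equal(b$bin_lo[filled], 20)
  expect_equal(b$mae[filled], mean(abs(pred - meas)))
  expect_equal(sum(b$n), length(meas))
  b0 <- mae_by_threshold_bins(meas, meas)
  expect_true(all(b0$mae[!is.na(b0$mae)] == 0))
})

test_that("error correlates recover exact and null relationships", {
  set.seed(9)
  err <- abs(rnorm(2000, 4, 1))
  cov <- data.frame(self = err, neg = -err, null = rnorm(2000))
  ec <- error_correlates(err, cov)
  expect_equal(ec$r[ec$covariate == "self"], 1)
  expect_equal(ec$r[ec$covariate == "neg"], -1)
  expect_lt(abs(ec$r[ec$covariate == "null"]), 0.1)
  expect_error(error_correlates(err[1:2], cov[1:2, ]), "at least 3")
})
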