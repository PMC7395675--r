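# a minimal normative fixture with analytically known values
fixture_normative <- function(intercept = 30, slope = -0.07) {
  structure(
    list(age_model = data.frame(point = 1:52, intercept = intercept,
                                slope = slope),
         td_percentiles = matrix(c(-2, -3, -4, -5), 52, 4, byrow = TRUE,
                                 dimnames = list(NULL, c("p5", "p2", "p1", "p0.5"))),
         pd_percentiles = matrix(c(-2, -3, -4, -5), 52, 4, byrow = TRUE,
                                 dimnames = list(NULL, c("p5", "p2", "p1", "p0.5"))),
         healthy_mean_rnfl = rep(100, 768),
         glaucoma_percentiles = NULL),
    class = "normative_tables")
}

test_that("total deviation is zero on normative input and tracks age", {
  nt <- fixture_normative()
  normals50 <- nt$age_model$intercept + nt$age_model$slope * 50
  expect_equal(total_deviation(normals50, 50, nt), rep(0, 52))
  expect_equal(total_deviation(normals50 - 5, 50, nt), rep(-5, 52))
  # identical thresholds at ages 50 vs 60: TD differs by slope * 10 = +0.7
  td50 <- total_deviation(normals50, 50, nt)
  td60 <- total_deviation(normals50, 60, nt)
  expect_equal(td60 - td50, rep(0.7, 52))
  expect_warning(total_deviation(normals50, 110, nt), "extrapolating")
})

test_that("pattern deviation subtracts the seventh-best total deviation", {
  expect_equal(pattern_deviation(rep(3, 52)), rep(0, 52))
  # six elevated points leave the general height at zero
  td <- c(rep(5, 6), rep(0, 46))
  expect_equal(pattern_deviation(td), td)
  # the sort-based oracle: seven elevated points move it
  td7 <- c(rep(5, 7), rep(0, 45))
  expect_equal(pattern_deviation(td7), td7 - 5)
  # shift invariance
  set.seed(12)
  tdr <- rnorm(52)
  expect_equal(pattern_deviation(tdr + 13.7), pattern_deviation(tdr))
  expect_error(pattern_deviation(rnorm(5)), "at least 7")
})

test_that("probability categories use inclusive boundaries toward abnormal", {
  nt <- fixture_normative()
  dev <- rep(0, 52)
  dev[1] <- -1.99   # above p5 -> ns
  dev[2] <- -2      # exactly at p5 -> <5%
  dev[3] <- -3.5    # below p2, above p1 -> <2%
  dev[4] <- -5      # at p0.5 -> <0.5%
  dev[5] <- -10
  cat <- probability_categories(dev, nt$td_percentiles)
  expect_equal(as.character(cat[1:5]), c("ns", "<5%", "<2%", "<0.5%", "<0.5%"))
  expect_true(is.ordered(cat))
  expect_error(probability_categories(dev[1:10], nt$td_percentiles), "cover")
})

test_that("global indices have exact zero and shift behavior", {
  z <- global_indices(rep(0, 52))
  expect_equal(z$md, 0); expect_equal(z$psd, 0)
  td <- c(-2, 0, 2, rep(0, 49))
  gi <- global_indices(td)
  expect_equal(gi$md, 0)
  expect_equal(gi$psd, sd(td))
  gi_shift <- global_indices(td + 3)
  expect_equal(gi_shift$md, 3)
  expect_equal(gi_shift$psd, gi$psd)
})

test_that("rendered reports are deterministic and round-trip thresholds", {
  nt <- fixture_normative()
  set.seed(3)
  th <- round(runif(52, 5, 35), 1)  # on the rendered 0.1 dB grid
  rep1 <- vf_report(th, 55, nt)
  lines1 <- render_report(rep1)
  lines2 <- render_report(vf_report(th, 55, nt))
  expect_identical(lines1, lines2)
  expect_equal(parse_report_text(lines1), th)
  # blind-spot positions are rendered as blanks, not numbers
  thr_block <- lines1[(which(lines1 == "Sensitivity thresholds [dB]:") + 1):
                        (which(lines1 == "Sensitivity thresholds [dB]:") + 8)]
  expect_equal(sum(grepl("---", thr_block)), 2)
})

test_that("about 5% of healthy total deviations fall below the 5th percentile line", {
  co <- small_cohort()
  healthy <- co[!co$exams$is_glaucoma]
  nt <- small_normative()
  below <- 0; total <- 0
  for (i in seq_len(nrow(healthy$exams))) {
    td <- total_deviation(healthy$vf[i, ], healthy$exams$age_years[i], nt)
    below <- below + sum(td <= nt$td_percentiles[, "p5"])
    total <- total + 52
  }
  frac <- below / total
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("report assembly is internally consistent", {
  nt <- fixture_normative()
  th <- rep(30 - 0.07 * 60, 52); th[10] <- th[10] - 12
  r <- vf_report(th, 60, nt)
  expect_equal(r$pattern_deviation,
               r$total_deviation - sort(r$total_deviation, decreasing = TRUE)[7])
  expect_equal(r$md, mean(r$total_deviation))
  expect_equal(as.character(r$td_prob[10]), "<0.5%")
  expect_equal(sum(r$td_prob != "ns"), 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_vf_report(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$md, r$md)
  expect_equal(back$thresholds, th)
})
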