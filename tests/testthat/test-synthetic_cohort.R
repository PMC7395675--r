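cfg0 <- generator_config()
grid0 <- build_grid_24_2("right")
sectors0 <- assign_gh_sectors(grid0)

test_that("generator configuration is validated", {
  expect_error(generator_config(n_patients = 0), "positive")
  expect_error(generator_config(fraction_glaucoma = 1.2), "fractions")
  expect_error(generator_config(sigma0 = -1), "non-negative")
  expect_error(generator_config(rnfl_floor = 60, profile_base = 50), "floor")
})

test_that("normative profile is a periodic double-hump curve with the configured mean", {
  expect_error(normative_rnfl_mean(360, cfg0), "angles")
  expect_gt(normative_rnfl_mean(80, cfg0), normative_rnfl_mean(0, cfg0))
  expect_gt(normative_rnfl_mean(280, cfg0), normative_rnfl_mean(180, cfg0))
  # continuity at the wrap point
  expect_equal(normative_rnfl_mean(0, cfg0),
               normative_rnfl_mean(360 - 1e-9, cfg0), tolerance = 1e-6)
  # sampled mean vs the analytic integral of the configured curve
  expect_lt(abs(mean(normative_rnfl_mean(rnfl_angles(), cfg0)) -
                  cfg0$healthy_global_mean), 2)
})

test_that("forward model reproduces the age-corrected normals on the healthy profile", {
  hm <- normative_rnfl_mean(rnfl_angles(), cfg0)
  s <- forward_sf_model(hm, 60, cfg0, sectors0)
  expect_equal(s, normal_sensitivity(60, cfg0, grid0), tolerance = 1e-12)
})

test_that("halving thickness above the floor costs 10*log10(2) dB", {
  hm <- normative_rnfl_mean(rnfl_angles(), cfg0)
  half <- cfg0$rnfl_floor + (hm - cfg0$rnfl_floor) / 2
  drop_db <- normal_sensitivity(60, cfg0, grid0) -
    forward_sf_model(half, 60, cfg0, sectors0)
  expect_equal(drop_db, rep(10 * log10(2), 52), tolerance = 1e-9)
})

test_that("a profile at the residual floor yields zero sensitivity everywhere", {
  s <- forward_sf_model(rep(cfg0$rnfl_floor, 768), 60, cfg0, sectors0)
  expect_equal(s, rep(0, 52))
})

test_that("degenerate floor configurations are rejected", {
  bad <- generator_config()
  bad$rnfl_floor <- 80  # above the temporal base after construction
  expect_error(forward_sf_model(rep(100, 768), 60, bad, sectors0), "degenerate")
})

test_that("noiseless forward model is monotone in the profile", {
  set.seed(31)
  for (i in 1:5) {
    lo <- runif(768, 30, 120)
    hi <- lo + runif(768, 0, 30)
    s_lo <- forward_sf_model(lo, 63, cfg0, sectors0)
    s_hi <- forward_sf_model(hi, 63, cfg0, sectors0)
    expect_true(all(s_lo <= s_hi + 1e-12))
  }
})

test_that("threshold noise grows below the knee and is flat above it", {
  s <- seq(0, 40, by = 0.5)
  sd_s <- threshold_noise_sd(s, cfg0)
  above <- s >= cfg0$noise_knee
  expect_true(all(sd_s[above] == cfg0$sigma0))
  below <- sd_s[!above]
  expect_true(all(diff(below) <= 0))          # decreasing toward the knee
  expect_true(all(below > cfg0$sigma0))
  expect_true(all(sd_s <= cfg0$noise_sd_cap))
})

test_that("cohort simulation is reproducible and responds to disease fraction", {
  a <- simulate_cohort(generator_config(n_patients = 40, seed = 9))
  b <- simulate_cohort(generator_config(n_patients = 40, seed = 9))
  expect_identical(a$rnfl, b$rnfl)
  expect_identical(a$vf, b$vf)
  expect_identical(a$exams, b$exams)
  healthy_co <- simulate_cohort(generator_config(n_patients = 40, seed = 9,
                                                 fraction_glaucoma = 0))
  expect_gt(mean(healthy_co$rnfl), mean(a$rnfl))
  expect_false(any(healthy_co$exams$is_glaucoma))
  # invariants on ranges
  expect_true(all(a$vf >= 0 & a$vf <= 50))
  expect_true(all(a$rnfl >= 0 & a$rnfl <= 250))
  expect_error(simulate_cohort(generator_config(n_patients = 0)), "positive")
})

test_that("an inferotemporal defect produces predominantly superior field loss", {
  hm <- normative_rnfl_mean(rnfl_angles(), cfg0)
  prof <- hm
  theta <- rnfl_angles()
  inside <- theta >= 270 & theta < 300
  prof[inside] <- prof[inside] * 0.3
  s_def <- forward_sf_model(prof, 63, cfg0, sectors0)
  s_base <- forward_sf_model(hm, 63, cfg0, sectors0)
  loss <- s_base - s_def
  sup <- grid0$points$y > 0
  expect_gt(mean(loss[sup]), mean(loss[!sup]))
  expect_gt(mean(loss[sup]), 1)  # a real defect, not numerical noise
})

test_that("normative tables order percentiles and recover the ageing slope", {
  co <- small_cohort()
  nt <- small_normative()
  gp <- nt$glaucoma_percentiles
  expect_true(all(gp[, "p1"] <= gp[, "p5"] + 1e-12))
  expect_true(all(gp[, "p5"] <= gp[, "p10"] + 1e-12))
  expect_true(all(gp[, "p10"] <= nt$healthy_mean_rnfl + 1e-12))
  # TD/PD percentile columns ordered
  for (m in list(nt$td_percentiles, nt$pd_percentiles)) {
    expect_true(all(m[, "p0.5"] <= m[, "p1"] + 1e-12))
    expect_true(all(m[, "p1"] <= m[, "p2"] + 1e-12))
    expect_true(all(m[, "p2"] <= m[, "p5"] + 1e-12))
  }
  # ageing slope of the generator is recovered by the healthy age regression
  big <- normalize_laterality(
    simulate_cohort(generator_config(n_patients = 220, seed = 77,
                                     fraction_glaucoma = 0)))
  nt_big <- suppressWarnings(derive_normative_tables(big, big[1:120]))
  slopes <- nt_big$age_model$slope
  expect_lt(abs(mean(slopes) - cfg0$age_slope), 0.02)
})

test_that("degenerate glaucoma sample yields identical percentile profiles", {
  co <- small_cohort()
  one <- co[rep(3, 60)]          # sixty copies of one exam
  nt <- suppressWarnings(derive_normative_tables(co[!co$exams$is_glaucoma], one))
  prof <- pmin(co$rnfl[3, ], nt$healthy_mean_rnfl)
  expect_equal(unname(nt$glaucoma_percentiles[, "p10"]), unname(prof))
  expect_equal(unname(nt$glaucoma_percentiles[, "p1"]), unname(prof))
})

test_that("percentile estimator matches a sort-based brute-force oracle", {
  # brute-force type-7: linear interpolation between order statistics
  brute_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  co <- small_cohort()
  gl <- co[which(co$exams$is_glaucoma)[1:25]]
  he <- co[which(!co$exams$is_glaucoma)[1:25]]
  nt <- suppressWarnings(derive_normative_tables(he, gl))
  for (k in c(1, 100, 500)) {
    for (q in c(0.10, 0.05, 0.01)) {
      expect_equal(unname(nt$glaucoma_percentiles[k, paste0("p", q * 100)]),
                   min(brute_q(gl$rnfl[, k], q), mean(he$rnfl[, k])),
                   tolerance = 1e-12)
    }
  }
})

test_that("cohorts round-trip through CSV/JSON", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(generator_config(n_patients = 8, seed = 3))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$rnfl, co$rnfl, ignore_attr = TRUE)
  expect_equal(back$vf, co$vf, ignore_attr = TRUE)
  expect_equal(back$exams$patient_id, co$exams$patient_id)
  expect_equal(back$config$seed, co$config$seed)
})
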