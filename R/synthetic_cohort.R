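# Synthetic paired-exam cohort: the stand-in for a private clinical registry.
# Generates hierarchical patients -> eyes -> test dates with glaucomatous RNFL
# loss (localized wedge defects + diffuse thinning) and visual fields produced
# by a known nonlinear forward model, so every downstream claim can be checked
# against ground truth.

#' Configuration of the synthetic cohort generator
#'
#' Collects every parameter of the generator: cohort structure, the healthy
#' double-hump TSNIT profile, defect and diffuse-loss distributions, the
#' structure-function forward model, the age model of normal sensitivity, and
#' the reliability/quality metadata model. All values have units in the field's
#' conventions (µm for thickness, dB for sensitivity, degrees for angles,
#' years for age).
#'
#' The forward model maps a profile to noiseless thresholds as
#' `S_i = clamp(N_i(age) + 10 * gamma * log10((t_i - b) / (tbar_i - b)), 0,
#' ceiling)` where `t_i` is the circular-Gaussian-weighted local thickness
#' around point i's disc entry angle (spread `sigma_map`), `tbar_i` the same
#' functional applied to the healthy mean profile, and `b` a residual
#' (non-axonal) thickness floor. Measurement noise has standard deviation
#' `sigma0 + sigma1 * max(0, knee - S)` capped at `noise_sd_cap`, so
#' variability grows steeply once sensitivity falls below the knee —
#' mirroring the well-known unreliability of perimetry below ~15 dB.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @param fraction_glaucoma Fraction of patients with glaucomatous loss; the
#'   remainder are healthy/suspect eyes without structural loss.
#' @param eyes_per_patient,tests_per_eye Probability vectors over 1..k eyes
#'   and 1..k paired tests per eye.
#' @param profile_base,profile_amp,profile_centers,profile_width Healthy
#'   double-hump profile: temporal base (µm), bump amplitudes (µm), bump
#'   centers (deg, superior-temporal and inferior-temporal peaks) and common
#'   Gaussian width (deg).
#' @param subject_base_sd,subject_amp_sd,subject_center_sd,exam_noise_sd
#'   Between-subject jitter of the profile parameters and within-eye exam
#'   measurement noise (µm).
#' @param defect_extra_prob Probability a glaucomatous eye carries a second
#'   localized defect.
#' @param defect_arcuate_prob Probability a defect centre is drawn from the
#'   arcuate bundles (Gaussians at 60° and 300°) rather than uniformly.
#' @param defect_width_range,defect_depth_range Angular width (deg) and
#'   fractional depth of localized defects (uniform ranges).
#' @param diffuse_range Multiplicative diffuse-loss factor range for
#'   glaucomatous eyes.
#' @param sigma_map Circular-Gaussian spread (deg) of the ground-truth
#'   structure-function weighting.
#' @param rnfl_floor Residual thickness floor `b` (µm) below which tissue
#'   carries no signal.
#' @param gamma dB-per-log10 slope multiplier of the forward model.
#' @param sigma0,sigma1,noise_knee,noise_sd_cap Threshold noise model (dB).
#' @param ceiling_db Sensitivity ceiling (dB).
#' @param sens50_base,sens50_ecc_slope Normal sensitivity at age 50: intercept
#'   at fixation (dB) and linear decline per degree of eccentricity.
#' @param age_mean,age_sd,age_range,age_slope Age distribution (years,
#'   truncated normal) and the uniform ageing slope of normal sensitivity
#'   (dB/yr, negative).
#' @param frac_unreliable,frac_low_quality,frac_late_oct Fractions of exams
#'   generated to fail the fixation/false-positive filters, the OCT quality
#'   filter, or the 180-day pairing window.
#' @return Object of class `oct2vf_config` (a validated list).
#' @export
generator_config <- function(n_patients = 1500,
                             seed = 1L,
                             fraction_glaucoma = 0.6,
                             eyes_per_patient = c(0.3, 0.7),
                             tests_per_eye = c(0.5, 0.3, 0.13, 0.07),
                             profile_base = 50,
                             profile_amp = c(45, 45),
                             profile_centers = c(80, 280),
                             profile_width = 35,
                             subject_base_sd = 4,
                             subject_amp_sd = 5,
                             subject_center_sd = 4,
                             exam_noise_sd = 2,
                             defect_extra_prob = 0.35,
                             defect_arcuate_prob = 0.7,
                             defect_width_range = c(20, 70),
                             defect_depth_range = c(0.35, 0.85),
                             diffuse_range = c(0.75, 1),
                             sigma_map = 15,
                             rnfl_floor = 30,
                             gamma = 1,
                             sigma0 = 1.5,
                             sigma1 = 0.4,
                             noise_knee = 25,
                             noise_sd_cap = 8,
                             ceiling_db = 40,
                             sens50_base = 34,
                             sens50_ecc_slope = -0.12,
                             age_mean = 63,
                             age_sd = 14,
                             age_range = c(25, 95),
                             age_slope = -0.07,
                             frac_unreliable = 0.06,
                             frac_low_quality = 0.04,
                             frac_late_oct = 0.03) {
  cfg <- as.list(environment())
  stop_if_not(n_patients >= 1, "n_patients must be positive")
  fracs <- c(fraction_glaucoma, defect_extra_prob, defect_arcuate_prob,
             frac_unreliable, frac_low_quality, frac_late_oct)
  stop_if_not(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0, 1]")
  sds <- c(subject_base_sd, subject_amp_sd, subject_center_sd, exam_noise_sd,
           sigma0, sigma1, age_sd, sigma_map)
  stop_if_not(all(sds >= 0), "variance parameters must be non-negative")
  stop_if_not(rnfl_floor < profile_base,
              "rnfl_floor must lie below the temporal base thickness")
  stop_if_not(age_slope <= 0, "age_slope is a decline (<= 0) in dB/yr")
  stop_if_not(abs(sum(eyes_per_patient) - 1) < 1e-8 &&
                abs(sum(tests_per_eye) - 1) < 1e-8,
              "eyes_per_patient and tests_per_eye must sum to 1")
  # analytic global mean of the default healthy curve (circular Gaussians)
  cfg$healthy_global_mean <- profile_base +
    sum(profile_amp) * profile_width * sqrt(2 * pi) / 360
  structure(cfg, class = "oct2vf_config")
}

#' Healthy mean RNFL profile (double-hump TSNIT curve)
#'
#' Smooth 360°-periodic normative curve: a temporal base plus two circular
#' Gaussian bumps at the superior-temporal and inferior-temporal peaks.
#'
#' @param angle_deg Angles in `[0, 360)` (vectorized).
#' @param cfg A [generator_config()].
#' @return Thickness in µm at each angle.
#' @export
#' @examples
#' cfg <- generator_config()
#' normative_rnfl_mean(c(0, 80, 180, 280), cfg)
normative_rnfl_mean <- function(angle_deg, cfg = generator_config()) {
  stop_if_not(all(angle_deg >= 0 & angle_deg < 360),
              "angles must lie in [0, 360)")
  healthy_curve(angle_deg, cfg$profile_base, cfg$profile_amp,
                cfg$profile_centers, cfg$profile_width)
}

healthy_curve <- function(angle, base, amp, centers, width) {
  v <- rep(base, length(angle))
  for (j in seq_along(centers)) {
    v <- v + amp[j] * exp(-0.5 * (circ_diff(angle, centers[j]) / width)^2)
  }
  v
}

# ---- Forward structure-function model --------------------------------------

#' Circular-Gaussian structure-function weight matrix
#'
#' Row i holds the normalized weights of the 768 profile samples for visual
#' field point i, a circular Gaussian centred on the point's optic-disc entry
#' angle. This is the ground-truth map of the generator which a trained model
#' must rediscover from data.
#'
#' @param sectors A [assign_gh_sectors()] result (supplies disc angles).
#' @param sigma_map Spread in degrees.
#' @param n_samples Profile length.
#' @return 52 x 768 matrix with rows summing to one.
#' @export
sf_weight_matrix <- function(sectors, sigma_map = 15, n_samples = 768L) {
  theta <- rnfl_angles(n_samples)
  w <- exp(-0.5 * (outer(sectors$disc_angle, theta, circ_diff) / sigma_map)^2)
  w / rowSums(w)
}

#' Age-corrected normal sensitivity of the generator
#'
#' `N_i(age) = sens50_base + sens50_ecc_slope * ecc_i + age_slope * (age - 50)`
#' for each grid point i, where `ecc_i` is the point's eccentricity.
#'
#' @param age Age in years (scalar or vector).
#' @param cfg A [generator_config()].
#' @param grid A [build_grid_24_2()] grid.
#' @return If `age` is scalar, a 52-vector; otherwise a `length(age)` x 52
#'   matrix.
#' @export
normal_sensitivity <- function(age, cfg = generator_config(),
                               grid = build_grid_24_2("right")) {
  ecc <- sqrt(grid$points$x^2 + grid$points$y^2)
  base <- cfg$sens50_base + cfg$sens50_ecc_slope * ecc
  if (length(age) == 1) base + cfg$age_slope * (age - 50)
  else outer(cfg$age_slope * (age - 50), base, `+`)
}

#' Noise SD of a sensitivity threshold
#'
#' Measurement noise of the generator: constant `sigma0` above the knee and
#' growing linearly by `sigma1` per dB below it, capped at `noise_sd_cap`.
#'
#' @param s Noiseless sensitivity (dB), vectorized.
#' @param cfg A [generator_config()].
#' @export
threshold_noise_sd <- function(s, cfg = generator_config()) {
  pmin(cfg$sigma0 + cfg$sigma1 * pmax(0, cfg$noise_knee - s), cfg$noise_sd_cap)
}

#' Ground-truth forward model: RNFL profile to visual-field thresholds
#'
#' Maps one or more 768-point profiles to 52 thresholds: local weighted
#' thickness via the circular-Gaussian weight matrix, log-scale floored
#' sensitivity loss relative to the healthy local mean, clamping to
#' `[0, ceiling_db]`, and (optionally) heteroscedastic measurement noise.
#' Pointwise-lower profiles never yield higher noiseless sensitivity.
#'
#' @param rnfl A 768-vector or an n x 768 matrix (µm), right-eye convention.
#' @param age Age in years (scalar, or length n).
#' @param cfg A [generator_config()].
#' @param sectors A [assign_gh_sectors()] result.
#' @param noisy Add measurement noise (uses the current RNG stream).
#' @return 52-vector or n x 52 matrix of thresholds (dB).
#' @export
forward_sf_model <- function(rnfl, age, cfg = generator_config(),
                             sectors = assign_gh_sectors(build_grid_24_2("right")),
                             noisy = FALSE) {
  one <- !is.matrix(rnfl)
  x <- if (one) matrix(rnfl, nrow = 1) else rnfl
  stop_if_not(ncol(x) == 768, "profiles must have 768 samples")
  w <- sf_weight_matrix(sectors, cfg$sigma_map, ncol(x))
  tbar <- as.vector(w %*% normative_rnfl_mean(rnfl_angles(ncol(x)), cfg))
  stop_if_not(all(tbar > cfg$rnfl_floor),
              "degenerate config: healthy local mean at or below rnfl_floor")
  t_loc <- x %*% t(w)                                     # n x 52
  eps <- 1e-3
  ratio <- pmax(t_loc - cfg$rnfl_floor, eps) /
    matrix(tbar - cfg$rnfl_floor, nrow(x), 52, byrow = TRUE)
  nrm <- normal_sensitivity(age, cfg)
  if (is.matrix(nrm) && nrow(nrm) == 1) nrm <- drop(nrm)
  if (!is.matrix(nrm)) nrm <- matrix(nrm, nrow(x), 52, byrow = TRUE)
  s <- clamp(nrm + 10 * cfg$gamma * log10(ratio), 0, cfg$ceiling_db)
  if (noisy) {
    s <- s + rnorm(length(s), sd = threshold_noise_sd(s, cfg))
    s <- clamp(s, 0, cfg$ceiling_db)
  }
  if (one) drop(s) else s
}

# ---- Cohort simulation ------------------------------------------------------

# Smooth (cosine-tapered) multiplicative wedge used for *generated* disease;
# the defect-simulation module uses abrupt percentile replacement instead.
defect_factor <- function(theta, center, width, depth) {
  d <- circ_diff(theta, center)
  half <- width / 2
  f <- rep(1, length(theta))
  inside <- d < half
  f[inside] <- 1 - depth * 0.5 * (1 + cos(pi * d[inside] / half))
  f
}

#' Simulate a paired-exam cohort
#'
#' Hierarchical sampling of patients, eyes and test dates. Each patient gets an
#' age and a disease state; each glaucomatous eye draws a diffuse-loss factor
#' and one or two localized wedge defects (random centre, width, depth) applied
#' multiplicatively to a per-subject jittered healthy profile. Every exam adds
#' measurement noise to the profile and generates its visual field with the
#' noisy forward model; reliability and quality metadata include configured
#' fractions of filter-failing exams, and a fraction of OCT dates falls outside
#' the pairing window. Left eyes are stored in left-eye convention (RNFL order
#' reflected) to exercise laterality handling downstream. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return Object of class `paired_cohort`: list with `exams` (metadata data
#'   frame), `rnfl` (n x 768, µm), `vf` (n x 52, dB), `vf_true` (noiseless
#'   ground truth, right-eye convention) and `config`.
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  stop_if_not(inherits(cfg, "oct2vf_config"), "cfg must be a generator_config()")
  set.seed(cfg$seed)
  grid <- build_grid_24_2("right")
  sectors <- assign_gh_sectors(grid)
  theta <- rnfl_angles()

  n_eyes_pat <- sample(seq_along(cfg$eyes_per_patient), cfg$n_patients,
                       replace = TRUE, prob = cfg$eyes_per_patient)
  ages <- clamp(rnorm(cfg$n_patients, cfg$age_mean, cfg$age_sd),
                cfg$age_range[1], cfg$age_range[2])
  glaucoma_pat <- runif(cfg$n_patients) < cfg$fraction_glaucoma

  rows <- list(); rnfl <- list(); vf <- list(); vf_true <- list()
  exam_id <- 0L
  for (p in seq_len(cfg$n_patients)) {
    # per-subject healthy profile parameters
    base_p <- cfg$profile_base + rnorm(1, 0, cfg$subject_base_sd)
    amp_p <- cfg$profile_amp + rnorm(2, 0, cfg$subject_amp_sd)
    cen_p <- cfg$profile_centers + rnorm(2, 0, cfg$subject_center_sd)
    for (e in seq_len(n_eyes_pat[p])) {
      lat <- if (e == 1) "right" else "left"
      healthy_e <- healthy_curve(theta, base_p, pmax(amp_p, 0), cen_p %% 360,
                                 cfg$profile_width)
      factor_e <- rep(1, 768)
      if (glaucoma_pat[p]) {
        factor_e <- factor_e * runif(1, cfg$diffuse_range[1], cfg$diffuse_range[2])
        n_def <- 1L + rbinom(1, 1, cfg$defect_extra_prob)
        for (d in seq_len(n_def)) {
          center <- if (runif(1) < cfg$defect_arcuate_prob) {
            (sample(c(60, 300), 1) + rnorm(1, 0, 25)) %% 360
          } else runif(1, 0, 360)
          width <- runif(1, cfg$defect_width_range[1], cfg$defect_width_range[2])
          depth <- runif(1, cfg$defect_depth_range[1], cfg$defect_depth_range[2])
          factor_e <- factor_e * defect_factor(theta, center, width, depth)
        }
      }
      true_profile <- healthy_e * factor_e
      n_tests <- sample(seq_along(cfg$tests_per_eye), 1, prob = cfg$tests_per_eye)
      base_date <- as.Date("2015-01-01") + round(runif(1, 0, 3000))
      for (tt in seq_len(n_tests)) {
        exam_id <- exam_id + 1L
        sap_date <- base_date + round(runif(1, 0, 400)) * (tt - 1) +
          round(runif(1, 0, 60))
        delta <- if (runif(1) < cfg$frac_late_oct) {
          sample(c(-1, 1), 1) * round(runif(1, 181, 365))
        } else round(rnorm(1, 0, 45))
        oct_date <- sap_date + delta
        prof <- pmax(true_profile + rnorm(768, 0, cfg$exam_noise_sd), 0)
        s_true <- forward_sf_model(prof, ages[p], cfg, sectors, noisy = FALSE)
        s_obs <- clamp(s_true + rnorm(52, sd = threshold_noise_sd(s_true, cfg)),
                       0, cfg$ceiling_db)
        if (lat == "left") prof <- rev_profile(prof)  # store in left-eye order
        unreliable <- runif(1) < cfg$frac_unreliable
        fl <- if (unreliable && runif(1) < 0.5) runif(1, 0.34, 0.6)
              else rbeta(1, 1.2, 8) * 0.33
        fp <- if (unreliable && fl <= 0.33) runif(1, 0.16, 0.4)
              else rbeta(1, 1.1, 12) * 0.15
        qual <- if (runif(1) < cfg$frac_low_quality) runif(1, 5, 14.9)
                else clamp(rnorm(1, 27, 5), 15, 40)
        rows[[exam_id]] <- data.frame(
          exam_id = exam_id,
          patient_id = sprintf("P%04d", p),
          eye_id = sprintf("P%04d_%s", p, if (lat == "right") "OD" else "OS"),
          laterality = lat,
          test_date_sap = sap_date, test_date_oct = oct_date,
          age_years = ages[p] + as.numeric(sap_date - base_date) / 365.25,
          fixation_loss_frac = fl, false_positive_frac = fp,
          oct_quality_score = qual,
          is_glaucoma = glaucoma_pat[p]
        )
        rnfl[[exam_id]] <- prof
        vf[[exam_id]] <- s_obs
        vf_true[[exam_id]] <- s_true
      }
    }
  }
  exams <- do.call(rbind, rows)
  rownames(exams) <- NULL
  structure(
    list(exams = exams,
         rnfl = do.call(rbind, rnfl),
         vf = do.call(rbind, vf),
         vf_true = do.call(rbind, vf_true),
         config = cfg),
    class = "paired_cohort"
  )
}

# reflect a single profile about the 0/180 axis (left-eye storage convention)
rev_profile <- function(prof) {
  n <- length(prof)
  k <- seq_len(n) - 1
  prof[((n - k) %% n) + 1]
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired cohort: %d exams, %d eyes, %d patients (%.0f%% glaucoma patients)\n",
              nrow(x$exams), length(unique(x$exams$eye_id)),
              length(unique(x$exams$patient_id)),
              100 * mean(tapply(x$exams$is_glaucoma, x$exams$patient_id, any))))
  invisible(x)
}

#' @export
`[.paired_cohort` <- function(x, i, ...) {
  structure(
    list(exams = x$exams[i, , drop = FALSE],
         rnfl = x$rnfl[i, , drop = FALSE],
         vf = x$vf[i, , drop = FALSE],
         vf_true = if (!is.null(x$vf_true)) x$vf_true[i, , drop = FALSE],
         config = x$config),
    class = "paired_cohort"
  )
}

n_exams <- function(cohort) nrow(cohort$exams)

#' Reflect all left-eye exams of a cohort into right-eye convention
#'
#' @param cohort A `paired_cohort`.
#' @return The cohort with left-eye RNFL profiles mirrored (visual fields are
#'   stored index-aligned across lateralities already) and laterality re-tagged.
#' @export
normalize_laterality <- function(cohort) {
  stop_if_not(!is.null(cohort$exams$laterality), "cohort lacks laterality tags")
  left <- cohort$exams$laterality == "left"
  if (any(left)) {
    cohort$rnfl[left, ] <- mirror_rnfl_to_right(cohort$rnfl[left, , drop = FALSE],
                                                "left")
    cohort$exams$laterality[left] <- "right"
    attr(cohort, "mirrored_from_left") <- which(left)
  }
  cohort
}

# ---- Normative tables -------------------------------------------------------

#' Derive normative tables from healthy and glaucoma cohorts
#'
#' From healthy exams: a per-point linear age regression of thresholds
#' (intercept + slope), empirical total- and pattern-deviation percentiles
#' ({5, 2, 1, 0.5}th) and the pointwise mean RNFL profile. From glaucoma
#' exams: pointwise empirical 10th/5th/1st percentile RNFL profiles (linear
#' interpolation between order statistics), floored at the healthy mean so a
#' percentile can never "thicken" a profile.
#'
#' @param healthy,glaucoma `paired_cohort` objects (right-eye convention).
#' @param min_healthy,min_glaucoma Sample sizes below which a warning is
#'   issued.
#' @return Object of class `normative_tables`: list with `age_model` (data
#'   frame point/intercept/slope), `td_percentiles`, `pd_percentiles`
#'   (52 x 4 matrices, columns `p5`,`p2`,`p1`,`p0.5`), `healthy_mean_rnfl`
#'   (768-vector) and `glaucoma_percentiles` (768 x 3, columns `p10`,`p5`,`p1`).
#' @export
derive_normative_tables <- function(healthy, glaucoma,
                                    min_healthy = 50, min_glaucoma = 100) {
  stop_if_not(n_exams(healthy) > 0 && n_exams(glaucoma) > 0,
              "healthy and glaucoma cohorts must be non-empty")
  if (n_exams(healthy) < min_healthy)
    warning(sprintf("only %d healthy exams (< %d recommended)",
                    n_exams(healthy), min_healthy))
  if (n_exams(glaucoma) < min_glaucoma)
    warning(sprintf("only %d glaucoma exams (< %d recommended)",
                    n_exams(glaucoma), min_glaucoma))

  age <- healthy$exams$age_years
  fit <- lm.fit(cbind(1, age), healthy$vf)
  cf <- fit$coefficients                      # 2 x 52
  age_model <- data.frame(point = seq_len(ncol(healthy$vf)),
                          intercept = cf[1, ], slope = cf[2, ])
  rownames(age_model) <- NULL

  normals <- cbind(1, age) %*% cf
  td <- healthy$vf - normals
  gh <- apply(td, 1, function(v) sort(v, decreasing = TRUE)[7])
  pd <- td - gh
  probs <- c(0.05, 0.02, 0.01, 0.005)
  qfun <- function(m) {
    q <- t(apply(m, 2, quantile, probs = probs, type = 7, names = FALSE))
    colnames(q) <- c("p5", "p2", "p1", "p0.5")
    q
  }
  healthy_mean <- colMeans(healthy$rnfl)
  gq <- t(apply(glaucoma$rnfl, 2, quantile, probs = c(0.10, 0.05, 0.01),
                type = 7, names = FALSE))
  gq <- pmin(gq, healthy_mean)                # defect semantics: never thicker
  colnames(gq) <- c("p10", "p5", "p1")

  structure(
    list(age_model = age_model,
         td_percentiles = qfun(td),
         pd_percentiles = qfun(pd),
         healthy_mean_rnfl = healthy_mean,
         glaucoma_percentiles = gq),
    class = "normative_tables"
  )
}

#' @export
print.normative_tables <- function(x, ...) {
  cat(sprintf(paste0("normative tables: age model + TD/PD percentiles for %d",
                     " points; RNFL profiles (healthy mean %.1f um)\n"),
              nrow(x$age_model), mean(x$healthy_mean_rnfl)))
  invisible(x)
}

#' Serialize normative tables to/from JSON
#'
#' @param tables A `normative_tables` object.
#' @param path File path.
#' @export
write_normative_tables <- function(tables, path) {
  jsonlite::write_json(
    list(age_model = tables$age_model,
         td_percentiles = as.data.frame(tables$td_percentiles),
         pd_percentiles = as.data.frame(tables$pd_percentiles),
         healthy_mean_rnfl = tables$healthy_mean_rnfl,
         glaucoma_percentiles = as.data.frame(tables$glaucoma_percentiles)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_normative_tables
#' @export
read_normative_tables <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(age_model = x$age_model,
         td_percentiles = as.matrix(x$td_percentiles),
         pd_percentiles = as.matrix(x$pd_percentiles),
         healthy_mean_rnfl = x$healthy_mean_rnfl,
         glaucoma_percentiles = as.matrix(x$glaucoma_percentiles)),
    class = "normative_tables"
  )
}

# ---- Cohort IO --------------------------------------------------------------

#' Write / read a cohort as plain-text files
#'
#' `exams.csv` holds the metadata, `measurements.csv` the wide-format profiles
#' (`rnfl_000..rnfl_767`) and fields (`vf_00..vf_51`), and `manifest.json` the
#' generator configuration and seed.
#'
#' @param cohort A `paired_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$exams, file.path(dir, "exams.csv"), row.names = FALSE)
  m <- cbind(cohort$rnfl, cohort$vf)
  colnames(m) <- c(sprintf("rnfl_%03d", 0:767), sprintf("vf_%02d", 0:51))
  write.csv(cbind(exam_id = cohort$exams$exam_id, as.data.frame(m)),
            file.path(dir, "measurements.csv"), row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.function, TRUE)],
                       file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  exams <- read.csv(file.path(dir, "exams.csv"))
  exams$test_date_sap <- as.Date(exams$test_date_sap)
  exams$test_date_oct <- as.Date(exams$test_date_oct)
  m <- read.csv(file.path(dir, "measurements.csv"))
  stop_if_not(all(m$exam_id == exams$exam_id), "exam id mismatch")
  cfgl <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(generator_config, cfgl[names(cfgl) %in%
                                          names(formals(generator_config))])
  structure(
    list(exams = exams,
         rnfl = as.matrix(m[, sprintf("rnfl_%03d", 0:767)]),
         vf = as.matrix(m[, sprintf("vf_%02d", 0:51)]),
         vf_true = NULL,
         config = cfg),
    class = "paired_cohort"
  )
}
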