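test_that("null-trained compensator passes a profile through unchanged", {
  set.seed(51)
  P <- 48
  v <- runif(P, 60, 140)
  cv <- list(age = 63, gender = "F", axial_length = 24,
             disc_fovea_distance = 5, disc_fovea_angle = 9)
  params <- null_compensator(P, reference_age = 63)
  out <- compensate_profile(v, cv, params)
  expect_equal(out, v, tolerance = 1e-9)
})

test_that("zero network weights reduce the pipeline to Phase 1 output", {
  set.seed(52)
  P <- 48
  slopes <- runif(P, 0.001, 0.005)
  params <- null_compensator(P, reference_age = 60, slopes = slopes)
  v <- runif(P, 60, 140)
  cv <- list(age = 72, gender = "M", axial_length = 25,
             disc_fovea_distance = 5.5, disc_fovea_angle = 3)
  expect_equal(compensate_profile(v, cv, params),
               apply_age_compensation(v, 72, params$age_model),
               tolerance = 1e-12)
})

test_that("missing covariates are named in the error", {
  params <- null_compensator(16)
  cv <- list(age = 63, gender = "F", axial_length = 24,
             disc_fovea_distance = 5, disc_fovea_angle = NA)
  expect_error(compensate_profile(runif(16, 60, 100), cv, params),
               "disc_fovea_angle")
})

test_that("a trained compensator restores the peaks of a long eye", {
  eff <- null_effects()
  eff$al_peak_convergence <- 6
  eff$al_thinning <- 0.015
  P <- 256
  x <- generate_cohort(300, 0, effects = eff, P = P, seed = 53)
  params <- train_compensator(x, fcn = list(max_iter = 300), seed = 5)

  ref <- reference_covariates()
  long_cv <- ref; long_cv$axial_length <- ref$axial_length + 2
  long_cv$gender <- "F"
  v_long <- render_profile(profile_template(), eff, long_cv, ref, P = P)
  v_ref <- render_profile(profile_template(), eff, ref, ref, P = P)
  comp <- compensate_profile(v_long, long_cv, params)

  peak_idx <- function(v, idx) idx[which.max(v[idx])]
  sup <- which(profile_angles(P) > 20 & profile_angles(P) < 120)
  inf <- which(profile_angles(P) > 240 & profile_angles(P) < 340)
  # uncompensated peaks sit several indices off; compensated within 3
  # (grid resolution 1.4 deg; the 2 mm elongation shifts peaks by 12 deg)
  expect_gt(abs(peak_idx(v_long, sup) - peak_idx(v_ref, sup)), 4)
  expect_lte(abs(peak_idx(comp, sup) - peak_idx(v_ref, sup)), 3)
  expect_lte(abs(peak_idx(comp, inf) - peak_idx(v_ref, inf)), 3)
})

test_that("rotating every training profile rotates the compensation", {
  eff <- null_effects(); eff$dfa_rotation <- 1.5; eff$noise_sd <- 2
  P <- 64
  x <- generate_cohort(80, 0, effects = eff, P = P, seed = 54)
  # rotate by two angular-basis spacings (M = 16 on P = 64) so the RBFN
  # basis is closed under the rotation and equivariance is exact
  shift <- 8
  y <- x
  y$profiles <- x$profiles[, wrap_index(seq_len(P) - shift, P)]

  px <- train_compensator(x, fcn = list(max_iter = 150),
                          rbfn = list(M = 16), seed = 6)
  py <- train_compensator(y, fcn = list(max_iter = 150),
                          rbfn = list(M = 16), seed = 6)
  cx <- compensate(x, px)$profiles
  cy <- compensate(y, py)$profiles
  expect_equal(cy, cx[, wrap_index(seq_len(P) - shift, P)],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("model artifact JSON round trip reproduces the compensator", {
  x <- generate_cohort(60, 0, P = 32, seed = 55)
  params <- train_compensator(x, fcn = list(max_iter = 60), seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_compensator(params, path)
  back <- read_compensator(path)
  v <- generate_cohort(5, 5, P = 32, seed = 56)
  expect_equal(compensate(v, back)$profiles, compensate(v, params)$profiles,
               tolerance = 1e-12)
  expect_equal(back$stage_variance, params$stage_variance,
               ignore_attr = TRUE)
})

test_that("cohort/compensator length mismatches are contract errors", {
  x <- generate_cohort(5, 0, P = 16, seed = 57)
  params <- null_compensator(32)
  expect_error(compensate(x, params), "P = 16")
})
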