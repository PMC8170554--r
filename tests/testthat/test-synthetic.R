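test_that("rendering at the reference covariates reproduces the template", {
  tpl <- profile_template()
  ref <- reference_covariates()
  v <- render_profile(tpl, effect_sizes(), ref, ref, P = 64, noise_sd = 0)
  expect_equal(v, rnflcomp:::template_eval(tpl, profile_angles(64)))
  expect_true(all(v > 0))
})

test_that("ten years of aging thins every point by (1 - 0.003)^10", {
  ref <- reference_covariates()
  cov <- ref; cov$age <- ref$age + 10
  eff <- effect_sizes(al_thinning = 0, al_peak_convergence = 0,
                      dfa_rotation = 0, dfd_scale = 0, gender_offset = 0,
                      noise_sd = 0, individual_sd = 0)
  v_ref <- render_profile(profile_template(), eff, ref, ref, P = 64)
  v_old <- render_profile(profile_template(), eff, cov, ref, P = 64)
  expect_equal(v_old / v_ref, rep(0.997^10, 64), tolerance = 1e-12)
})

test_that("axial elongation converges the bundle peaks toward temporal", {
  ref <- reference_covariates()
  cov <- ref; cov$axial_length <- ref$axial_length + 2
  eff <- null_effects(); eff$al_peak_convergence <- 2   # 2 deg per mm
  P <- 1440                                             # 0.25 deg grid
  v_ref <- render_profile(profile_template(), eff, ref, ref, P = P)
  v_long <- render_profile(profile_template(), eff, cov, ref, P = P)
  ang <- profile_angles(P)
  peak_near <- function(v, lo, hi) ang[which(ang >= lo & ang <= hi)[
    which.max(v[ang >= lo & ang <= hi])]]
  # superotemporal peak moves from +70 toward 0 by 4 degrees
  expect_equal(peak_near(v_long, 30, 110), peak_near(v_ref, 30, 110) - 4,
               tolerance = 0.3)
  # inferotemporal peak (at 290) moves toward 360
  expect_equal(peak_near(v_long, 250, 330), peak_near(v_ref, 250, 330) + 4,
               tolerance = 0.3)
})

test_that("profile rotation follows the disc-fovea angle", {
  ref <- reference_covariates()
  cov <- ref; cov$disc_fovea_angle <- ref$disc_fovea_angle + 9
  eff <- null_effects(); eff$dfa_rotation <- 1
  P <- 360
  v_ref <- render_profile(profile_template(), eff, ref, ref, P = P)
  v_rot <- render_profile(profile_template(), eff, cov, ref, P = P)
  # rotated render equals the reference sampled 9 degrees earlier
  expect_equal(v_rot, v_ref[wrap_index(seq_len(P) - 9, P)], tolerance = 1e-9)
})

test_that("defect injection carves a tapered wedge and diffuse loss", {
  v <- rep(100, 360)
  expect_equal(inject_defect(v, 90, 30, 0, 0), v)
  expect_equal(inject_defect(v, 90, 30, 0, 0.5), v / 2)
  d <- inject_defect(v, 90, 30, 0.6, 0)
  ang <- profile_angles(360)
  expect_equal(min(d), 40)
  expect_equal(ang[which.min(d)], 90)
  outside <- abs(rnflcomp:::angle_diff(ang, 90)) > 15
  expect_equal(d[outside], v[outside])
  inside <- abs(rnflcomp:::angle_diff(ang, 90)) < 15 &
    abs(rnflcomp:::angle_diff(ang, 90)) > 0
  expect_true(all(d[inside] < 100 & d[inside] >= 40))
})

test_that("sampled covariates match the configured marginals", {
  dn <- covariate_distribution("normal")
  cv <- sample_covariates(dn, 1e4, seed = 42)
  se <- function(v) v[2] / sqrt(1e4)
  expect_lt(abs(mean(cv$axial_length) - 23.18), 3 * se(dn$axial_length))
  expect_lt(abs(mean(cv$disc_fovea_distance) - 4.88),
            3 * se(dn$disc_fovea_distance))
  expect_lt(abs(mean(cv$disc_fovea_angle) - 7.59),
            3 * se(dn$disc_fovea_angle))
  expect_lt(abs(mean(cv$gender == "M") - 0.434), 3 * 0.005)
  # age is truncated asymmetrically at the 50-year inclusion bound, which
  # biases the realized mean upward by ~1.5 years
  expect_gt(mean(cv$age), 62.3)
  expect_lt(mean(cv$age), 65)
  expect_true(all(cv$axial_length >= 18.96 & cv$axial_length <= 28.87))

  dg <- covariate_distribution("glaucoma")
  cg <- sample_covariates(dg, 1e4, seed = 42)
  expect_lt(abs(mean(cg$axial_length) - 23.77), 3 * se(dg$axial_length))
  expect_lt(abs(mean(cg$gender == "M") - 0.543), 3 * 0.005)
})

test_that("cohort generation is deterministic and labels its groups", {
  a <- generate_cohort(12, 8, P = 32, seed = 7)
  b <- generate_cohort(12, 8, P = 32, seed = 7)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$covariates, b$covariates)
  expect_equal(table(a$covariates$label)[["normal"]], 12)
  expect_equal(table(a$covariates$label)[["glaucoma"]], 8)
  expect_true(all(a$covariates$quality_score >= 15))
  c <- generate_cohort(12, 8, P = 32, seed = 8)
  expect_false(identical(a$profiles, c$profiles))
})

test_that("with all effects off, normative profiles are identical", {
  x <- generate_cohort(10, 0, effects = null_effects(), P = 48, seed = 3)
  expect_lt(max(apply(x$profiles, 2, sd)), 1e-12)
})

test_that("defects strictly thin the affected eye", {
  set.seed(4)
  v <- render_profile(profile_template(), null_effects(),
                      reference_covariates(), P = 128)
  d <- sample_defects(20)
  for (j in 1:20) {
    w <- inject_defect(v, d$center_angle[j], d$width[j],
                       d$depth_fraction[j], d$diffuse_fraction[j])
    expect_lt(mean(w), mean(v))
  }
})

test_that("impossible effect configurations are rejected", {
  ref <- reference_covariates()
  cov <- ref; cov$axial_length <- ref$axial_length + 3
  eff <- null_effects(); eff$al_thinning <- 0.5
  expect_error(render_profile(profile_template(), eff, cov, ref, P = 32),
               "non-positive")
})
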