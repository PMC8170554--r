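test_that("normative limits: degenerate, order-statistic, and Gaussian cases", {
  const <- matrix(100, 100, 3)
  expect_equal(fit_normative_limits(const, "empirical_p5")$lower_bound,
               rep(100, 3))
  expect_equal(fit_normative_limits(const, "gaussian_1645")$lower_bound,
               rep(100, 3))

  # 1..100 at one point: interpolated 5th percentile is 5.95
  m <- matrix(1:100, 100, 2)
  expect_equal(fit_normative_limits(m, "empirical_p5")$lower_bound[1], 5.95)

  set.seed(61)
  g <- matrix(rnorm(1e5, 100, 10), 1e5, 1)
  b <- fit_normative_limits(g, "gaussian_1645")$lower_bound
  expect_lt(abs(b - 83.55), 0.2)

  expect_error(fit_normative_limits(matrix(100, 10, 4), "empirical_p5"),
               "gaussian_1645")
})

test_that("limits are monotone in the percentile", {
  set.seed(62)
  m <- matrix(rnorm(50 * 8, 100, 12), 50, 8)
  b5 <- fit_normative_limits(m, percentile = 0.05)$lower_bound
  b10 <- fit_normative_limits(m, percentile = 0.10)$lower_bound
  b25 <- fit_normative_limits(m, percentile = 0.25)$lower_bound
  expect_true(all(b5 <= b10) && all(b10 <= b25))
})

test_that("detection score counts the longest circular run below limit", {
  lim <- structure(list(lower_bound = rep(50, 768), method = "empirical_p5",
                        percentile = 0.05, reference_n = 100, P = 768),
                   class = "normative_limits")
  expect_equal(detection_score(rep(60, 768), lim), 0)
  expect_equal(detection_score(rep(40, 768), lim), 768)
  v <- rep(60, 768)
  v[c(766, 767, 768, 1, 2)] <- 40      # indices 765..767, 0, 1 (0-based)
  expect_equal(detection_score(v, lim), 5)
  v2 <- rep(60, 768)
  v2[10] <- 50                          # exactly at the bound: not below
  expect_equal(detection_score(v2, lim), 0)
})

test_that("detection score agrees with the brute-force oracle", {
  set.seed(63)
  for (rep_i in 1:200) {
    P <- sample(4:64, 1)
    below <- runif(P) < runif(1, 0.1, 0.9)
    lim <- structure(list(lower_bound = rep(0.5, P), method = "empirical_p5",
                          percentile = 0.05, reference_n = 100, P = P),
                     class = "normative_limits")
    v <- ifelse(below, 0, 1)
    expect_identical(as.integer(detection_score(v, lim)),
                     as.integer(brute_circular_run(below)))
  }
})

test_that("ROC handles separation, ties, and degenerate scores", {
  expect_equal(roc_curve(c(0, 1, 5, 9),
                         c("normal", "normal", "glaucoma", "glaucoma"))$auroc, 1)
  expect_equal(roc_curve(c(1, 2, 2, 3),
                         c("normal", "normal", "glaucoma", "glaucoma"))$auroc,
               0.875)
  expect_equal(roc_curve(rep(3, 6), rep(c("normal", "glaucoma"), 3))$auroc, 0.5)
  expect_error(roc_curve(1:4, rep("normal", 4)), "both classes")
})

test_that("AUROC equals pair counting and the trapezoidal curve area", {
  set.seed(64)
  for (rep_i in 1:25) {
    n <- sample(10:50, 1)
    labels <- c(rep("normal", ceiling(n / 2)), rep("glaucoma", floor(n / 2)))
    scores <- sample(0:12, n, replace = TRUE)
    r <- roc_curve(scores, labels)
    expect_equal(r$auroc, pair_count_auroc(scores, labels), tolerance = 1e-12)
    # trapezoid over the stored operating points
    o <- r$points[order(r$points$fpr, r$points$sensitivity), ]
    area <- sum(diff(o$fpr) * (head(o$sensitivity, -1) + tail(o$sensitivity, -1)) / 2)
    expect_equal(r$auroc, area, tolerance = 1e-12)
  }
})

test_that("AUROC matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  scores <- c(rnorm(30, 5, 3), rnorm(25, 8, 3))
  labels <- c(rep("normal", 30), rep("glaucoma", 25))
  ours <- roc_curve(scores, labels)$auroc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("normal", "glaucoma"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("threshold metrics reproduce their defining arithmetic", {
  p <- performance_at(c(0, 0, 9, 9), c("normal", "normal", "glaucoma", "glaucoma"), 5)
  expect_equal(unlist(p[c("accuracy", "sensitivity", "specificity", "ppv", "npv")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  # tp=3 fp=1 tn=4 fn=2
  scores <- c(7, 7, 7, 2, 2, 6, 1, 1, 1, 1)
  labels <- c(rep("glaucoma", 5), rep("normal", 5))
  p <- performance_at(scores, labels, 5)
  expect_equal(p$tp, 3); expect_equal(p$fn, 2)
  expect_equal(p$fp, 1); expect_equal(p$tn, 4)
  expect_equal(p$sensitivity, 0.6)
  expect_equal(p$specificity, 0.8)
  expect_equal(p$ppv, 0.75)
  expect_equal(p$npv, 2 / 3)
  expect_equal(p$accuracy, 0.7)

  hi <- performance_at(scores, labels, 100)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_true(is.nan(hi$ppv))
})

test_that("axial-length subgroups take the longest eyes deterministically", {
  x <- generate_cohort(40, 40, P = 16, seed = 66)
  expect_equal(al_subgroup(x, 1)$covariates$eye_id, x$covariates$eye_id)
  s <- al_subgroup(x, 0.1)
  expect_equal(n_eyes(s), 8)
  expect_gt(mean(s$covariates$axial_length), mean(x$covariates$axial_length))
  expect_gte(min(s$covariates$axial_length),
             sort(x$covariates$axial_length, decreasing = TRUE)[9])
  expect_identical(al_subgroup(x, 0.1)$covariates, s$covariates)
})

test_that("relative AUROC gain is the printed percentage", {
  expect_equal(relative_auroc_gain(0.5, 0.5), 0)
  expect_equal(relative_auroc_gain(0.70, 0.84), 20)
  g1 <- relative_auroc_gain(0.70, 0.9)
  g2 <- relative_auroc_gain(0.80, 0.9)
  expect_gt(g1, g2)
})

test_that("group mean profile is the pointwise average", {
  expect_equal(group_mean_profile(matrix(5, 1, 4)), rep(5, 4))
  expect_equal(group_mean_profile(rbind(rep(0, 4), rep(2, 4))), rep(1, 4))
  set.seed(67)
  m <- matrix(runif(60), 12, 5)
  expect_equal(group_mean_profile(m),
               apply(m, 2, function(v) sum(v) / length(v)),
               tolerance = 1e-12)
})
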