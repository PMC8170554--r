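#' Per-point one-sided lower normative limits
#'
#' For each angular position, the one-sided 95% lower bound of thickness in
#' a reference set of healthy profiles: either the empirical 5th percentile
#' (linearly interpolated order statistic, `stats::quantile()` type 7) or
#' the Gaussian bound `mean - 1.645 * SD`.
#'
#' @param profiles matrix of reference normal profiles (eyes x positions),
#'   or an `rnfl_cohort` (its profiles are used)
#' @param method `"empirical_p5"` (default) or `"gaussian_1645"`
#' @param percentile lower tail probability of the empirical bound
#' @return an object of class `normative_limits`: `lower_bound` (length
#'   `P`), `method`, `percentile`, `reference_n`
#' @export
fit_normative_limits <- function(profiles,
                                 method = c("empirical_p5", "gaussian_1645"),
                                 percentile = 0.05) {
  method <- match.arg(method)
  if (inherits(profiles, "rnfl_cohort")) profiles <- profiles$profiles
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (method == "empirical_p5" && n < 20)
    stop("empirical_p5 needs >= 20 reference profiles (got ", n,
         "); use method = 'gaussian_1645'")
  lb <- switch(method,
    empirical_p5 = apply(profiles, 2, stats::quantile,
                         probs = percentile, type = 7, names = FALSE),
    gaussian_1645 = colMeans(profiles) - 1.645 * apply(profiles, 2, stats::sd))
  structure(list(lower_bound = pmax(lb, 0), method = method,
                 percentile = percentile, reference_n = n,
                 P = ncol(profiles)),
            class = "normative_limits")
}

#' Consecutive-points-below-limit detection score
#'
#' The detector marks an eye by how long a stretch of its profile dips
#' below the normative floor: the score is the maximum length of a
#' *circular* run of consecutive points strictly below the per-point lower
#' bound (a run may wrap across the temporal origin).  0 when no point is
#' below; `P` when the whole profile is.  Points exactly on the bound count
#' as not below.
#'
#' @param values profile vector, um
#' @param limits a `normative_limits` of matching length
#' @return integer run length in `0..P`
#' @export
detection_score <- function(values, limits) {
  stopifnot(inherits(limits, "normative_limits"),
            length(values) == length(limits$lower_bound))
  below <- values < limits$lower_bound
  P <- length(below)
  if (!any(below)) return(0L)
  if (all(below)) return(P)
  r <- rle(c(below, below))            # doubling captures the wrap-around run
  max(r$lengths[r$values])
}

# detection scores for every row of a profile matrix / cohort
detection_scores <- function(profiles, limits) {
  if (inherits(profiles, "rnfl_cohort")) profiles <- profiles$profiles
  apply(profiles, 1, detection_score, limits = limits)
}

#' ROC curve and AUROC of a detection score
#'
#' Sweeps every distinct score value as the decision threshold (classify
#' glaucoma when `score >= t`) and records the operating points.  The AUROC
#' is the Mann-Whitney probability that a random glaucomatous eye scores
#' higher than a random normal eye, with ties counted 1/2 - identical to
#' the trapezoidal area under the stored operating points.
#'
#' @param scores numeric vector of per-eye scores (higher = more
#'   glaucoma-like)
#' @param labels matching vector with values `"normal"` / `"glaucoma"`
#' @return an object of class `roc_result`: data frame `points` with
#'   columns `threshold`, `sensitivity`, `fpr`, and the scalar `auroc`
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  is_g <- labels == "glaucoma"
  n1 <- sum(is_g); n0 <- sum(!is_g)
  if (n1 == 0 || n0 == 0)
    stop("ROC needs both classes present (got ", n1, " glaucoma, ",
         n0, " normal)")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[is_g] >= t), 0),
    fpr = vapply(thr, function(t) mean(scores[!is_g] >= t), 0))
  r <- rank(scores)                     # midranks handle ties as 1/2
  auroc <- (sum(r[is_g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = pts, auroc = auroc), class = "roc_result")
}

#' Classification metrics at a fixed run-length threshold
#'
#' Confusion counts for the rule "glaucoma when `score >= threshold`" and
#' the derived proportions.  A ratio with a zero denominator is reported as
#' `NaN`; the counts disambiguate.
#'
#' @param scores,labels as in [roc_curve()]
#' @param threshold decision threshold on the score
#' @return an object of class `performance_report`: `tp`, `fp`, `tn`, `fn`,
#'   `threshold`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#' @export
performance_at <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  is_g <- labels == "glaucoma"
  if (!any(is_g) || all(is_g)) stop("need both classes present")
  pos <- scores >= threshold
  tp <- sum(pos & is_g); fp <- sum(pos & !is_g)
  fn <- sum(!pos & is_g); tn <- sum(!pos & !is_g)
  ratio <- function(a, b) if (b == 0) NaN else a / b
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold,
                 accuracy = (tp + tn) / length(scores),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn)),
            class = "performance_report")
}

#' Longest-axial-length subgroup of a cohort
#'
#' Returns the `ceiling(fraction * n)` records with the longest axial
#' length, ties broken by `eye_id` so the subgroup is deterministic.  Both
#' labels are retained: subgroup AUROCs compare glaucoma vs normal within
#' the long-eyed stratum.
#'
#' @param x an `rnfl_cohort`
#' @param fraction proportion of eyes to keep, in `(0, 1]`
#' @return the subgroup `rnfl_cohort`
#' @export
al_subgroup <- function(x, fraction) {
  stopifnot(inherits(x, "rnfl_cohort"), fraction > 0, fraction <= 1)
  n <- n_eyes(x)
  m <- ceiling(fraction * n)
  ord <- order(-x$covariates$axial_length, x$covariates$eye_id)
  x[sort(ord[seq_len(m)])]
}

#' Relative AUROC gain, percent
#'
#' @param auroc_before,auroc_after AUROCs in `(0, 1]`
#' @return `100 * (after - before) / before`
#' @export
relative_auroc_gain <- function(auroc_before, auroc_after) {
  stopifnot(auroc_before > 0, auroc_before <= 1,
            auroc_after > 0, auroc_after <= 1)
  100 * (auroc_after - auroc_before) / auroc_before
}

#' Pointwise mean profile of a group of eyes
#'
#' @param profiles matrix (eyes x positions) or `rnfl_cohort`
#' @return numeric vector of length `P`
#' @export
group_mean_profile <- function(profiles) {
  if (inherits(profiles, "rnfl_cohort")) profiles <- profiles$profiles
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 1)
  colMeans(profiles)
}

#' Evaluate original vs compensated detection on a validation cohort
#'
#' Builds normative limits from the training normals (original profiles for
#' the original arm, compensated profiles for the compensated arm - limits
#' are never refit on validation data), scores every validation eye with the
#' circular run-length detector, and reports before/after ROC results for
#' each axial-length percentile subgroup, together with the mean absolute
#' compensation magnitude and threshold metrics.
#'
#' @param train_normals `rnfl_cohort` of normative training eyes
#' @param validation `rnfl_cohort` containing both labels
#' @param params a `compensator_params`
#' @param fractions axial-length subgroup fractions to report
#' @param method normative-limit method, see [fit_normative_limits()]
#' @param run_threshold run length used for the fixed-threshold metrics
#' @return an object of class `evaluation_report`: per-subgroup list with
#'   `n`, `n_glaucoma`, `mean_axial_length`, `auroc_original`,
#'   `auroc_compensated`, `relative_gain_pct`, `mean_abs_compensation`,
#'   and `metrics_original` / `metrics_compensated`
#'   ([performance_at()] results at `run_threshold`)
#' @export
evaluate_compensation <- function(train_normals, validation, params,
                                  fractions = c(0.1, 0.2, 0.3, 1.0),
                                  method = "empirical_p5",
                                  run_threshold = 30) {
  stopifnot(inherits(train_normals, "rnfl_cohort"),
            inherits(validation, "rnfl_cohort"))
  if (validation$P != params$P)
    stop("validation P = ", validation$P,
         " but compensator was trained at P = ", params$P)
  comp_train <- compensate(train_normals, params)
  comp_val <- compensate(validation, params)
  limits_orig <- fit_normative_limits(train_normals, method = method)
  limits_comp <- fit_normative_limits(comp_train, method = method)
  scores_orig <- detection_scores(validation, limits_orig)
  scores_comp <- detection_scores(comp_val, limits_comp)
  abs_comp <- rowMeans(abs(comp_val$profiles - validation$profiles))

  subgroups <- lapply(fractions, function(f) {
    sub <- al_subgroup(validation, f)
    idx <- match(sub$covariates$eye_id, validation$covariates$eye_id)
    lab <- sub$covariates$label
    both <- length(unique(lab)) == 2
    out <- list(fraction = f,
                n = length(idx),
                n_glaucoma = sum(lab == "glaucoma"),
                mean_axial_length = mean(sub$covariates$axial_length),
                auroc_original = NA_real_,
                auroc_compensated = NA_real_,
                relative_gain_pct = NA_real_,
                mean_abs_compensation = mean(abs_comp[idx]),
                metrics_original = NULL,
                metrics_compensated = NULL)
    if (both) {          # a tiny subgroup may hold one class only
      ro <- roc_curve(scores_orig[idx], lab)
      rc <- roc_curve(scores_comp[idx], lab)
      out$auroc_original <- ro$auroc
      out$auroc_compensated <- rc$auroc
      out$relative_gain_pct <- relative_auroc_gain(ro$auroc, rc$auroc)
      out$metrics_original <- performance_at(scores_orig[idx], lab,
                                             run_threshold)
      out$metrics_compensated <- performance_at(scores_comp[idx], lab,
                                                run_threshold)
    }
    out
  })
  names(subgroups) <- paste0("top_", round(100 * fractions), "pct")
  structure(list(subgroups = subgroups,
                 run_threshold = run_threshold,
                 method = method,
                 mean_profile_original = group_mean_profile(validation),
                 mean_profile_compensated = group_mean_profile(comp_val)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (limits:", x$method,
      "; run threshold:", x$run_threshold, ")\n")
  for (nm in names(x$subgroups)) {
    s <- x$subgroups[[nm]]
    cat(sprintf(
      "  %-10s n=%4d  AUROC %.3f -> %.3f  (gain %+.1f%%)  |comp| %.2f um\n",
      nm, s$n, s$auroc_original, s$auroc_compensated,
      s$relative_gain_pct, s$mean_abs_compensation))
  }
  invisible(x)
}
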