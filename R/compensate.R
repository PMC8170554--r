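#' Train the full two-phase profile compensator
#'
#' Runs the complete normative training pipeline on a cohort of healthy
#' eyes: Phase 1 fits the circularly smooth per-point age-slope field
#' ([fit_age_model()]) and age-normalizes every profile; Phase 2 first
#' trains the fully connected scale/shift network ([train_fcn()]) on the
#' age-compensated profiles, applies its removal, then fits the residual
#' radial basis function network ([train_rbfn()]) on the result.  The summed
#' per-point across-subject variance is recorded after every stage.
#'
#' @param x an `rnfl_cohort` of normative eyes
#' @param reference_age,smoothing_lambda passed to [fit_age_model()]
#' @param fcn list of overrides for [train_fcn()] (e.g. `gamma`, `max_iter`)
#' @param rbfn list of overrides for [train_rbfn()] (e.g. `K`, `M`, `ridge`)
#' @param seed master seed; per-stage seeds are derived from it
#' @return an object of class `compensator_params`: `age_model`,
#'   `fcn` (`fcn_params`), `rbfn` (`rbfn_params`), `P`, and
#'   `stage_variance`, the summed per-point variance of the training
#'   profiles at the four pipeline taps (raw, age-compensated,
#'   scale/shift-compensated, residual-compensated)
#' @export
train_compensator <- function(x, reference_age = NULL,
                              smoothing_lambda = NULL,
                              fcn = list(), rbfn = list(), seed = 1) {
  stopifnot(inherits(x, "rnfl_cohort"))
  if (any(x$covariates$label != "normal"))
    stop("compensator must be trained on normative eyes only")

  v_of <- function(m) sum(apply(m, 2, stats::var))
  age_model <- fit_age_model(x, reference_age, smoothing_lambda)
  Y1 <- age_compensate_matrix(x, age_model)

  fcn_args <- utils::modifyList(
    list(profiles = Y1, covariates = x$covariates,
         seed = derive_seed(seed, 1)), fcn)
  fcn_params <- do.call(train_fcn, fcn_args)
  pred <- fcn_predict(fcn_params, x$covariates)
  Y2 <- scale_shift_matrix(Y1, pred$s, pred$delta)

  X <- covariate_design(x$covariates, std = fcn_params$std)$X
  rbfn_args <- utils::modifyList(
    list(profiles = Y2, X = X, seed = derive_seed(seed, 2)), rbfn)
  rbfn_params <- do.call(train_rbfn, rbfn_args)
  Y3 <- pmax(Y2 - rbfn_design(X, rbfn_params), 0)

  structure(list(age_model = age_model, fcn = fcn_params,
                 rbfn = rbfn_params, P = x$P,
                 stage_variance = c(raw = v_of(x$profiles),
                                    age = v_of(Y1),
                                    scale_shift = v_of(Y2),
                                    residual = v_of(Y3))),
            class = "compensator_params")
}

#' @export
print.compensator_params <- function(x, ...) {
  cat("compensator_params: P =", x$P, "\n")
  cat("  stage variance (sum over points):\n")
  print(round(x$stage_variance, 2))
  invisible(x)
}

#' Compensate one profile for its covariates
#'
#' The deterministic three-step pipeline: age normalization, removal of the
#' network-predicted vertical scale and horizontal shift, subtraction of the
#' smooth residual field, clipped at 0 um.
#'
#' @param values profile vector, um
#' @param covariates one-row list/data frame with `age`, `gender`,
#'   `axial_length`, `disc_fovea_distance`, `disc_fovea_angle`
#' @param params a `compensator_params` from [train_compensator()]
#' @return the compensated profile vector
#' @export
compensate_profile <- function(values, covariates, params) {
  stopifnot(inherits(params, "compensator_params"),
            length(values) == params$P)
  for (f in c("age", "gender", "axial_length", "disc_fovea_distance",
              "disc_fovea_angle"))
    if (is.null(covariates[[f]]) || is.na(covariates[[f]]))
      stop("missing covariate: ", f)
  y <- apply_age_compensation(values, covariates$age, params$age_model)
  pred <- fcn_predict(params$fcn, as.data.frame(covariates))
  y <- apply_scale_shift(y, pred$s, pred$delta)
  x <- covariate_design(as.data.frame(covariates), std = params$fcn$std)$X
  pmax(y - rbfn_design(as.numeric(x), params$rbfn), 0)
}

#' Compensate every profile of a cohort
#'
#' @param x an `rnfl_cohort`
#' @param params a `compensator_params`
#' @return a cohort with the same covariates and compensated profiles
#' @export
compensate <- function(x, params) {
  stopifnot(inherits(x, "rnfl_cohort"), inherits(params, "compensator_params"))
  if (x$P != params$P)
    stop("cohort P = ", x$P, " but compensator was trained at P = ", params$P)
  cv <- x$covariates
  for (f in c("age", "gender", "axial_length", "disc_fovea_distance",
              "disc_fovea_angle"))
    if (anyNA(cv[[f]])) stop("missing covariate: ", f)
  Y <- age_compensate_matrix(x, params$age_model)
  pred <- fcn_predict(params$fcn, cv)
  Y <- scale_shift_matrix(Y, pred$s, pred$delta)
  X <- covariate_design(cv, std = params$fcn$std)$X
  Y <- pmax(Y - rbfn_design(X, params$rbfn), 0)
  cohort(Y, cv)
}

# ---- JSON artifact ---------------------------------------------------------

#' Write a trained compensator to a JSON artifact
#'
#' All weights, centers, standardization constants and stage variances are
#' stored at full double precision, so a write/read round trip reproduces
#' the compensator exactly.
#'
#' @param params a `compensator_params`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_compensator <- function(params, path) {
  stopifnot(inherits(params, "compensator_params"))
  art <- list(
    package = "rnflcomp",
    version = as.character(utils::packageVersion("rnflcomp")),
    P = params$P,
    stage_variance = as.list(params$stage_variance),
    age_model = list(slopes = params$age_model$slopes,
                     reference_age = params$age_model$reference_age,
                     smoothing_lambda = params$age_model$smoothing_lambda,
                     point_means = params$age_model$point_means),
    fcn = list(W = lapply(params$fcn$W, identity),
               b = params$fcn$b,
               hidden = params$fcn$hidden,
               s_max = params$fcn$s_max,
               delta_max = params$fcn$delta_max,
               offset = params$fcn$offset,
               gamma = params$fcn$gamma,
               std = list(center = as.list(params$fcn$std$center),
                          scale = as.list(params$fcn$std$scale)),
               trajectory = params$fcn$trajectory),
    rbfn = list(centers = params$rbfn$centers,
                cov_bandwidth = params$rbfn$cov_bandwidth,
                ang_width = params$rbfn$ang_width,
                M = params$rbfn$M,
                V = params$rbfn$V,
                ridge = params$rbfn$ridge,
                mu = params$rbfn$mu))
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a compensator back from its JSON artifact
#'
#' @param path path written by [write_compensator()]
#' @return a `compensator_params`
#' @export
read_compensator <- function(path) {
  art <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- art$P
  age_model <- structure(list(slopes = art$age_model$slopes,
                              reference_age = art$age_model$reference_age,
                              smoothing_lambda = art$age_model$smoothing_lambda,
                              point_means = art$age_model$point_means,
                              P = P),
                         class = "age_model")
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  fcn <- structure(list(W = lapply(art$fcn$W, as_mat),
                        b = lapply(art$fcn$b, as.numeric),
                        hidden = art$fcn$hidden,
                        s_max = art$fcn$s_max,
                        delta_max = art$fcn$delta_max,
                        offset = as.numeric(art$fcn$offset),
                        std = list(center = unlist(art$fcn$std$center),
                                   scale = unlist(art$fcn$std$scale)),
                        gamma = art$fcn$gamma, P = P,
                        trajectory = art$fcn$trajectory,
                        n_iter = length(art$fcn$trajectory) - 1),
                   class = "fcn_params")
  rbfn <- structure(list(centers = as_mat(art$rbfn$centers),
                         cov_bandwidth = art$rbfn$cov_bandwidth,
                         ang_width = art$rbfn$ang_width,
                         M = art$rbfn$M,
                         Psi = angular_basis(P, art$rbfn$M, art$rbfn$ang_width),
                         V = as_mat(art$rbfn$V),
                         ridge = art$rbfn$ridge,
                         mu = art$rbfn$mu, P = P),
                    class = "rbfn_params")
  structure(list(age_model = age_model, fcn = fcn, rbfn = rbfn, P = P,
                 stage_variance = unlist(art$stage_variance)),
            class = "compensator_params")
}
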