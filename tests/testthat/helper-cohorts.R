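# shared fixtures, built in code

# effect configuration with every covariate influence switched off
null_effects <- function(noise_sd = 0) {
  effect_sizes(age_rate = 0, al_thinning = 0, al_peak_convergence = 0,
               dfa_rotation = 0, dfd_scale = 0, gender_offset = 0,
               noise_sd = noise_sd, individual_sd = 0)
}

# tiny hand-assembled cohort
toy_cohort <- function(profiles, age = NULL, label = "normal",
                       axial_length = 23, quality = 20) {
  n <- nrow(profiles)
  cohort(profiles,
         data.frame(eye_id = sprintf("t%02d", seq_len(n)),
                    age = age %||% seq(55, 75, length.out = n),
                    gender = rep_len(c("M", "F"), n),
                    axial_length = rep_len(axial_length, n),
                    disc_fovea_distance = 4.9,
                    disc_fovea_angle = 7.6,
                    quality_score = quality,
                    label = rep_len(label, n),
                    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force maximum circular run of TRUE, O(P^2)
brute_circular_run <- function(below) {
  P <- length(below)
  if (all(below)) return(P)
  best <- 0
  for (start in seq_len(P)) {
    len <- 0
    for (k in seq_len(P)) {
      if (below[((start + k - 2) %% P) + 1]) len <- len + 1 else break
    }
    best <- max(best, len)
  }
  best
}

# pair-counting Mann-Whitney AUROC with ties at 1/2
pair_count_auroc <- function(scores, labels) {
  g <- scores[labels == "glaucoma"]
  h <- scores[labels == "normal"]
  tot <- 0
  for (a in g) for (b in h) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(g) * length(h))
}

# compensator with all network weights zero: the full pipeline must then
# reduce to the identity (at reference age) / to Phase 1 alone
null_compensator <- function(P, reference_age = 63, slopes = rep(0, P)) {
  sizes <- c(4, 16, 16, 2)
  W <- list(); b <- list()
  for (l in 1:3) {
    W[[l]] <- matrix(0, sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  age_model <- structure(list(slopes = slopes, reference_age = reference_age,
                              smoothing_lambda = 1, point_means = rep(0, P),
                              P = P),
                         class = "age_model")
  fcn <- structure(list(W = W, b = b, hidden = c(16, 16), s_max = 1,
                        delta_max = P / 8, offset = c(0, 0),
                        std = list(center = c(axial_length = 23.18,
                                              disc_fovea_distance = 4.88,
                                              disc_fovea_angle = 7.59),
                                   scale = c(0.96, 0.27, 3.4)),
                        gamma = 10, P = P, trajectory = 0, n_iter = 0),
                   class = "fcn_params")
  rbfn <- structure(list(centers = matrix(0, 2, 4), cov_bandwidth = 1,
                         ang_width = P / 8, M = 4,
                         Psi = rnflcomp:::angular_basis(P, 4, P / 8),
                         V = matrix(0, 2, 4), ridge = 1, mu = rep(0, P),
                         P = P),
                    class = "rbfn_params")
  structure(list(age_model = age_model, fcn = fcn, rbfn = rbfn, P = P,
                 stage_variance = c(raw = 0, age = 0, scale_shift = 0,
                                    residual = 0)),
            class = "compensator_params")
}

# the full-scale default experiment, computed once per test run
default_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train <- generate_cohort(2223, 0, seed = derive_seed(1, 1))
      val <- generate_cohort(254, 254, seed = derive_seed(1, 2))
      params <- train_compensator(train, seed = derive_seed(1, 3))
      report <- evaluate_compensation(train, val, params)
      cache <<- list(train = train, val = val, params = params,
                     report = report)
    }
    cache
  }
})
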