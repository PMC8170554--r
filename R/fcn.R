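#' Apply a vertical scale and horizontal circular shift to a profile
#'
#' The elementary compensation move of Phase 2: the profile is multiplied by
#' `exp(-s)` and resampled at circularly wrapped positions `i + delta` with
#' circular linear interpolation.  `(s, delta)` is the deformation the
#' network attributes to the eye's covariates, so applying `exp(-s)` and the
#' `+delta` resampling removes it; `s = 0, delta = 0` is the exact identity.
#'
#' @param values profile vector, um
#' @param s log vertical scale of the deformation to remove
#' @param delta horizontal shift of the deformation to remove, in (real)
#'   index units; `delta = P` is a full turn
#' @return the transformed profile vector
#' @export
apply_scale_shift <- function(values, s, delta) {
  P <- length(values)
  k <- floor(delta)
  f <- delta - k
  i0 <- wrap_index(seq_len(P) + k, P)
  i1 <- wrap_index(seq_len(P) + k + 1, P)
  exp(-s) * ((1 - f) * values[i0] + f * values[i1])
}

# ---- small fully connected network: covariates -> (s, delta) --------------

# standardized covariate design matrix: z-scored axial length, disc-fovea
# distance and angle, plus a 0/1 gender code
covariate_design <- function(covariates, std = NULL) {
  cont <- as.matrix(covariates[, c("axial_length", "disc_fovea_distance",
                                   "disc_fovea_angle")])
  if (is.null(std))
    std <- list(center = colMeans(cont), scale = apply(cont, 2, stats::sd))
  scale_safe <- ifelse(std$scale > 0, std$scale, 1)
  Z <- sweep(sweep(cont, 2, std$center), 2, scale_safe, "/")
  X <- cbind(Z, gender = gender_code(covariates$gender))
  list(X = X, std = std)
}

# Glorot-uniform initialization of the layer weights; the output layer is
# scaled down so training starts near the identity transform (large random
# initial shifts would place eyes outside the attraction basin of their true
# displacement)
fcn_init <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  L <- length(sizes) - 1
  for (l in seq_len(L)) {
    a <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -a, a),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  W[[L]] <- 0.01 * W[[L]]
  list(W = W, b = b)
}

# forward pass; returns squashed outputs and cached activations.  `offset`
# (length 2) is subtracted from the squashed outputs: during training it is
# the running batch mean (identifiability by construction), at prediction
# time the frozen training mean.
fcn_forward <- function(theta, X, s_max, delta_max, offset = c(0, 0)) {
  H <- list(X)
  L <- length(theta$W)
  A <- X
  for (l in seq_len(L)) {
    A <- sweep(A %*% theta$W[[l]], 2, theta$b[[l]], "+")
    if (l < L) A <- tanh(A)
    H[[l + 1]] <- A
  }
  list(s = s_max * tanh(A[, 1]) - offset[1],
       delta = delta_max * tanh(A[, 2]) - offset[2],
       O = A, H = H)
}

# backward pass: gradients of the loss given dL/ds and dL/ddelta
fcn_backward <- function(theta, fw, g_s, g_d, s_max, delta_max) {
  L <- length(theta$W)
  dO <- cbind(g_s * s_max * (1 - tanh(fw$O[, 1])^2),
              g_d * delta_max * (1 - tanh(fw$O[, 2])^2))
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dO
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(theta$W[[l]])) * (1 - fw$H[[l]]^2)
  }
  list(W = gW, b = gb)
}

theta_axpy <- function(theta, grad, alpha) {
  for (l in seq_along(theta$W)) {
    theta$W[[l]] <- theta$W[[l]] - alpha * grad$W[[l]]
    theta$b[[l]] <- theta$b[[l]] - alpha * grad$b[[l]]
  }
  theta
}

grad_sqnorm <- function(grad)
  sum(vapply(grad$W, function(g) sum(g^2), 0)) +
  sum(vapply(grad$b, function(g) sum(g^2), 0))

#' Train the scale/shift network (Phase 2a)
#'
#' Fits a small fully connected network (default 4-16-16-2, tanh hidden
#' layers) mapping standardized covariates (axial length, disc-fovea
#' distance, disc-fovea angle, gender) to a per-eye log vertical scale `s`
#' and horizontal circular shift `delta`.  Training minimizes the
#' across-subject per-point variance of the compensated profiles,
#' normalized by the input variance so the objective is dimensionless.
#'
#' The variance objective alone cannot identify (and would even reward) a
#' component of `s` or `delta` shared by every eye: a common down-scaling
#' shrinks variance without removing any structure.  Two guards are built
#' in.  First, the applied outputs are centered on their batch mean, which
#' projects the common component out exactly (the training means are stored
#' and reused as fixed offsets at prediction time).  Second, a penalty
#' `gamma * ((mean s / s_max)^2 + (mean delta / delta_max)^2)` on the raw
#' (uncentered) outputs keeps them away from tanh saturation.  Outputs are
#' bounded (`|s| <= s_max`, `|delta| <= delta_max`).
#'
#' Optimization is deterministic full-batch gradient descent with an Armijo
#' backtracking line search (step grows 1.5x after an accepted step, halves
#' on rejection), so the recorded loss trajectory is non-increasing by
#' construction.  Initialization is Glorot-uniform from `seed` with a
#' down-scaled output layer, so training starts next to the identity
#' transform.
#'
#' @param profiles n x P matrix of age-compensated normative profiles, um
#' @param covariates matching covariate data frame
#' @param hidden hidden layer sizes
#' @param gamma weight of the mean-zero identifiability penalty
#' @param s_max,delta_max output bounds; `delta_max` defaults to `P / 8`
#' @param max_iter iteration budget
#' @param lr initial line-search step size
#' @param tol early-stop threshold on the relative loss change
#' @param seed seed of the weight initialization
#' @return an object of class `fcn_params`: the layer weights, output
#'   bounds, covariate standardization constants, and the loss `trajectory`
#' @export
train_fcn <- function(profiles, covariates, hidden = c(16, 16),
                      gamma = 10, s_max = 1, delta_max = NULL,
                      max_iter = 600, lr = 1e-2, tol = 1e-8, seed = 1) {
  Y <- as.matrix(profiles)
  n <- nrow(Y); P <- ncol(Y)
  stopifnot(nrow(covariates) == n)
  delta_max <- delta_max %||% (P / 8)
  des <- covariate_design(covariates)
  X <- des$X
  sizes <- c(ncol(X), hidden, 2)
  theta <- fcn_init(sizes, seed)
  V0 <- mean(sweep(Y, 2, colMeans(Y))^2)   # input per-point variance scale
  if (V0 <= 0) V0 <- 1

  eval_loss <- function(theta, want_grad) {
    fw <- fcn_forward(theta, X, s_max, delta_max)
    sc <- fw$s - mean(fw$s)                # batch-centered applied outputs
    dc <- fw$delta - mean(fw$delta)
    cl <- cpp_scale_shift_loss(Y, sc, dc, 0, 0, want_grad, FALSE)
    loss <- cl$loss / V0 +
      gamma * ((mean(fw$s) / s_max)^2 + (mean(fw$delta) / delta_max)^2)
    if (!is.finite(loss))
      stop("FCN training diverged: non-finite loss")
    if (!want_grad) return(list(loss = loss))
    g_s <- cl$grad_s / V0
    g_d <- cl$grad_d / V0
    # through the centering, then add the raw-mean penalty
    g_s <- g_s - mean(g_s) + 2 * gamma * mean(fw$s) / (n * s_max^2)
    g_d <- g_d - mean(g_d) + 2 * gamma * mean(fw$delta) / (n * delta_max^2)
    grad <- fcn_backward(theta, fw, g_s, g_d, s_max, delta_max)
    list(loss = loss, grad = grad)
  }

  cur <- eval_loss(theta, TRUE)
  trajectory <- cur$loss
  alpha <- lr
  for (it in seq_len(max_iter)) {
    g2 <- grad_sqnorm(cur$grad)
    if (g2 == 0) break
    accepted <- FALSE
    for (try in 1:40) {
      cand <- theta_axpy(theta, cur$grad, alpha)
      cand_loss <- eval_loss(cand, FALSE)$loss
      if (cand_loss <= cur$loss - 1e-4 * alpha * g2) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    theta <- cand
    prev_loss <- cur$loss
    cur <- eval_loss(theta, TRUE)
    trajectory <- c(trajectory, cur$loss)
    alpha <- min(alpha * 1.5, 1)
    if (abs(prev_loss - cur$loss) <= tol * max(prev_loss, .Machine$double.eps))
      break
  }

  fw <- fcn_forward(theta, X, s_max, delta_max)
  structure(list(W = theta$W, b = theta$b, hidden = hidden,
                 s_max = s_max, delta_max = delta_max,
                 offset = c(mean(fw$s), mean(fw$delta)),
                 std = des$std, gamma = gamma, P = P,
                 trajectory = trajectory, n_iter = length(trajectory) - 1),
            class = "fcn_params")
}

#' Predict the covariate-attributable scale and shift for eyes
#'
#' @param params an `fcn_params` from [train_fcn()]
#' @param covariates covariate data frame (any number of rows)
#' @return data frame with columns `s` (log scale) and `delta` (index shift)
#' @export
fcn_predict <- function(params, covariates) {
  stopifnot(inherits(params, "fcn_params"))
  X <- covariate_design(covariates, std = params$std)$X
  fw <- fcn_forward(list(W = params$W, b = params$b), X,
                    params$s_max, params$delta_max,
                    offset = params$offset %||% c(0, 0))
  data.frame(s = fw$s, delta = fw$delta)
}

# apply the predicted scale/shift removal to every row of a profile matrix
scale_shift_matrix <- function(Y, s, delta) {
  cpp_scale_shift_loss(as.matrix(Y), s, delta, 0, 0, FALSE, TRUE)$profiles
}
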