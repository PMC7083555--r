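## Gaussian-process normative regression, exact inference.
##
## Kernel on covariates x = (age_std, sex, ...):
##   k(x, x') = sf2 * exp(-(a - a')^2 / (2 * ell^2))   smooth nonlinear age term
##            + wv  * <x, x'>                          linear trend term
##            + bv                                     bias (intercept) term
##            + nv  * 1{i == j}                        white noise
## All five hyperparameters are optimised on the log scale by L-BFGS-B from
## several dispersed deterministic starts, maximising the exact log marginal
## likelihood. A jitter of 1e-8 * mean(diag(K)) is added before factorisation
## (oracle comparisons must include it).

GP_JITTER_REL <- 1e-8

# squared age distances and linear gram matrix from a standardized design
gp_gram <- function(X1, X2 = X1) {
  list(D2 = outer(X1[, 1], X2[, 1], `-`)^2,
       XL = X1 %*% t(X2))
}

gp_kernel_cross <- function(theta, gram) {
  p <- exp(theta)
  p[["sf2"]] * exp(-0.5 * gram$D2 / p[["ell"]]^2) + p[["wv"]] * gram$XL +
    p[["bv"]]
}

gp_kernel_train <- function(theta, gram, n) {
  p <- exp(theta)
  K <- gp_kernel_cross(theta, gram)
  Kn <- K + diag(p[["nv"]], n)
  jit <- GP_JITTER_REL * mean(diag(Kn))
  list(K = Kn + diag(jit, n), jitter = jit)
}

# prior (latent) variance at test points
gp_prior_var <- function(theta, Xstar) {
  p <- exp(theta)
  p[["sf2"]] + p[["wv"]] * rowSums(Xstar^2) + p[["bv"]]
}

# Negative pooled log marginal likelihood and gradient for Y (n x V), all
# voxels sharing one kernel. Returns list(value, gradient-on-log-scale).
gp_neg_lml <- function(theta, gram, Y) {
  n <- nrow(Y); V <- ncol(Y)
  p <- exp(theta)
  Kt <- gp_kernel_train(theta, gram, n)
  R <- chol(Kt$K)
  alpha <- backsolve(R, backsolve(R, Y, transpose = TRUE))
  lml <- -0.5 * sum(Y * alpha) - V * sum(log(diag(R))) -
    n * V / 2 * log(2 * pi)
  Kinv <- chol2inv(R)
  W <- tcrossprod(alpha) - V * Kinv
  Krbf <- p[["sf2"]] * exp(-0.5 * gram$D2 / p[["ell"]]^2)
  g <- c(
    sf2 = 0.5 * sum(W * Krbf),
    ell = 0.5 * sum(W * (Krbf * gram$D2 / p[["ell"]]^2)),
    wv  = 0.5 * sum(W * gram$XL) * p[["wv"]],
    bv  = 0.5 * sum(W) * p[["bv"]],
    nv  = 0.5 * sum(diag(W)) * p[["nv"]])
  list(value = -lml, gradient = -g)
}

# Deterministic dispersed starts, scaled to the data: `vbar` is the average
# per-voxel variance, `m2` the average squared voxel mean (absorbed by the
# bias term when voxels are not centred).
gp_default_starts <- function(vbar = 1, m2 = 0) {
  b <- function(f) log(m2 + f * vbar)
  list(
    c(sf2 = log(0.5 * vbar), ell = log(1), wv = log(0.5 * vbar),
      bv = b(0.1), nv = log(0.5 * vbar)),
    c(sf2 = log(0.1 * vbar), ell = log(0.3), wv = log(1 * vbar),
      bv = b(0.1), nv = log(0.1 * vbar)),
    c(sf2 = log(1 * vbar), ell = log(3), wv = log(0.1 * vbar),
      bv = b(0.5), nv = log(1 * vbar)))
}

# Optimise the shared kernel hyperparameters on conditioned data.
gp_optimize_theta <- function(gram, Y, restarts = 3, maxit = 100) {
  vbar <- mean(apply(Y, 2, var))
  m2 <- mean(colMeans(Y)^2)
  starts <- gp_default_starts(vbar, m2)[seq_len(max(1, min(restarts, 3)))]
  lower <- c(rep(log(1e-6), 5))
  upper <- c(rep(log(1e6), 5))
  cache <- new.env(parent = emptyenv())
  evalf <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    val <- gp_neg_lml(par, gram, Y)
    cache$key <- key; cache$val <- val
    val
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, fn = function(p) evalf(p)$value,
            gr = function(p) evalf(p)$gradient,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("GP hyperparameter optimisation failed from all starts")
  list(theta = best$par, lml = -best$value,
       converged = best$convergence %in% c(0L, 1L))
}

# Standardise covariates: age z-scored by training stats, sex as 0/1.
gp_design <- function(cohort_like, age_mean = NULL, age_sd = NULL) {
  age <- cohort_like$age
  sex <- if (is.numeric(cohort_like$sex)) cohort_like$sex else
    as.numeric(cohort_like$sex == "male")
  if (any(!is.finite(age)) || any(!is.finite(sex)))
    stop_config("missing values in covariates")
  if (is.null(age_mean)) age_mean <- mean(age)
  if (is.null(age_sd)) {
    age_sd <- sd(age)
    if (!is.finite(age_sd) || age_sd == 0) age_sd <- 1
  }
  list(X = cbind(age = (age - age_mean) / age_sd, sex = sex),
       age_mean = age_mean, age_sd = age_sd)
}

#' Fit a Gaussian-process normative model for a single voxel
#'
#' Regresses the voxel's volume on age and sex with an exact GP (squared
#' exponential on standardized age + linear + bias + white noise). With
#' `theta = NULL` the hyperparameters maximise the log marginal likelihood
#' (multi-restart L-BFGS-B on log parameters, bounds `[1e-6, 1e6]`); a fixed
#' `theta` (named log-scale vector `sf2, ell, wv, bv, nv`) skips optimisation.
#' Zero-variance targets yield a degenerate constant-mean model, flagged in
#' the result.
#'
#' @param X data.frame or list with elements `age` (years) and `sex`
#'   (`"female"`/`"male"` or 0/1), one entry per training subject.
#' @param y numeric vector of training volumes.
#' @param theta optional fixed log-scale hyperparameters.
#' @param standardize_y centre/scale `y` internally (default: only when
#'   optimising). Z-scores are invariant to this choice.
#' @param restarts number of optimisation restarts (<= 3).
#' @return object of class `voxel_gp` with elements `theta`, `lml`,
#'   `degenerate`, standardisation statistics and factorised training state.
#' @export
fit_voxel_gp <- function(X, y, theta = NULL, standardize_y = is.null(theta),
                         restarts = 3) {
  if (length(y) != length(X$age)) stop_config("X and y sizes differ")
  if (any(!is.finite(y))) stop_config("non-finite training targets")
  des <- gp_design(X)
  n <- length(y)
  if (is.null(theta) && n < 10)
    warning("fewer than 10 training subjects; hyperparameter fit is fragile")
  y_sd <- sd(y)
  if (!is.finite(y_sd)) y_sd <- 0
  if (y_sd == 0) {
    model <- list(degenerate = TRUE, y_mean = mean(y), n = n, des = des,
                  theta = NULL, lml = NA_real_)
    class(model) <- "voxel_gp"
    return(model)
  }
  y_center <- if (standardize_y) mean(y) else 0
  y_scale <- if (standardize_y) y_sd else 1
  ys <- (y - y_center) / y_scale
  gram <- gp_gram(des$X)
  if (is.null(theta)) {
    opt <- gp_optimize_theta(gram, cbind(ys), restarts = restarts)
    theta <- opt$theta
  }
  Kt <- gp_kernel_train(theta, gram, n)
  R <- chol(Kt$K)
  alpha <- backsolve(R, backsolve(R, ys, transpose = TRUE))
  lml <- -0.5 * sum(ys * alpha) - sum(log(diag(R))) - n / 2 * log(2 * pi)
  model <- list(theta = theta, lml = lml, degenerate = FALSE,
                des = des, X = des$X, R = R, alpha = alpha,
                y_center = y_center, y_scale = y_scale, n = n,
                jitter = Kt$jitter)
  class(model) <- "voxel_gp"
  model
}

#' Predictive mean and variance of a voxel model at new covariates
#'
#' Exact GP prediction: `mean = k*' K^-1 y`,
#' `latent variance = k** - k*' K^-1 k*`, and
#' `predictive variance = latent variance + noise variance` (always positive).
#' Degenerate (zero-variance) models predict their constant with zero latent
#' variance and a unit predictive floor.
#'
#' @param model a `voxel_gp` from [fit_voxel_gp()].
#' @param Xstar data.frame/list with `age` and `sex` for the test subjects.
#' @return data.frame with columns `mean`, `var_latent`, `var_pred`.
#' @export
predict_voxel <- function(model, Xstar) {
  stopifnot(inherits(model, "voxel_gp"))
  m <- length(Xstar$age)
  if (model$degenerate) {
    return(data.frame(mean = rep(model$y_mean, m), var_latent = 0,
                      var_pred = 1))
  }
  des <- gp_design(Xstar, model$des$age_mean, model$des$age_sd)
  gram <- gp_gram(des$X, model$X)
  Ks <- gp_kernel_cross(model$theta, gram)
  mu <- as.numeric(Ks %*% model$alpha)
  Vh <- backsolve(model$R, t(Ks), transpose = TRUE)
  var_lat <- pmax(gp_prior_var(model$theta, des$X) - colSums(Vh^2), 0)
  nv <- exp(model$theta[["nv"]])
  data.frame(mean = model$y_center + model$y_scale * mu,
             var_latent = model$y_scale^2 * var_lat,
             var_pred = model$y_scale^2 * (var_lat + nv))
}

#' Deviation Z-score
#'
#' `Z = (observed - predicted mean) / sqrt(predictive variance)`. Negative Z
#' means less volume than the normative prediction.
#'
#' @param y_observed observed values.
#' @param mean predictive mean.
#' @param var_pred predictive variance (> 0).
#' @return numeric Z-scores.
#' @export
zscore <- function(y_observed, mean, var_pred) {
  if (any(!is.finite(var_pred)) || any(var_pred <= 0))
    stop("predictive variance must be positive and finite")
  (y_observed - mean) / sqrt(var_pred)
}

#' Simulate voxel data from the GP model class
#'
#' Draws `n_voxels` independent target vectors from the exact generative
#' model of the kernel (latent GP + white noise) at uniform ages and
#' Bernoulli sex, for calibration studies.
#'
#' @param n subjects.
#' @param n_voxels voxels.
#' @param theta named log-scale hyperparameters (defaults: a mostly linear
#'   age trend with moderate noise).
#' @param age_range,p_male covariate distribution.
#' @param seed RNG seed.
#' @return list with `cohort` (age/sex data.frame) and `Y` (n x n_voxels).
#' @export
simulate_gp_voxels <- function(n, n_voxels,
                               theta = c(sf2 = log(0.2), ell = log(1.5),
                                         wv = log(0.5), bv = log(0.3),
                                         nv = log(0.5)),
                               age_range = c(18, 65), p_male = 0.5,
                               seed = 1) {
  with_seed(seed, {
    cohort <- data.frame(
      age = runif(n, age_range[1], age_range[2]),
      sex = ifelse(runif(n) < p_male, "male", "female"),
      stringsAsFactors = FALSE)
    des <- gp_design(cohort)
    gram <- gp_gram(des$X)
    Kf <- gp_kernel_cross(theta, gram)  # latent kernel (no noise)
    Rf <- chol(Kf + diag(1e-10, n))
    F <- t(Rf) %*% matrix(rnorm(n * n_voxels), n, n_voxels)
    Y <- F + sqrt(exp(theta[["nv"]])) * matrix(rnorm(n * n_voxels), n, n_voxels)
    list(cohort = cohort, Y = Y, theta = theta)
  })
}
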