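#' Construct a deviation stack
#'
#' Per-subject, per-voxel Z deviation scores with their mask and provenance
#' (`"crossval-control"` for scores obtained under k-fold cross-validation in
#' the reference group, `"out-of-sample-patient"` for target subjects scored
#' by the model trained on all reference subjects).
#'
#' @param z subjects x in-mask-voxels matrix of Z-scores.
#' @param mask logical 3D array.
#' @param subject_id ids, one per row.
#' @param provenance character vector (length 1 or `nrow(z)`).
#' @param voxel_size voxel edge (mm).
#' @return object of class `deviation_stack`.
#' @export
deviation_stack <- function(z, mask, subject_id, provenance, voxel_size = 1) {
  stopifnot(is.matrix(z), sum(mask) == ncol(z))
  if (nrow(z) > 0 && any(!is.finite(z)))
    stop_config("non-finite Z inside the mask")
  provenance <- rep(provenance, length.out = nrow(z))
  structure(list(z = z, mask = mask, subject_id = subject_id,
                 provenance = provenance, voxel_size = voxel_size),
            class = "deviation_stack")
}

#' @export
print.deviation_stack <- function(x, ...) {
  cat(sprintf("deviation_stack: %d subjects x %d voxels [%s]\n",
              nrow(x$z), ncol(x$z),
              paste(unique(x$provenance), collapse = ", ")))
  invisible(x)
}

# Fit shared hyperparameters on a deterministic voxel subsample (evenly
# spaced across non-degenerate voxels), then factorise once for all voxels.
#
# Voxels are NOT standardized individually: the bias and linear kernel terms
# absorb per-voxel intercepts and trends, and a single global scale is used
# for optimiser conditioning only (Z is invariant to it). With one shared
# kernel the predictive variance is common to all voxels, which is exactly
# calibrated when the noise is homoscedastic across voxels -- true of the
# synthetic worlds this package models; heteroscedastic data needs the
# per-voxel path. Per-voxel standardization would make the shared noise
# variance wrong for every voxel whose realized signal fraction differs from
# the average, which measurably inflates the |Z| > 2.6 tail.
fit_shared_gp <- function(Ytr, des, subsample = 128, restarts = 2,
                          theta = NULL) {
  n <- nrow(Ytr); V <- ncol(Ytr)
  sds <- apply(Ytr, 2, sd)
  degenerate <- !is.finite(sds) | sds <= 0
  if (all(degenerate)) stop_config("all voxels are degenerate")
  # user-supplied theta refers to the data's own units
  gscale <- if (is.null(theta)) stats::median(sds[!degenerate]) else 1
  Ys <- Ytr / gscale
  gram <- gp_gram(des$X)
  if (is.null(theta)) {
    ok <- which(!degenerate)
    pick <- ok[unique(pmax(1L, round(seq(1L, length(ok),
                                         length.out = min(subsample, length(ok))))))]
    opt <- gp_optimize_theta(gram, Ys[, pick, drop = FALSE],
                             restarts = restarts)
    theta <- opt$theta
  }
  Kt <- gp_kernel_train(theta, gram, n)
  R <- chol(Kt$K)
  alpha <- backsolve(R, backsolve(R, Ys, transpose = TRUE))
  list(theta = theta, R = R, alpha = alpha, des = des, gscale = gscale,
       degenerate = degenerate, n = n, V = V)
}

# Z-scores of new observations under a fitted shared-kernel batch model.
predict_shared_z <- function(fit, cohort_new, Ynew) {
  des_new <- gp_design(cohort_new, fit$des$age_mean, fit$des$age_sd)
  gram <- gp_gram(des_new$X, fit$des$X)
  Ks <- gp_kernel_cross(fit$theta, gram)
  mu <- Ks %*% fit$alpha                      # m x V, conditioning units
  Vh <- backsolve(fit$R, t(Ks), transpose = TRUE)
  var_lat <- pmax(gp_prior_var(fit$theta, des_new$X) - colSums(Vh^2), 0)
  var_pred <- var_lat + exp(fit$theta[["nv"]])  # per test subject, all voxels
  z <- (Ynew / fit$gscale - mu) / sqrt(var_pred)
  z[, fit$degenerate] <- 0
  z
}

# per-voxel exact path: optimise hyperparameters voxel by voxel
predict_per_voxel_z <- function(cohort_tr, Ytr, cohort_new, Ynew, restarts = 3) {
  V <- ncol(Ytr)
  z <- matrix(0, nrow(Ynew), V)
  for (v in seq_len(V)) {
    m <- fit_voxel_gp(cohort_tr, Ytr[, v], restarts = restarts)
    if (isTRUE(m$degenerate)) next
    pr <- predict_voxel(m, cohort_new)
    z[, v] <- zscore(Ynew[, v], pr$mean, pr$var_pred)
  }
  z
}

# run a scoring function on each sex separately and reassemble the rows of
# the requested diagnosis group in cohort order
split_by_sex <- function(volumes, cohort, fun, group) {
  keep <- which(cohort$diagnosis == group)
  z <- matrix(NA_real_, length(keep), ncol(volumes$data))
  for (s in c("female", "male")) {
    rows <- which(cohort$sex == s)
    if (!any(cohort$diagnosis[rows] == group)) next
    sub_vol <- volume_stack(volumes$data[rows, , drop = FALSE], volumes$mask,
                            volumes$voxel_size, volumes$subject_id[rows],
                            volumes$affine)
    sub_dev <- fun(sub_vol, cohort[rows, ])
    z[match(sub_dev$subject_id, cohort$subject_id[keep]), ] <- sub_dev$z
  }
  prov <- if (group == "control") "crossval-control" else "out-of-sample-patient"
  deviation_stack(z, volumes$mask, cohort$subject_id[keep], prov,
                  volumes$voxel_size)
}

# Stratified (by sex) deterministic fold assignment: subjects are shuffled
# within sex, the strata are concatenated, and folds are dealt round-robin
# across the whole sequence, so fold sizes differ by at most one and each sex
# is spread evenly.
make_folds <- function(sex, k, seed) {
  order <- with_seed(seed, unlist(lapply(sort(unique(sex)), function(s) {
    idx <- which(sex == s)
    idx[sample.int(length(idx))]
  })))
  fold <- integer(length(sex))
  fold[order] <- rep_len(seq_len(k), length(sex))
  fold
}

#' Cross-validated deviation scores for the reference group
#'
#' Fits the normative model in the reference (control) subjects under k-fold
#' cross-validation (folds stratified by sex, seeded shuffle): each control's
#' voxelwise Z-score is computed from a model that never saw that control.
#'
#' @param volumes a [volume_stack()] covering the whole cohort.
#' @param cohort the matching cohort table.
#' @param k number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed seed for the fold shuffle.
#' @param shared_hyperparameters use the shared-kernel fast path (one
#'   hyperparameter set per fold, estimated on `subsample` voxels). `FALSE`
#'   optimises every voxel separately (exact but slow; small grids only).
#' @param subsample voxels used for the pooled hyperparameter fit.
#' @param restarts optimisation restarts.
#' @param separate_sexes fit an independent normative model per sex (sex then
#'   drops out of each model's linear term); default models both sexes
#'   jointly with sex as a covariate.
#' @return a [deviation_stack()] for the controls, with a `folds` attribute.
#' @export
crossval_reference <- function(volumes, cohort, k = 10, seed = 1,
                               shared_hyperparameters = TRUE,
                               subsample = 256, restarts = 2,
                               separate_sexes = FALSE) {
  validate_cohort(cohort)
  stopifnot(inherits(volumes, "volume_stack"))
  if (separate_sexes) {
    return(split_by_sex(volumes, cohort, function(v, c) {
      crossval_reference(v, c, k = k, seed = seed,
                         shared_hyperparameters = shared_hyperparameters,
                         subsample = subsample, restarts = restarts)
    }, group = "control"))
  }
  ctrl <- which(cohort$diagnosis == "control")
  if (k > length(ctrl)) stop_config("k = %d exceeds the %d controls", k, length(ctrl))
  if (k < 2) stop_config("k must be >= 2")
  fold <- make_folds(cohort$sex[ctrl], k, seed)
  Y <- volumes$data[ctrl, , drop = FALSE]
  z <- matrix(NA_real_, length(ctrl), ncol(Y))
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    coh_tr <- cohort[ctrl[tr], ]
    coh_te <- cohort[ctrl[te], ]
    if (shared_hyperparameters) {
      fit <- fit_shared_gp(Y[tr, , drop = FALSE], gp_design(coh_tr),
                           subsample = subsample, restarts = restarts)
      z[te, ] <- predict_shared_z(fit, coh_te, Y[te, , drop = FALSE])
    } else {
      z[te, ] <- predict_per_voxel_z(coh_tr, Y[tr, , drop = FALSE],
                                     coh_te, Y[te, , drop = FALSE],
                                     restarts = restarts)
    }
  }
  out <- deviation_stack(z, volumes$mask, cohort$subject_id[ctrl],
                         "crossval-control", volumes$voxel_size)
  attr(out, "folds") <- fold
  out
}

#' Deviation scores for target (patient) subjects
#'
#' Trains the normative model on all reference subjects and scores every
#' patient out-of-sample.
#'
#' @inheritParams crossval_reference
#' @return a [deviation_stack()] for the patients (empty if there are none).
#' @export
score_targets <- function(volumes, cohort, shared_hyperparameters = TRUE,
                          subsample = 256, restarts = 2,
                          separate_sexes = FALSE) {
  validate_cohort(cohort)
  stopifnot(inherits(volumes, "volume_stack"))
  if (separate_sexes) {
    return(split_by_sex(volumes, cohort, function(v, c) {
      score_targets(v, c, shared_hyperparameters = shared_hyperparameters,
                    subsample = subsample, restarts = restarts)
    }, group = "patient"))
  }
  ctrl <- which(cohort$diagnosis == "control")
  pat <- which(cohort$diagnosis == "patient")
  if (!length(ctrl)) stop_config("no controls to train on")
  if (!length(pat)) {
    return(deviation_stack(matrix(0, 0, ncol(volumes$data)), volumes$mask,
                           character(0), character(0), volumes$voxel_size))
  }
  coh_tr <- cohort[ctrl, ]
  coh_te <- cohort[pat, ]
  if (shared_hyperparameters) {
    fit <- fit_shared_gp(volumes$data[ctrl, , drop = FALSE], gp_design(coh_tr),
                         subsample = subsample, restarts = restarts)
    z <- predict_shared_z(fit, coh_te, volumes$data[pat, , drop = FALSE])
  } else {
    z <- predict_per_voxel_z(coh_tr, volumes$data[ctrl, , drop = FALSE],
                             coh_te, volumes$data[pat, , drop = FALSE],
                             restarts = restarts)
  }
  deviation_stack(z, volumes$mask, cohort$subject_id[pat],
                  "out-of-sample-patient", volumes$voxel_size)
}
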