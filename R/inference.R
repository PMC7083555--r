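#' TFCE parameters
#'
#' @param H height exponent (default 2).
#' @param E extent exponent (default 0.5).
#' @param dh integration step; `NULL` means `max(|stat|)/100` at transform
#'   time.
#' @param connectivity neighbourhood: 6, 18 or 26 (default 26).
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26) {
  if (H <= 0 || E <= 0) stop_config("H and E must be > 0")
  if (!is.null(dh) && dh <= 0) stop_config("dh must be > 0")
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over thresholds `h = dh, 2dh, ...`,
#' where `e(h, v)` is the size of the suprathreshold connected component
#' containing `v`. The negative tail is enhanced by applying the transform to
#' the negated map and subtracting, so the output is signed.
#'
#' @param stat_map 3D numeric array (zero outside the analysis mask).
#' @param params a [tfce_params()].
#' @return enhanced 3D array of the same dimension.
#' @export
tfce_transform <- function(stat_map, params = tfce_params()) {
  stopifnot(length(dim(stat_map)) == 3)
  if (any(!is.finite(stat_map))) stop_config("non-finite values in stat map")
  mx <- max(abs(stat_map))
  if (mx == 0) return(array(0, dim(stat_map)))
  dh <- params$dh %||% (mx / 100)
  pos <- .tfce_cpp(pmax(stat_map, 0), dim(stat_map), params$H, params$E, dh,
                   params$connectivity)
  neg <- .tfce_cpp(pmax(-stat_map, 0), dim(stat_map), params$H, params$E, dh,
                   params$connectivity)
  out <- pos - neg
  dim(out) <- dim(stat_map)
  out
}

inflate <- function(values, mask) {
  out <- array(0, dim(mask))
  out[mask] <- values
  out
}

group_stat_map <- function(stat, z_equivalent, p, p_adj, significant, mask,
                           n_perm, enhancement, extra = list()) {
  structure(c(list(stat = stat, z_equivalent = z_equivalent,
                   p_uncorrected = p, p_corrected = p_adj,
                   significant_mask = significant, mask = mask,
                   n_permutations = n_perm, enhancement = enhancement),
              extra),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("group_stat_map: %d voxels, %d permutations, enhancement=%s, %d significant\n",
              length(x$stat), x$n_permutations, x$enhancement,
              sum(x$significant_mask)))
  invisible(x)
}

#' One-sample permutation map of group mean deviation
#'
#' Voxelwise one-sample t statistics of the group's Z-scores against zero,
#' with a sign-flipping permutation null (valid because deviations are
#' symmetric about 0 under H0). Two-sided permutation p-values are converted
#' to z-equivalents via the normal quantile, and a `display_mask` thresholds
#' the z-equivalent map at +/- `display_z`. The full set of 2^n sign flips is
#' enumerated when it is no larger than `n_perm`.
#'
#' @param deviations a [deviation_stack()] of one group.
#' @param n_perm number of sign-flip permutations (default 500).
#' @param seed RNG seed for the flips.
#' @param display_z display threshold for the z-equivalent map (default 2.6).
#' @return a `group_stat_map` (vectors over in-mask voxels) with
#'   `display_mask` and `mask` for inflation.
#' @export
group_mean_map <- function(deviations, n_perm = 500, seed = 1,
                           display_z = 2.6) {
  stopifnot(inherits(deviations, "deviation_stack"))
  Z <- deviations$z
  n <- nrow(Z)
  if (n < 2) stop_config("need at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations")
  ssq <- colSums(Z^2)
  t_of_means <- function(m) {
    s2 <- pmax((ssq / n - m^2) * n / (n - 1), 0)
    se <- sqrt(s2 / n)
    tt <- m / se
    tt[!is.finite(tt)] <- 0
    tt
  }
  t_obs <- t_of_means(colMeans(Z))
  exact <- 2^n <= n_perm
  if (exact) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    B <- nrow(S)
    exceed <- rep(0L, ncol(Z))
    for (b in seq_len(B)) {
      tb <- t_of_means(as.numeric(S[b, ] %*% Z) / n)
      exceed <- exceed + (abs(tb) >= abs(t_obs) - 1e-12)
    }
    p <- exceed / B
  } else {
    S <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                n_perm, n))
    M <- (S %*% Z) / n
    exceed <- rep(0L, ncol(Z))
    for (b in seq_len(n_perm)) {
      tb <- t_of_means(M[b, ])
      exceed <- exceed + (abs(tb) >= abs(t_obs))
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  z_eq <- sign(t_obs) * qnorm(1 - p / 2)
  p_adj <- p.adjust(p, "BH")
  group_stat_map(t_obs, z_eq, p, p_adj, significant = p_adj <= 0.05,
                 mask = deviations$mask,
                 n_perm = if (exact) 2^n else n_perm,
                 enhancement = "none",
                 extra = list(display_mask = abs(z_eq) > display_z,
                              display_z = display_z))
}

two_sample_t <- function(sum1, ssq1, n1, tot, totsq, n) {
  n2 <- n - n1
  sum2 <- tot - sum1
  ssq2 <- totsq - ssq1
  m1 <- sum1 / n1
  m2 <- sum2 / n2
  ss <- pmax(ssq1 - n1 * m1^2, 0) + pmax(ssq2 - n2 * m2^2, 0)
  sp2 <- ss / (n - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- 0
  tt
}

#' Two-sample permutation contrast map with TFCE and FDR
#'
#' Voxelwise pooled-variance two-sample t statistics (patients minus
#' controls), group-label permutation null, optional threshold-free cluster
#' enhancement of every permuted map, two-sided voxelwise permutation
#' p-values of the (enhanced) statistic, and Benjamini-Hochberg FDR across
#' in-mask voxels at level `q`. The TFCE integration step is fixed from the
#' observed map (`max(|t|)/100`) and reused for all permutations. Labels are
#' fully enumerated when `choose(n, n_patients) <= n_perm`.
#'
#' @param dev_controls,dev_patients [deviation_stack()]s on the same grid.
#' @param tfce a [tfce_params()], or `NULL` to skip enhancement.
#' @param q FDR level (default 0.05).
#' @param n_perm label permutations (default 500).
#' @param seed RNG seed.
#' @return a `group_stat_map`; `stat` is the observed t map, `enhanced` the
#'   TFCE map (when enabled), `significant_mask` the FDR-corrected result.
#' @export
group_contrast_map <- function(dev_controls, dev_patients,
                               tfce = tfce_params(), q = 0.05,
                               n_perm = 500, seed = 1) {
  stopifnot(inherits(dev_controls, "deviation_stack"),
            inherits(dev_patients, "deviation_stack"))
  if (!identical(dim(dev_controls$mask), dim(dev_patients$mask)))
    stop_config("deviation stacks live on different grids")
  if (nrow(dev_controls$z) == 0 || nrow(dev_patients$z) == 0)
    stop_config("both groups must be nonempty")
  if (nrow(dev_controls$z) == 1 || nrow(dev_patients$z) == 1)
    warning("a group of size 1 gives a degenerate permutation space")
  Z <- rbind(dev_patients$z, dev_controls$z)
  n1 <- nrow(dev_patients$z)
  n <- nrow(Z)
  mask <- dev_controls$mask
  tot <- colSums(Z)
  totsq <- colSums(Z^2)
  Z2 <- Z^2

  stat_of <- function(idx1) {
    two_sample_t(colSums(Z[idx1, , drop = FALSE]),
                 colSums(Z2[idx1, , drop = FALSE]), length(idx1), tot, totsq, n)
  }
  t_obs <- stat_of(seq_len(n1))

  use_tfce <- !is.null(tfce)
  if (use_tfce) {
    mx <- max(abs(t_obs))
    dh <- tfce$dh %||% (if (mx > 0) mx / 100 else 1)
    params <- tfce_params(tfce$H, tfce$E, dh, tfce$connectivity)
    enh_obs <- tfce_transform(inflate(t_obs, mask), params)[mask]
  } else {
    enh_obs <- t_obs
  }

  exact <- !is.na(suppressWarnings(choose(n, n1))) &&
    choose(n, n1) <= n_perm
  perms <- if (exact) {
    cmb <- utils::combn(n, n1)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    with_seed(seed, lapply(seq_len(n_perm), function(b) sample.int(n, n1)))
  }
  exceed <- rep(0L, ncol(Z))
  for (idx1 in perms) {
    tb <- stat_of(idx1)
    eb <- if (use_tfce) tfce_transform(inflate(tb, mask), params)[mask] else tb
    exceed <- exceed + (abs(eb) >= abs(enh_obs) - 1e-12)
  }
  B <- length(perms)
  p <- if (exact) exceed / B else (1 + exceed) / (B + 1)
  p_adj <- p.adjust(p, "BH")
  z_eq <- sign(t_obs) * qnorm(1 - p / 2)
  group_stat_map(t_obs, z_eq, p, p_adj, significant = p_adj <= q, mask = mask,
                 n_perm = B, enhancement = if (use_tfce) "tfce" else "none",
                 extra = list(enhanced = enh_obs, q = q,
                              tfce = if (use_tfce) params else NULL))
}

#' Bonferroni-Holm step-down correction
#'
#' Holm-adjusted p-values with monotonicity enforcement; `m` may exceed the
#' number of observed p-values to correct against a larger declared family.
#'
#' @param p numeric p-values in \[0, 1\] (0 only arises from degenerate
#'   perfect fits and is passed through).
#' @param m family size (default `length(p)`).
#' @return adjusted p-values in the input order (empty input gives empty
#'   output).
#' @export
holm_correct <- function(p, m = length(p)) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_config("p-values must be in [0, 1]")
  if (m < length(p)) stop_config("family size m cannot be below length(p)")
  p.adjust(p, method = "holm", n = m)
}

#' Diagnosis effect on extreme-deviation scores (Wald chi-square in a GLM)
#'
#' Models each subject's extreme-voxel count as an overdispersed binomial
#' (quasibinomial GLM: events = extreme voxels, trials = in-mask voxels) with
#' diagnosis as the predictor, and tests the diagnosis coefficient with a
#' 1-df Wald chi-square. Group mean percentages with 95% confidence intervals
#' are reported on the response scale. Optionally the Wald statistic is
#' referenced against a diagnosis-label permutation distribution.
#'
#' @param scores data.frame from [extreme_scores()].
#' @param cohort cohort table with `subject_id` and `diagnosis`.
#' @param measure `"pct_negative"` or `"pct_positive"`.
#' @param n_perm label permutations for the non-parametric reference
#'   (0 = skip).
#' @param seed RNG seed for the permutations.
#' @return list of class `score_test_result`: `statistic`, `df`, `p`,
#'   `effect_direction`, `group_estimates` (pct with CI), optionally
#'   `p_permutation`.
#' @export
score_group_test <- function(scores, cohort, measure = "pct_negative",
                             n_perm = 0, seed = 1) {
  stopifnot(measure %in% c("pct_negative", "pct_positive"))
  d <- merge(scores, as.data.frame(cohort)[, c("subject_id", "diagnosis")],
             by = "subject_id", sort = FALSE)
  if (length(unique(d$diagnosis)) < 2)
    stop_config("both diagnosis groups must be present")
  if (any(d$n_mask_voxels <= 0)) stop_config("zero in-mask voxels")
  k <- round(d[[measure]] / 100 * d$n_mask_voxels)
  trials <- d$n_mask_voxels
  diagnosis <- factor(d$diagnosis, levels = c("control", "patient"))
  wald_of <- function(grp) {
    fit <- glm(cbind(k, trials - k) ~ grp, family = quasibinomial())
    sm <- summary(fit)$coefficients
    list(stat = (sm[2, 1] / sm[2, 2])^2, est = sm[2, 1], fit = fit)
  }
  obs <- wald_of(diagnosis)
  pval <- pchisq(obs$stat, df = 1, lower.tail = FALSE)
  est <- vapply(levels(diagnosis), function(g) {
    fit <- obs$fit
    pr <- predict(fit, newdata = data.frame(grp = factor(g, levels(diagnosis))),
                  type = "link", se.fit = TRUE)
    ci <- plogis(pr$fit + c(0, -1.96, 1.96) * pr$se.fit) * 100
    ci
  }, numeric(3))
  rownames(est) <- c("pct", "ci_lo", "ci_hi")
  out <- list(statistic = obs$stat, df = 1L, p = pval,
              effect_direction = sign(obs$est),
              group_estimates = t(est), measure = measure,
              n = table(diagnosis))
  if (n_perm > 0) {
    perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      wald_of(sample(diagnosis))$stat
    }, 0))
    out$p_permutation <- (1 + sum(perm_stats >= obs$stat)) / (n_perm + 1)
    out$n_permutations <- n_perm
  }
  class(out) <- "score_test_result"
  out
}

#' @export
print.score_test_result <- function(x, ...) {
  cat(sprintf("Wald chi2(%d) = %.2f, p = %.3g [%s]\n", x$df, x$statistic,
              x$p, x$measure))
  print(round(x$group_estimates, 3))
  invisible(x)
}

#' Run the diagnosis score test for several measures with Holm correction
#'
#' @inheritParams score_group_test
#' @param measures score columns to test.
#' @param family_m Holm family size (default: number of measures).
#' @return list of `score_test_result`s with `p_corrected` filled in.
#' @export
score_group_tests <- function(scores, cohort,
                              measures = c("pct_negative", "pct_positive"),
                              family_m = length(measures), n_perm = 0,
                              seed = 1) {
  res <- lapply(measures, function(m)
    score_group_test(scores, cohort, m, n_perm = n_perm, seed = seed))
  pc <- holm_correct(vapply(res, `[[`, 0, "p"), m = family_m)
  for (i in seq_along(res)) res[[i]]$p_corrected <- pc[i]
  names(res) <- measures
  res
}

#' Associations between extreme-deviation scores and covariates
#'
#' Within one diagnosis group (patients by default), regresses each
#' standardized score measure on each standardized covariate and reports the
#' standardized coefficient (beta-weight), its p-value, and the Holm-corrected
#' p within a declared family of `family_m` tests per measure.
#'
#' @param scores data.frame from [extreme_scores()].
#' @param cohort cohort table.
#' @param covariates covariate column names in `cohort`.
#' @param measures score columns to analyse.
#' @param group diagnosis group to analyse.
#' @param family_m Holm family size per measure (default 8).
#' @return data.frame with `measure`, `covariate`, `beta`, `p`, `p_corrected`,
#'   `n`, `family_m`; constant covariates are skipped.
#' @export
association_tests <- function(scores, cohort,
                              covariates = c("age", "hyperactivity",
                                             "inattention", "medication",
                                             "comorbidity"),
                              measures = c("pct_negative", "pct_positive"),
                              group = "patient", family_m = 8) {
  d <- merge(scores, as.data.frame(cohort), by = "subject_id", sort = FALSE)
  d <- d[d$diagnosis == group, , drop = FALSE]
  miss <- setdiff(covariates, names(d))
  if (length(miss))
    stop_config("covariates not in cohort: %s", paste(miss, collapse = ", "))
  rows <- list()
  for (meas in measures) {
    y <- d[[meas]]
    betas <- ps <- numeric(0)
    used <- character(0)
    for (cv in covariates) {
      x <- d[[cv]]
      if (is.character(x) || is.factor(x)) x <- as.numeric(x == "yes")
      if (sd(x) == 0 || sd(y) == 0) next
      fit <- lm(scale(y) ~ scale(x))
      sm <- summary(fit)$coefficients
      betas <- c(betas, sm[2, 1]); ps <- c(ps, sm[2, 4]); used <- c(used, cv)
    }
    if (!length(used)) next
    pc <- holm_correct(ps, m = max(family_m, length(ps)))
    rows[[meas]] <- data.frame(measure = meas, covariate = used, beta = betas,
                               p = ps, p_corrected = pc, n = nrow(d),
                               family_m = max(family_m, length(ps)),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @importFrom stats plogis predict
NULL
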