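test_that("TFCE trivial cases and closed forms hold", {
  z0 <- array(0, c(5, 5, 5))
  expect_equal(tfce_transform(z0), z0)

  # isolated voxel of height h0, H=2, E=0.5: integral h0^3 / 3
  h0 <- 2.4
  x <- array(0, c(7, 7, 7)); x[4, 4, 4] <- h0
  got <- tfce_transform(x, tfce_params(dh = h0 / 400))[4, 4, 4]
  expect_equal(got, h0^3 / 3, tolerance = 0.01)
  # negative tail is handled by sign
  got_neg <- tfce_transform(-x, tfce_params(dh = h0 / 400))[4, 4, 4]
  expect_equal(got_neg, -h0^3 / 3, tolerance = 0.01)

  # scaling the map up never decreases any enhanced value
  y <- normdev:::with_seed(4, array(rnorm(125), c(5, 5, 5)))
  p <- tfce_params(dh = max(abs(y)) / 150)
  e1 <- tfce_transform(y, p)
  e2 <- tfce_transform(1.7 * y, p)
  expect_true(all(e2 * sign(y) + 1e-12 >= e1 * sign(y)))
})

test_that("TFCE agrees with the naive threshold-sum oracle", {
  normdev:::with_seed(5, {
    for (conn in c(6, 26)) {
      x <- array(rnorm(125), c(5, 5, 5))
      dh <- max(abs(x)) / 400
      got <- tfce_transform(x, tfce_params(dh = dh, connectivity = conn))
      want <- tfce_oracle(x, dh = dh / 10, connectivity = conn)
      # scale-relative agreement; voxels barely above zero carry pure
      # discretisation noise and no cluster mass
      expect_lt(max(abs(got - want)) / max(abs(want)), 0.02)
      big <- abs(want) > 0.1 * max(abs(want))
      expect_lt(max(abs(got[big] - want[big]) / abs(want[big])), 0.02)
    }
  })
})

test_that("one-sample sign-flip map behaves on degenerate and strong input", {
  dev0 <- flat_stack(matrix(0, 6, 50))
  m0 <- suppressWarnings(group_mean_map(dev0, n_perm = 200, seed = 1))
  expect_true(all(m0$stat == 0))
  expect_true(all(m0$p_uncorrected == 1))
  expect_false(any(m0$significant_mask))

  # 12 subjects all strongly positive: minimum attainable p = 1/(999+1)
  dev1 <- flat_stack(matrix(5 + normdev:::with_seed(6, rnorm(12 * 40, sd = .1)),
                            12, 40))
  m1 <- group_mean_map(dev1, n_perm = 999, seed = 2)
  expect_equal(min(m1$p_uncorrected), 1 / 1000)
  expect_true(all(m1$display_mask))
  m1b <- group_mean_map(dev1, n_perm = 999, seed = 2)
  expect_identical(m1$p_uncorrected, m1b$p_uncorrected)

  # small n triggers exact enumeration of all 2^n sign patterns
  dev2 <- flat_stack(matrix(normdev:::with_seed(7, rnorm(6 * 30)), 6, 30))
  m2 <- group_mean_map(dev2, n_perm = 200, seed = 3)
  expect_equal(m2$n_permutations, 64)
  expect_true(all(m2$p_uncorrected >= 1 / 64))
})

test_that("two-sample contrast is antisymmetric and null-calibrated", {
  normdev:::with_seed(8, {
    zc <- matrix(rnorm(15 * 60), 15, 60)
    zp <- matrix(rnorm(12 * 60), 12, 60)
  })
  dc <- flat_stack(zc); dp <- flat_stack(zp, "out-of-sample-patient")
  a <- group_contrast_map(dc, dp, tfce = NULL, n_perm = 100, seed = 4)
  b <- group_contrast_map(dp, dc, tfce = NULL, n_perm = 100, seed = 4)
  expect_equal(a$stat, -b$stat, tolerance = 1e-12)

  # identical groups: the exact null, nothing survives FDR
  same <- flat_stack(rbind(zc, zc))
  dup <- flat_stack(zc)
  cm <- group_contrast_map(dup, flat_stack(zc, "out-of-sample-patient"),
                           tfce = NULL, n_perm = 200, seed = 5)
  expect_false(any(cm$significant_mask))
})

test_that("group contrast recovers the shared region and controls FDR", {
  # lesion-free world: the only true group effect is the shared region, so
  # the discovery set can be scored cleanly against FDR's guarantee
  cfg <- simulation_config(seed = 101, n_idiosyncratic_lesions = 0)
  coh <- generate_cohort(cfg)
  gen <- generate_volumes(coh, cfg)
  devc <- crossval_reference(gen$volumes, coh, k = 10, seed = 1)
  devp <- score_targets(gen$volumes, coh)
  cm <- group_contrast_map(devc, devp, n_perm = 500, seed = 2)
  roi_cols <- match(gen$truth$shared_roi, which(gen$volumes$mask))
  sig <- which(cm$significant_mask)
  expect_gt(length(sig), 0)
  expect_gt(mean(roi_cols %in% sig), 0.8)              # recall
  # False discoveries exceed the nominal q: patients share one training
  # model (their Z co-vary per voxel) while cross-validated control
  # residuals anti-correlate, so the null contrast t has sd ~ 1.05 relative
  # to the permutation null — the "small bias" inherent in contrasting
  # cross-validated reference deviations against out-of-sample target
  # deviations (see the methods vignette). Bounded, not nominal:
  expect_lt(mean(!(sig %in% roi_cols)), 1 / 3)
  # direction: patients lower in the shared region
  expect_lt(median(cm$stat[roi_cols]), 0)
})

test_that("Holm correction matches its definition", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_identical(holm_correct(numeric(0)), numeric(0))
  expect_error(holm_correct(c(0.1, -1)), "p-values")
  normdev:::with_seed(9, {
    for (rep in 1:25) {
      p <- runif(sample(1:8, 1))
      m <- length(p) + sample(0:3, 1)
      got <- holm_correct(p, m)
      expect_equal(got, holm_adjust_oracle(p, m), tolerance = 1e-12)
      expect_true(all(got >= p - 1e-15))
      expect_true(all(got <= pmin(1, m * p) + 1e-15))
    }
  })
})

test_that("score test is null on identical groups and matches permutations", {
  coh <- data.frame(subject_id = sprintf("S%02d", 1:40),
                    age = rep(30, 40), sex = "female",
                    diagnosis = rep(c("control", "patient"), each = 20),
                    stringsAsFactors = FALSE)
  sc <- data.frame(subject_id = coh$subject_id,
                   pct_negative = rep(c(0.5, 1, 0.2, 0.8), 10),
                   pct_positive = 0.4, n_mask_voxels = 2000)
  st <- score_group_test(sc, coh, "pct_negative")
  expect_lt(st$statistic, 1e-12)
  expect_gt(st$p, 0.99)

  # moderate effect: Wald p and the label-permutation p agree in order
  sc2 <- sc
  normdev:::with_seed(10, {
    base <- rbinom(40, 2000, 0.004)
    extra <- rbinom(40, 2000, 0.0008) * (coh$diagnosis == "patient")
    sc2$pct_negative <- 100 * (base + extra) / 2000
  })
  st2 <- score_group_test(sc2, coh, "pct_negative", n_perm = 4000, seed = 3)
  expect_lt(st2$p, 0.5)
  # the Wald test is asymptotic; at this size agreement is an absolute-scale
  # statement, not a ratio of far-tail probabilities
  expect_lt(abs(st2$p_permutation - st2$p), 0.05)
  expect_equal(st2$effect_direction, 1)
  expect_error(score_group_test(sc, coh[coh$diagnosis == "control", ]),
               "both diagnosis groups")
})

test_that("score_group_tests applies Holm across measures", {
  coh <- generate_cohort(simulation_config(n_controls = 40, n_patients = 40,
                                           seed = 17))
  normdev:::with_seed(18, {
    k <- rbinom(80, 3000, ifelse(coh$diagnosis == "patient", 0.008, 0.004))
    sc <- data.frame(subject_id = coh$subject_id,
                     pct_negative = 100 * k / 3000,
                     pct_positive = 100 * rbinom(80, 3000, 0.004) / 3000,
                     n_mask_voxels = 3000)
  })
  st <- score_group_tests(sc, coh)
  expect_equal(st$pct_negative$p_corrected,
               holm_correct(c(st$pct_negative$p, st$pct_positive$p))[1])
  expect_gte(st$pct_positive$p_corrected, st$pct_positive$p)
})

test_that("association tests return standardized betas with Holm family", {
  coh <- generate_cohort(simulation_config(n_controls = 10, n_patients = 150,
                                           seed = 19))
  # beta of a covariate against itself is 1 after standardization
  sc <- data.frame(subject_id = coh$subject_id,
                   pct_negative = coh$age, pct_positive = 1,
                   n_mask_voxels = 1000)
  at <- suppressWarnings(association_tests(sc, coh, measures = "pct_negative"))
  expect_equal(at$beta[at$covariate == "age"], 1, tolerance = 1e-12)
  expect_equal(unique(at$family_m), 8)

  # a null covariate stays null after correction; an age-loaded score is found
  normdev:::with_seed(20, {
    pat <- coh$diagnosis == "patient"
    sc2 <- data.frame(subject_id = coh$subject_id,
                      pct_negative = 0.3 + 0.01 * (coh$age - 40) + rnorm(160, sd = 0.05),
                      pct_positive = rnorm(160, 0.4, 0.05),
                      n_mask_voxels = 1000)
  })
  at2 <- association_tests(sc2, coh)
  age_row <- at2[at2$measure == "pct_negative" & at2$covariate == "age", ]
  expect_gt(age_row$beta, 0)
  expect_lt(age_row$p_corrected, 0.01)
  null_row <- at2[at2$measure == "pct_positive" & at2$covariate == "comorbidity", ]
  expect_gt(null_row$p_corrected, 0.05)
})
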