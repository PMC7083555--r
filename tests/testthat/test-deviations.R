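test_that("fixed thresholding is strict and sign-correct", {
  z <- c(0, 2.6, -2.6, 2.61, -2.61, 3, -3)
  pair <- threshold_map(z)
  expect_equal(which(pair$positive), c(4, 6))
  expect_equal(which(pair$negative), c(5, 7))
  expect_false(any(pair$positive & pair$negative))

  empty <- threshold_map(rep(0, 10))
  expect_false(any(empty$positive) || any(empty$negative))

  one <- threshold_map(c(rep(0, 4), -3.0))
  expect_equal(sum(one$negative), 1)
  expect_equal(sum(one$positive), 0)

  expect_error(threshold_map(z, threshold = 0), "> 0")
  expect_error(threshold_map(c(1, NA, 2)), "non-finite")
})

test_that("standard-normal Z yields the analytic extreme fraction", {
  z <- normdev:::with_seed(1, rnorm(1e5))
  pair <- threshold_map(z, 2.6)
  p0 <- pnorm(-2.6)
  ci <- p0 + c(-1, 1) * 1.96 * sqrt(p0 * (1 - p0) / 1e5)
  expect_gt(mean(pair$negative), ci[1])
  expect_lt(mean(pair$negative), ci[2])
})

test_that("per-subject FDR matches the exhaustive step-up oracle", {
  # the textbook list: all five survive at q = 0.05 (p(5) <= (5/5) * 0.05);
  # nudged inside the boundary so the z round trip cannot flip the tie in
  # floating point
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05) - 1e-9
  z <- -qnorm(p / 2)  # two-sided p recovers the input
  pair <- threshold_map_fdr(z, q = 0.05)
  expect_true(all(pair$positive))

  expect_false(any(threshold_map_fdr(rep(0, 20))$positive))

  normdev:::with_seed(2, {
    for (rep in 1:50) {
      z <- rnorm(sample(3:40, 1), sd = sample(c(1, 2), 1))
      pair <- threshold_map_fdr(z, q = 0.05)
      rej <- bh_reject_oracle(2 * pnorm(-abs(z)), 0.05)
      expect_identical(pair$positive | pair$negative, rej)
      # sign split
      expect_identical(pair$negative, rej & z < 0)
      # FDR rejections are a subset of the fixed threshold at the realized cutoff
      if (any(rej)) {
        fixed <- threshold_map(z, threshold = pair$z_cutoff * (1 - 1e-12))
        expect_true(all(which(pair$negative) %in% which(fixed$negative)))
        expect_true(all(which(pair$positive) %in% which(fixed$positive)))
      }
    }
  })
})

test_that("extreme scores are plain percentages with preserved order", {
  z <- matrix(0, 2, 1000)
  z[1, 1:5] <- -3  # 5 extreme negative voxels
  dev <- flat_stack(z)
  sc <- extreme_scores(dev)
  expect_equal(sc$pct_positive, c(0, 0))
  expect_equal(sc$pct_negative, c(0.5, 0))
  expect_equal(sc$n_mask_voxels, c(1000, 1000))
  expect_equal(sc$subject_id, dev$subject_id)

  # invariant to voxel ordering
  perm <- normdev:::with_seed(3, sample(1000))
  sc2 <- extreme_scores(flat_stack(z[, perm, drop = FALSE]))
  expect_equal(sc2$pct_negative, sc$pct_negative)
})

test_that("overlap maps count subjects per voxel", {
  mk <- function(pos) {
    v <- rep(0, 10); v[pos] <- 3
    threshold_map(v)
  }
  # single subject: overlap equals its own mask
  om1 <- overlap_map(list(mk(2)), "positive")
  expect_equal(om1$proportion, as.numeric(seq_len(10) == 2))

  # two disjoint subjects: max proportion 1/2
  om2 <- overlap_map(list(mk(1), mk(2)), "positive")
  expect_equal(max(om2$proportion), 0.5)

  # {a}, {a,b}, {b} -> a: 2/3, b: 2/3
  om3 <- overlap_map(list(mk(1), mk(c(1, 2)), mk(2)), "positive")
  expect_equal(om3$proportion[1:2], c(2, 2) / 3)

  # adding a subject with an empty mask never increases any proportion
  om4 <- overlap_map(list(mk(1), mk(c(1, 2)), mk(2), mk(integer(0))), "positive")
  expect_true(all(om4$proportion <= om3$proportion))

  # strict exceedance reading of the cut
  omc <- overlap_map(rep(list(mk(1)), 50), "positive", cut = 1)
  expect_false(any(omc$exceed))

  expect_error(overlap_map(list(mk(1), threshold_map(rep(0, 5))), "positive"),
               "different grids")
  expect_error(overlap_map(list(), "positive"), "at least one")
})
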