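test_that("log marginal likelihood matches the dense formula at fixed theta", {
  normdev:::with_seed(11, {
    X <- list(age = runif(5, 20, 60), sex = c("male", "female")[rbinom(5, 1, .5) + 1])
    y <- rnorm(5)
    th <- c(sf2 = log(.4), ell = log(1.2), wv = log(.6), bv = log(.2), nv = log(.3))
    m <- fit_voxel_gp(X, y, theta = th, standardize_y = FALSE)
    o <- dense_gp_oracle(X, y, X, th)
    expect_equal(m$lml, o$lml, tolerance = 1e-9)
  })
})

test_that("predictive moments equal the closed-form dense solution", {
  normdev:::with_seed(12, {
    X <- list(age = c(25, 40, 55), sex = c("male", "female", "male"))
    y <- c(0.3, -0.1, 0.2)
    Xs <- list(age = c(30, 50), sex = c("female", "male"))
    th <- random_theta()
    m <- fit_voxel_gp(X, y, theta = th, standardize_y = FALSE)
    pr <- predict_voxel(m, Xs)
    o <- dense_gp_oracle(X, y, Xs, th)
    expect_equal(pr$mean, o$mean, tolerance = 1e-6)
    expect_equal(pr$var_latent, o$var_latent, tolerance = 1e-6)
    expect_equal(pr$var_pred, o$var_pred, tolerance = 1e-6)
  })
})

test_that("a pure linear age trend is recovered against the OLS oracle", {
  normdev:::with_seed(13, {
    age <- seq(20, 60, length.out = 10)
    X <- list(age = age, sex = rep("female", 10))
    noise_sd <- 0.01
    y <- 1 + 0.05 * age + rnorm(10, sd = noise_sd)
    m <- fit_voxel_gp(X, y)
    interior <- list(age = seq(25, 55, length.out = 7), sex = rep("female", 7))
    pr <- predict_voxel(m, interior)
    ols <- lm(y ~ age)
    ols_pred <- predict(ols, data.frame(age = interior$age))
    expect_lt(max(abs(pr$mean - ols_pred)), 3 * noise_sd)
  })
})

test_that("zero-variance targets give a degenerate constant-mean model", {
  m <- fit_voxel_gp(list(age = seq(20, 60, 4), sex = rep("male", 11)),
                    rep(2.5, 11))
  expect_true(m$degenerate)
  pr <- predict_voxel(m, list(age = 33, sex = "female"))
  expect_equal(pr$mean, 2.5)
  expect_equal(pr$var_latent, 0)
})

test_that("interpolation and prior-reversion limits hold", {
  X <- list(age = c(20, 30, 40, 50, 60), sex = rep("female", 5))
  y <- c(0.1, 0.4, 0.2, -0.3, 0.5)
  th <- c(sf2 = log(1), ell = log(0.5), wv = log(1e-6), bv = log(1e-6),
          nv = log(1e-10))
  m <- fit_voxel_gp(X, y, theta = th, standardize_y = FALSE)
  at_train <- predict_voxel(m, list(age = 40, sex = "female"))
  expect_equal(at_train$mean, 0.2, tolerance = 1e-5)
  expect_lt(at_train$var_latent, 1e-6)
  # far from all training ages the stationary term reverts to its prior
  far <- predict_voxel(m, list(age = 200, sex = "female"))
  expect_equal(far$var_latent, 1, tolerance = 1e-3)
  expect_equal(far$mean, 0, tolerance = 1e-3)
})

test_that("zscore obeys its contract", {
  expect_equal(zscore(5, 5, 2), 0)
  expect_equal(zscore(5 - 2.6 * sqrt(2), 5, 2), -2.6)
  expect_equal(zscore(5 + sqrt(2), 5, 2), 1)
  # monotone in y, antisymmetric in (y - mean)
  z <- zscore(seq(-3, 3, 0.5), 0, 1.7)
  expect_true(all(diff(z) > 0))
  expect_equal(zscore(4, 1, 2), -zscore(-2, 1, 2))
  expect_error(zscore(1, 0, 0), "positive")
  expect_error(zscore(1, 0, -1), "positive")
})

test_that("Z is invariant to affine rescaling of the volumes (per-voxel path)", {
  normdev:::with_seed(14, {
    X <- list(age = runif(20, 18, 65),
              sex = c("male", "female")[rbinom(20, 1, .5) + 1])
    y <- 0.5 - 0.002 * X$age + rnorm(20, sd = 0.05)
    Xs <- list(age = c(22, 47), sex = c("female", "male"))
    ys <- c(0.43, 0.41)
    m1 <- fit_voxel_gp(X, y)
    m2 <- fit_voxel_gp(X, 100 * y + 7)
    z1 <- zscore(ys, predict_voxel(m1, Xs)$mean, predict_voxel(m1, Xs)$var_pred)
    z2 <- zscore(100 * ys + 7, predict_voxel(m2, Xs)$mean,
                 predict_voxel(m2, Xs)$var_pred)
    expect_equal(z1, z2, tolerance = 1e-6)
  })
})

test_that("optimised fit reproduces its stored log marginal likelihood", {
  normdev:::with_seed(15, {
    X <- list(age = runif(25, 18, 65),
              sex = c("male", "female")[rbinom(25, 1, .5) + 1])
    y <- 0.3 + 0.01 * X$age + rnorm(25, sd = 0.1)
    m <- fit_voxel_gp(X, y)
    ys <- (y - m$y_center) / m$y_scale
    o <- dense_gp_oracle(X, ys, X, m$theta)
    expect_equal(m$lml, o$lml, tolerance = 1e-6)
  })
})
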