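test_that("kernel_matrix scales pairwise Tanimoto similarities", {
  X <- matrix(c(1, 1, 0, 0, 0,
                0, 1, 1, 0, 0,
                0, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
  K1 <- kernel_matrix(X, amplitude = 1)
  expect_equal(diag(K1), rep(1, 3))
  expect_equal(K1, t(K1))
  # bit sets {1,2}, {2,3}, {5}: brute-force pairwise values
  expect_equal(K1[1, 2], 1 / 3)
  expect_equal(K1[1, 3], 0)
  expect_equal(K1, brute_tanimoto(X))
  expect_equal(kernel_matrix(X, amplitude = 2), 2 * K1)
})

test_that("posterior equals an explicit dense solve on small random pools", {
  withr::with_seed(11, {
    for (rep in 1:8) {
      n <- sample(3:20, 1)
      fp <- matrix(rbinom(n * 32, 1, 0.35), nrow = n)
      fp[rowSums(fp) == 0, 1] <- 1
      y <- rnorm(n, 6, 1.2)
      fq <- matrix(rbinom(4 * 32, 1, 0.35), nrow = 4)
      fq[rowSums(fq) == 0, 2] <- 1
      hp <- gp_hyperparams(amplitude = 1.3, noise_variance = 0.05)
      fit <- suppressWarnings(fit_gp(fp, y, hyper = hp))
      post <- predict(fit, fq)
      oracle <- dense_gp_oracle(fp, y, fq, 1.3, 0.05)
      expect_equal(post$mean, oracle$mean, tolerance = 1e-8)
      expect_equal(post$variance, oracle$variance, tolerance = 1e-8)
    }
  })
})

test_that("five-point fit matches the hand-built linear algebra", {
  fp <- diag(5)[, rep(1:5, each = 2)] # 5 disjoint 2-bit fingerprints
  y <- c(5.5, 6.0, 7.2, 6.8, 5.9)
  fit <- fit_gp(fp, y, hyper = gp_hyperparams(amplitude = 1, noise_variance = 0.1))
  post <- predict(fit, fp)
  oracle <- dense_gp_oracle(fp, y, fp, 1, 0.1)
  expect_equal(post$mean, oracle$mean, tolerance = 1e-8)
  expect_equal(post$variance, oracle$variance, tolerance = 1e-8)
})

test_that("single-point and degenerate fits behave", {
  fp <- matrix(c(1, 1, 0, 0), nrow = 1)
  fit <- fit_gp(fp, 7, hyper = gp_hyperparams(amplitude = 1, noise_variance = 0.1))
  # with one point the standardized label is 0, so the shrunk prediction at
  # the training point equals the label itself
  expect_equal(predict(fit, fp)$mean, 7)

  # duplicate rows with equal labels succeed via jitter
  fp2 <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), nrow = 2, byrow = TRUE)
  fit2 <- fit_gp(fp2, c(5, 5), hyper = gp_hyperparams(noise_variance = 1e-6))
  expect_s3_class(fit2, "tanimoto_gp")
})

test_that("interpolation and prior-fallback limits hold", {
  withr::with_seed(4, {
    fp <- matrix(rbinom(6 * 24, 1, 0.5), nrow = 6)
    fp[, 24] <- 0 # reserve one bit unseen in training
    fp[rowSums(fp) == 0, 1] <- 1
  })
  y <- c(5, 6, 7, 8, 6.5, 7.5)
  fit <- fit_gp(fp, y, hyper = gp_hyperparams(amplitude = 1, noise_variance = 1e-6))
  post <- predict(fit, fp)
  expect_equal(post$mean, y, tolerance = 1e-3)
  expect_true(all(post$variance < 1e-3))
  # variance at training inputs never exceeds the noise level (plus jitter)
  expect_true(all(post$variance <= (1e-6 + 2e-6) * fit$sd_y^2 + 1e-8))

  # a query sharing no bits with training falls back to the prior
  far <- matrix(0, nrow = 1, ncol = 24)
  far[1, 24] <- 1
  post_far <- predict(fit, far)
  expect_equal(post_far$mean, fit$hyper$mean_constant * fit$sd_y + fit$mu_y)
  expect_equal(post_far$variance, fit$hyper$amplitude * fit$sd_y^2)

  expect_error(predict(fit, matrix(1, 1, 10)), "length")
})

test_that("conditioning on more data never inflates posterior variance", {
  withr::with_seed(9, {
    fp <- matrix(rbinom(15 * 32, 1, 0.4), nrow = 15)
    fp[rowSums(fp) == 0, 1] <- 1
    y <- rnorm(15, 6, 1)
    fq <- matrix(rbinom(3 * 32, 1, 0.4), nrow = 3)
    fq[rowSums(fq) == 0, 1] <- 1
  })
  # fits with different training subsets must share one prior, so hold the
  # label scale fixed instead of re-standardizing per subset
  hp <- gp_hyperparams(amplitude = 1, noise_variance = 0.1)
  for (n in c(3, 6, 10, 14)) {
    v_small <- predict(fit_gp(fp[1:n, ], y[1:n], hyper = hp, standardize = FALSE),
                       fq)$variance
    v_big <- predict(fit_gp(fp[1:(n + 1), ], y[1:(n + 1)], hyper = hp, standardize = FALSE),
                     fq)$variance
    expect_true(all(v_big <= v_small + 1e-8))
  }
})

test_that("marginal-likelihood ascent improves the fit and respects `fix`", {
  withr::with_seed(2, {
    pool <- generate_library(synthetic_scenario(
      120, 6, seed = 2, fingerprint_length = 256, core_bits_per_cluster = 12,
      substituent_bits = 12, cluster_effect_sd = 1, substituent_effect_sd = 0.2,
      residual_sd = 0.3))
  })
  fp <- pool$fingerprint
  init <- gp_hyperparams(fit_iterations = 80)
  fixed_fit <- fit_gp(fp, pool$potency, hyper = init)
  opt_fit <- fit_gp(fp, pool$potency, hyper = "optimize", init = init)
  expect_gt(opt_fit$log_marginal_likelihood, fixed_fit$log_marginal_likelihood)

  pinned <- fit_gp(fp, pool$potency, hyper = "optimize", init = init,
                   fix = c("amplitude", "mean_constant"))
  expect_equal(pinned$hyper$amplitude, 1)
  expect_equal(pinned$hyper$mean_constant, 0)
  expect_false(isTRUE(all.equal(pinned$hyper$noise_variance, 0.1)))
  expect_error(fit_gp(fp, pool$potency, fix = "bandwidth"), "Unknown hyperparameter")
})

test_that("optimized noise variance tracks the generative residual noise", {
  residual_sds <- c(0.05, 0.3, 0.6, 1.0, 1.6)
  noise_hat <- vapply(seq_along(residual_sds), function(i) {
    pool <- generate_library(synthetic_scenario(
      150, 6, seed = 100 + i, fingerprint_length = 256,
      core_bits_per_cluster = 12, substituent_bits = 12,
      cluster_effect_sd = 1, substituent_effect_sd = 0.2,
      residual_sd = residual_sds[i]))
    fit <- fit_gp(pool$fingerprint, pool$potency, hyper = "optimize",
                  init = gp_hyperparams(fit_iterations = 120), fix = "amplitude")
    fit$hyper$noise_variance
  }, numeric(1))
  expect_gt(cor(noise_hat, residual_sds^2, method = "spearman"), 0.8)
})

test_that("tidy and glance summarize a fitted GP", {
  fit <- fit_gp(make_random_pool(10, 24)$fingerprint, make_random_pool(10, 24)$potency,
                hyper = gp_hyperparams())
  td <- tidy(fit)
  expect_equal(td$term, c("amplitude", "noise_variance", "mean_constant"))
  gl <- glance(fit)
  expect_equal(gl$n_train, 10)
  expect_true(is.finite(gl$log_marginal_likelihood))
})
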