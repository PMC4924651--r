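test_that("standardize_profile centers, scales and rejects constants", {
  z <- standardize_profile(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(order(z), 1:3)
  expect_equal(standardize_profile(z), z, tolerance = 1e-12)
  expect_error(standardize_profile(c(5, 5, 5)), "constant")
})

test_that("neural-network covariance matches its closed form and is symmetric", {
  # hand evaluation with x~ = [1, 0]: asin(1 / 2)
  expect_equal(nn_covariance(0, 0, l = 1, sf2 = 1), asin(0.5))
  set.seed(42)
  for (i in 1:100) {
    x <- runif(1, -1, 2); x2 <- runif(1, -1, 2)
    l <- runif(1, 0.05, 3); sf2 <- runif(1, 0.1, 4)
    expect_equal(nn_covariance(x, x2, l, sf2), nn_covariance(x2, x, l, sf2))
    expect_lte(abs(nn_covariance(x, x2, l, sf2)), sf2 * pi / 2 + 1e-12)
  }
  # infinite length scale drives the asin argument, hence k, to zero
  expect_lt(abs(nn_covariance(0.3, 0.7, l = 1e8, sf2 = 1)), 1e-12)
  expect_error(nn_covariance(0, 1, l = -1, sf2 = 1), "positive")
})

test_that("Gram matrices are symmetric and almost positive semi-definite", {
  set.seed(7)
  for (i in 1:100) {
    x <- runif(sample(3:20, 1), 0, 1)
    K <- nn_covariance(x, x, runif(1, 0.05, 2), runif(1, 0.1, 4))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("gp_log_marginal equals the dense multivariate-normal oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    x <- runif(n); y <- rnorm(n)
    h <- list(l = runif(1, 0.05, 1.5), sf2 = runif(1, 0.1, 3),
              sn2 = runif(1, 0.01, 0.9))
    C <- nn_covariance(x, x, h$l, h$sf2) + diag(h$sn2 + 1e-8, n)
    oracle <- -0.5 * drop(t(y) %*% solve(C, y)) -
      0.5 * as.numeric(determinant(C)$modulus) - n / 2 * log(2 * pi)
    expect_equal(gp_log_marginal(x, y, h), oracle, tolerance = 1e-8)
  }
  # n = 1 scalar closed form
  h <- list(l = 0.3, sf2 = 1.2, sn2 = 0.2)
  expect_equal(gp_log_marginal(0.4, 0.7, h),
               dnorm(0.7, 0, sqrt(nn_covariance(0.4, 0.4, h$l, h$sf2) + h$sn2 + 1e-8),
                     log = TRUE),
               tolerance = 1e-9)
  # invariance under joint permutation
  set.seed(3)
  x <- runif(12); y <- rnorm(12); p <- sample(12)
  expect_equal(gp_log_marginal(x, y, h), gp_log_marginal(x[p], y[p], h),
               tolerance = 1e-9)
})

test_that("gp_predict matches direct linear-system solutions", {
  set.seed(5)
  x <- c(0, 6, 12, 24, 48, 72)
  y <- standardize_profile(sin(x / 20) + rnorm(6, 0, 0.05))
  fit <- fit_gp_map(x, y, restarts = 2, seed = 1)
  pred <- gp_predict(fit, x)
  h <- fit$hyperparams
  xs <- x / 72
  C <- nn_covariance(xs, xs, h$l, h$sf2) + diag(h$sn2, 6)
  ks <- nn_covariance(xs, xs, h$l, h$sf2)
  mu_oracle <- drop(t(ks) %*% solve(C, y))
  expect_equal(pred$mean, mu_oracle, tolerance = 1e-6)
  # predictive variance at a training point cannot exceed the noise floor
  expect_true(all(pred$var <= h$sn2 + 1e-6))
  expect_true(all(pred$var >= 0))
  expect_equal(nrow(gp_predict(fit, numeric())), 0L)
  expect_warning(gp_predict(fit, 120), "extrapolat")
})

test_that("interpolation approaches the data as the noise floor is reached", {
  # length scale short enough that the Gram matrix stays well conditioned:
  # the smoothing bias then vanishes as sn2 reaches its floor
  x <- c(0, 12, 24, 48, 72)
  y <- standardize_profile(c(-1, -0.5, 0.6, 1.2, 1.4))
  h <- list(l = 0.1, sf2 = 2, sn2 = 1e-4)
  xs <- x / 72
  C <- nn_covariance(xs, xs, h$l, h$sf2) + diag(h$sn2, 5)
  mu <- drop(nn_covariance(xs, xs, h$l, h$sf2) %*% solve(C, y))
  expect_equal(mu, y, tolerance = 0.01)
})

test_that("hyperprior density behaves as specified", {
  # signal-variance prior peaks near its shape-rate mode (10 - 1) / 10 = 0.9
  grid <- seq(0.05, 3, by = 0.01)
  dens <- vapply(grid, function(s)
    hyperprior_logdensity(list(l = 5 / 30, sf2 = s, sn2 = 0.1), 0.1), 0)
  expect_equal(grid[which.max(dens)], 0.9, tolerance = 0.02)
  # outside the admissible region: -Inf, not an error
  expect_identical(hyperprior_logdensity(list(l = 0.2, sf2 = 1, sn2 = 1.5), 0.1),
                   -Inf)
  expect_identical(hyperprior_logdensity(list(l = -1, sf2 = 1, sn2 = 0.5), 0.1),
                   -Inf)
  expect_identical(
    hyperprior_logdensity(list(l = 0.2, sf2 = 1, sn2 = 0.5, dt = 30), 0.1),
    -Inf)
  set.seed(13)
  for (i in 1:100) {
    h <- list(l = runif(1, 0.01, 2), sf2 = runif(1, 0.05, 4),
              sn2 = runif(1, 1e-3, 1), dt = runif(1, -24, 24))
    expect_true(is.finite(hyperprior_logdensity(h, runif(1, 0.01, 1))))
  }
})

test_that("MAP fitting is deterministic and noise-dominated for pure noise", {
  x <- rep(c(0, 6, 12, 24, 48, 72), each = 5)
  set.seed(9)
  y <- standardize_profile(rnorm(30))
  f1 <- fit_gp_map(x, y, restarts = 3, seed = 4)
  f2 <- fit_gp_map(x, y, restarts = 3, seed = 4)
  expect_identical(f1$hyperparams, f2$hyperparams)
  # i.i.d. standardized noise should be absorbed by the noise variance
  expect_gte(f1$hyperparams$sn2, 0.5)
  # and the MAP objective dominates a grid over the hyperparameter box
  grid <- expand.grid(l = exp(seq(log(0.03), log(1.5), length.out = 12)),
                      sf2 = exp(seq(log(0.08), log(4), length.out = 12)),
                      sn2 = seq(0.05, 1, length.out = 12))
  gobj <- vapply(seq_len(nrow(grid)), function(i)
    gp_log_marginal(x / 72, y, list(l = grid$l[i], sf2 = grid$sf2[i],
                                    sn2 = grid$sn2[i])) +
      hyperprior_logdensity(list(l = grid$l[i], sf2 = grid$sf2[i],
                                 sn2 = grid$sn2[i]), f1$noise_mode), 0)
  expect_gte(f1$log_map_objective, max(gobj))
})

test_that("fit_shared recovers zero shift for identical profiles", {
  x <- rep(paper_timepoints, each = 3)
  set.seed(2)
  sim <- simulate_ortholog_timecourse(1, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0.05, seed = 2)
  yh <- standardize_profile(log2(sim$human$values[1, ] + 1))
  ym <- standardize_profile(log2(sim$mouse$values[1, ] + 1))
  fs <- fit_shared(x, yh, x, ym, dt_grid = c(-12, 0, 12), seed = 1)
  expect_equal(fs$hyperparams$dt, 0)
  expect_equal(fs$dt_grid, c(-12, 0, 12))
  expect_equal(which.max(fs$dt_objectives), 2L)
  # grid of length 1 returns that value
  one <- fit_shared(x, yh, x, ym, dt_grid = 6, seed = 1)
  expect_equal(one$hyperparams$dt, 6)
  expect_error(fit_shared(x, yh, x, ym, dt_grid = numeric()), "non-empty")
})

test_that("Bayes factor separates duplicated from unrelated profiles", {
  x <- rep(paper_timepoints, each = 3)
  sim <- simulate_ortholog_timecourse(1, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0, seed = 6)
  base <- standardize_profile(log2(sim$human$values[1, ] + 1))
  withr::with_seed(8, {
    yh <- standardize_profile(base + rnorm(30, 0, 0.05))
    ym <- standardize_profile(base + rnorm(30, 0, 0.05))
    noise <- standardize_profile(rnorm(30))
  })
  dup <- bayes_factor_pair(x, yh, x, ym, dt_grid = c(-6, 0, 6), seed = 1)
  expect_equal(dup$call, "shared")
  expect_gt(dup$bf, 10)
  diff <- bayes_factor_pair(x, yh, x, noise, dt_grid = c(-6, 0, 6), seed = 1)
  expect_equal(diff$call, "different")
})

test_that("the Bayes factor is symmetric in species for identical data", {
  x <- rep(paper_timepoints, each = 2)
  sim <- simulate_ortholog_timecourse(1, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0.1, n_replicates = 2, seed = 12)
  y <- standardize_profile(log2(sim$human$values[1, ] + 1))
  a <- bayes_factor_pair(x, y, x, y, dt_grid = 0, seed = 5)
  b <- bayes_factor_pair(x, y, x, y, dt_grid = 0, seed = 5)
  expect_equal(a$bf, b$bf)
  expect_equal(a$logml_human, a$logml_mouse)
})

test_that("batch driver skips constant genes and keeps pair metadata", {
  sim <- simulate_ortholog_timecourse(3, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0.1, seed = 10)
  sim$human$values[2, ] <- 5  # constant profile
  bft <- bayes_factor_table(sim$human, sim$mouse, sim$orthologs,
                            dt_grid = c(-6, 0, 6), seed = 2)
  expect_equal(nrow(bft), 2L)
  expect_equal(attr(bft, "skipped"), "HG0002/MG0002")
  expect_true(all(c("human_gene", "mouse_gene", "bf", "dt_hat", "call") %in%
                    colnames(bft)))
})
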