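test_that("grid_predict: identity at sigma 0, Gaussian spread of a point
           mass, and the semigroup property", {
  gd <- grid_density(0, 15, 400)
  expect_identical(grid_predict(gd, 0), gd)

  # point mass at lambda = 5 spreads into a discretized N(5, 0.5)
  gd$mass <- as.numeric(abs(gd$points - 5) < 1e-9)
  gd$mass <- gd$mass / sum(gd$mass)
  sp <- grid_predict(gd, 0.5)
  ref <- dnorm(gd$points, 5, 0.5); ref <- ref / sum(ref)
  expect_lt(max(abs(sp$mass - ref)), 1e-8)

  # two sigma-steps equal one sqrt(2) sigma step
  gd2 <- grid_density(0, 15, 300)
  gd2$mass <- dnorm(gd2$points, 6, 1); gd2$mass <- gd2$mass / sum(gd2$mass)
  two <- grid_predict(grid_predict(gd2, 0.3), 0.3)
  one <- grid_predict(gd2, 0.3 * sqrt(2))
  expect_lt(max(abs(two$mass - one$mass)), 1e-6)
  expect_error(grid_predict(gd2, -1), ">= 0")
})

test_that("grid_update has the likelihood shape, accumulates evidence
           additively, and stays normalized", {
  gd <- grid_density(0, 15, 500)
  gd$mass <- rep(1 / 500, 500)  # flat prior
  up <- grid_update(gd, 0)
  ref <- exp(-gd$points); ref <- ref / sum(ref)
  expect_lt(max(abs(up$density$mass - ref)), 1e-12)
  expect_lt(abs(sum(up$density$mass) - 1), 1e-10)

  set.seed(1)
  xs <- rpois(30, 3)
  gd <- grid_density(0, 15, 300)
  inc_sum <- 0
  for (x in xs) {
    up <- grid_update(gd, x)
    gd <- up$density
    inc_sum <- inc_sum + up$increment
    expect_lt(abs(sum(gd$mass) - 1), 1e-10)
  }
  expect_equal(gd$log_evidence, inc_sum)
  expect_error(grid_update(gd, -1), "non-negative")
})

test_that("with sigma 0 the lattice reproduces the conjugate Gamma filter", {
  set.seed(2)
  x <- rpois(100, 2.5)
  g <- grid_filter_run(x, lambda_grid = c(0, 15, 200),
                       sigma_grid = c(0, 0, 1))
  for (t in c(1, 10, 100)) {
    shape <- 1 + sum(x[seq_len(t)]); rate <- 0.5 + t
    expect_lt(abs(g$summary$mean[t] - shape / rate) / (shape / rate), 0.005)
    expect_lt(abs(g$summary$sd[t] - sqrt(shape) / rate) /
                (sqrt(shape) / rate), 0.005)
  }
  # pure accumulation: the SD trend is contraction (an individual step can
  # tick upward when a large count lands, exactly as the conjugate form
  # sqrt(1 + sum x) / (0.5 + t) does)
  sd_s <- sma(g$summary$sd, 10)
  expect_true(all(diff(sd_s[10:100]) < 0))
  expect_lt(g$summary$sd[100], 0.5 * g$summary$sd[1])
  conj_sd <- sqrt(1 + cumsum(x)) / (0.5 + seq_along(x))
  expect_lt(max(abs(g$summary$sd - conj_sd) / conj_sd), 0.005)
})

test_that("a single observation under a flat prior returns the likelihood", {
  g <- grid_filter_run(3L, lambda_grid = c(0, 15, 400),
                       sigma_grid = c(0, 0, 1),
                       lambda_prior = prior_spec("uniform", min = 0,
                                                 max = 15))
  lik <- dpois(3, seq(0, 15, length.out = 400))
  expect_lt(abs(g$summary$mean[1] - sum(lik * seq(0, 15, length.out = 400)) /
                  sum(lik)), 1e-6)
})

test_that("doubling the lattice resolution moves the final mean < 0.1%", {
  set.seed(3)
  sim <- simulate_dataset(coal_model(), 60, seed = 77)
  g1 <- grid_filter_run(sim$series$count, lambda_grid = c(0, 15, 200),
                        sigma_grid = c(0, 1, 20))
  g2 <- grid_filter_run(sim$series$count, lambda_grid = c(0, 15, 400),
                        sigma_grid = c(0, 1, 20))
  m1 <- tail(g1$summary$mean, 1); m2 <- tail(g2$summary$mean, 1)
  expect_lt(abs(m1 - m2) / m2, 0.001)
})

test_that("the filter recovers a known dynamic rate within the prior scale", {
  sim <- simulate_dataset(coal_model(), 110, seed = 41)
  g <- grid_filter_run(sim$series$count)
  truth <- sim$theta[-1, 1]
  mae <- mean(abs(g$summary$mean - truth))
  expect_lt(mae, 2)  # prior SD of Exp(0.5) is 2
  expect_gt(min(g$summary$sd), 0)
  expect_true(is.finite(g$log_evidence))
  expect_error(grid_filter_run(integer(0)), "empty")
})
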