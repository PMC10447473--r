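static_poisson_model <- function() {
  superstat_model(low_level_spec("poisson"), transition_spec("static"))
}

test_that("SBC rank bookkeeping: truths below every draw rank zero", {
  m <- static_poisson_model()
  degenerate <- function(series, checkpoints, n_draws) {
    # all draws far above any plausible rate
    list(theta = array(100, c(length(checkpoints), n_draws, 1)),
         eta = array(0, c(length(checkpoints), n_draws, 0)))
  }
  res <- suppressWarnings(
    sbc(m, degenerate, T = 10, n_sim = 20, n_draws = 50, seed = 1))
  expect_true(all(res$ranks[[1]] == 0))
  expect_true(res$summary$ecdf_violation[1])
})

test_that("the exact conjugate sampler passes SBC uniformity and a shifted
           sampler fails it", {
  m <- static_poisson_model()
  res <- sbc(m, conjugate_poisson_sampler(), T = 40, n_sim = 200,
             n_draws = 250, checkpoints = c(20, 40), seed = 2)
  expect_true(all(res$summary$ks_p > 0.01))
  expect_false(any(res$summary$ecdf_violation))
  bad <- sbc(m, conjugate_poisson_sampler(shift = 0.5), T = 40,
             n_sim = 200, n_draws = 250, seed = 3)
  expect_lt(bad$summary$ks_p[1], 0.01)
  expect_warning(sbc(m, conjugate_poisson_sampler(), T = 5, n_sim = 20,
                     n_draws = 20, seed = 4), "underpowered")
})

test_that("recovery reduces to closed forms for perfect and offset
           estimates", {
  m <- ddm_model("static")
  sims <- lapply(1:4, function(i) simulate_dataset(m, 20, seed = 30 + i))
  mk_fit <- function(sim, delta = 0) {
    th <- sim$theta[-1, , drop = FALSE] + delta
    arr <- array(0, c(20, 2, 3))
    arr[, 1, ] <- th; arr[, 2, ] <- th
    structure(list(theta = arr, eta = array(0, c(20, 2, 0)),
                   theta_names = colnames(sim$theta), eta_names = character(0),
                   T = 20L, n = 2L), class = "superstat_filter")
  }
  rep0 <- recovery(sims, lapply(sims, mk_fit))
  expect_true(all(rep0$mae == 0))
  repd <- recovery(sims, lapply(sims, mk_fit, delta = 0.25),
                   t_scatter = 10)
  expect_true(all(abs(repd$mae - 0.25) < 1e-12))
  expect_true(all(repd$scatter$correlation > 0.999))
  expect_error(recovery(sims[1:2], lapply(sims[1:3], mk_fit)), "match")
})

test_that("retrodictive bands collapse for a degenerate posterior and cover
           well-specified data", {
  m <- coal_model()
  sim <- simulate_dataset(m, 60, seed = 5)
  T <- 60
  # degenerate single-draw posterior at the truth
  arr <- array(sim$theta[-1, 1], c(T, 1, 1))
  fit1 <- structure(list(theta = arr, eta = array(0, c(T, 1, 1)),
                         theta_names = "lambda", eta_names = "sigma_lambda",
                         T = T, n = 1L), class = "superstat_filter")
  b1 <- retrodictive_check(m, fit1, n = 1, seed = 6)
  expect_true(all(b1$band$lower == b1$band$upper))
  expect_equal(nrow(b1$band), T)

  # wide posterior (exact conjugate, sigma = 0 data): ~95% pointwise coverage
  ms <- static_poisson_model()
  covs <- c()
  for (i in 1:25) {
    s <- simulate_dataset(ms, 40, seed = 600 + i)
    cs <- cumsum(s$series$count)
    arr <- array(0, c(40, 200, 1))
    for (t in 1:40) arr[t, , 1] <- rgamma(200, 1 + cs[t], rate = 0.5 + t)
    fit <- structure(list(theta = arr, eta = array(0, c(40, 200, 0)),
                          theta_names = "lambda", eta_names = character(0),
                          T = 40L, n = 200L), class = "superstat_filter")
    band <- retrodictive_check(ms, fit, n = 200, seed = 700 + i)
    covs <- c(covs, band_coverage(band, s$series$count))
  }
  expect_gt(mean(covs), 0.90)
  expect_true(all(b1$band$lower <= b1$band$median &
                    b1$band$median <= b1$band$upper))
})

test_that("multi-horizon bands: empty at horizon zero, observation-noise
           width under frozen dynamics", {
  m <- coal_model()
  th <- matrix(4, 50, 1); et <- matrix(0, 50, 1,
                                       dimnames = list(NULL, "sigma_lambda"))
  b0 <- multi_horizon_predict(m, th, et, horizon = 0, n = 20, seed = 7)
  expect_equal(nrow(b0$band), 0)
  b <- multi_horizon_predict(m, th, et, horizon = 200, n = 400, seed = 8)
  # frozen rate 4: the band should match Poisson(4) quantiles
  expect_equal(median(b$band$median), 4, tolerance = 0.3)
  expect_true(all(b$band$lower >= qpois(0.001, 4) &
                    b$band$upper <= qpois(0.999, 4) + 1))
  expect_error(multi_horizon_predict(m, th, et, horizon = -1), ">= 0")
})

test_that("unbiased MMD agrees with a brute-force double loop and separates
           distinct distributions", {
  set.seed(9)
  A <- matrix(rnorm(40 * 2), 40, 2)
  B <- matrix(rnorm(35 * 2, 0.3), 35, 2)
  est <- mmd(A, B)
  h <- attr(est, "bandwidth")
  kern <- function(x, y) exp(-sum((x - y)^2) / (2 * h^2))
  sAA <- 0; for (i in 1:40) for (j in 1:40) if (i != j)
    sAA <- sAA + kern(A[i, ], A[j, ])
  sBB <- 0; for (i in 1:35) for (j in 1:35) if (i != j)
    sBB <- sBB + kern(B[i, ], B[j, ])
  sAB <- 0; for (i in 1:40) for (j in 1:35)
    sAB <- sAB + kern(A[i, ], B[j, ])
  brute <- sAA / (40 * 39) + sBB / (35 * 34) - 2 * sAB / (40 * 35)
  expect_equal(attr(est, "raw"), brute, tolerance = 1e-12)

  expect_equal(as.numeric(mmd(A, A)), 0, tolerance = 1e-12)

  x <- matrix(rnorm(500), ncol = 1); y <- matrix(rnorm(500), ncol = 1)
  null_est <- mmd(x, y)
  expect_lt(as.numeric(null_est), 0.02)

  z <- matrix(rnorm(500, 3), ncol = 1)
  sep <- as.numeric(mmd(x, z, bandwidth = attr(null_est, "bandwidth")))
  # permutation null from the pooled (x, y) sample
  pool <- rbind(x, y)
  null_dist <- replicate(60, {
    idx <- sample(1000, 500)
    as.numeric(mmd(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE],
                   bandwidth = attr(null_est, "bandwidth")))
  })
  expect_gt(sep, quantile(null_dist, 0.99))
  expect_error(mmd(x, matrix(0, 5, 2)), "dimension")
})

test_that("trailing moving average handles constants, identity, arithmetic,
           and degenerate periods", {
  expect_equal(sma(rep(2.5, 10), 4), rep(2.5, 10))
  x <- rnorm(20)
  expect_equal(sma(x, 1), x)
  s <- sma(1:10, 5)
  expect_equal(s[10], mean(6:10))  # = 8
  expect_equal(s[1:4], c(1, 1.5, 2, 2.5))
  expect_warning(out <- sma(1:3, 5), "period")
  expect_equal(out, c(1, 1.5, 2))
  expect_error(sma(1:3, 0), "positive")
})
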