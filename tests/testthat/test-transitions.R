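test_that("random-walk step is theta + sigma * xi with scale validation", {
  expect_equal(transition_random_walk(1.0, 0, 0.7), 1.0)
  expect_equal(transition_random_walk(1.0, 0.1, 1.0), 1.1)
  expect_equal(transition_random_walk(c(1, 2), c(0.5, 0), c(2, 9)),
               c(2, 2))
  expect_error(transition_random_walk(1, -0.1, 0), ">= 0")
  expect_error(transition_random_walk(c(1, 2), c(0.1, 0.1), 1), "lengths")
})

test_that("random-walk increments match their nominal scale and normality", {
  set.seed(3)
  n <- 1e5
  xi <- rnorm(n)
  inc <- vapply(seq_len(n),
                function(i) transition_random_walk(0, 0.05, xi[i]),
                numeric(1))
  # SD of the sample SD is about sigma / sqrt(2 n)
  expect_lt(abs(sd(inc) - 0.05), 3 * 0.05 / sqrt(2 * n))
  expect_lt(abs(mean(inc)), 3 * 0.05 / sqrt(n))
  # moment-based normality: skewness ~ 0, excess kurtosis ~ 0
  z <- inc / sd(inc)
  expect_lt(abs(mean(z^3)), 3 * sqrt(6 / n))
  expect_lt(abs(mean(z^4) - 3), 3 * sqrt(24 / n))
})

test_that("VAR step reduces to known closed forms", {
  d <- 2
  eta <- list(c = rep(0, d), A = list(diag(d)), sigma = 0)
  th <- c(1.3, -0.4)
  expect_equal(transition_var(rbind(th), eta, rep(0, d)), th)
  eta$A <- list(0.5 * diag(d))
  expect_equal(transition_var(rbind(c(2, 2)), eta, rep(0, d)), c(1, 1))
  expect_error(transition_var(rbind(th), list(c = 0, A = list(diag(3))),
                              0), "must be|mismatch")
})

test_that("VAR(1) long run reaches the stationary mean c (I - A)^-1", {
  set.seed(4)
  d <- 2
  A <- matrix(c(0.6, 0.1, 0.0, 0.7), 2, 2)
  cc <- c(1, -2)
  eta <- list(c = cc, A = list(A), sigma = 0.3)
  stat_mean <- solve(diag(d) - A, cc)
  th <- stat_mean  # start at the mean, measure the time average
  n <- 2e4
  acc <- matrix(0, n, d)
  for (t in seq_len(n)) {
    th <- transition_var(rbind(th), eta, rnorm(d, 0, eta$sigma))
    acc[t, ] <- th
  }
  # stationary SD per component is bounded by sigma/sqrt(1-rho^2) ~ 0.45;
  # time-averaged mean converges much faster than iid, use a generous 5 SE
  expect_lt(max(abs(colMeans(acc) - stat_mean)), 5 * 0.45 / sqrt(n / 20))
})

test_that("GP trajectories: zero amplitude, long length-scale, PSD kernel", {
  set.seed(5)
  tr <- sample_gp_trajectory(50, list(sigma = 0, l = 0.2), mean = c(1.5))
  expect_true(all(tr == 1.5))
  # l much longer than the grid span: sample paths are nearly constant
  tr2 <- sample_gp_trajectory(100, list(sigma = 1, l = 50), mean = 0)
  expect_lt(sd(tr2), 0.05 * 1)
  for (T in c(16, 128, 512)) for (l in c(0.05, 0.3, 1)) {
    K <- se_kernel_matrix(T, sigma = 0.7, l = l)
    expect_equal(K, t(K))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(sample_gp_trajectory(50, list(sigma = 1, l = 0), 0), "> 0")
})

test_that("GP empirical covariance matches the SE kernel", {
  set.seed(6)
  T <- 10; sig <- 0.8; l <- 0.4
  n <- 8000
  draws <- replicate(n,
    sample_gp_trajectory(T, list(sigma = sig, l = l), mean = 0)[, 1])
  K <- sig^2 * exp(-outer(seq(0, 1, length.out = T + 1),
                          seq(0, 1, length.out = T + 1), "-")^2 / (2 * l^2))
  emp <- cov(t(draws))
  # MC SE of a covariance entry is roughly sqrt((K_tt K_ss + K_ts^2)/n)
  for (i in c(1, 5, 11)) for (j in c(1, 8)) {
    se <- sqrt((K[i, i] * K[j, j] + K[i, j]^2) / n)
    expect_lt(abs(emp[i, j] - K[i, j]), 3.5 * se + 1e-6)
  }
})

test_that("regime switching is the identity off switch times and jumps
           uniformly within bounds at them", {
  spec <- transition_spec("regime_switch", switch_times = c(10L, 20L))
  spec$jump_bounds <- cbind(rep(0, 3), rep(1, 3))
  th <- c(0.2, 5, -3)
  expect_identical(transition_regime_switch(th, 5L, spec), th)
  set.seed(7)
  for (i in 1:20) {
    j <- transition_regime_switch(th, 10L, spec)
    expect_true(all(j >= 0 & j <= 1))
  }
  expect_error(transition_spec("regime_switch", switch_times = c(20L, 10L)),
               "increasing")
})

test_that("regime-switching DDM trajectory has exactly 4 constant segments
           for switches at 100/200/300 and T = 400", {
  m <- ddm_model(transition_spec("regime_switch",
                                 switch_times = c(100L, 200L, 300L)))
  sim <- simulate_dataset(m, 400, seed = 8)
  seg <- function(rows) {
    apply(sim$theta[rows, , drop = FALSE], 2,
          function(x) diff(range(x)))
  }
  # rows are t = 0..400 (offset by 1); jumps land at t = 100, 200, 300
  expect_true(all(seg(1:100) == 0))    # t = 0..99
  expect_true(all(seg(101:200) == 0))  # t = 100..199
  expect_true(all(seg(201:300) == 0))  # t = 200..299
  expect_true(all(seg(301:401) == 0))  # t = 300..400
  expect_false(all(sim$theta[101, ] == sim$theta[100, ]))
})

test_that("inter-trial variability is memoryless with the declared scale", {
  expect_equal(transition_itv(c(1, 2), 0), c(1, 2))
  m <- ddm_model("itv")
  sim <- simulate_dataset(m, 2000, seed = 9)
  ztraj <- superstat:::link_transform(m$low_level, sim$theta)[-1, ]
  scales <- sim$eta[paste0("scale_", m$low_level$par_names)]
  for (j in 1:3) {
    x <- ztraj[, j]
    n <- length(x)
    r1 <- cor(x[-1], x[-n])
    expect_lt(abs(r1), 4 / sqrt(n))   # lag-1 autocorrelation ~ 0
    expect_lt(abs(sd(x) - scales[j]),
              4 * scales[j] / sqrt(2 * n) + 0.003)
  }
  expect_error(transition_itv(1, -1), ">= 0")
})
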