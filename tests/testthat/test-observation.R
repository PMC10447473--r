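test_that("poisson_logpmf matches closed forms and normalizes", {
  expect_equal(poisson_logpmf(0, 1), -1)
  expect_equal(poisson_logpmf(2, 2), log(2 * exp(-2)))
  total <- sum(exp(poisson_logpmf(0:200, 3)))
  expect_lt(abs(total - 1), 1e-12)
  expect_error(poisson_logpmf(2, 0), "> 0")
  expect_error(poisson_logpmf(-1, 2), "non-negative")
})

test_that("zero drift from the midpoint gives a symmetric choice split and
           rt never undercuts the non-decision time", {
  set.seed(1)
  tr <- ddm_first_passage(0, 2, 0.3, n = 1e4)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(tr$choice) - 0.5), 3 * se)
  expect_true(all(tr$rt[!tr$timeout] >= 0.3))
})

test_that("simulated choice probability and mean decision time match the
           two-boundary Wiener closed forms", {
  set.seed(2)
  v <- 1; a <- 2; tau <- 0.3
  tr <- ddm_first_passage(v, a, tau, n = 1e4, dt = 1e-3)
  tr <- tr[!tr$timeout, ]
  p_hat <- mean(tr$choice)
  p_true <- 1 / (1 + exp(-v * a))
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / nrow(tr)))
  dt_mean <- mean(tr$rt - tau)
  m_true <- (a / (2 * v)) * tanh(v * a / 2)  # = tanh(1) here
  expect_lt(abs(dt_mean - m_true), 3 * sd(tr$rt) / sqrt(nrow(tr)))
})

test_that("wfpt density integrates to the absorption probabilities", {
  for (pars in list(c(1, 2, 0.3), c(-0.8, 1.2, 0.2), c(0, 1.5, 0.4))) {
    v <- pars[1]; a <- pars[2]; tau <- pars[3]
    f1 <- integrate(function(u) wfpt_density(u, 1, v, a, tau), tau, Inf,
                    rel.tol = 1e-10)$value
    f0 <- integrate(function(u) wfpt_density(u, 0, v, a, tau), tau, Inf,
                    rel.tol = 1e-10)$value
    expect_lt(abs(f1 + f0 - 1), 1e-4)
    expect_lt(abs(f1 - ddm_prob_upper(v, a)), 1e-4)
  }
  expect_equal(wfpt_density(0.2, 1, v = 1, a = 2, tau = 0.3), 0)
})

test_that("simulator and analytic density agree across the prior bulk", {
  set.seed(3)
  grid <- list(c(1, 2, 0.3), c(0.5, 1, 0.2), c(-1.5, 1.5, 0.4),
               c(2.5, 0.8, 0.3))
  for (pars in grid) {
    v <- pars[1]; a <- pars[2]; tau <- pars[3]
    n <- 2e4
    tr <- ddm_first_passage(v, a, tau, n = n, dt = 1e-3)
    tr <- tr[!tr$timeout, ]
    for (ch in 0:1) {
      rts <- tr$rt[tr$choice == ch]
      if (length(rts) < 500) next
      qs <- quantile(rts, c(0.1, 0.25, 0.5, 0.75, 0.9))
      p_ch <- length(rts) / nrow(tr)
      for (q in qs) {
        p_num <- integrate(function(u) wfpt_density(u, ch, v, a, tau),
                           tau, q, rel.tol = 1e-9)$value / p_ch
        p_emp <- mean(rts <= q)
        se <- sqrt(p_emp * (1 - p_emp) / length(rts))
        expect_lt(abs(p_num - p_emp), 4 * se + 0.005)
      }
    }
  }
})

test_that("halving the Euler step does not shift choice or rt beyond MC
           error (bridge-corrected convergence)", {
  set.seed(4)
  n <- 1e4
  a1 <- ddm_first_passage(1, 2, 0.3, n = n, dt = 1e-3)
  a2 <- ddm_first_passage(1, 2, 0.3, n = n, dt = 2.5e-4)
  se_p <- sqrt(2 * 0.25 / n)
  expect_lt(abs(mean(a1$choice) - mean(a2$choice)), 3 * se_p)
  se_m <- sqrt(var(a1$rt) / n + var(a2$rt) / n)
  expect_lt(abs(mean(a1$rt) - mean(a2$rt)), 3 * se_m)
})

test_that("timeouts are rare under the default priors and flagged", {
  set.seed(5)
  m <- ddm_model("static")
  n_trials <- 0L; n_to <- 0L
  for (i in 1:200) {
    sim <- simulate_dataset(m, 100, seed = 500 + i)
    n_trials <- n_trials + nrow(sim$series)
    n_to <- n_to + sum(sim$series$timeout)
  }
  expect_lt(n_to / n_trials, 0.001)
})

test_that("observe emits IID trials under a constant trajectory and tracks
           the rate / condition structure", {
  set.seed(6)
  mp <- coal_model()
  lam <- 4
  ser <- observe(mp, matrix(lam, 1e4, 1))
  expect_lt(abs(mean(ser$count) - lam), 3 * sqrt(lam / 1e4))
  md <- ddm_model(n_drifts = 4L)
  theta <- cbind(v1 = 2, v2 = 1, v3 = -1, v4 = -2, a = 1.5, tau = 0.3)
  T <- 6000
  th <- theta[rep(1, T), ]
  cond <- rep(0:3, length.out = T)
  ser <- observe(md, th, condition = cond)
  # accuracy (choosing the boundary the drift points to) orders with |v|
  acc <- vapply(0:3, function(cl) {
    ch <- ser$choice[ser$condition == cl]
    v <- theta[1, cl + 1]
    mean(if (v > 0) ch == 1 else ch == 0)
  }, numeric(1))
  expect_gt(acc[1], acc[2])  # |v|=2 beats |v|=1
  expect_gt(acc[4], acc[3])
  p2 <- 1 / (1 + exp(-2 * 1.5)); p1 <- 1 / (1 + exp(-1 * 1.5))
  expect_lt(abs(acc[1] - p2), 4 * sqrt(p2 * (1 - p2) / (T / 4)))
  expect_lt(abs(acc[2] - p1), 4 * sqrt(p1 * (1 - p1) / (T / 4)))
})
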