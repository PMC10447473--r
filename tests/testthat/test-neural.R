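# offsets of the bias blocks inside the flat parameter vector (mirrors the
# layout in src/nnet.cpp)
par_block_offsets <- function(dims) {
  n_in <- dims[1]; H <- dims[2]; H2 <- dims[3]; d <- dims[4]; k <- dims[5]
  sizes <- c(Wx = 4 * H * n_in, Wh = 4 * H * H, b = 4 * H,
             W1 = H2 * H, b1 = H2,
             Wm_e = k * H2, bm_e = k, Ws_e = k * H2, bs_e = k,
             W2 = H2 * (H2 + k), b2 = H2,
             Wm_t = d * H2, bm_t = d, Ws_t = d * H2, bs_t = d)
  off <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(off) <- names(sizes)
  list(offset = off, size = sizes)
}

tiny_coal_net <- function(hidden = 8L, seed = 1) {
  suppressWarnings(nf_init(coal_model(),
                           nf_config(hidden = hidden, head_hidden = hidden),
                           t_pilot = 20L, n_pilot = 100L, seed = seed))
}

test_that("backpropagated gradients match finite differences", {
  set.seed(1)
  dims <- c(2L, 3L, 4L, 2L, 2L)
  np <- superstat:::cpp_nf_par_len(dims)
  par <- rnorm(np, 0, 0.3)
  B <- 3L; T <- 5L
  X <- array(rnorm(dims[1] * B * T), c(dims[1], B, T))
  TH <- array(rnorm(dims[4] * B * T), c(dims[4], B, T))
  ETA <- matrix(rnorm(dims[5] * B), dims[5], B)
  tw <- rep(1, T)
  out <- superstat:::cpp_nf_loss_grad(par, dims, X, TH, ETA, tw)
  eps <- 1e-6
  idx <- sample(np, 25)
  for (i in idx) {
    pp <- par; pp[i] <- pp[i] + eps
    pm <- par; pm[i] <- pm[i] - eps
    fd <- (superstat:::cpp_nf_loss_grad(pp, dims, X, TH, ETA, tw,
                                        want_grad = FALSE)$loss -
           superstat:::cpp_nf_loss_grad(pm, dims, X, TH, ETA, tw,
                                        want_grad = FALSE)$loss) / (2 * eps)
    expect_lt(abs(fd - out$grad[i]), 1e-5 + 1e-4 * abs(fd))
  }
})

test_that("a standard-normal head with zero targets yields the closed-form
           per-step loss", {
  dims <- c(1L, 2L, 3L, 2L, 1L)
  np <- superstat:::cpp_nf_par_len(dims)
  B <- 4L; T <- 6L
  out <- superstat:::cpp_nf_loss_grad(
    numeric(np), dims,
    array(0, c(1, B, T)), array(0, c(2, B, T)), matrix(0, 1, B), rep(1, T),
    want_grad = FALSE)
  expect_equal(out$loss, T * (2 + 1) * 0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("summary states have the contracted shape, are deterministic,
           and are causal", {
  net <- tiny_coal_net()
  sim <- simulate_dataset(coal_model(), 25, seed = 2)
  H1 <- summarize(net, sim$series)
  expect_equal(dim(H1), c(25, 8))
  expect_identical(H1, summarize(net, sim$series))
  ser2 <- sim$series
  ser2$count[20] <- ser2$count[20] + 5L
  H2 <- summarize(net, ser2)
  expect_identical(H1[1:19, ], H2[1:19, ])
  expect_false(identical(H1[20, ], H2[20, ]))
  ser3 <- sim$series; ser3$count[5] <- NA
  expect_error(summarize(net, ser3), "NaN|NA")
})

test_that("loss is invariant to batch order and finite on generated data", {
  net <- tiny_coal_net()
  recs <- lapply(1:6, function(i)
    simulate_dataset(coal_model(), 15, seed = 100 + i))
  l1 <- nf_loss(net, recs)
  l2 <- nf_loss(net, rev(recs))
  expect_true(is.finite(l1))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("a head with collapsed scales returns its predicted means", {
  net <- tiny_coal_net()
  off <- par_block_offsets(net$dims)
  net$par[] <- 0
  # push the log-sd biases of both heads to the clamp floor
  net$par[off$offset["bs_e"] + seq_len(off$size["bs_e"])] <- -20
  net$par[off$offset["bs_t"] + seq_len(off$size["bs_t"])] <- -20
  net$trained <- TRUE
  h <- rep(0.3, net$dims[2])
  dr <- posterior_sample(net, h, n = 200, seed = 3)
  # residual spread is exp(-7) on the standardized scale
  expect_lt(max(apply(dr$theta, 2, sd)), 5e-3)
  expect_lt(max(apply(dr$eta, 2, sd)), 1e-3)
})

test_that("posterior draw moments are stable across seeds", {
  net <- tiny_coal_net()
  net$trained <- TRUE
  h <- seq(-0.5, 0.5, length.out = net$dims[2])
  a <- posterior_sample(net, h, n = 4000, seed = 4)
  b <- posterior_sample(net, h, n = 4000, seed = 5)
  for (j in seq_len(ncol(a$theta))) {
    pooled_sd <- sd(c(a$theta[, j], b$theta[, j]))
    expect_lt(abs(mean(a$theta[, j]) - mean(b$theta[, j])),
              4 * pooled_sd * sqrt(2 / 4000))
  }
})

test_that("training reduces the loss on a fixed offline record store", {
  set.seed(6)
  net <- tiny_coal_net(hidden = 16L)
  store <- lapply(1:64, function(i)
    simulate_dataset(coal_model(), 30, seed = 200 + i))
  cfg <- nf_train_config(mode = "offline", records = store, epochs = 6L,
                         iter_per_epoch = 8L, batch_size = 8L)
  net2 <- nf_train(net, cfg, seed = 7)
  expect_true(net2$trained)
  expect_lt(tail(net2$epoch_loss, 1), net2$epoch_loss[1])
  expect_lt(nf_loss(net2, store[1:16]), nf_loss(net, store[1:16]))
})

test_that("two training runs with the same seed give identical loss curves", {
  net <- tiny_coal_net()
  cfg <- nf_train_config(epochs = 2L, iter_per_epoch = 5L, batch_size = 4L,
                         t_range = c(12L, 20L))
  a <- nf_train(net, cfg, seed = 8)
  b <- nf_train(net, cfg, seed = 8)
  expect_identical(a$loss_curve, b$loss_curve)
  expect_identical(a$par, b$par)
})

test_that("a network trained on a length range accepts any length inside it
           and flags extrapolation", {
  net <- tiny_coal_net()
  cfg <- nf_train_config(epochs = 1L, iter_per_epoch = 4L, batch_size = 4L,
                         t_range = c(15L, 30L))
  net <- nf_train(net, cfg, seed = 9)
  sim <- simulate_dataset(coal_model(), 22, seed = 10)
  expect_silent(fit <- amortized_filter(net, sim$series, n = 50))
  expect_equal(fit$T, 22)
  sim2 <- simulate_dataset(coal_model(), 40, seed = 11)
  expect_warning(amortized_filter(net, sim2$series, n = 10),
                 "extrapolat")
})

test_that("n = 0 yields an empty but well-formed filtering posterior", {
  net <- tiny_coal_net()
  net$trained <- TRUE
  sim <- simulate_dataset(coal_model(), 12, seed = 12)
  suppressWarnings(fit <- amortized_filter(net, sim$series, n = 0))
  expect_equal(dim(fit$theta), c(12, 0, 1))
  expect_equal(fit$n, 0L)
  s <- filter_summary(fit)
  expect_equal(dim(s$mean), c(12, 1))
})

test_that("checkpoints round-trip with their transforms and constants", {
  net <- tiny_coal_net()
  path <- tempfile(fileext = ".rds")
  nf_save(net, path)
  net2 <- nf_load(path)
  expect_identical(net$par, net2$par)
  expect_identical(net$std, net2$std)
  expect_error(nf_load(tempfile()), "no checkpoint")
})
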