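#' Configuration for the recurrent neural approximator
#'
#' @param hidden LSTM hidden width (summary-state length).
#' @param head_hidden width of the dense layers inside the posterior head.
#' @param head posterior head kind; `"gaussian"` — a conditional diagonal
#'   Gaussian in standardized transformed parameter space, sampled
#'   ancestrally as q(eta | h_t) then q(theta_t | h_t, eta).
#' @return list of class `nf_config`.
#' @export
nf_config <- function(hidden = 64L, head_hidden = 64L, head = "gaussian") {
  head <- match.arg(head, "gaussian")
  structure(list(hidden = as.integer(hidden),
                 head_hidden = as.integer(head_hidden), head = head),
            class = "nf_config")
}

#' Training configuration
#'
#' @param mode `"online"` (fresh simulations every batch) or `"offline"`
#'   (cycle a fixed store of records).
#' @param epochs number of epochs; `iter_per_epoch` batches per epoch.
#' @param iter_per_epoch batches per epoch; the online simulation budget is
#'   `epochs * iter_per_epoch * batch_size` records.
#' @param batch_size records per batch.
#' @param t_range integer range `c(min, max)`; each batch uses one series
#'   length drawn uniformly from this range, so the trained network accepts
#'   any length in the range.
#' @param lr,lr_min cosine-decayed Adam learning rate (from `lr` to
#'   `lr_min`).
#' @param clip global gradient-norm clip.
#' @param sim_dt Euler step used for training simulations (DDM only).
#' @param t_subsample if in (0, 1), the fraction of time steps whose loss
#'   terms are kept per batch (uniform subsample; default off).
#' @param records offline store (list of [simulate_dataset()] results),
#'   required for `mode = "offline"`.
#' @return list of class `nf_train_config`.
#' @export
nf_train_config <- function(mode = "online", epochs = 20L,
                            iter_per_epoch = 25L, batch_size = 32L,
                            t_range = c(110L, 110L), lr = 2e-3,
                            lr_min = 1e-4, clip = 5, sim_dt = 2.5e-3,
                            t_subsample = 0, records = NULL) {
  mode <- match.arg(mode, c("online", "offline"))
  if (mode == "offline" && is.null(records))
    stop("nf_train_config: offline mode requires a record store",
         call. = FALSE)
  structure(list(mode = mode, epochs = as.integer(epochs),
                 iter_per_epoch = as.integer(iter_per_epoch),
                 batch_size = as.integer(batch_size),
                 t_range = as.integer(t_range), lr = lr, lr_min = lr_min,
                 clip = clip, sim_dt = sim_dt, t_subsample = t_subsample,
                 records = records),
            class = "nf_train_config")
}

## transform descriptors for eta components, from their prior supports
eta_transforms <- function(model) {
  ep <- model$transition$eta_priors
  lapply(ep, function(p) {
    if (is.finite(p$lower) && is.finite(p$upper))
      list(type = "logit", lo = p$lower, hi = p$upper)
    else if (is.finite(p$lower))
      list(type = "log", lo = p$lower, hi = Inf)
    else list(type = "identity", lo = -Inf, hi = Inf)
  })
}

eta_to_trans <- function(trs, eta) {
  eta <- rbind(eta)
  for (j in seq_along(trs)) {
    tr <- trs[[j]]
    if (tr$type == "logit") {
      u <- (eta[, j] - tr$lo) / (tr$hi - tr$lo)
      eta[, j] <- stats::qlogis(pmin(pmax(u, 1e-6), 1 - 1e-6))
    } else if (tr$type == "log") {
      eta[, j] <- log(pmax(eta[, j] - tr$lo, 1e-9))
    }
  }
  eta
}

eta_from_trans <- function(trs, z) {
  z <- rbind(z)
  for (j in seq_along(trs)) {
    tr <- trs[[j]]
    if (tr$type == "logit")
      z[, j] <- tr$lo + (tr$hi - tr$lo) * stats::plogis(z[, j])
    else if (tr$type == "log")
      z[, j] <- tr$lo + exp(z[, j])
  }
  z
}

## encode one observation series into an n_in x T feature matrix
encode_series <- function(net, series) {
  low <- net$model$low_level
  if (low$kind == "poisson") {
    if (!"count" %in% names(series))
      stop("encode_series: poisson series needs a 'count' column",
           call. = FALSE)
    x <- series$count
    if (any(!is.finite(x))) stop("encode_series: NaN/NA in inputs",
                                 call. = FALSE)
    return(matrix((x - net$std$x_mean) / net$std$x_sd, nrow = 1))
  }
  need <- c("rt", "choice")
  if (!all(need %in% names(series)))
    stop("encode_series: ddm series needs rt and choice columns",
         call. = FALSE)
  rt <- series$rt; ch <- series$choice
  if (any(!is.finite(rt)) || any(!is.finite(ch)))
    stop("encode_series: NaN/NA in inputs", call. = FALSE)
  if (any(rt <= 0)) stop("encode_series: rt must be > 0", call. = FALSE)
  feats <- rbind((log(rt) - net$std$x_mean[1]) / net$std$x_sd[1],
                 2 * ch - 1)
  C <- low$n_drifts
  if (C > 1) {
    cond <- series$condition %||% rep(0L, length(rt))
    onehot <- matrix(0, C, length(rt))
    onehot[cbind(cond + 1L, seq_along(rt))] <- 1
    feats <- rbind(feats, onehot)
  }
  feats
}

n_input_features <- function(model) {
  low <- model$low_level
  if (low$kind == "poisson") 1L
  else 2L + if (low$n_drifts > 1) low$n_drifts else 0L
}

#' Initialize an untrained amortized filtering network
#'
#' Runs a pilot simulation to freeze input/target standardization constants
#' into the network (they travel with every checkpoint), then draws small
#' random initial weights (forget-gate bias 1).
#'
#' @param model a [superstat_model()].
#' @param config an [nf_config()].
#' @param t_pilot series length for the pilot simulation.
#' @param n_pilot number of pilot records (defaults: 2000 for Poisson
#'   models, 300 for DDM models — moment estimates are stable at these
#'   sizes).
#' @param sim_dt Euler step for pilot DDM simulation.
#' @param seed integer seed.
#' @return object of class `nf_net`.
#' @export
nf_init <- function(model, config = nf_config(), t_pilot = 110L,
                    n_pilot = NULL, sim_dt = 2.5e-3, seed = 1L) {
  stopifnot(inherits(model, "superstat_model"))
  set.seed(seed)
  low <- model$low_level
  n_pilot <- n_pilot %||% if (low$kind == "poisson") 2000L else 300L
  pmodel <- model
  pmodel$low_level$sim_dt <- sim_dt
  d <- length(low$par_names)
  k <- n_eta(model)
  trs <- eta_transforms(model)

  xs <- c(); ths <- NULL; ets <- NULL
  for (i in seq_len(n_pilot)) {
    sim <- simulate_dataset(pmodel, t_pilot)
    xv <- if (low$kind == "poisson") sim$series$count else log(sim$series$rt)
    xs <- c(xs, xv)
    ths <- rbind(ths, link_transform(low, sim$theta[-1, , drop = FALSE]))
    if (k > 0) ets <- rbind(ets, eta_to_trans(trs, rbind(sim$eta)))
  }
  std <- list(
    x_mean = mean(xs), x_sd = max(stats::sd(xs), 1e-8),
    th_mean = colMeans(ths),
    th_sd = pmax(apply(ths, 2, stats::sd), 1e-8),
    eta_mean = if (k > 0) colMeans(ets) else numeric(0),
    eta_sd = if (k > 0) pmax(apply(ets, 2, stats::sd), 1e-8) else numeric(0))

  dims <- c(n_input_features(model), config$hidden, config$head_hidden, d, k)
  np <- cpp_nf_par_len(dims)
  par <- stats::runif(np, -0.08, 0.08)
  ## forget-gate bias block starts after Wx and Wh, offset H within b
  H <- config$hidden
  off_b <- 4 * H * dims[1] + 4 * H * H
  par[(off_b + H + 1):(off_b + 2 * H)] <- 1.0
  structure(list(par = par, dims = dims, model = model, config = config,
                 std = std, eta_trs = trs, t_range = NULL,
                 loss_curve = NULL, trained = FALSE, seed = seed),
            class = "nf_net")
}

#' @export
print.nf_net <- function(x, ...) {
  cat("<nf_net>", if (x$trained) "trained" else "untrained",
      "| hidden", x$dims[2], "| d =", x$dims[4], "k =", x$dims[5],
      "|", length(x$par), "weights\n")
  if (!is.null(x$t_range))
    cat("  trained on T in [", x$t_range[1], ",", x$t_range[2], "]\n")
  invisible(x)
}

## mirror of the C++ parameter layout
nf_unpack <- function(par, dims) {
  n_in <- dims[1]; H <- dims[2]; H2 <- dims[3]; d <- dims[4]; k <- dims[5]
  o <- 0L
  take <- function(r, c) {
    m <- matrix(par[(o + 1L):(o + r * c)], r, c); o <<- o + r * c; m
  }
  takev <- function(r) { v <- par[(o + 1L):(o + r)]; o <<- o + r; v }
  list(Wx = take(4 * H, n_in), Wh = take(4 * H, H), b = takev(4 * H),
       W1 = take(H2, H), b1 = takev(H2),
       Wm_e = take(k, H2), bm_e = takev(k),
       Ws_e = take(k, H2), bs_e = takev(k),
       W2 = take(H2, H2 + k), b2 = takev(H2),
       Wm_t = take(d, H2), bm_t = takev(d),
       Ws_t = take(d, H2), bs_t = takev(d))
}

## records -> training arrays (X cube, TH cube, ETA mat), standardized
nf_make_arrays <- function(net, records) {
  low <- net$model$low_level
  d <- net$dims[4]; k <- net$dims[5]
  B <- length(records); T <- nrow(records[[1]]$series)
  X <- array(0, c(net$dims[1], B, T))
  TH <- array(0, c(d, B, T))
  ETA <- matrix(0, max(k, 1), B)
  for (b in seq_len(B)) {
    r <- records[[b]]
    if (nrow(r$series) != T)
      stop("nf_make_arrays: records have unequal length", call. = FALSE)
    X[, b, ] <- encode_series(net, r$series)
    th <- link_transform(low, r$theta[-1, , drop = FALSE])
    TH[, b, ] <- t((th - matrix(net$std$th_mean, T, d, byrow = TRUE)) /
                   matrix(net$std$th_sd, T, d, byrow = TRUE))
    if (k > 0) {
      et <- drop(eta_to_trans(net$eta_trs, rbind(r$eta)))
      ETA[, b] <- (et - net$std$eta_mean) / net$std$eta_sd
    }
  }
  if (k == 0) ETA <- matrix(0, 0, B)
  list(X = X, TH = TH, ETA = ETA)
}

#' Training criterion on a batch of simulated records
#'
#' Mean over the batch of the summed negative log posterior density
#' -sum_t log q(theta_t, eta | x_1:t) under the current weights. Finite and
#' differentiable in the weights; invariant to the ordering of the batch.
#'
#' @param net an `nf_net`.
#' @param records list of [simulate_dataset()] results of equal length T.
#' @param t_weights optional 0/1 vector of length T masking time steps.
#' @return scalar loss.
#' @export
nf_loss <- function(net, records, t_weights = NULL) {
  arr <- nf_make_arrays(net, records)
  T <- dim(arr$X)[3]
  tw <- t_weights %||% rep(1, T)
  out <- cpp_nf_loss_grad(net$par, net$dims, arr$X, arr$TH, arr$ETA, tw,
                          want_grad = FALSE)
  if (!is.finite(out$loss))
    stop("nf_loss: non-finite log-density on this batch", call. = FALSE)
  out$loss
}

#' Train the amortized filtering network
#'
#' Minimizes the simulation-based criterion (the mean over simulated
#' records of the summed negative log posterior over all prefixes) with
#' Adam, cosine learning-rate decay, and global gradient-norm clipping.
#' With a fixed seed (and fixed BLAS threading) two runs produce identical
#' loss curves.
#'
#' @param net an [nf_init()] network.
#' @param config an [nf_train_config()].
#' @param seed integer seed controlling simulation and subsampling.
#' @param verbose print one line per epoch?
#' @return the trained `nf_net`, with `loss_curve` (per-iteration) and
#'   `epoch_loss` recorded.
#' @export
nf_train <- function(net, config = nf_train_config(), seed = 1L,
                     verbose = FALSE) {
  stopifnot(inherits(net, "nf_net"), inherits(config, "nf_train_config"))
  set.seed(seed)
  smodel <- net$model
  smodel$low_level$sim_dt <- config$sim_dt
  total <- config$epochs * config$iter_per_epoch
  m <- v <- numeric(length(net$par))
  beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
  losses <- numeric(total)
  bad <- 0L; it <- 0L
  last_good <- net$par
  offline <- config$mode == "offline"
  store <- config$records
  for (ep in seq_len(config$epochs)) {
    if (offline) ord <- sample(length(store))
    for (j in seq_len(config$iter_per_epoch)) {
      it <- it + 1L
      if (offline) {
        idx <- ord[((j - 1L) * config$batch_size) %% length(store) +
                     seq_len(config$batch_size)]
        idx <- ((idx - 1L) %% length(store)) + 1L
        batch <- store[idx]
        batch_T <- nrow(batch[[1]]$series)
        batch <- lapply(batch, function(r) {
          r$series <- r$series[seq_len(batch_T), , drop = FALSE]; r
        })
      } else {
        T <- sample(config$t_range[1]:config$t_range[2], 1)
        batch <- replicate(config$batch_size,
                           simulate_dataset(smodel, T), simplify = FALSE)
        batch_T <- T
      }
      tw <- rep(1, batch_T)
      if (config$t_subsample > 0 && config$t_subsample < 1) {
        keep <- sample(batch_T, max(1, round(config$t_subsample * batch_T)))
        tw <- as.numeric(seq_len(batch_T) %in% keep)
      }
      arr <- nf_make_arrays(net, batch)
      out <- cpp_nf_loss_grad(net$par, net$dims, arr$X, arr$TH, arr$ETA, tw)
      if (!is.finite(out$loss) || any(!is.finite(out$grad))) {
        bad <- bad + 1L
        if (bad > 20L) {
          warning("nf_train: divergence; returning last good checkpoint")
          net$par <- last_good
          net$loss_curve <- losses[seq_len(it)]
          return(net)
        }
        losses[it] <- NA_real_
        next
      }
      bad <- 0L
      g <- out$grad
      gn <- sqrt(sum(g^2))
      if (gn > config$clip) g <- g * (config$clip / gn)
      lr_t <- config$lr_min + 0.5 * (config$lr - config$lr_min) *
        (1 + cos(pi * (it - 1) / max(total - 1, 1)))
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^it)
      vhat <- v / (1 - beta2^it)
      net$par <- net$par - lr_t * mhat / (sqrt(vhat) + epsa)
      last_good <- net$par
      losses[it] <- out$loss
    }
    if (verbose) {
      i0 <- (ep - 1L) * config$iter_per_epoch + 1L
      cat(sprintf("epoch %3d  mean loss %10.3f\n", ep,
                  mean(losses[i0:it], na.rm = TRUE)))
    }
  }
  net$loss_curve <- losses
  net$epoch_loss <- colMeans(matrix(losses, config$iter_per_epoch,
                                    config$epochs), na.rm = TRUE)
  net$t_range <- if (offline) rep(nrow(store[[1]]$series), 2) else
    config$t_range
  net$trained <- TRUE
  net$train_config <- config
  net
}

#' Summary states of a series under the trained recurrence
#'
#' One forward pass of the LSTM; state t depends only on x_1:t (causal).
#'
#' @param net an `nf_net`.
#' @param series observation data.frame (`count`, or `rt`/`choice`(/
#'   `condition`)).
#' @return T x hidden matrix of summary states.
#' @export
summarize <- function(net, series) {
  X <- encode_series(net, series)
  Hc <- cpp_lstm_hidden(net$par, net$dims, array(X, c(nrow(X), 1, ncol(X))))
  t(matrix(Hc, net$dims[2], dim(Hc)[3]))
}

## draws from the head given one summary state h (vector); returns
## standardized-transformed draws (theta n x d, eta n x k)
head_sample_std <- function(net, h, n) {
  P <- nf_unpack(net$par, net$dims)
  d <- net$dims[4]; k <- net$dims[5]
  z <- tanh(drop(P$W1 %*% h) + P$b1)
  if (k > 0) {
    mx <- drop(P$Wm_e %*% z) + P$bm_e
    sx <- pmin(pmax(drop(P$Ws_e %*% z) + P$bs_e, -7), 7)
    eta_std <- matrix(stats::rnorm(n * k), n, k,
                      byrow = FALSE) * rep(exp(sx), each = n) +
      rep(mx, each = n)
    U <- rbind(matrix(z, length(z), n), t(eta_std))
  } else {
    eta_std <- matrix(0, n, 0)
    U <- matrix(z, length(z), n)
  }
  Z2 <- tanh(P$W2 %*% U + P$b2)
  Mt <- P$Wm_t %*% Z2 + P$bm_t
  St <- pmin(pmax(P$Ws_t %*% Z2 + P$bs_t, -7), 7)
  th_std <- t(Mt + exp(St) * matrix(stats::rnorm(d * n), d, n))
  list(theta = th_std, eta = eta_std)
}

## back-transform standardized draws to the natural scale
head_back_transform <- function(net, draws) {
  low <- net$model$low_level
  d <- net$dims[4]; k <- net$dims[5]
  th <- draws$theta * matrix(net$std$th_sd, nrow(draws$theta), d,
                             byrow = TRUE) +
    matrix(net$std$th_mean, nrow(draws$theta), d, byrow = TRUE)
  th <- link_back_transform(low, th)
  colnames(th) <- low$par_names
  if (k > 0) {
    et <- draws$eta * matrix(net$std$eta_sd, nrow(draws$eta), k,
                             byrow = TRUE) +
      matrix(net$std$eta_mean, nrow(draws$eta), k, byrow = TRUE)
    et <- eta_from_trans(net$eta_trs, et)
    ep <- net$model$transition$eta_priors
    for (j in seq_len(k))
      et[, j] <- pmin(pmax(et[, j], ep[[j]]$lower), ep[[j]]$upper)
    colnames(et) <- names(ep)
  } else et <- matrix(0, nrow(th), 0)
  list(theta = th, eta = et)
}

#' Joint posterior draws given one summary state
#'
#' Ancestral sampling: eta ~ q(eta | h_t), then theta_t ~ q(theta_t | h_t,
#' eta); draws are back-transformed to the natural parameter scale (positive
#' parameters via the exp link, bounded static parameters via scaled
#' logistic) and clamped into their declared supports.
#'
#' @param net a trained `nf_net`.
#' @param h_t summary state vector (a row of [summarize()]).
#' @param n number of joint draws (`n = 0` gives empty, well-formed output).
#' @param seed optional seed.
#' @return list with `theta` (n x d) and `eta` (n x k), natural scale.
#' @export
posterior_sample <- function(net, h_t, n, seed = NULL) {
  if (!net$trained) warning("posterior_sample: network is untrained")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(list(theta = matrix(0, 0, net$dims[4],
                               dimnames = list(NULL,
                                 net$model$low_level$par_names)),
                eta = matrix(0, 0, net$dims[5])))
  }
  head_back_transform(net, head_sample_std(net, h_t, n))
}

#' Amortized filtering of one observation series
#'
#' One summary pass plus posterior sampling at every prefix length t yields
#' the full set of filtering posteriors p(theta_t, eta | x_1:t), t = 1..T,
#' in time linear in T and without re-estimation.
#'
#' @param net a trained `nf_net`.
#' @param series observation data.frame.
#' @param n draws per time step.
#' @param seed optional seed.
#' @return object of class `superstat_filter`: `theta` (T x n x d array,
#'   natural scale), `eta` (T x n x k array), `theta_names`, `eta_names`,
#'   `T`, `n`.
#' @export
amortized_filter <- function(net, series, n = 500L, seed = NULL) {
  if (!net$trained) warning("amortized_filter: network is untrained")
  if (!is.null(seed)) set.seed(seed)
  T <- nrow(series)
  if (!is.null(net$t_range) &&
      (T < net$t_range[1] || T > net$t_range[2]))
    warning("amortized_filter: series length ", T,
            " outside the trained range [", net$t_range[1], ", ",
            net$t_range[2], "] (extrapolating)")
  H <- summarize(net, series)
  d <- net$dims[4]; k <- net$dims[5]
  th <- array(0, c(T, n, d))
  et <- array(0, c(T, n, k))
  for (t in seq_len(T)) {
    if (n == 0) break
    dr <- head_back_transform(net, head_sample_std(net, H[t, ], n))
    th[t, , ] <- dr$theta
    if (k > 0) et[t, , ] <- dr$eta
  }
  structure(list(theta = th, eta = et,
                 theta_names = net$model$low_level$par_names,
                 eta_names = names(net$model$transition$eta_priors),
                 T = T, n = as.integer(n)),
            class = "superstat_filter")
}

#' @export
print.superstat_filter <- function(x, ...) {
  cat("<superstat_filter> T =", x$T, "| draws per t =", x$n,
      "| params:", paste(x$theta_names, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary trajectories of a filtering result
#'
#' @param fit a `superstat_filter`.
#' @param what `"theta"` or `"eta"`.
#' @return list with `mean` and `sd` matrices (T x d).
#' @export
filter_summary <- function(fit, what = c("theta", "eta")) {
  what <- match.arg(what)
  arr <- fit[[what]]
  if (dim(arr)[3] == 0 || fit$n == 0)
    return(list(mean = matrix(0, fit$T, dim(arr)[3]),
                sd = matrix(0, fit$T, dim(arr)[3])))
  list(mean = apply(arr, c(1, 3), mean), sd = apply(arr, c(1, 3), stats::sd))
}

#' Save / load a self-describing network checkpoint
#'
#' The checkpoint stores weights, architecture, model declaration,
#' transforms, and standardization constants together.
#' @param net an `nf_net`; `path` an `.rds` file path.
#' @param path checkpoint file.
#' @return `nf_load` returns the `nf_net`.
#' @export
nf_save <- function(net, path) { saveRDS(net, path); invisible(path) }

#' @rdname nf_save
#' @export
nf_load <- function(path) {
  if (!file.exists(path)) stop("nf_load: no checkpoint at ", path,
                               call. = FALSE)
  net <- readRDS(path)
  if (!inherits(net, "nf_net"))
    stop("nf_load: file is not an nf_net checkpoint", call. = FALSE)
  net
}
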