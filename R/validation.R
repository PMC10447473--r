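#' Simulation-based calibration of a posterior sampler
#'
#' For `n_sim` records simulated from the model, the rank of each true
#' parameter among `n_draws` posterior draws is recorded at each requested
#' checkpoint time. If the sampler targets the true filtering posterior the
#' ranks are uniform on {0, ..., n_draws}; uniformity is assessed per
#' parameter and checkpoint with a Kolmogorov-Smirnov test (on jittered
#' normalized ranks) and an exact order-statistic ECDF band.
#'
#' @param model a [superstat_model()].
#' @param sampler function `(series, checkpoints, n_draws)` returning a list
#'   with `theta` (array `length(checkpoints) x n_draws x d`) and `eta`
#'   (array `length(checkpoints) x n_draws x k`); see [nf_sbc_sampler()].
#' @param T series length per simulation.
#' @param n_sim number of simulations (a warning below 100 — underpowered).
#' @param n_draws posterior draws per simulation.
#' @param checkpoints time indices at which theta_t is ranked (default: T).
#' @param include_eta rank the static parameters as well?
#' @param seed integer seed.
#' @return object of class `sbc_result`: data.frame `summary` (parameter,
#'   checkpoint, KS statistic and p-value, ECDF-band violation flag) and
#'   `ranks` (named list of rank vectors).
#' @export
sbc <- function(model, sampler, T, n_sim = 200L, n_draws = 250L,
                checkpoints = NULL, include_eta = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sim < 100L) warning("sbc: n_sim < 100 is underpowered")
  checkpoints <- checkpoints %||% T
  low <- model$low_level
  d <- length(low$par_names); k <- n_eta(model)
  nc <- length(checkpoints)
  th_ranks <- array(NA_real_, c(n_sim, nc, d))
  eta_ranks <- if (include_eta && k > 0) matrix(NA_real_, n_sim, k) else NULL
  for (i in seq_len(n_sim)) {
    sim <- simulate_dataset(model, T)
    dr <- sampler(sim$series, checkpoints, n_draws)
    for (ci in seq_len(nc)) {
      truth <- sim$theta[checkpoints[ci] + 1L, ]
      for (j in seq_len(d))
        th_ranks[i, ci, j] <- sum(dr$theta[ci, , j] < truth[j])
    }
    if (!is.null(eta_ranks))
      for (j in seq_len(k))
        eta_ranks[i, j] <- sum(dr$eta[nc, , j] < sim$eta[j])
  }
  rows <- list(); ranks <- list()
  for (ci in seq_len(nc)) for (j in seq_len(d)) {
    nm <- paste0(low$par_names[j], "@t", checkpoints[ci])
    r <- th_ranks[, ci, j]
    ranks[[nm]] <- r
    rows[[nm]] <- sbc_uniformity_row(nm, r, n_draws)
  }
  if (!is.null(eta_ranks)) for (j in seq_len(k)) {
    nm <- names(model$transition$eta_priors)[j]
    ranks[[nm]] <- eta_ranks[, j]
    rows[[nm]] <- sbc_uniformity_row(nm, eta_ranks[, j], n_draws)
  }
  structure(list(summary = do.call(rbind, rows), ranks = ranks,
                 n_draws = n_draws, n_sim = n_sim),
            class = "sbc_result")
}

sbc_uniformity_row <- function(name, ranks, n_draws) {
  u <- (ranks + stats::runif(length(ranks))) / (n_draws + 1)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  data.frame(parameter = name, ks_stat = unname(ks$statistic),
             ks_p = ks$p.value,
             ecdf_violation = ecdf_band_violation(ranks, n_draws),
             row.names = NULL)
}

#' Exact order-statistic ECDF band check for SBC ranks
#'
#' Sorted normalized ranks are compared against pointwise Beta order-statistic
#' quantiles at level `alpha` with a Bonferroni correction over the sample
#' size, giving a conservative simultaneous band; returns `TRUE` when the
#' empirical CDF leaves the band anywhere.
#'
#' @param ranks integer ranks in `0..n_draws`.
#' @param n_draws number of posterior draws the ranks were computed from.
#' @param alpha simultaneous band level.
#' @return logical flag.
#' @export
ecdf_band_violation <- function(ranks, n_draws, alpha = 0.01) {
  n <- length(ranks)
  u <- sort((ranks + 0.5) / (n_draws + 1))
  i <- seq_len(n)
  lo <- stats::qbeta(alpha / (2 * n), i, n - i + 1)
  hi <- stats::qbeta(1 - alpha / (2 * n), i, n - i + 1)
  any(u < lo | u > hi)
}

#' @export
print.sbc_result <- function(x, ...) {
  cat("<sbc_result>", x$n_sim, "simulations,", x$n_draws, "draws\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Posterior sampler adapter for [sbc()] based on a trained network
#'
#' @param net a trained `nf_net`.
#' @return a function `(series, checkpoints, n_draws)` suitable for [sbc()].
#' @export
nf_sbc_sampler <- function(net) {
  force(net)
  function(series, checkpoints, n_draws) {
    fit <- amortized_filter(net, series, n = n_draws)
    list(theta = fit$theta[checkpoints, , , drop = FALSE],
         eta = fit$eta[checkpoints, , , drop = FALSE])
  }
}

#' Parameter-recovery report
#'
#' Compares ground-truth trajectories with filtering posteriors across a set
#' of simulated records: per-parameter median absolute error over time,
#' median posterior SD over time with a median-absolute-deviation band, and
#' truth-versus-posterior-mean correlation at selected time points.
#'
#' @param truths list of [simulate_dataset()] records.
#' @param posteriors list of matching `superstat_filter` fits.
#' @param t_scatter time indices for the truth/estimate scatter summaries.
#' @return object of class `recovery_report`: `mae` (T x d), `post_sd`
#'   (T x d medians), `post_sd_mad` (T x d), `scatter` (data.frame with
#'   correlation per parameter and t), `par_names`.
#' @export
recovery <- function(truths, posteriors, t_scatter = NULL) {
  if (length(truths) != length(posteriors))
    stop("recovery: truths and posteriors must match in length",
         call. = FALSE)
  n <- length(truths)
  T <- posteriors[[1]]$T
  d <- length(posteriors[[1]]$theta_names)
  for (i in seq_len(n))
    if (nrow(truths[[i]]$series) != T || posteriors[[i]]$T != T)
      stop("recovery: record ", i, " has mismatched length", call. = FALSE)
  pm <- array(0, c(n, T, d)); ps <- array(0, c(n, T, d))
  tr <- array(0, c(n, T, d))
  for (i in seq_len(n)) {
    s <- filter_summary(posteriors[[i]])
    pm[i, , ] <- s$mean; ps[i, , ] <- s$sd
    tr[i, , ] <- truths[[i]]$theta[-1, , drop = FALSE]
  }
  abs_err <- abs(tr - pm)
  mae <- apply(abs_err, c(2, 3), stats::median)
  sd_med <- apply(ps, c(2, 3), stats::median)
  sd_mad <- apply(ps, c(2, 3), stats::mad)
  scatter <- NULL
  for (t0 in (t_scatter %||% integer(0))) {
    for (j in seq_len(d)) {
      scatter <- rbind(scatter, data.frame(
        t = t0, parameter = posteriors[[1]]$theta_names[j],
        correlation = stats::cor(tr[, t0, j], pm[, t0, j]),
        truth_sd = stats::sd(tr[, t0, j])))
    }
  }
  structure(list(mae = mae, post_sd = sd_med, post_sd_mad = sd_mad,
                 scatter = scatter,
                 par_names = posteriors[[1]]$theta_names),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> T =", nrow(x$mae), "| final-step MAE:",
      paste(x$par_names, signif(x$mae[nrow(x$mae), ], 3), sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$scatter)) print(x$scatter, row.names = FALSE)
  invisible(x)
}

## pull the observable column of a series
observable_of <- function(series) {
  if ("count" %in% names(series)) series$count else series$rt
}

#' Retrodictive (posterior re-simulation) check
#'
#' Draws `n` parameter trajectories from the filtering posterior (one joint
#' draw index per re-simulation) and re-simulates the observed span from the
#' low-level model; observables are summarized per time step by the median
#' and an equal-tailed 95% interval, optionally after smoothing both data
#' and simulations with a trailing moving average.
#'
#' @param model a [superstat_model()].
#' @param fit a `superstat_filter` covering the span.
#' @param n number of re-simulated series.
#' @param sma_period optional smoothing period applied to band and data.
#' @param condition condition codes of the observed series (multi-drift DDM).
#' @param seed optional seed.
#' @return object of class `prediction_band`: data.frame `band`
#'   (`t, lower, median, upper`), `horizon_start = 1`, `n`.
#' @export
retrodictive_check <- function(model, fit, n = 100L, sma_period = NULL,
                               condition = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- fit$T
  sims <- matrix(0, n, T)
  for (i in seq_len(n)) {
    idx <- sample.int(fit$n, 1)
    th <- matrix(fit$theta[, idx, ], T, dim(fit$theta)[3])
    colnames(th) <- fit$theta_names
    ser <- observe(model, th, condition = condition)
    x <- observable_of(ser)
    sims[i, ] <- if (is.null(sma_period)) x else sma(x, sma_period)
  }
  band <- data.frame(
    t = seq_len(T),
    lower = apply(sims, 2, stats::quantile, 0.025),
    median = apply(sims, 2, stats::median),
    upper = apply(sims, 2, stats::quantile, 0.975))
  structure(list(band = band, horizon_start = 1L, n = n,
                 sma_period = sma_period),
            class = "prediction_band")
}

#' Multi-horizon posterior prediction
#'
#' Propagates aligned joint posterior draws (theta at the forecast origin
#' and eta from the same draw index) through fresh transition trajectories
#' of length `horizon`, simulates observations from each, and summarizes
#' them as a median and equal-tailed 95% band per future time step.
#'
#' @param model a [superstat_model()].
#' @param theta_draws matrix of natural-scale theta draws at the origin
#'   (rows aligned with `eta_draws`).
#' @param eta_draws matrix of eta draws (named columns as the transition
#'   priors).
#' @param horizon number of future steps (> 0; `horizon = 0` returns an
#'   empty band).
#' @param n number of propagated trajectories (draw rows are recycled /
#'   subsampled as needed).
#' @param sma_period optional smoothing period.
#' @param condition future condition codes (multi-drift DDM).
#' @param seed optional seed.
#' @return a `prediction_band` with `horizon_start = 1` indexing the first
#'   future step.
#' @export
multi_horizon_predict <- function(model, theta_draws, eta_draws, horizon,
                                  n = 100L, sma_period = NULL,
                                  condition = NULL, seed = NULL) {
  if (horizon < 0) stop("multi_horizon_predict: horizon must be >= 0",
                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  theta_draws <- rbind(theta_draws); eta_draws <- rbind(eta_draws)
  if (nrow(theta_draws) != nrow(eta_draws) && ncol(eta_draws) > 0)
    stop("multi_horizon_predict: theta and eta draws must be aligned",
         call. = FALSE)
  if (horizon == 0) {
    band <- data.frame(t = integer(0), lower = numeric(0),
                       median = numeric(0), upper = numeric(0))
    return(structure(list(band = band, horizon_start = 1L, n = n,
                          sma_period = sma_period),
                     class = "prediction_band"))
  }
  sims <- matrix(0, n, horizon)
  idx <- sample.int(nrow(theta_draws), n, replace = n > nrow(theta_draws))
  for (i in seq_len(n)) {
    eta <- if (ncol(eta_draws)) {
      e <- eta_draws[idx[i], ]; names(e) <- colnames(eta_draws); e
    } else numeric(0)
    ztraj <- simulate_trajectory_trans(model, eta,
                                       rbind(theta_draws[idx[i], ]), horizon)
    th <- link_back_transform(model$low_level, ztraj)[-1, , drop = FALSE]
    colnames(th) <- model$low_level$par_names
    ser <- observe(model, th, condition = condition)
    x <- observable_of(ser)
    sims[i, ] <- if (is.null(sma_period)) x else sma(x, sma_period)
  }
  band <- data.frame(
    t = seq_len(horizon),
    lower = apply(sims, 2, stats::quantile, 0.025),
    median = apply(sims, 2, stats::median),
    upper = apply(sims, 2, stats::quantile, 0.975))
  structure(list(band = band, horizon_start = 1L, n = n,
                 sma_period = sma_period),
            class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat("<prediction_band>", nrow(x$band), "steps from", x$n,
      "simulations\n")
  invisible(x)
}

#' Fraction of observed points inside a 95% prediction band
#'
#' @param band a `prediction_band`.
#' @param observed numeric vector aligned with `band$band$t`; smoothed with
#'   the band's `sma_period` if one was used.
#' @return fraction in `[0, 1]`.
#' @export
band_coverage <- function(band, observed) {
  b <- band$band
  if (length(observed) != nrow(b))
    stop("band_coverage: length mismatch", call. = FALSE)
  if (!is.null(band$sma_period)) observed <- sma(observed, band$sma_period)
  mean(observed >= b$lower & observed <= b$upper)
}

#' Unbiased squared maximum mean discrepancy
#'
#' U-statistic estimate of the squared MMD between two samples with a
#' Gaussian kernel whose bandwidth follows the median heuristic (median
#' pairwise Euclidean distance of the pooled sample); negative estimates are
#' clipped at 0 for reporting (the raw value and bandwidth are attached as
#' attributes).
#'
#' @param sample_a,sample_b numeric vectors or matrices (rows = draws).
#' @param bandwidth optional fixed kernel bandwidth.
#' @return non-negative scalar, with attributes `raw` and `bandwidth`.
#' @export
mmd <- function(sample_a, sample_b, bandwidth = NULL) {
  A <- as.matrix(sample_a); B <- as.matrix(sample_b)
  if (ncol(A) != ncol(B)) stop("mmd: dimension mismatch", call. = FALSE)
  m <- nrow(A); n <- nrow(B)
  if (m < 2 || n < 2) stop("mmd: need at least 2 draws per sample",
                           call. = FALSE)
  D2 <- function(X, Y) {
    xx <- rowSums(X^2); yy <- rowSums(Y^2)
    d2 <- outer(xx, yy, "+") - 2 * tcrossprod(X, Y)
    pmax(d2, 0)
  }
  if (is.null(bandwidth)) {
    P <- rbind(A, B)
    d2 <- D2(P, P)
    bandwidth <- sqrt(stats::median(d2[upper.tri(d2)]))
    if (bandwidth <= 0) bandwidth <- 1
  }
  kAA <- exp(-D2(A, A) / (2 * bandwidth^2)); diag(kAA) <- 0
  kBB <- exp(-D2(B, B) / (2 * bandwidth^2)); diag(kBB) <- 0
  kAB <- exp(-D2(A, B) / (2 * bandwidth^2))
  raw <- sum(kAA) / (m * (m - 1)) + sum(kBB) / (n * (n - 1)) -
    2 * mean(kAB)
  structure(max(raw, 0), raw = raw, bandwidth = bandwidth)
}

#' Trailing simple moving average
#'
#' Element t is the mean of the last `period` points up to and including t;
#' the first `period - 1` elements use the available prefix, so the output
#' has the length of the input.
#'
#' @param series numeric vector.
#' @param period window length (>= 1); a period longer than the series
#'   yields full-prefix means with a warning.
#' @return smoothed numeric vector.
#' @export
sma <- function(series, period) {
  if (period < 1 || period != round(period))
    stop("sma: period must be a positive integer", call. = FALSE)
  n <- length(series)
  if (period > n) {
    warning("sma: period exceeds series length; returning prefix means")
    period <- n
  }
  cs <- cumsum(series)
  out <- numeric(n)
  head_idx <- seq_len(min(period - 1, n))
  out[head_idx] <- cs[head_idx] / head_idx
  if (n >= period)
    out[period:n] <- (cs[period:n] -
                        c(0, cs)[(period:n) - period + 1L]) / period
  out
}
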