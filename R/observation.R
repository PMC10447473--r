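#' Poisson log-probability mass
#'
#' Point-wise log likelihood of a count under rate `lam` (the coal-style
#' low-level model). Thin validated wrapper around [stats::dpois()].
#'
#' @param x non-negative integer count(s).
#' @param lam rate(s), > 0.
#' @return log PMF value(s).
#' @export
poisson_logpmf <- function(x, lam) {
  if (any(lam <= 0)) stop("poisson_logpmf: lam must be > 0", call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("poisson_logpmf: x must be a non-negative integer", call. = FALSE)
  stats::dpois(x, lam, log = TRUE)
}

#' Simulate first-passage trials of the diffusion decision model
#'
#' Euler-Maruyama simulation of the evidence SDE dx = v dt + sqrt(dt) z,
#' z ~ N(0, 1), from the starting point a/2 until absorption at a (choice 1)
#' or 0 (choice 0); the returned rt adds the non-decision time tau. A
#' within-step Brownian-bridge crossing check removes the leading
#' discrete-monitoring bias, so choice probabilities and mean decision times
#' converge to the continuous-process values already at moderate step sizes.
#' Trials that do not absorb by `t_max` are flagged (`timeout = TRUE`, with
#' choice set by the sign of the final evidence relative to a/2) and should
#' be excluded from likelihood-based analyses.
#'
#' @param v drift rate (evidence/s).
#' @param a boundary separation (> 0).
#' @param tau non-decision time (s, > 0).
#' @param n number of trials.
#' @param dt Euler step (s).
#' @param t_max timeout (s), must exceed `tau`.
#' @param bridge apply the within-step bridge crossing check?
#' @return data.frame with columns `rt`, `choice`, `timeout`.
#' @examples
#' set.seed(1)
#' tr <- ddm_first_passage(v = 1, a = 2, tau = 0.3, n = 1000)
#' mean(tr$choice)  # ~ 1 / (1 + exp(-2))
#' @export
ddm_first_passage <- function(v, a, tau, n = 1L, dt = 1e-3, t_max = 10,
                              bridge = TRUE) {
  if (a <= 0 || tau <= 0) stop("ddm_first_passage: need a > 0 and tau > 0",
                               call. = FALSE)
  if (dt <= 0 || t_max <= tau)
    stop("ddm_first_passage: need dt > 0 and t_max > tau", call. = FALSE)
  out <- cpp_ddm_trials(rep(v, n), rep(a, n), rep(tau, n), dt, t_max, bridge)
  data.frame(rt = out$rt, choice = out$choice, timeout = out$timeout)
}

## Density of the normalized first passage time at the LOWER boundary of a
## zero-drift unit diffusion on (0, 1), start w, evaluated at normalized
## time tt = u / a^2. Small-time and large-time series expansions with the
## truncation bound chosen per target error; the cheaper series is used.
wfpt_f1 <- function(tt, w, err = 1e-10) {
  ## number of terms needed by each expansion
  if (pi * tt * err < 1) {
    kl <- sqrt(-2 * log(pi * tt * err) / (pi^2 * tt))
    kl <- max(kl, 1 / (pi * sqrt(tt)))
  } else kl <- 1 / (pi * sqrt(tt))
  if (2 * sqrt(2 * pi * tt) * err < 1) {
    ks <- 2 + sqrt(-2 * tt * log(2 * sqrt(2 * pi * tt) * err))
    ks <- max(ks, sqrt(tt) + 1)
  } else ks <- 2
  if (ks < kl) {
    K <- ceiling(ks)
    k <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    p <- sum((w + 2 * k) * exp(-((w + 2 * k)^2) / (2 * tt)))
    p / sqrt(2 * pi * tt^3)
  } else {
    K <- ceiling(kl)
    k <- seq_len(K)
    p <- sum(k * exp(-(k^2) * pi^2 * tt / 2) * sin(k * pi * w))
    p * pi
  }
}

#' Wiener first-passage-time density
#'
#' Analytic density of (rt, choice) under the diffusion decision model with
#' drift `v`, boundary separation `a`, non-decision time `tau`, relative
#' starting point `w` (default 1/2), and unit diffusion coefficient.
#' Computed by the standard small-time/large-time series expansion with
#' truncation for an absolute error well below 1e-6; serves as the analytic
#' oracle for the stochastic simulator. Integrating over rt for one choice
#' yields that boundary's absorption probability.
#'
#' @param rt response time(s) in seconds; values `<= tau` return density 0.
#' @param choice 1 = upper boundary, 0 = lower (scalar or vector).
#' @param v,a,tau DDM parameters.
#' @param w relative starting point in (0, 1).
#' @return density value(s).
#' @export
wfpt_density <- function(rt, choice, v, a, tau, w = 0.5) {
  if (a <= 0 || tau <= 0 || w <= 0 || w >= 1)
    stop("wfpt_density: invalid parameters", call. = FALSE)
  n <- max(length(rt), length(choice))
  rt <- rep_len(rt, n); choice <- rep_len(choice, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- rt[i] - tau
    if (!is.finite(u) || u <= 0) next
    if (choice[i] == 1) { vv <- -v; ww <- 1 - w } else { vv <- v; ww <- w }
    tt <- u / a^2
    out[i] <- wfpt_f1(tt, ww) * exp(-vv * a * ww - vv^2 * u / 2) / a^2
  }
  out
}

#' Closed-form absorption probability at the upper boundary
#'
#' For the two-boundary Wiener process with unit diffusion, drift `v`,
#' separation `a`, and relative start `w`:
#' P(upper) = (1 - exp(-2 v a w)) / (1 - exp(-2 v a)) (limit w at v = 0).
#' With w = 1/2 this reduces to 1 / (1 + exp(-v a)).
#'
#' @param v,a,w process parameters.
#' @return probability of absorbing at the upper boundary.
#' @export
ddm_prob_upper <- function(v, a, w = 0.5) {
  if (abs(v) < 1e-12) return(w)
  expm1(-2 * v * a * w) / expm1(-2 * v * a)
}
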