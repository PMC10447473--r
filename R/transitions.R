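#' Declare a high-level transition model
#'
#' The transition model governs how the low-level parameters theta_t evolve
#' across time steps. Available kinds:
#' \describe{
#'   \item{`static`}{theta_t = theta_0 for all t (stationary reduction).}
#'   \item{`random_walk`}{Gaussian random walk theta_t = theta_(t-1) +
#'     sigma * xi_t, xi_t ~ N(0, 1), one diffusion scale per parameter.}
#'   \item{`var`}{vector autoregression of order `p`:
#'     theta_t = c + A_1 theta_(t-1) + ... + A_p theta_(t-p) + xi_t with
#'     xi_t ~ N(0, sigma).}
#'   \item{`gp`}{independent Gaussian processes over the normalized time
#'     grid with squared-exponential covariance
#'     k(t, t') = sigma^2 exp(-(t - t')^2 / (2 l^2)); static parameters are
#'     the amplitude sigma_k and length-scale l_k per low-level parameter.}
#'   \item{`regime_switch`}{parameters constant except at pre-declared switch
#'     times, where each jumps to an independent uniform draw within bounds.}
#'   \item{`itv`}{inter-trial variability: memoryless independent draws
#'     N(mean, scale) around a constant value each step.}
#' }
#'
#' Transitions act on the *unconstrained* scale of each parameter (see
#' [low_level_spec()] links); bounds are enforced by the simulator.
#'
#' @param kind transition kind, see above.
#' @param eta_priors named list of [prior_spec()] for the static high-level
#'   parameters. Defaults: `random_walk`/`itv` scales ~ Beta(1, 25) per
#'   low-level parameter; `gp` amplitude ~ Gamma(1.5, 5) and length-scale
#'   ~ Gamma(5, 10) per parameter; `var` intercept ~ N(0, 0.5), diagonal
#'   AR weight ~ Uniform(0.5, 0.95), noise scale ~ Beta(1, 25).
#' @param p VAR order (kind `var` only), >= 1.
#' @param switch_times integer vector of strictly increasing switch times
#'   (kind `regime_switch`), each < T at simulation time.
#' @param jump_bounds 2-column matrix (one row per low-level parameter) of
#'   lower/upper bounds for the uniform jumps (kind `regime_switch`), on the
#'   unconstrained scale.
#' @return object of class `transition_spec`.
#' @export
transition_spec <- function(kind, eta_priors = NULL, p = 1L,
                            switch_times = NULL, jump_bounds = NULL) {
  kind <- match.arg(kind,
    c("static", "random_walk", "var", "gp", "regime_switch", "itv"))
  if (kind == "var" && (!is.numeric(p) || p < 1))
    stop("transition_spec: VAR order p must be >= 1", call. = FALSE)
  if (kind == "regime_switch") {
    if (is.null(switch_times) || any(diff(switch_times) <= 0) ||
        any(switch_times < 1))
      stop("transition_spec: switch_times must be strictly increasing and >= 1",
           call. = FALSE)
    if (!is.null(jump_bounds)) {
      jump_bounds <- as.matrix(jump_bounds)
      if (ncol(jump_bounds) != 2 || any(jump_bounds[, 1] >= jump_bounds[, 2]))
        stop("transition_spec: jump_bounds must be a 2-column matrix with lower < upper",
             call. = FALSE)
    }
  }
  if (!is.null(eta_priors)) {
    ok <- vapply(eta_priors, is_prior_spec, logical(1))
    if (!all(ok) || is.null(names(eta_priors)))
      stop("transition_spec: eta_priors must be a named list of prior_spec",
           call. = FALSE)
  }
  structure(list(kind = kind, eta_priors = eta_priors, p = as.integer(p),
                 switch_times = as.integer(switch_times %||% integer(0)),
                 jump_bounds = jump_bounds),
            class = "transition_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transition_spec <- function(x, ...) {
  cat("<transition_spec> kind =", x$kind)
  if (x$kind == "var") cat(" (p =", x$p, ")")
  if (x$kind == "regime_switch")
    cat(" switches at", paste(x$switch_times, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' One Gaussian random-walk step
#'
#' Computes theta_(t-1) + sigma * xi elementwise. The caller supplies the
#' standard-normal noise so that the operation is deterministic and directly
#' testable; [simulate_dataset()] draws the noise from the model RNG stream.
#'
#' @param theta_prev numeric vector, current parameter row (unconstrained
#'   scale).
#' @param sigma per-parameter diffusion scales, all >= 0 (recycled if scalar).
#' @param xi standard-normal noise row, same length as `theta_prev`.
#' @return numeric vector theta_t.
#' @examples
#' transition_random_walk(1, 0.1, 1)  # 1.1
#' @export
transition_random_walk <- function(theta_prev, sigma, xi) {
  if (length(sigma) == 1L) sigma <- rep(sigma, length(theta_prev))
  if (length(sigma) != length(theta_prev) || length(xi) != length(theta_prev))
    stop("transition_random_walk: argument lengths disagree", call. = FALSE)
  if (any(sigma < 0))
    stop("transition_random_walk: sigma must be >= 0", call. = FALSE)
  theta_prev + sigma * xi
}

#' One vector-autoregression step
#'
#' theta_t = c + A_1 theta_(t-1) + ... + A_p theta_(t-p) + xi, where the
#' noise xi ~ N(0, sigma) is supplied by the caller (already scaled, i.e.
#' `xi` is the realized noise vector, not standard normal).
#'
#' @param theta_hist matrix with the last p parameter rows, most recent row
#'   LAST (row p is theta_(t-1)).
#' @param eta list with elements `c` (intercept vector), `A` (list of p
#'   square matrices, `A[[k]]` multiplying theta_(t-k)).
#' @param xi realized noise vector.
#' @return numeric vector theta_t.
#' @export
transition_var <- function(theta_hist, eta, xi) {
  theta_hist <- rbind(theta_hist)
  p <- length(eta$A)
  d <- length(eta$c)
  if (nrow(theta_hist) < p)
    stop("transition_var: history shorter than VAR order", call. = FALSE)
  if (ncol(theta_hist) != d || length(xi) != d)
    stop("transition_var: dimension mismatch", call. = FALSE)
  out <- eta$c + xi
  for (k in seq_len(p)) {
    A <- eta$A[[k]]
    if (!is.matrix(A) || any(dim(A) != d))
      stop("transition_var: A[[", k, "]] must be ", d, "x", d, call. = FALSE)
    out <- out + drop(A %*% theta_hist[nrow(theta_hist) - k + 1L, ])
  }
  out
}

#' Sample a Gaussian-process parameter trajectory
#'
#' Each parameter's trajectory (length `T + 1`, indices t = 0..T) is an
#' independent draw from a GP on the time grid normalized to [0, 1], with
#' squared-exponential covariance k(t, t') = sigma^2 exp(-(t - t')^2 /
#' (2 l^2)), mean equal to the starting row, and a 1e-6 diagonal jitter for
#' Cholesky stability.
#'
#' @param T number of time steps (>= 2); the returned matrix has T + 1 rows.
#' @param eta list with numeric vectors `sigma` (amplitudes, >= 0) and
#'   `l` (length-scales, > 0), one element per parameter.
#' @param mean numeric vector, the GP mean (row 0 value) per parameter.
#' @return (T + 1) x d matrix on the unconstrained scale; row 1 equals
#'   `mean` plus the GP fluctuation at t = 0.
#' @export
sample_gp_trajectory <- function(T, eta, mean) {
  d <- length(mean)
  sig <- rep_len(eta$sigma, d); l <- rep_len(eta$l, d)
  if (T < 2) stop("sample_gp_trajectory: T must be >= 2", call. = FALSE)
  if (any(l <= 0))
    stop("sample_gp_trajectory: length-scales must be > 0", call. = FALSE)
  if (any(sig < 0))
    stop("sample_gp_trajectory: amplitudes must be >= 0", call. = FALSE)
  grid <- seq(0, 1, length.out = T + 1L)
  D2 <- outer(grid, grid, "-")^2
  out <- matrix(0, T + 1L, d)
  for (j in seq_len(d)) {
    if (sig[j] == 0) { out[, j] <- mean[j]; next }
    K <- sig[j]^2 * exp(-D2 / (2 * l[j]^2))
    diag(K) <- diag(K) + 1e-6
    L <- chol(K)
    out[, j] <- mean[j] + drop(crossprod(L, stats::rnorm(T + 1L)))
  }
  out
}

#' Squared-exponential kernel matrix over a normalized time grid
#'
#' Exposed mainly for testing (symmetry / positive semi-definiteness).
#' @param T number of steps; grid is `seq(0, 1, length.out = T + 1)`.
#' @param sigma amplitude, `l` length-scale; `jitter` added to the diagonal.
#' @param l length-scale (> 0).
#' @param jitter diagonal stabilizer.
#' @return (T+1) x (T+1) covariance matrix.
#' @export
se_kernel_matrix <- function(T, sigma, l, jitter = 1e-6) {
  grid <- seq(0, 1, length.out = T + 1L)
  K <- sigma^2 * exp(-outer(grid, grid, "-")^2 / (2 * l^2))
  diag(K) <- diag(K) + jitter
  K
}

#' One regime-switching step
#'
#' Off switch times the parameters are carried over unchanged; at a switch
#' time each parameter jumps to an independent uniform draw within its
#' declared bounds (drawn from the current RNG stream).
#'
#' @param theta_prev numeric parameter row.
#' @param t current time index (1-based trial index).
#' @param spec a `transition_spec` of kind `regime_switch`.
#' @return numeric vector theta_t.
#' @export
transition_regime_switch <- function(theta_prev, t, spec) {
  stopifnot(inherits(spec, "transition_spec"), spec$kind == "regime_switch")
  if (!(t %in% spec$switch_times)) return(theta_prev)
  b <- spec$jump_bounds
  if (is.null(b))
    stop("transition_regime_switch: spec has no jump_bounds", call. = FALSE)
  stats::runif(length(theta_prev), b[, 1], b[, 2])
}

#' One inter-trial-variability step
#'
#' Memoryless independent draw N(mean_row, scales) — the classic extended-DDM
#' assumption that parameters fluctuate homogeneously around a constant value.
#'
#' @param mean_row constant center per parameter.
#' @param scales per-parameter SDs (>= 0).
#' @return numeric vector theta_t.
#' @export
transition_itv <- function(mean_row, scales) {
  if (length(scales) == 1L) scales <- rep(scales, length(mean_row))
  if (any(scales < 0))
    stop("transition_itv: scales must be >= 0", call. = FALSE)
  stats::rnorm(length(mean_row), mean_row, scales)
}

## Default eta priors per transition kind, given d low-level parameters and
## their names. Random-walk scales mirror the coal benchmark's Beta(1, 25).
default_eta_priors <- function(kind, par_names, p = 1L) {
  d <- length(par_names)
  switch(kind,
    static = list(),
    random_walk = stats::setNames(
      replicate(d, prior_spec("beta", shape1 = 1, shape2 = 25),
                simplify = FALSE),
      paste0("sigma_", par_names)),
    itv = stats::setNames(
      replicate(d, prior_spec("beta", shape1 = 1, shape2 = 25),
                simplify = FALSE),
      paste0("scale_", par_names)),
    gp = c(
      stats::setNames(
        replicate(d, prior_spec("gamma", shape = 1.5, rate = 5),
                  simplify = FALSE),
        paste0("sigma_", par_names)),
      stats::setNames(
        replicate(d, prior_spec("gamma", shape = 5, rate = 10),
                  simplify = FALSE),
        paste0("l_", par_names))),
    var = c(
      stats::setNames(
        replicate(d, prior_spec("normal", mean = 0, sd = 0.5),
                  simplify = FALSE),
        paste0("c_", par_names)),
      stats::setNames(
        replicate(d * p, prior_spec("uniform", min = 0.5, max = 0.95),
                  simplify = FALSE),
        paste0("a_", rep(seq_len(p), each = d), "_", rep(par_names, p))),
      list(sigma = prior_spec("beta", shape1 = 1, shape2 = 25))),
    regime_switch = list())
}
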