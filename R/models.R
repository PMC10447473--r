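#' Declare a low-level observation model
#'
#' The low-level model generates one data point per time step given the
#' current parameter row theta_t. Two kinds are built in:
#' \describe{
#'   \item{`poisson`}{a count emission with rate `lambda` (events/step).
#'     Default prior lambda_0 ~ Exp(0.5); `lambda` is propagated on the
#'     natural scale and clamped to `[0.001, 15]` so that lattice-based
#'     filtering on the same range is an exact oracle.}
#'   \item{`ddm`}{the diffusion decision model with drift(s) `v`
#'     (evidence/s), boundary separation `a` (evidence units), and
#'     non-decision time `tau` (s); starting point fixed at `a/2` and
#'     diffusion coefficient fixed at 1. With `n_drifts > 1` there is one
#'     drift per condition code. `a` and `tau` evolve on the log scale
#'     (keeping Gaussian transitions well-defined on positive parameters),
#'     `v` on the natural scale.}
#' }
#'
#' @param kind `"poisson"` or `"ddm"`.
#' @param n_drifts number of condition-specific drift rates (ddm only; 1 or
#'   more — lexical-decision designs typically use 4, one per stimulus
#'   class).
#' @param theta0_priors optional named list of [prior_spec()] overriding the
#'   defaults (natural scale): `v ~ N(0, 2.5)`, `a ~ Gamma(4, 3)`,
#'   `tau ~ Gamma(1.5, 5)`, `lambda ~ Exp(0.5)`.
#' @param bounds optional 2-column matrix of hard natural-scale support
#'   bounds per parameter (rows named as the parameters).
#' @param sim_dt Euler step (s) for the DDM simulator; `t_max` simulation
#'   timeout (s).
#' @param t_max timeout per trial (s), ddm only.
#' @return object of class `low_level_spec`.
#' @export
low_level_spec <- function(kind, n_drifts = 1L, theta0_priors = NULL,
                           bounds = NULL, sim_dt = 1e-3, t_max = 10) {
  kind <- match.arg(kind, c("poisson", "ddm"))
  if (kind == "poisson") {
    par_names <- "lambda"
    links <- c(lambda = "identity")
    def_bounds <- matrix(c(1e-3, 15), 1, 2,
                         dimnames = list(par_names, c("lower", "upper")))
    def_priors <- list(lambda = prior_spec("exponential", rate = 0.5))
    units <- c(lambda = "events/step")
  } else {
    n_drifts <- as.integer(n_drifts)
    if (n_drifts < 1) stop("low_level_spec: n_drifts must be >= 1",
                           call. = FALSE)
    vn <- if (n_drifts == 1) "v" else paste0("v", seq_len(n_drifts))
    par_names <- c(vn, "a", "tau")
    links <- c(stats::setNames(rep("identity", n_drifts), vn),
               a = "log", tau = "log")
    def_bounds <- rbind(
      matrix(rep(c(-8, 8), each = n_drifts), n_drifts, 2),
      c(0.05, 6), c(0.02, 2))
    dimnames(def_bounds) <- list(par_names, c("lower", "upper"))
    def_priors <- c(
      stats::setNames(replicate(n_drifts,
        prior_spec("normal", mean = 0, sd = 2.5), simplify = FALSE), vn),
      list(a   = prior_spec("gamma", shape = 4,   rate = 3),
           tau = prior_spec("gamma", shape = 1.5, rate = 5)))
    units <- c(stats::setNames(rep("evidence/s", n_drifts), vn),
               a = "evidence units", tau = "s")
  }
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != length(par_names) || ncol(bounds) != 2)
      stop("low_level_spec: bounds must be ", length(par_names),
           " x 2", call. = FALSE)
    def_bounds[] <- bounds
  }
  if (!is.null(theta0_priors)) {
    for (nm in names(theta0_priors)) {
      if (!nm %in% par_names)
        stop("low_level_spec: unknown parameter '", nm, "' in theta0_priors",
             call. = FALSE)
      def_priors[[nm]] <- theta0_priors[[nm]]
    }
  }
  structure(list(kind = kind, par_names = par_names, links = links,
                 bounds = def_bounds, theta0_priors = def_priors,
                 n_drifts = if (kind == "ddm") n_drifts else 0L,
                 units = units, sim_dt = sim_dt, t_max = t_max),
            class = "low_level_spec")
}

#' @export
print.low_level_spec <- function(x, ...) {
  cat("<low_level_spec>", x$kind, "with parameters",
      paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

## link / inverse-link on vectors or matrices, columnwise by parameter
link_transform <- function(low, theta) {
  theta <- rbind(theta)
  for (j in seq_along(low$par_names))
    if (low$links[j] == "log") theta[, j] <- log(theta[, j])
  theta
}

link_back_transform <- function(low, z, clamp = TRUE) {
  z <- rbind(z)
  for (j in seq_along(low$par_names))
    if (low$links[j] == "log") z[, j] <- exp(z[, j])
  if (clamp)
    for (j in seq_along(low$par_names))
      z[, j] <- pmin(pmax(z[, j], low$bounds[j, 1]), low$bounds[j, 2])
  z
}

## bounds on the transformed (unconstrained-walk) scale
trans_bounds <- function(low) {
  b <- low$bounds
  for (j in seq_along(low$par_names))
    if (low$links[j] == "log") b[j, ] <- log(b[j, ])
  b
}

clamp_rows <- function(z, b) {
  for (j in seq_len(ncol(z))) z[, j] <- pmin(pmax(z[, j], b[j, 1]), b[j, 2])
  z
}

#' Combine a low-level and a transition model into a generative model
#'
#' @param low_level a [low_level_spec()].
#' @param transition a [transition_spec()]; if its `eta_priors` are `NULL`,
#'   kind-appropriate defaults are attached (see [transition_spec()]).
#' @return object of class `superstat_model`.
#' @examples
#' m <- coal_model()
#' sim <- simulate_dataset(m, T = 110, seed = 1)
#' @export
superstat_model <- function(low_level, transition) {
  stopifnot(inherits(low_level, "low_level_spec"),
            inherits(transition, "transition_spec"))
  if (is.null(transition$eta_priors))
    transition$eta_priors <- default_eta_priors(
      transition$kind, low_level$par_names, transition$p)
  if (transition$kind == "regime_switch" && is.null(transition$jump_bounds)) {
    ## default jumps: uniform within a plausible transformed-scale box
    b <- trans_bounds(low_level)
    if (low_level$kind == "ddm") {
      vidx <- grep("^v", low_level$par_names)
      b[vidx, ] <- rep(c(-6, 6), each = length(vidx))
      b["a", ] <- log(c(0.5, 3)); b["tau", ] <- log(c(0.1, 1))
    }
    transition$jump_bounds <- b
  }
  structure(list(low_level = low_level, transition = transition),
            class = "superstat_model")
}

#' @export
print.superstat_model <- function(x, ...) {
  cat("<superstat_model>\n  low-level : ", x$low_level$kind,
      " (", paste(x$low_level$par_names, collapse = ", "), ")\n",
      "  transition: ", x$transition$kind, "\n", sep = "")
  invisible(x)
}

#' The coal-mining style benchmark model
#'
#' Poisson counts whose rate follows a Gaussian random walk on the natural
#' scale (clamped to `[0.001, 15]`), with lambda_0 ~ Exp(0.5) and walk scale
#' sigma ~ Beta(1, 25).
#' @return a [superstat_model()].
#' @export
coal_model <- function() {
  superstat_model(low_level_spec("poisson"), transition_spec("random_walk"))
}

#' A non-stationary DDM with a chosen transition model
#'
#' @param transition transition kind (default `"random_walk"`) or a full
#'   [transition_spec()].
#' @param n_drifts number of condition-specific drift rates.
#' @param ... passed to [low_level_spec()].
#' @return a [superstat_model()].
#' @export
ddm_model <- function(transition = "random_walk", n_drifts = 1L, ...) {
  if (is.character(transition)) transition <- transition_spec(transition)
  superstat_model(low_level_spec("ddm", n_drifts = n_drifts, ...), transition)
}

n_eta <- function(model) length(model$transition$eta_priors)

#' Draw initial low-level parameters and high-level parameters from priors
#'
#' @param model a [superstat_model()].
#' @param n number of joint draws (>= 1).
#' @param seed optional integer seed; identical seeds give identical draws.
#' @return list with `theta0` (n x d matrix, natural scale) and `eta`
#'   (n x k matrix, natural scale, named columns).
#' @export
sample_prior <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "superstat_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  low <- model$low_level
  theta0 <- vapply(low$par_names,
                   function(nm) prior_sample(low$theta0_priors[[nm]], n),
                   numeric(n))
  theta0 <- matrix(theta0, n, length(low$par_names),
                   dimnames = list(NULL, low$par_names))
  theta0 <- t(apply(theta0, 1, function(r)
    pmin(pmax(r, low$bounds[, 1]), low$bounds[, 2])))
  if (length(low$par_names) == 1L) theta0 <- t(theta0)
  ep <- model$transition$eta_priors
  eta <- if (length(ep))
    vapply(names(ep), function(nm) prior_sample(ep[[nm]], n), numeric(n))
  else matrix(0, n, 0)
  eta <- matrix(eta, n, length(ep), dimnames = list(NULL, names(ep)))
  list(theta0 = theta0, eta = eta)
}

## Assemble the VAR eta list (c, A_1..A_p, sigma) from a named eta vector.
var_eta_list <- function(eta, d, p, par_names) {
  A <- vector("list", p)
  for (k in seq_len(p))
    A[[k]] <- diag(eta[paste0("a_", k, "_", par_names)], d, d)
  list(c = unname(eta[paste0("c_", par_names)]), A = A,
       sigma = unname(eta["sigma"]))
}

## Simulate a transformed-scale parameter trajectory, rows t = 0..T.
simulate_trajectory_trans <- function(model, eta, theta0_nat, T) {
  low <- model$low_level
  d <- length(low$par_names)
  b <- trans_bounds(low)
  z0 <- drop(link_transform(low, theta0_nat))
  kind <- model$transition$kind
  out <- matrix(0, T + 1L, d)
  out[1, ] <- z0
  if (kind == "static") {
    out <- matrix(z0, T + 1L, d, byrow = TRUE)
  } else if (kind == "random_walk") {
    sig <- unname(eta[paste0("sigma_", low$par_names)])
    if (any(sig < 0)) stop("negative random-walk scale", call. = FALSE)
    noise <- matrix(stats::rnorm(T * d), T, d)
    ## fast path: free cumulative walk; fall back to a stepwise clamped walk
    ## only for columns that leave the support box
    z0v <- as.numeric(z0); lo <- unname(b[, 1]); hi <- unname(b[, 2])
    for (j in seq_len(d)) {
      w <- z0v[j] + cumsum(sig[j] * noise[, j])
      if (sig[j] == 0 || (w[which.max(w)] <= hi[j] &&
                          w[which.min(w)] >= lo[j])) {
        out[-1L, j] <- w
      } else {
        z <- z0v[j]
        for (t in seq_len(T)) {
          z <- z + sig[j] * noise[t, j]
          if (z < lo[j]) z <- lo[j] else if (z > hi[j]) z <- hi[j]
          out[t + 1L, j] <- z
        }
      }
    }
  } else if (kind == "itv") {
    sc <- unname(eta[paste0("scale_", low$par_names)])
    for (t in seq_len(T))
      out[t + 1L, ] <- pmin(pmax(transition_itv(z0, sc), b[, 1]), b[, 2])
  } else if (kind == "gp") {
    sig <- unname(eta[paste0("sigma_", low$par_names)])
    l   <- unname(eta[paste0("l_", low$par_names)])
    raw <- sample_gp_trajectory(T, list(sigma = sig, l = l), rep(0, d))
    ## pin the fluctuation to zero at t = 0 so that row 0 equals theta_0
    ## (conditional SE GP given f(0) = 0)
    grid <- seq(0, 1, length.out = T + 1L)
    for (j in seq_len(d)) {
      if (sig[j] == 0) { out[, j] <- z0[j]; next }
      k0 <- exp(-grid^2 / (2 * l[j]^2))  # corr with t = 0
      f <- raw[, j] - k0 * raw[1, j]
      out[, j] <- z0[j] + f
    }
    out <- clamp_rows(out, b)
  } else if (kind == "regime_switch") {
    z <- z0
    for (t in seq_len(T)) {
      z <- transition_regime_switch(z, t, model$transition)
      z <- pmin(pmax(z, b[, 1]), b[, 2])
      out[t + 1L, ] <- z
    }
  } else if (kind == "var") {
    el <- var_eta_list(eta, d, model$transition$p, low$par_names)
    p <- model$transition$p
    hist <- matrix(z0, p, d, byrow = TRUE)
    for (t in seq_len(T)) {
      xi <- stats::rnorm(d, 0, el$sigma)
      z <- transition_var(hist, el, xi)
      z <- pmin(pmax(z, b[, 1]), b[, 2])
      out[t + 1L, ] <- z
      hist <- rbind(hist[-1, , drop = FALSE], z)
    }
  }
  colnames(out) <- low$par_names
  out
}

#' Emit an observation series from a parameter trajectory
#'
#' Trial t is generated from the low-level model with parameter row
#' `theta[t, ]` (and, for a multi-drift DDM, the drift matching
#' `condition[t]`).
#'
#' @param model a [superstat_model()] (only the low-level part is used).
#' @param theta T x d natural-scale parameter matrix (one row per trial,
#'   NOT including the t = 0 row).
#' @param condition integer vector of 0-based condition codes (multi-drift
#'   DDM only); defaults to all zeros.
#' @param dt,t_max DDM simulator settings (default from the low-level spec).
#' @return data.frame: `trial, rt, choice, condition, timeout` (ddm) or
#'   `t, count` (poisson).
#' @export
observe <- function(model, theta, condition = NULL, dt = NULL, t_max = NULL) {
  low <- if (inherits(model, "superstat_model")) model$low_level else model
  theta <- rbind(theta)
  T <- nrow(theta)
  if (low$kind == "poisson") {
    lam <- theta[, 1]
    if (any(lam < 0)) stop("observe: negative rate", call. = FALSE)
    return(data.frame(t = seq_len(T), count = stats::rpois(T, lam)))
  }
  C <- max(1L, low$n_drifts)
  if (is.null(condition)) condition <- rep(0L, T)
  if (length(condition) != T || any(condition < 0 | condition >= C))
    stop("observe: condition codes must be in 0..", C - 1L, call. = FALSE)
  vidx <- grep("^v", low$par_names)
  v <- theta[cbind(seq_len(T), vidx[condition + 1L])]
  a <- theta[, "a"]; tau <- theta[, "tau"]
  if (any(a <= 0) || any(tau <= 0))
    stop("observe: a and tau must be > 0", call. = FALSE)
  dt <- dt %||% low$sim_dt; t_max <- t_max %||% low$t_max
  tr <- cpp_ddm_trials(v, a, tau, dt, t_max, TRUE)
  data.frame(trial = seq_len(T), rt = tr$rt, choice = tr$choice,
             condition = condition, timeout = tr$timeout)
}

#' Simulate a complete (eta, theta_0:T, x_1:T) record
#'
#' Draws theta_0 and eta from their priors, propagates the declared
#' transition model, and emits observations. The record stores the seed; the
#' RNG stream is split into a transition-noise and an observation-noise
#' substream, so re-running with the stored seed reproduces all components
#' bit-identically and observation noise is reproducible independently of
#' trajectory noise.
#'
#' @param model a [superstat_model()].
#' @param T series length (>= 1).
#' @param seed optional integer seed.
#' @param condition optional 0-based condition codes of length T.
#' @return object of class `superstat_sim`: list with `eta` (named vector),
#'   `theta` ((T+1) x d natural-scale matrix, row 1 = theta_0), `series`
#'   (data.frame), `seed`, `model`.
#' @export
simulate_dataset <- function(model, T, seed = NULL, condition = NULL) {
  stopifnot(inherits(model, "superstat_model"), T >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  low <- model$low_level
  set.seed(sub[1])
  pr <- sample_prior(model, 1)
  eta <- drop(pr$eta)
  if (length(pr$eta)) names(eta) <- colnames(pr$eta)
  set.seed(sub[2])
  ztraj <- simulate_trajectory_trans(model, eta, pr$theta0, T)
  theta <- link_back_transform(low, ztraj)
  colnames(theta) <- low$par_names
  if (low$kind == "ddm" && low$n_drifts > 1 && is.null(condition)) {
    condition <- sample.int(low$n_drifts, T, replace = TRUE) - 1L
  }
  set.seed(sub[3])
  series <- observe(model, theta[-1, , drop = FALSE], condition = condition)
  structure(list(eta = eta, theta = theta, series = series, seed = seed,
                 model = model),
            class = "superstat_sim")
}

#' @export
print.superstat_sim <- function(x, ...) {
  cat("<superstat_sim> T =", nrow(x$series), "|",
      x$model$low_level$kind, "+", x$model$transition$kind, "\n")
  if (length(x$eta)) {
    cat("  eta:", paste(names(x$eta), signif(x$eta, 3), sep = "=",
                        collapse = ", "), "\n")
  }
  invisible(x)
}
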