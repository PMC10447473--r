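#' Declare a prior distribution for a model parameter
#'
#' A `prior_spec` is a lightweight descriptor of a univariate prior used for
#' initial low-level parameters (theta_0) and static high-level parameters
#' (eta). Supported families: `"normal"`, `"truncnorm"` (truncated normal),
#' `"gamma"` (shape/rate), `"exponential"` (rate), `"beta"`, `"uniform"`.
#'
#' @param family character; one of the families above.
#' @param ... family parameters: `mean`, `sd` (normal, truncnorm);
#'   `shape`, `rate` (gamma); `rate` (exponential); `shape1`, `shape2` (beta);
#'   `min`, `max` (uniform).
#' @param lower,upper optional truncation bounds (finite or infinite). For
#'   `truncnorm` they define the truncation interval; for other families they
#'   must be consistent with the family's natural support.
#' @return an object of class `prior_spec`.
#' @examples
#' p <- prior_spec("exponential", rate = 0.5)
#' mean(prior_sample(p, 1e4))  # ~ 2
#' @export
prior_spec <- function(family, ..., lower = NULL, upper = NULL) {
  family <- match.arg(family,
    c("normal", "truncnorm", "gamma", "exponential", "beta", "uniform"))
  pars <- list(...)
  need <- switch(family,
    normal      = c("mean", "sd"),
    truncnorm   = c("mean", "sd"),
    gamma       = c("shape", "rate"),
    exponential = "rate",
    beta        = c("shape1", "shape2"),
    uniform     = c("min", "max"))
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop("prior_spec('", family, "'): missing parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in need) {
    v <- pars[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("prior_spec: parameter '", nm, "' must be a single number",
           call. = FALSE)
  }
  if (family %in% c("normal", "truncnorm") && pars$sd < 0)
    stop("prior_spec: sd must be >= 0", call. = FALSE)
  if (family == "gamma" && (pars$shape <= 0 || pars$rate <= 0))
    stop("prior_spec: gamma shape and rate must be > 0", call. = FALSE)
  if (family == "exponential" && pars$rate <= 0)
    stop("prior_spec: exponential rate must be > 0", call. = FALSE)
  if (family == "beta" && (pars$shape1 <= 0 || pars$shape2 <= 0))
    stop("prior_spec: beta shapes must be > 0", call. = FALSE)
  if (family == "uniform" && pars$min >= pars$max)
    stop("prior_spec: uniform requires min < max", call. = FALSE)

  natural <- switch(family,
    normal      = c(-Inf, Inf),
    truncnorm   = c(-Inf, Inf),
    gamma       = c(0, Inf),
    exponential = c(0, Inf),
    beta        = c(0, 1),
    uniform     = c(pars$min, pars$max))
  lo <- if (is.null(lower)) natural[1] else lower
  hi <- if (is.null(upper)) natural[2] else upper
  if (is.na(lo) || is.na(hi) || lo >= hi)
    stop("prior_spec: invalid bounds [", lo, ", ", hi, "]", call. = FALSE)
  if (lo < natural[1] || hi > natural[2])
    stop("prior_spec: bounds inconsistent with the support of family '",
         family, "'", call. = FALSE)
  structure(list(family = family, pars = pars, lower = lo, upper = hi),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> ", x$family, "(",
      paste(names(x$pars), unlist(x$pars), sep = "=", collapse = ", "),
      ") on [", x$lower, ", ", x$upper, "]\n", sep = "")
  invisible(x)
}

is_prior_spec <- function(x) inherits(x, "prior_spec")

#' Draw from a prior
#'
#' Sampling uses the current R RNG stream; truncation (when bounds are
#' tighter than the family's natural support) is performed by inverse-CDF so
#' no draws are rejected.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`, inside `[spec$lower, spec$upper]`.
#' @export
prior_sample <- function(spec, n) {
  stopifnot(is_prior_spec(spec), n >= 0)
  if (n == 0) return(numeric(0))
  p <- spec$pars
  cdf <- prior_cdf_fun(spec)
  qf  <- prior_quantile_fun(spec)
  natural_lo <- switch(spec$family,
    normal = -Inf, truncnorm = -Inf, gamma = 0, exponential = 0,
    beta = 0, uniform = p$min)
  natural_hi <- switch(spec$family,
    normal = Inf, truncnorm = Inf, gamma = Inf, exponential = Inf,
    beta = 1, uniform = p$max)
  if (spec$lower > natural_lo || spec$upper < natural_hi ||
      spec$family == "truncnorm") {
    a <- cdf(spec$lower); b <- cdf(spec$upper)
    u <- stats::runif(n, a, b)
    x <- qf(u)
  } else {
    x <- switch(spec$family,
      normal      = stats::rnorm(n, p$mean, p$sd),
      gamma       = stats::rgamma(n, shape = p$shape, rate = p$rate),
      exponential = stats::rexp(n, p$rate),
      beta        = stats::rbeta(n, p$shape1, p$shape2),
      uniform     = stats::runif(n, p$min, p$max))
  }
  pmin(pmax(x, spec$lower), spec$upper)
}

prior_cdf_fun <- function(spec) {
  p <- spec$pars
  switch(spec$family,
    normal      = function(x) stats::pnorm(x, p$mean, p$sd),
    truncnorm   = function(x) stats::pnorm(x, p$mean, p$sd),
    gamma       = function(x) stats::pgamma(x, shape = p$shape, rate = p$rate),
    exponential = function(x) stats::pexp(x, p$rate),
    beta        = function(x) stats::pbeta(x, p$shape1, p$shape2),
    uniform     = function(x) stats::punif(x, p$min, p$max))
}

prior_quantile_fun <- function(spec) {
  p <- spec$pars
  switch(spec$family,
    normal      = function(u) stats::qnorm(u, p$mean, p$sd),
    truncnorm   = function(u) stats::qnorm(u, p$mean, p$sd),
    gamma       = function(u) stats::qgamma(u, shape = p$shape, rate = p$rate),
    exponential = function(u) stats::qexp(u, p$rate),
    beta        = function(u) stats::qbeta(u, p$shape1, p$shape2),
    uniform     = function(u) stats::qunif(u, p$min, p$max))
}

#' Prior density evaluated on a vector of points
#'
#' Truncated priors are renormalized over `[lower, upper]`.
#'
#' @param spec a [prior_spec()].
#' @param x numeric vector.
#' @param log return the log density?
#' @return numeric vector of (log) densities; zero (`-Inf`) outside support.
#' @export
prior_density <- function(spec, x, log = FALSE) {
  stopifnot(is_prior_spec(spec))
  p <- spec$pars
  d <- switch(spec$family,
    normal      = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    truncnorm   = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    gamma       = stats::dgamma(x, shape = p$shape, rate = p$rate, log = TRUE),
    exponential = stats::dexp(x, p$rate, log = TRUE),
    beta        = stats::dbeta(x, p$shape1, p$shape2, log = TRUE),
    uniform     = stats::dunif(x, p$min, p$max, log = TRUE))
  cdf <- prior_cdf_fun(spec)
  z <- cdf(spec$upper) - cdf(spec$lower)
  d <- d - base::log(z)
  d[x < spec$lower | x > spec$upper] <- -Inf
  if (log) d else exp(d)
}
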