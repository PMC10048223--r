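#' Tweedie compound Poisson parameterizations
#'
#' A Tweedie random variable with power parameter \eqn{1 < p < 2} is a
#' compound Poisson sum \eqn{Y = \sum_{i=1}^U X_i} with
#' \eqn{U \sim \mathrm{Poisson}(\lambda)} and \eqn{X_i} i.i.d. gamma with
#' shape \eqn{\alpha} and scale \eqn{\gamma} (mean \eqn{\alpha\gamma},
#' variance \eqn{\alpha\gamma^2}). `tw_params()` holds the mean
#' parameterization \eqn{(\mu, \phi, p)} with \eqn{E(Y)=\mu} and
#' \eqn{\mathrm{Var}(Y)=\phi\mu^p}; `tw_natural()` holds the compound
#' parameterization \eqn{(\lambda, \alpha, \gamma)}. The two are linked by
#' the bijection
#' \deqn{\lambda = \mu^{2-p}/(\phi(2-p)), \quad \alpha = (2-p)/(p-1),
#'       \quad \gamma = \phi(p-1)\mu^{p-1}.}
#'
#' @param mu positive mean.
#' @param phi positive dispersion.
#' @param p power parameter, strictly inside (1, 2).
#' @return An object of class `tw_params` or `tw_natural` (a named list).
#' @examples
#' tw_to_natural(tw_params(mu = 1, phi = 0.5, p = 1.5))
#' @export
tw_params <- function(mu, phi, p) {
  stopifnot(length(mu) == length(phi), length(phi) == length(p))
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive")
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("'phi' must be positive")
  if (any(!is.finite(p)) || any(p <= 1) || any(p >= 2))
    stop("'p' must lie strictly inside (1, 2)")
  structure(list(mu = mu, phi = phi, p = p), class = "tw_params")
}

#' @param lambda positive Poisson rate.
#' @param shape positive gamma shape.
#' @param scale positive gamma scale.
#' @rdname tw_params
#' @export
tw_natural <- function(lambda, shape, scale) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("'lambda' must be positive")
  if (any(!is.finite(shape)) || any(shape <= 0)) stop("'shape' must be positive")
  if (any(!is.finite(scale)) || any(scale <= 0)) stop("'scale' must be positive")
  structure(list(lambda = lambda, shape = shape, scale = scale),
            class = "tw_natural")
}

#' Convert between the mean and compound parameterizations
#'
#' @param params a [tw_params()] object.
#' @return `tw_to_natural()` returns a [tw_natural()] object;
#'   `tw_to_mean()` returns a [tw_params()] object.
#' @export
tw_to_natural <- function(params) {
  stopifnot(inherits(params, "tw_params"))
  with(params, tw_natural(lambda = mu^(2 - p) / (phi * (2 - p)),
                          shape  = (2 - p) / (p - 1),
                          scale  = phi * (p - 1) * mu^(p - 1)))
}

#' @param nat a [tw_natural()] object.
#' @rdname tw_to_natural
#' @export
tw_to_mean <- function(nat) {
  stopifnot(inherits(nat, "tw_natural"))
  mu <- nat$lambda * nat$shape * nat$scale
  p <- (nat$shape + 2) / (nat$shape + 1)
  phi <- nat$lambda^(1 - p) * (nat$shape * nat$scale)^(2 - p) / (2 - p)
  tw_params(mu = mu, phi = phi, p = p)
}

# Vectorized bare-bones conversion used in the sampler hot path: mu may be a
# vector, phi and p scalars; lambda/gamma come back as vectors, shape scalar.
.tw_nat <- function(mu, phi, p) {
  list(lambda = mu^(2 - p) / (phi * (2 - p)),
       shape = (2 - p) / (p - 1),
       scale = phi * (p - 1) * mu^(p - 1))
}

#' Simulate Tweedie compound Poisson draws with their latent counts
#'
#' Draws are generated through the compound representation: a Poisson count
#' \eqn{u}, then \eqn{y \mid u \sim \mathrm{Gamma}(u\alpha, \gamma)}
#' (with \eqn{y = 0} exactly when \eqn{u = 0}). Returning the latent count
#' alongside the outcome is what makes the augmented-data sampler possible.
#'
#' @param n number of draws; `mu` may also be a vector of length `n`.
#' @inheritParams tw_params
#' @return A data frame with columns `y` and `u`.
#' @examples
#' set.seed(1)
#' d <- rtweedie_cp(1000, mu = 1, phi = 0.5, p = 1.5)
#' mean(d$y)            # close to mu
#' mean(d$y == 0)       # close to exp(-lambda)
#' @export
rtweedie_cp <- function(n, mu, phi, p) {
  stopifnot(n >= 1)
  tw_params(mu[1], phi[1], p[1])  # domain checks
  if (length(mu) == 1) mu <- rep(mu, n)
  stopifnot(length(mu) == n)
  nat <- .tw_nat(mu, phi, p)
  u <- rpois(n, nat$lambda)
  y <- numeric(n)
  pos <- u > 0
  y[pos] <- rgamma(sum(pos), shape = u[pos] * nat$shape,
                   scale = if (length(nat$scale) == 1) nat$scale else nat$scale[pos])
  data.frame(y = y, u = u)
}

#' Joint log-density of an outcome and its latent Poisson count
#'
#' The joint density of \eqn{(Y, U)} factorizes as a point mass
#' \eqn{e^{-\lambda}} at \eqn{(0, 0)} and, for \eqn{y > 0},
#' \eqn{u \ge 1}, the product of the \eqn{\mathrm{Gamma}(u\alpha, \gamma)}
#' density of \eqn{y} and the Poisson(\eqn{\lambda}) mass of \eqn{u}.
#' Inconsistent pairs (positive \eqn{y} with \eqn{u = 0}, or the reverse)
#' return `-Inf`.
#'
#' @param y nonnegative outcome values.
#' @param u nonnegative integer latent counts, same length as `y`.
#' @param params a [tw_params()] or [tw_natural()] object (scalar, or with
#'   components matching `length(y)`).
#' @return Vector of log-density values.
#' @export
tw_joint_logpdf <- function(y, u, params) {
  nat <- if (inherits(params, "tw_params")) tw_to_natural(params) else params
  stopifnot(inherits(nat, "tw_natural"), length(y) == length(u))
  lam <- rep_len(nat$lambda, length(y))
  gam <- rep_len(nat$scale, length(y))
  cpp_tw_joint_loglik(as.numeric(y), as.integer(u), lam, nat$shape[1], gam)
}

#' Marginal Tweedie log-density by series summation
#'
#' The marginal density has no closed-form normalizing constant for
#' \eqn{y > 0}; it is recovered by summing the joint density over the latent
#' count. The series is expanded adaptively around its mode until terms fall
#' 37 nats below the running maximum, capped at `max_terms` (a warning is
#' issued if the cap is hit). `y = 0` returns exactly \eqn{-\lambda}.
#'
#' @inheritParams tw_joint_logpdf
#' @param max_terms series truncation cap.
#' @return Vector of log-density values (a log point-mass at zero).
#' @export
tw_marginal_logpdf <- function(y, params, max_terms = 1e4) {
  nat <- if (inherits(params, "tw_params")) tw_to_natural(params) else params
  stopifnot(inherits(nat, "tw_natural"))
  lam <- rep_len(nat$lambda, length(y))
  gam <- rep_len(nat$scale, length(y))
  out <- rep(-lam, length.out = length(y))
  pos <- y > 0
  if (any(pos)) {
    ser <- cpp_u_logsum(y[pos], lam[pos], nat$shape[1], gam[pos],
                        as.integer(max_terms))
    out[pos] <- -log(y[pos]) - y[pos] / gam[pos] - lam[pos] + ser
  }
  out
}
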