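#' Linear predictor of the partial linear mixed model
#'
#' Computes \eqn{\eta_{ij} = x_{ij}^T\beta + z_{ij}^T b_i + g(t_{ij})} for
#' every row of a long-format dataset, where \eqn{g} is the B-spline
#' expansion with coefficients `xi`. The conditional mean of the Tweedie
#' response is \eqn{\mu_{ij} = e^{\eta_{ij}}}. To guard against overflow in
#' downstream density evaluations, \eqn{\eta} is clipped to
#' \eqn{|\eta| \le clip} with a warning.
#'
#' @param X covariate matrix (missing entries already imputed).
#' @param Z random-effect design matrix.
#' @param b n by r matrix of subject random effects.
#' @param id integer subject index per row.
#' @param B basis matrix from [build_basis()].
#' @param beta fixed-effect coefficient vector.
#' @param xi spline coefficient vector.
#' @param clip absolute bound on the linear predictor.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(X, Z, b, id, B, beta, xi, clip = 30) {
  eta <- drop(X %*% beta) + rowSums(Z * b[id, , drop = FALSE]) +
    drop(B %*% xi)
  if (any(abs(eta) > clip)) {
    warning("linear predictor clipped to +/-", clip)
    eta <- pmin(pmax(eta, -clip), clip)
  }
  eta
}

#' Complete-data log-likelihood of the augmented model
#'
#' The joint log-likelihood of the outcomes, their latent Poisson counts,
#' and the random effects:
#' \deqn{\ell = \sum_{ij} \log p(y_{ij}, u_{ij} \mid \mu_{ij}, \phi, p)
#'       + \sum_i \log N_r(b_i; 0, \Sigma),}
#' with the joint Tweedie density evaluated through the compound
#' parameterization, so the intractable marginal normalizing constant never
#' appears. Missing responses and covariates must be filled with their
#' current imputations; a latent count inconsistent with its outcome yields
#' `-Inf`.
#'
#' @param y outcome vector (imputations filled in).
#' @param u latent count vector.
#' @param eta linear predictor vector (see [linear_predictor()]).
#' @param phi dispersion.
#' @param p power parameter in (1, 2).
#' @param b n by r matrix of random effects.
#' @param Sigma r by r random-effect covariance.
#' @return Scalar log-likelihood.
#' @export
complete_loglik <- function(y, u, eta, phi, p, b, Sigma) {
  nat <- .tw_nat(exp(eta), phi, p)
  ll <- cpp_tw_joint_loglik(y, as.integer(u), nat$lambda, nat$shape, nat$scale)
  sum(ll) + .log_dmvnorm_rows(b, Sigma)
}

# sum of N_r(b_i; 0, Sigma) log densities over the rows of b
.log_dmvnorm_rows <- function(b, Sigma) {
  b <- as.matrix(b)
  Sigma <- as.matrix(Sigma)
  r <- ncol(Sigma)
  ch <- chol(Sigma)
  q <- rowSums((b %*% chol2inv(ch)) * b)
  sum(-0.5 * q) - nrow(b) * (sum(log(diag(ch))) + 0.5 * r * log(2 * pi))
}

# Independent transcription of the complete-data log-likelihood in its
# expanded form: the mu^{2-p} exponential-family term over all cells plus
# the positive-outcome correction terms. Used as a cross-check of the
# compound-representation path; the two must agree to numerical precision.
.complete_loglik_direct <- function(y, u, eta, phi, p, b, Sigma) {
  mu <- exp(eta)
  a <- (2 - p) / (p - 1)
  out <- -sum(mu^(2 - p)) / (phi * (2 - p))
  pos <- y > 0
  if (any(pos)) {
    yp <- y[pos]; up <- u[pos]; mp <- mu[pos]
    out <- out -
      sum(yp * mp^(1 - p) / (phi * (p - 1)) +
            lgamma(up * a) + lgamma(up + 1) + log(yp)) +
      sum(up * (a * log(yp / (p - 1)) - log(phi) / (p - 1) - log(2 - p)))
  }
  out + .log_dmvnorm_rows(b, Sigma)
}
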