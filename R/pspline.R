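#' B-spline configuration for the nonparametric time effect
#'
#' The smooth time effect \eqn{g(t) = \sum_{h=1}^H \xi_h B_h(t)} is built
#' from `num_basis` B-spline basis functions of the given degree. Knots are
#' placed either equidistantly over `domain` or at quantiles of the observed
#' times. Defaults (cubic basis, H = 20, equidistant knots) follow common
#' Bayesian P-spline practice.
#'
#' @param num_basis number of basis functions H (at least `degree + 1`).
#' @param degree polynomial degree of the basis (3 = cubic).
#' @param domain numeric length-2 interval on which the spline lives.
#' @param knot_rule `"equidistant"` or `"quantile"`.
#' @return An object of class `spline_config`.
#' @export
spline_config <- function(num_basis = 20, degree = 3, domain = c(0, 1),
                          knot_rule = c("equidistant", "quantile")) {
  knot_rule <- match.arg(knot_rule)
  stopifnot(length(domain) == 2, is.finite(domain), domain[1] < domain[2])
  if (num_basis < degree + 1)
    stop("'num_basis' must be at least degree + 1")
  structure(list(num_basis = as.integer(num_basis),
                 degree = as.integer(degree),
                 domain = as.numeric(domain), knot_rule = knot_rule),
            class = "spline_config")
}

.spline_knots <- function(config, times = NULL) {
  H <- config$num_basis; k <- config$degree + 1
  n_int <- H - k
  interior <- if (n_int <= 0) numeric(0)
  else if (config$knot_rule == "equidistant")
    seq(config$domain[1], config$domain[2], length.out = n_int + 2)[-c(1, n_int + 2)]
  else {
    if (is.null(times)) stop("quantile knot rule needs the observed times")
    as.numeric(quantile(times, probs = seq_len(n_int) / (n_int + 1)))
  }
  c(rep(config$domain[1], k), interior, rep(config$domain[2], k))
}

#' Evaluate the B-spline basis at a set of times
#'
#' Returns the design matrix whose rows are the H basis functions evaluated
#' at each time. Times outside the configured domain are clamped to the
#' boundary with a warning. Rows sum to one (partition of unity).
#'
#' @param times numeric vector of evaluation points.
#' @param config a [spline_config()].
#' @param knots optional full knot sequence (as stored in the `"knots"`
#'   attribute of a previously built basis) to guarantee an identical basis
#'   on a prediction grid.
#' @return A `length(times)` by H matrix with attribute `"knots"`.
#' @export
build_basis <- function(times, config, knots = NULL) {
  if (length(times) == 0) stop("'times' is empty")
  if (is.null(knots)) knots <- .spline_knots(config, times)
  lo <- config$domain[1]; hi <- config$domain[2]
  if (any(times < lo | times > hi)) {
    warning("times outside the spline domain were clamped to the boundary")
    times <- pmin(pmax(times, lo), hi)
  }
  B <- splines::splineDesign(knots, times, ord = config$degree + 1,
                             outer.ok = FALSE)
  stopifnot(ncol(B) == config$num_basis)
  attr(B, "knots") <- knots
  B
}

#' Locally adaptive first-order random-walk penalty matrix
#'
#' The P-spline prior on the coefficients is a first-order random walk,
#' \eqn{\xi_h = \xi_{h-1} + v_h} with \eqn{v_h \sim N(0, \tau_\xi^2/\delta_h)},
#' so the prior kernel is \eqn{\exp\{-\xi^T Q \xi / (2\tau_\xi^2)\}} with
#' \eqn{Q = D^T \mathrm{diag}(\delta_2, \dots, \delta_H) D} and D the
#' first-difference matrix. Q is symmetric positive semidefinite of rank
#' H - 1; its null space is the constant vector (the prior on the level of
#' the curve is flat).
#'
#' @param delta positive local smoothing weights \eqn{(\delta_2,\dots,\delta_H)},
#'   length H - 1.
#' @return The H by H penalty matrix.
#' @export
penalty_matrix <- function(delta) {
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("'delta' must be positive")
  H <- length(delta) + 1
  D <- diff(diag(H))                       # (H-1) x H first differences
  crossprod(D * sqrt(delta))               # D^T diag(delta) D
}

#' Log prior density of the spline coefficients
#'
#' Returns \eqn{-\xi^T Q(\delta)\, \xi / (2\tau_\xi^2)}, the random-walk
#' prior log-kernel up to an additive constant free of \eqn{\xi}. The prior
#' is partially improper: the first coefficient carries a flat prior.
#'
#' @param xi coefficient vector of length H.
#' @param tau2 positive global smoothing variance.
#' @param delta positive local weights of length H - 1.
#' @return Scalar log-kernel value (always \eqn{\le 0}).
#' @export
log_prior_xi <- function(xi, tau2, delta) {
  stopifnot(length(delta) == length(xi) - 1, tau2 > 0)
  -sum(delta * diff(xi)^2) / (2 * tau2)
}
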