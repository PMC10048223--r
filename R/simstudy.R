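#' Simulation-study designs for the replication engine
#'
#' Two longitudinal designs with n subjects and `n_i` visits each. The
#' complete data are generated as: \eqn{x_3 \sim N(0,1)},
#' \eqn{x_1 \mid x_3 \sim N(0.05 + 0.5 x_3,\ 0.25)},
#' \eqn{x_2 \mid x_1, x_3 \sim N(-0.9 + 0.05 x_1 + 0.9 x_3,\ 0.36)},
#' \eqn{b_i \sim N(0, 0.64)}, \eqn{t \sim U(0,1)}, and
#' \eqn{y \mid \cdot \sim Tw_{1.5}(e^\eta, 0.5)} with
#' \eqn{\eta = x_1 + x_2 - x_3 + b_i + \sin(2\pi t)} (no intercept).
#' The designs differ only in the missingness mechanism: `"sim1"` uses
#' variant A (response selection on the current and lagged response;
#' covariate selection on covariate values and preceding indicators),
#' `"sim2"` uses variant B (all selection logits involve the response).
#' True selection coefficients are
#' \eqn{\varphi_y = (-2.4, 0.1, 0.1)}, \eqn{\varphi_{x1} = (-2.5, 0.1)},
#' \eqn{\varphi_{x2} = (-1.9, 0.05, 0.05, 0.3)} for `"sim1"` and
#' \eqn{\varphi_y = (-2.2, 0.1, 0.1, 0.1)},
#' \eqn{\varphi_{x1} = (-2.5, 0.2, 0.1)},
#' \eqn{\varphi_{x2} = (-1.9, 0.05, 0.05, -0.3)} for `"sim2"`.
#'
#' @param design `"sim1"` or `"sim2"`.
#' @param n number of subjects.
#' @param n_i visits per subject.
#' @param baseline baseline convention for the response selection model
#'   (see [mechanism_spec()]).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(design = c("sim1", "sim2"), n = 150, n_i = 4,
                       baseline = c("observed", "lag_zero")) {
  design <- match.arg(design)
  baseline <- match.arg(baseline)
  mech <- if (design == "sim1")
    mechanism_spec("A", phi_y = c(-2.4, 0.1, 0.1),
                   phi_x = list(c(-2.5, 0.1), c(-1.9, 0.05, 0.05, 0.3)),
                   baseline = baseline)
  else
    mechanism_spec("B", phi_y = c(-2.2, 0.1, 0.1, 0.1),
                   phi_x = list(c(-2.5, 0.2, 0.1), c(-1.9, 0.05, 0.05, -0.3)),
                   baseline = baseline)
  structure(list(name = design, n = as.integer(n), n_i = as.integer(n_i),
                 beta = c(1, 1, -1), p = 1.5, phi = 0.5, Sigma = 0.64,
                 alpha = list(c(0.05, 0.5), c(-0.9, 0.05, 0.9)),
                 sigma2 = c(0.25, 0.36), mechanism = mech,
                 g_true = function(t) sin(2 * pi * t)),
            class = "sim_design")
}

#' True parameter values of a design, named like the sampler's draws
#'
#' @param design a [sim_design()].
#' @return Named numeric vector (22 parameters for `"sim1"`, 24 for
#'   `"sim2"`).
#' @export
sim_truth <- function(design) {
  mech <- design$mechanism
  c(setNames(design$beta, paste0("beta", seq_along(design$beta))),
    p = design$p, phi = design$phi, Sigma = design$Sigma,
    setNames(unlist(design$alpha),
             unlist(lapply(seq_along(design$alpha), function(k)
               paste0("alpha", k, seq_along(design$alpha[[k]]) - 1)))),
    setNames(mech$phi_y, paste0("phi_y", seq_along(mech$phi_y) - 1)),
    setNames(unlist(mech$phi_x),
             unlist(lapply(seq_along(mech$phi_x), function(k)
               paste0("phi_x", k, seq_along(mech$phi_x[[k]]) - 1)))),
    setNames(design$sigma2, paste0("sigma2_x", seq_along(design$sigma2))))
}

#' Generate one replication of a simulation design
#'
#' Draws the complete data, then the missingness indicators from the
#' design's selection mechanism, and returns the masked dataset. The
#' complete values and masks are kept as attributes for evaluation.
#'
#' @param design a [sim_design()].
#' @param seed RNG seed for this replication.
#' @return A [long_data()] object with attributes `y_full`, `X_full`,
#'   `b`, `indicators`, `design`.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n; n_i <- design$n_i; N <- n * n_i
  id <- rep(seq_len(n), each = n_i)
  visit <- rep(seq_len(n_i), n)
  x3 <- rnorm(N)
  x1 <- rnorm(N, design$alpha[[1]][1] + design$alpha[[1]][2] * x3,
              sqrt(design$sigma2[1]))
  x2 <- rnorm(N, design$alpha[[2]][1] + design$alpha[[2]][2] * x1 +
                design$alpha[[2]][3] * x3, sqrt(design$sigma2[2]))
  b <- rnorm(n, 0, sqrt(design$Sigma))
  tt <- runif(N)
  eta <- cbind(x1, x2, x3) %*% design$beta + b[id] + design$g_true(tt)
  yu <- rtweedie_cp(N, mu = exp(drop(eta)), phi = design$phi, p = design$p)
  ind <- generate_indicators(yu$y, cbind(x1, x2, x3), id, visit,
                             design$mechanism)
  y_obs <- yu$y; y_obs[ind$r_y] <- NA
  X_obs <- cbind(x1 = x1, x2 = x2, x3 = x3)
  X_full <- X_obs
  X_obs[, 1][ind$r_x[, 1]] <- NA
  X_obs[, 2][ind$r_x[, 2]] <- NA
  dat <- long_data(id = id, time = tt, y = y_obs, X = X_obs, m = 2)
  attr(dat, "y_full") <- yu$y
  attr(dat, "u_full") <- yu$u
  attr(dat, "X_full") <- X_full
  attr(dat, "b") <- b
  attr(dat, "indicators") <- ind
  attr(dat, "design") <- design$name
  dat
}

#' Mean missing proportions over replications
#'
#' Regenerates `reps` datasets and averages the per-replication missing
#' fractions of the response and each missing-prone covariate.
#'
#' @param design a [sim_design()].
#' @param reps number of replications.
#' @param seed base seed; replication r uses `seed + r`.
#' @return Named vector of mean missing proportions in percent
#'   (`x1`, ..., `y`).
#' @export
missing_rates <- function(design, reps = 50, seed = 1) {
  rates <- vapply(seq_len(reps), function(r) {
    d <- simulate_dataset(design, seed = seed + r)
    c(colMeans(d$r_x), mean(d$r_y))
  }, numeric(design$mechanism$m + 1))
  out <- 100 * rowMeans(rates)
  names(out) <- c(paste0("x", seq_len(design$mechanism$m)), "y")
  per_rep <- 100 * t(rates)
  colnames(per_rep) <- names(out)
  attr(out, "per_rep") <- per_rep
  out
}

#' Prior settings of the three informativeness scenarios
#'
#' Type I centres the normal priors of the regression blocks at the true
#' values with tight covariance 0.25 I (a good piece of prior
#' information); Type II centres them at twice the truth with covariance
#' 0.75 I (inaccurate); Type III is zero-centred with covariance 100 I
#' (noninformative). All types share rho0 = 8, R0 = 2 for the
#' random-effect variance, the nearly diffuse smoothing prior
#' (a_tau = 1, b_tau = 0.005, a_delta = b_delta = 0.5), and vague
#' inverse-gamma (0.01, 0.01) priors on the covariate-model variances.
#'
#' @param type `"I"`, `"II"` or `"III"`.
#' @param design a [sim_design()] supplying the true values and block
#'   dimensions.
#' @return A [prior_spec()].
#' @export
prior_from_type <- function(type = c("I", "II", "III"), design) {
  type <- match.arg(type)
  mech <- design$mechanism
  mult <- switch(type, I = 1, II = 2, III = 0)
  v <- switch(type, I = 0.25, II = 0.75, III = 100)
  prior_spec(beta_mean = mult * design$beta,
             beta_cov = diag(v, length(design$beta)),
             rho0 = 8, R0 = matrix(2),
             phi_y_mean = mult * mech$phi_y,
             phi_y_cov = diag(v, length(mech$phi_y)),
             phi_x_mean = lapply(mech$phi_x, function(x) mult * x),
             phi_x_cov = lapply(mech$phi_x, function(x) diag(v, length(x))),
             alpha_mean = lapply(design$alpha, function(a) mult * a),
             alpha_cov = lapply(design$alpha, function(a) diag(v, length(a))),
             a_sigma = 0.01, b_sigma = 0.01)
}

#' Bias / SD / RMS summaries of replication estimates
#'
#' Bias is the mean of the per-replication posterior means minus the
#' truth; SD is the standard deviation of the estimates across
#' replications; RMS is the root mean square of estimate minus truth.
#' The three satisfy \eqn{RMS^2 = Bias^2 + SD^2 (R-1)/R}.
#'
#' @param estimates replications by parameters matrix of posterior means.
#' @param truth named truth vector matching the columns.
#' @return A data frame of class `recovery_table` with columns
#'   `parameter`, `truth`, `bias`, `sd`, `rms`.
#' @export
recovery_table <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  stopifnot(ncol(estimates) == length(truth))
  err <- sweep(estimates, 2, truth)
  out <- data.frame(parameter = names(truth), truth = unname(truth),
                    bias = colMeans(err),
                    sd = apply(estimates, 2, sd),
                    rms = sqrt(colMeans(err^2)), row.names = NULL)
  class(out) <- c("recovery_table", "data.frame")
  attr(out, "estimates") <- estimates
  out
}

#' Run the replication study of a simulation design
#'
#' For each replication: generate a dataset, fit the full model with the
#' hybrid sampler (imputing missing responses, covariates, and latent
#' counts), and record the posterior means; then summarise bias, SD and
#' RMS per parameter. Replications whose chain fails are dropped with a
#' recorded count.
#'
#' @param design a [sim_design()].
#' @param prior_type `"I"`, `"II"` or `"III"` (see [prior_from_type()]).
#' @param reps number of replications.
#' @param iterations,burnin MCMC protocol per replication.
#' @param seed base seed; replication r uses `seed + r` for both data
#'   generation and the chain.
#' @param spline a [spline_config()].
#' @return A [recovery_table()] with attributes `estimates`, `failures`.
#' @export
run_replications <- function(design, prior_type = "I", reps = 10,
                             iterations = 2000, burnin = 2000, seed = 1,
                             spline = spline_config()) {
  priors <- prior_from_type(prior_type, design)
  truth <- sim_truth(design)
  est <- matrix(NA_real_, reps, length(truth),
                dimnames = list(NULL, names(truth)))
  failures <- 0L
  for (r in seq_len(reps)) {
    dat <- simulate_dataset(design, seed = seed + r)
    fit <- tryCatch(
      tw_plmm(dat, design$mechanism, priors = priors, spline = spline,
              control = mcmc_control(iterations = iterations,
                                     burnin = burnin, seed = seed + r)),
      error = function(e) {
        warning("replication ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) { failures <- failures + 1L; next }
    est[r, ] <- colMeans(fit$draws)[names(truth)]
  }
  ok <- stats::complete.cases(est)
  out <- recovery_table(est[ok, , drop = FALSE], truth)
  attr(out, "failures") <- failures
  out
}
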