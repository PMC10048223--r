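#' Nonignorable missingness mechanism specification
#'
#' Two logistic selection-model variants for a semicontinuous response and
#' the `m` missing-prone covariates:
#'
#' * **Variant A** — the response selection logit depends on the current
#'   and previous response,
#'   \eqn{\varphi_{y0} + \varphi_{y1} y_{ij} + \varphi_{y2} y_{i,j-1}};
#'   the logit for covariate k depends on covariates \eqn{x_1,\dots,x_k}
#'   and the preceding covariate missingness indicators
#'   \eqn{r_{x1},\dots,r_{x,k-1}}.
#' * **Variant B** — the response selection logit depends on the current
#'   response and the missing-prone covariates; the logit for covariate k
#'   depends on \eqn{x_1,\dots,x_k} and the response.
#'
#' Both are nonignorable: each logit involves quantities that may themselves
#' be missing, whose current imputations enter during estimation.
#'
#' The `baseline` option controls the response model at the first visit,
#' where the lagged response of variant A is undefined: `"observed"` (the
#' default) treats the baseline response as observed by design, so the
#' selection model applies from the second visit onward; `"lag_zero"`
#' applies the model at every visit with \eqn{y_{i,0} = 0}.
#'
#' @param variant `"A"` or `"B"`.
#' @param phi_y response selection coefficients: length 3 for variant A;
#'   length `m + 2` for variant B.
#' @param phi_x list of m covariate selection coefficient vectors; the k-th
#'   has length `2k` (variant A) or `k + 2` (variant B).
#' @param baseline `"observed"` or `"lag_zero"` (variant A response model
#'   at the first visit; also honoured by variant B for comparability of
#'   the two designs).
#' @return An object of class `mechanism_spec`.
#' @export
mechanism_spec <- function(variant = c("A", "B"), phi_y, phi_x,
                           baseline = c("observed", "lag_zero")) {
  variant <- match.arg(variant)
  baseline <- match.arg(baseline)
  stopifnot(is.list(phi_x))
  m <- length(phi_x)
  len_y <- if (variant == "A") 3L else m + 2L
  if (length(phi_y) != len_y)
    stop("variant ", variant, " needs length-", len_y, " 'phi_y'")
  for (k in seq_len(m)) {
    len_k <- if (variant == "A") 2L * k else k + 2L
    if (length(phi_x[[k]]) != len_k)
      stop("variant ", variant, " needs length-", len_k, " 'phi_x[[", k, "]]'")
  }
  structure(list(variant = variant, phi_y = as.numeric(phi_y),
                 phi_x = lapply(phi_x, as.numeric), m = m,
                 baseline = baseline),
            class = "mechanism_spec")
}

# previous-visit response within subject, 0 at the first visit
.lag_y <- function(y, id) {
  lag <- c(0, y[-length(y)])
  lag[c(TRUE, id[-1] != id[-length(id)])] <- 0
  lag
}

.bernoulli_ll <- function(r, v) plogis((2 * r - 1) * v, log.p = TRUE)

#' Selection-model logits
#'
#' `response_missing_logit()` returns the linear predictor of the response
#' missingness probability for each cell; `covariate_missing_logit()` the
#' same for the k-th missing-prone covariate. All arguments are vectors or
#' matrices over cells, with missing entries replaced by their current
#' imputations.
#'
#' @param y response values.
#' @param y_prev previous-visit response (variant A; 0 at baseline).
#' @param X_mis cell by m matrix of missing-prone covariate values
#'   (variant B response model; always used by the covariate models).
#' @param spec a [mechanism_spec()].
#' @return Vector of logits; the missingness probability is `plogis()` of it.
#' @export
response_missing_logit <- function(y, y_prev = NULL, X_mis = NULL, spec) {
  ph <- spec$phi_y
  if (spec$variant == "A") {
    if (is.null(y_prev)) stop("variant A needs 'y_prev'")
    ph[1] + ph[2] * y + ph[3] * y_prev
  } else {
    if (is.null(X_mis)) stop("variant B needs 'X_mis'")
    X_mis <- as.matrix(X_mis)
    stopifnot(ncol(X_mis) == spec$m)
    ph[1] + ph[2] * y + drop(X_mis %*% ph[-(1:2)])
  }
}

#' @param k index of the missing-prone covariate (1..m).
#' @param R_x cell by m matrix of covariate missingness indicators
#'   (variant A uses the first k - 1 columns).
#' @rdname response_missing_logit
#' @export
covariate_missing_logit <- function(k, X_mis, R_x = NULL, y = NULL, spec) {
  stopifnot(k >= 1, k <= spec$m)
  ph <- spec$phi_x[[k]]
  X_mis <- as.matrix(X_mis)
  v <- ph[1] + drop(X_mis[, seq_len(k), drop = FALSE] %*% ph[2:(k + 1)])
  if (spec$variant == "A") {
    if (k > 1) {
      if (is.null(R_x)) stop("variant A needs 'R_x' for k > 1")
      v <- v + drop(as.matrix(R_x)[, seq_len(k - 1), drop = FALSE] %*%
                      ph[(k + 2):(2 * k)])
    }
    v
  } else {
    if (is.null(y)) stop("variant B needs 'y'")
    v + ph[k + 2] * y
  }
}

#' Log-likelihood of the missingness indicators
#'
#' Sum of Bernoulli log-likelihoods of the response and covariate
#' missingness indicators under the selection models, evaluated at the
#' current (imputed) data values. Under the `"observed"` baseline
#' convention, first-visit cells do not contribute to the response part.
#'
#' @param data a [long_data()] object supplying the indicators and the
#'   visit structure.
#' @param y,X response vector and covariate matrix with imputations filled.
#' @param spec a [mechanism_spec()].
#' @return Scalar log-likelihood.
#' @export
missing_loglik <- function(data, y, X, spec) {
  X_mis <- X[, seq_len(spec$m), drop = FALSE]
  vy <- response_missing_logit(y, .lag_y(y, data$id), X_mis, spec)
  cells <- if (spec$baseline == "observed") data$visit > 1 else rep(TRUE, data$n_obs)
  out <- sum(.bernoulli_ll(data$r_y[cells], vy[cells]))
  for (k in seq_len(spec$m)) {
    vk <- covariate_missing_logit(k, X_mis, data$r_x, y, spec)
    out <- out + sum(.bernoulli_ll(data$r_x[, k], vk))
  }
  out
}

#' Sequential normal models for missing-prone continuous covariates
#'
#' The joint density of the m missing-prone covariates given the fully
#' observed ones factorizes into a sequence of one-dimensional conditionals,
#' each normal with a linear mean: the k-th conditional regresses
#' \eqn{x_k} on an intercept, its missing-prone predecessors
#' \eqn{x_1,\dots,x_{k-1}}, and the fully observed covariates.
#'
#' @param alpha list of m coefficient vectors; the k-th has length
#'   `k + q - m` where q is the total number of covariates.
#' @param sigma2 vector of m positive conditional variances.
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(alpha, sigma2) {
  stopifnot(is.list(alpha), length(sigma2) == length(alpha))
  if (any(sigma2 <= 0)) stop("'sigma2' must be positive")
  structure(list(alpha = lapply(alpha, as.numeric),
                 sigma2 = as.numeric(sigma2), m = length(alpha)),
            class = "covariate_model")
}

# regression design for the k-th sequential conditional
.covariate_design <- function(k, X, m) {
  q <- ncol(X)
  cbind(1, X[, seq_len(k - 1), drop = FALSE],
        X[, setdiff(seq_len(q), seq_len(m)), drop = FALSE])
}

#' @param X covariate matrix with imputations filled.
#' @param model a [covariate_model()].
#' @param m number of missing-prone covariates.
#' @return `covariate_logpdf()`: per-row total log-density of
#'   \eqn{(x_1,\dots,x_m)} given the observed tail.
#' @rdname covariate_model
#' @export
covariate_logpdf <- function(X, model, m = model$m) {
  out <- numeric(nrow(X))
  for (k in seq_len(m)) {
    mu_k <- drop(.covariate_design(k, X, m) %*% model$alpha[[k]])
    out <- out + dnorm(X[, k], mu_k, sqrt(model$sigma2[k]), log = TRUE)
  }
  out
}

#' @param X_obs matrix of the fully observed covariates (the columns after
#'   the first m).
#' @return `sample_covariates()`: an `nrow(X_obs)` by m matrix of draws.
#' @rdname covariate_model
#' @export
sample_covariates <- function(X_obs, model) {
  X_obs <- as.matrix(X_obs)
  m <- model$m
  X <- cbind(matrix(NA_real_, nrow(X_obs), m), X_obs)
  for (k in seq_len(m)) {
    mu_k <- drop(.covariate_design(k, X, m) %*% model$alpha[[k]])
    X[, k] <- rnorm(nrow(X), mu_k, sqrt(model$sigma2[k]))
  }
  X[, seq_len(m), drop = FALSE]
}

#' Draw missingness indicators from the selection models
#'
#' Given complete data, draws each cell's indicator from a Bernoulli with
#' the mechanism's logistic probability. Variant A draws the covariate
#' indicators sequentially, since the k-th logit involves the preceding
#' indicators. Under the `"observed"` baseline convention the first-visit
#' response is never missing.
#'
#' @param y complete response vector.
#' @param X complete covariate matrix.
#' @param id integer subject index per row (rows contiguous by subject).
#' @param visit within-subject visit number.
#' @param spec a [mechanism_spec()].
#' @return List with logical `r_y` (length cells) and `r_x` (cells by m).
#' @export
generate_indicators <- function(y, X, id, visit, spec) {
  n_obs <- length(y)
  X_mis <- as.matrix(X)[, seq_len(spec$m), drop = FALSE]
  r_x <- matrix(FALSE, n_obs, spec$m)
  for (k in seq_len(spec$m)) {
    vk <- covariate_missing_logit(k, X_mis, r_x, y, spec)
    r_x[, k] <- runif(n_obs) < plogis(vk)
  }
  vy <- response_missing_logit(y, .lag_y(y, id), X_mis, spec)
  r_y <- runif(n_obs) < plogis(vy)
  if (spec$baseline == "observed") r_y[visit == 1] <- FALSE
  list(r_y = r_y, r_x = r_x)
}
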