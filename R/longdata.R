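#' Long-format longitudinal data container
#'
#' Stores one row per subject-visit: a semicontinuous response `y` (NA where
#' missing), a fixed-effect covariate matrix `X` whose first `m` columns are
#' the missing-prone covariates (in their declared sequential-model order)
#' and whose remaining columns are fully observed, a fully observed
#' random-effect design `Z` (default: random intercept), and the fully
#' observed spline covariate `time`. Ragged visit counts are supported.
#' Observed responses below `1e-12` are coerced to exact zeros, since the
#' model places a point mass at zero.
#'
#' @param id subject identifiers (any atomic type), one per row.
#' @param time spline covariate (e.g. visit time), fully observed.
#' @param y nonnegative response with NA for missing entries.
#' @param X numeric covariate matrix; NA allowed only in the first `m`
#'   columns.
#' @param m number of missing-prone covariates (leading columns of `X`).
#' @param Z random-effect design matrix; default a column of ones.
#' @return An object of class `long_data`: a list with elements `id`
#'   (integer subject index 1..n), `subjects`, `visit` (within-subject visit
#'   number), `time`, `y`, `X`, `Z`, `m`, `r_y` and `r_x` (logical
#'   missingness indicators), `n`, `n_obs`.
#' @export
long_data <- function(id, time, y, X, m = 0, Z = NULL) {
  n_obs <- length(y)
  X <- as.matrix(X)
  if (is.null(Z)) Z <- matrix(1, n_obs, 1)
  Z <- as.matrix(Z)
  stopifnot(length(id) == n_obs, length(time) == n_obs,
            nrow(X) == n_obs, nrow(Z) == n_obs, m >= 0, m <= ncol(X))
  if (anyNA(time) || anyNA(Z)) stop("'time' and 'Z' must be fully observed")
  if (any(y < 0, na.rm = TRUE)) stop("responses must be nonnegative")
  if (m < ncol(X) && anyNA(X[, seq(m + 1, ncol(X)), drop = FALSE]))
    stop("NA found in a covariate declared fully observed")
  y[!is.na(y) & y < 1e-12] <- 0
  subjects <- unique(id)
  idx <- match(id, subjects)
  if (is.unsorted(idx)) stop("rows of the same subject must be contiguous")
  visit <- stats::ave(rep(1, n_obs), idx, FUN = seq_along)
  r_x <- is.na(X[, seq_len(m), drop = FALSE])
  structure(list(id = idx, subjects = subjects, visit = as.integer(visit),
                 time = as.numeric(time), y = as.numeric(y), X = X, Z = Z,
                 m = as.integer(m), r_y = is.na(y), r_x = r_x,
                 n = length(subjects), n_obs = n_obs),
            class = "long_data")
}

#' @export
print.long_data <- function(x, ...) {
  cat("Longitudinal semicontinuous data:", x$n, "subjects,", x$n_obs,
      "subject-visits\n")
  cat("  covariates:", ncol(x$X), "fixed (", x$m, "missing-prone ),",
      ncol(x$Z), "random-effect column(s)\n")
  cat(sprintf("  missing: y %.1f%%", 100 * mean(x$r_y)))
  if (x$m > 0)
    cat(",", paste(sprintf("x%d %.1f%%", seq_len(x$m),
                           100 * colMeans(x$r_x)), collapse = ", "))
  cat("\n")
  invisible(x)
}
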