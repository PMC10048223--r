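# Small in-code fixtures shared across test files.

# a tiny complete longitudinal dataset with known structure
tiny_data <- function(n = 6, n_i = 3, seed = 99, m = 2) {
  set.seed(seed)
  N <- n * n_i
  id <- rep(seq_len(n), each = n_i)
  x3 <- rnorm(N)
  x1 <- rnorm(N, 0.05 + 0.5 * x3, 0.5)
  x2 <- rnorm(N, -0.9 + 0.05 * x1 + 0.9 * x3, 0.6)
  tt <- runif(N)
  b <- rnorm(n, 0, 0.8)
  eta <- x1 + x2 - x3 + b[id] + sin(2 * pi * tt)
  yu <- rtweedie_cp(N, mu = exp(eta), phi = 0.5, p = 1.5)
  list(data = long_data(id, tt, yu$y, cbind(x1 = x1, x2 = x2, x3 = x3), m = m),
       u = yu$u, b = b, eta = eta)
}

# textbook Cox-de Boor recursion, independent of the splines package
bspline_cdb <- function(x, knots, i, ord) {
  if (ord == 1)
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  d1 <- knots[i + ord - 1] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * bspline_cdb(x, knots, i, ord - 1) else 0
  t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 * bspline_cdb(x, knots, i + 1, ord - 1) else 0
  t1 + t2
}

# a dataset carrying no information about beta (X identically zero) and none
# about the response-selection slopes (all outcomes zero)
flat_fit <- function(iterations, burnin, thin, seed) {
  n <- 6; n_i <- 2; N <- n * n_i
  dat <- long_data(id = rep(1:n, each = n_i), time = runif(N),
                   y = rep(0, N), X = matrix(0, N, 2), m = 0)
  mech <- mechanism_spec("A", c(-2, 0, 0), list(), baseline = "lag_zero")
  pr <- default_priors(q = 2, m = 0, r = 1, variant = "A")
  pr$beta_mean <- c(1, -1); pr$beta_cov <- diag(c(4, 9))
  tw_plmm(dat, mech, priors = pr,
          spline = spline_config(num_basis = 6, degree = 2),
          control = mcmc_control(iterations = iterations, burnin = burnin,
                                 thin = thin, seed = seed))
}
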