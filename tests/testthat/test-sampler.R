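# inverse-gamma CDF helper for conjugate-draw checks
pinvgamma <- function(x, shape, rate)
  pgamma(1 / x, shape, rate = rate, lower.tail = FALSE)

test_that("latent-count conditional draws match exhaustive enumeration", {
  lam <- 2; a <- 1.2; gam <- 0.3; y <- 0.9
  lw <- dpois(1:100, lam, log = TRUE) +
    dgamma(y, shape = (1:100) * a, scale = gam, log = TRUE)
  pr <- exp(lw - max(lw)); pr <- pr / sum(pr)
  n <- 3e4
  set.seed(41)
  u <- tweedieplmm:::cpp_draw_u(rep(y, n), rep(lam, n), a, rep(gam, n),
                                runif(n), 10000L)
  emp <- tabulate(u, 100) / n
  expect_lt(max(abs(emp - pr)), 0.01)
  # zero outcomes force a zero count
  expect_identical(tweedieplmm:::cpp_draw_u(0, 4, 1, 0.25, 0.5, 1000L), 0L)
  # small rate: conditional mode at one
  lw_small <- dpois(1:50, 0.1, log = TRUE) +
    dgamma(0.2, shape = (1:50) * a, scale = gam, log = TRUE)
  expect_equal(which.max(lw_small), 1)
  u2 <- tweedieplmm:::cpp_draw_u(rep(0.2, 5000), rep(0.1, 5000), a,
                                 rep(gam, 5000), runif(5000), 10000L)
  expect_equal(as.numeric(names(which.max(table(u2)))), 1)
})

test_that("conjugate smoothing-variance draw matches a grid posterior", {
  set.seed(51)
  H <- 8; a_tau <- 1; b_tau <- 0.005
  # constant coefficients: posterior is the prior with only the rank term
  xi0 <- rep(2, H); delta <- rgamma(H - 1, 2)
  d0 <- replicate(3000, tweedieplmm:::.draw_tau2(xi0, delta, a_tau, b_tau))
  ks0 <- ks.test(d0, pinvgamma, shape = a_tau + (H - 1) / 2, rate = b_tau)
  expect_gt(ks0$p.value, 0.01)

  # non-constant coefficients: check against brute-force grid integration
  xi <- rnorm(H)
  quad <- sum(delta * diff(xi)^2)
  shape <- a_tau + (H - 1) / 2; rate <- b_tau + quad / 2
  grid <- exp(seq(log(1e-4), log(50), length.out = 8000))
  logpost <- (-a_tau - 1) * log(grid) - b_tau / grid +   # IG prior kernel
    vapply(grid, function(t2)
      sum(dnorm(diff(xi), 0, sqrt(t2 / delta), log = TRUE)), numeric(1))
  f <- exp(logpost - max(logpost))
  w <- c(0, (f[-1] + f[-length(f)]) / 2 * diff(grid))    # trapezoid rule
  cdf_grid <- cumsum(w) / sum(w)
  cdf_closed <- pinvgamma(grid, shape, rate)
  expect_lt(max(abs(cdf_grid - cdf_closed)), 1e-3)
  d1 <- replicate(3000, tweedieplmm:::.draw_tau2(xi, delta, a_tau, b_tau))
  expect_gt(ks.test(d1, pinvgamma, shape = shape, rate = rate)$p.value, 0.01)
})

test_that("local weight draws follow their gamma full conditional", {
  set.seed(52)
  H <- 5; xi <- rnorm(H); tau2 <- 0.4
  d <- t(replicate(4000, tweedieplmm:::.draw_delta(xi, tau2, 0.5, 0.5)))
  for (h in 1:(H - 1)) {
    ks <- ks.test(d[, h], pgamma, shape = 1,
                  rate = 0.5 + diff(xi)[h]^2 / (2 * tau2))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("random-effect covariance draw matches a one-dimensional grid posterior", {
  set.seed(53)
  n <- 3; b <- matrix(c(0.9, -0.4, 0.3), n, 1)
  rho0 <- 8; R0 <- matrix(2)
  # grid posterior: IW_1(rho0, R0) prior x normal likelihood of known b
  grid <- exp(seq(log(0.005), log(30), length.out = 8000))
  logpost <- (-(rho0 + 2) / 2) * log(grid) - R0[1] / (2 * grid) +
    vapply(grid, function(s2) sum(dnorm(b, 0, sqrt(s2), log = TRUE)), numeric(1))
  f <- exp(logpost - max(logpost))
  w <- c(0, (f[-1] + f[-length(f)]) / 2 * diff(grid))    # trapezoid rule
  cdf_grid <- cumsum(w) / sum(w)
  # closed-form conjugacy: IG((rho0 + n)/2, (R0 + sum b^2)/2)
  cdf_closed <- pinvgamma(grid, (rho0 + n) / 2, (R0[1] + sum(b^2)) / 2)
  expect_lt(max(abs(cdf_grid - cdf_closed)), 1e-3)
  draws <- replicate(4000, tweedieplmm:::.draw_Sigma(b, rho0, R0)[1, 1])
  expect_gt(ks.test(draws, pinvgamma, shape = (rho0 + n) / 2,
                    rate = (R0[1] + sum(b^2)) / 2)$p.value, 0.01)
})

test_that("covariate-model draws match closed-form Bayesian linear regression", {
  set.seed(54)
  W <- cbind(1, rnorm(20)); v <- drop(W %*% c(0.5, -1)) + rnorm(20, 0, 0.4)
  sigma2 <- 0.16
  prior_mean <- c(0, 0); prior_prec <- diag(1 / 4, 2)
  P <- prior_prec + crossprod(W) / sigma2
  post_cov <- solve(P)
  post_mean <- drop(post_cov %*% (prior_prec %*% prior_mean +
                                    crossprod(W, v) / sigma2))
  d <- t(replicate(5000, tweedieplmm:::.draw_alpha(W, v, sigma2, prior_mean,
                                                   prior_prec)))
  expect_lt(max(abs(colMeans(d) - post_mean)),
            4 * max(sqrt(diag(post_cov) / 5000)))
  expect_lt(max(abs(cov(d) - post_cov)), 0.1 * max(diag(post_cov)))
  # variance draw follows its inverse-gamma conditional
  alpha <- c(0.5, -1)
  rss <- sum((v - drop(W %*% alpha))^2)
  s2 <- replicate(4000, tweedieplmm:::.draw_sigma2(W, v, alpha, 0.01, 0.01))
  expect_gt(ks.test(s2, pinvgamma, shape = 0.01 + 10, rate = 0.01 + rss / 2)$p.value,
            0.01)
})

test_that("with no information a block's chain reproduces its prior", {
  set.seed(61)
  fit <- flat_fit(iterations = 12000, burnin = 1500, thin = 20, seed = 611)
  # beta never enters the likelihood: posterior = N(prior mean, prior sd)
  ks <- function(v, s) suppressWarnings(ks.test(v, pnorm, 0, s)$p.value)
  expect_gt(suppressWarnings(ks.test(fit$draws[, "beta1"], pnorm, 1, 2)$p.value),
            0.01)
  expect_gt(suppressWarnings(ks.test(fit$draws[, "beta2"], pnorm, -1, 3)$p.value),
            0.01)
  # response-selection slopes multiply outcomes that are all zero
  expect_gt(ks(fit$draws[, "phi_y1"], 10), 0.01)
  expect_gt(ks(fit$draws[, "phi_y2"], 10), 0.01)
})

test_that("vanishing proposal steps drive every MH acceptance rate to one", {
  fix <- tiny_data(n = 8, n_i = 3, seed = 71)
  d <- fix$data
  # plant a few missing values
  y <- d$y; y[c(2, 5, 9)] <- NA
  X <- d$X; X[c(3, 7), 1] <- NA; X[c(4, 11), 2] <- NA
  dat <- long_data(rep(1:8, each = 3), d$time, y, X, m = 2)
  mech <- mechanism_spec("A", c(-1, 0.1, 0.1),
                         list(c(-1, 0.1), c(-1, 0.1, 0.1, 0.3)))
  tiny <- setNames(rep(1e-9, 10),
                   c("beta", "b", "p", "phi", "phiy", "phix1", "phix2",
                     "xmis1", "xmis2", "xi"))
  fit <- tw_plmm(dat, mech,
                 spline = spline_config(num_basis = 5, degree = 2),
                 control = mcmc_control(iterations = 40, burnin = 0,
                                        seed = 5, step_init = tiny))
  mh <- setdiff(names(fit$accept), "ymis")
  expect_true(all(fit$accept[mh] > 0.97))
})

test_that("ignorable-case imputation is exact model simulation; selection tilts it", {
  set.seed(81)
  n <- 40; n_i <- 4; N <- n * n_i
  id <- rep(1:n, each = n_i)
  x <- matrix(rnorm(N), N, 1)
  b <- rnorm(n, 0, 0.5)
  tt <- runif(N)
  yu <- rtweedie_cp(N, exp(0.5 * x[, 1] + b[id]), 0.5, 1.5)
  y <- yu$y
  y[runif(N) < 0.25] <- NA   # missing completely at random
  dat <- long_data(id, tt, y, x, m = 0)
  mech <- mechanism_spec("A", c(-1, 0, 0), list(), baseline = "lag_zero")
  pr <- default_priors(1, 0, 1, "A")
  # pin the selection slopes at zero: the acceptance ratio is identically one
  pr$phi_y_mean <- c(-1, 0, 0)
  pr$phi_y_cov <- diag(c(4, 1e-10, 1e-10))
  fit <- tw_plmm(dat, mech, priors = pr,
                 spline = spline_config(num_basis = 5, degree = 2),
                 control = mcmc_control(iterations = 600, burnin = 400, seed = 9))
  expect_gt(fit$accept["ymis"], 0.999)
  # pooled imputations against fresh compound Poisson draws at the chain's
  # own (mu, phi, p): same posterior mixture in the ignorable case
  rows <- seq(1, nrow(fit$ymis_draws), by = 5)
  imp <- as.vector(fit$ymis_draws[rows, ])
  mus <- as.vector(fit$ymis_mu[rows, ])
  phis <- rep(fit$draws[rows, "phi"], times = ncol(fit$ymis_mu))
  ps <- rep(fit$draws[rows, "p"], times = ncol(fit$ymis_mu))
  lam <- mus^(2 - ps) / (phis * (2 - ps))
  sh <- (2 - ps) / (ps - 1)
  sc <- phis * (ps - 1) * mus^(ps - 1)
  uu <- rpois(length(lam), lam)
  fresh <- ifelse(uu > 0, rgamma(length(lam), shape = uu * sh, scale = sc), 0)
  ks <- suppressWarnings(ks.test(imp[imp > 0], fresh[fresh > 0]))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(imp == 0) - mean(fresh == 0)), 0.05)

  # a positive selection slope on y makes imputations stochastically larger
  pr2 <- pr
  pr2$phi_y_mean <- c(-1, 1, 0)
  fit2 <- tw_plmm(dat, mech, priors = pr2,
                  spline = spline_config(num_basis = 5, degree = 2),
                  control = mcmc_control(iterations = 600, burnin = 400, seed = 9))
  expect_lt(fit2$accept["ymis"], 0.999)
  expect_gt(mean(fit2$ymis_draws), mean(fit$ymis_draws))
})

test_that("chains are reproducible and summaries average the draws", {
  fix <- tiny_data(n = 6, n_i = 3, seed = 91)
  d <- fix$data
  y <- d$y; y[c(2, 8)] <- NA
  dat <- long_data(rep(1:6, each = 3), d$time, y, d$X, m = 2)
  mech <- mechanism_spec("A", c(-1, 0.1, 0.1),
                         list(c(-1, 0.1), c(-1, 0.1, 0.1, 0.3)))
  ctl <- mcmc_control(iterations = 60, burnin = 30, seed = 77)
  f1 <- tw_plmm(dat, mech, spline = spline_config(num_basis = 5, degree = 2),
                control = ctl)
  f2 <- tw_plmm(dat, mech, spline = spline_config(num_basis = 5, degree = 2),
                control = ctl)
  expect_identical(f1$draws, f2$draws)
  s <- summary(f1)
  expect_equal(s$mean, unname(colMeans(f1$draws)))
  expect_equal(s$sd, unname(apply(f1$draws, 2, sd)))
  expect_true(all(s$sd >= 0))
})
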