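sim1_mech <- function(baseline = "observed")
  mechanism_spec("A", phi_y = c(-2.4, 0.1, 0.1),
                 phi_x = list(c(-2.5, 0.1), c(-1.9, 0.05, 0.05, 0.3)),
                 baseline = baseline)

sim2_mech <- function(baseline = "observed")
  mechanism_spec("B", phi_y = c(-2.2, 0.1, 0.1, 0.1),
                 phi_x = list(c(-2.5, 0.2, 0.1), c(-1.9, 0.05, 0.05, -0.3)),
                 baseline = baseline)

test_that("selection logits reproduce hand-computed probabilities", {
  mA <- sim1_mech()
  # response at y = y_prev = 0: logit is the intercept -2.4
  expect_equal(response_missing_logit(0, 0, spec = mA), -2.4)
  expect_equal(plogis(response_missing_logit(0, 0, spec = mA)),
               1 / (1 + exp(2.4)))
  expect_equal(response_missing_logit(2, 1, spec = mA), -2.4 + 0.2 + 0.1)
  # first covariate at x1 = 0: logistic(-2.5)
  expect_equal(plogis(covariate_missing_logit(1, matrix(c(0, 0), 1), spec = mA)),
               plogis(-2.5), tolerance = 1e-12)
  # second covariate includes the first indicator
  v <- covariate_missing_logit(2, matrix(c(1, 2), 1),
                               R_x = matrix(c(TRUE, FALSE), 1), spec = mA)
  expect_equal(v, -1.9 + 0.05 * 1 + 0.05 * 2 + 0.3)
  # variant B logits involve the response
  mB <- sim2_mech()
  expect_equal(response_missing_logit(1, X_mis = matrix(c(2, 3), 1), spec = mB),
               -2.2 + 0.1 * 1 + 0.1 * 2 + 0.1 * 3)
  expect_equal(covariate_missing_logit(1, matrix(c(2, 0), 1), y = 3, spec = mB),
               -2.5 + 0.2 * 2 + 0.1 * 3)
  # MCAR degenerate case: zero slopes make the probability constant
  m0 <- mechanism_spec("A", c(-1, 0, 0), list(c(-2, 0), c(-1, 0, 0, 0)))
  expect_equal(response_missing_logit(c(0, 5, 50), c(0, 1, 9), spec = m0),
               rep(-1, 3))
  # coefficient-length validation
  expect_error(mechanism_spec("A", c(-1, 0), list(c(-2, 0))), "length-3")
  expect_error(mechanism_spec("B", c(-1, 0, 0), list(c(-2, 0, 0), c(0, 0, 0, 0))),
               "length-4")
})

test_that("missingness log-likelihood agrees with a per-cell Bernoulli oracle", {
  set.seed(14)
  for (variant in c("A", "B")) {
    fix <- tiny_data(seed = 100 + match(variant, c("A", "B")))
    d <- fix$data
    mech <- if (variant == "A") sim1_mech("lag_zero") else sim2_mech("lag_zero")
    # plant some indicators
    d$r_y <- runif(d$n_obs) < 0.3
    d$r_x <- matrix(runif(2 * d$n_obs) < 0.25, d$n_obs, 2)
    got <- missing_loglik(d, d$y, d$X, mech)
    ref <- 0
    for (i in seq_len(d$n_obs)) {
      yprev <- if (d$visit[i] == 1) 0 else d$y[i - 1]
      vy <- if (variant == "A")
        mech$phi_y[1] + mech$phi_y[2] * d$y[i] + mech$phi_y[3] * yprev
      else
        mech$phi_y[1] + mech$phi_y[2] * d$y[i] +
          mech$phi_y[3] * d$X[i, 1] + mech$phi_y[4] * d$X[i, 2]
      py <- plogis(vy)
      ref <- ref + log(ifelse(d$r_y[i], py, 1 - py))
      for (k in 1:2) {
        ph <- mech$phi_x[[k]]
        vk <- ph[1] + sum(ph[2:(k + 1)] * d$X[i, 1:k]) +
          if (variant == "A") {
            if (k == 2) ph[4] * d$r_x[i, 1] else 0
          } else ph[k + 2] * d$y[i]
        pk <- plogis(vk)
        ref <- ref + log(ifelse(d$r_x[i, k], pk, 1 - pk))
      }
    }
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # single cell at logit zero contributes log(1/2)
  one <- long_data(id = 1, time = 0.5, y = NA, X = matrix(c(1, 1, 1), 1), m = 2)
  m0 <- mechanism_spec("A", c(0, 0, 0), list(c(0, 0), c(0, 0, 0, 0)),
                       baseline = "lag_zero")
  expect_equal(missing_loglik(one, 1, one$X, m0), 3 * log(0.5))
})

test_that("sequential covariate models match their stated conditionals", {
  mod <- covariate_model(alpha = list(c(0.05, 0.5), c(-0.9, 0.05, 0.9)),
                         sigma2 = c(0.25, 0.36))
  # x3 = 0: x1 ~ N(0.05, 0.25); then x1 = 0 gives x2 ~ N(-0.9, 0.36)
  X <- matrix(c(0, -0.9, 0), 1)
  expect_equal(covariate_logpdf(X, mod),
               dnorm(0, 0.05, 0.5, log = TRUE) +
                 dnorm(-0.9, -0.9, 0.6, log = TRUE))
  set.seed(18)
  X_obs <- matrix(rnorm(4000), ncol = 1)
  draws <- sample_covariates(X_obs, mod)
  expect_equal(mean(draws[, 1]), 0.05, tolerance = 0.05)
  expect_equal(var(draws[, 1]), 0.25 + 0.25 * 1, tolerance = 0.05)
  # average log-density matches the (negative) sum of Gaussian entropies
  lp <- covariate_logpdf(cbind(draws, X_obs), mod)
  entropy <- sum(0.5 * log(2 * pi * exp(1) * mod$sigma2))
  expect_equal(mean(-lp), entropy, tolerance = 4 * sd(lp) / sqrt(nrow(draws)))
  expect_error(covariate_model(list(c(0, 0)), sigma2 = -1), "positive")
})

test_that("indicator generation respects extremes and the law of large numbers", {
  set.seed(25)
  N <- 5000
  id <- rep(seq_len(N / 4), each = 4)
  visit <- rep(1:4, N / 4)
  y <- rexp(N); X <- cbind(rnorm(N), rnorm(N), rnorm(N))
  none <- mechanism_spec("A", c(-1000, 0.1, 0.1),
                         list(c(-1000, 0.1), c(-1000, 0, 0, 0.3)))
  ind <- generate_indicators(y, X, id, visit, none)
  expect_false(any(ind$r_y) || any(ind$r_x))
  all_y <- mechanism_spec("A", c(1000, 0.1, 0.1),
                          list(c(-1000, 0.1), c(-1000, 0, 0, 0.3)),
                          baseline = "lag_zero")
  expect_true(all(generate_indicators(y, X, id, visit, all_y)$r_y))

  mech <- sim1_mech("lag_zero")
  ind <- generate_indicators(y, X, id, visit, mech)
  vy <- response_missing_logit(y, tweedieplmm:::.lag_y(y, id),
                               X[, 1:2], mech)
  expect_equal(mean(ind$r_y), mean(plogis(vy)),
               tolerance = 4 * sqrt(0.1 / N))
  # baseline-observed convention: no missing response at the first visit
  ind_b <- generate_indicators(y, X, id, visit, sim1_mech("observed"))
  expect_false(any(ind_b$r_y[visit == 1]))
})

test_that("the second covariate's missingness reacts to the first indicator", {
  set.seed(33)
  N <- 40000
  id <- rep(seq_len(N / 4), each = 4); visit <- rep(1:4, N / 4)
  y <- rexp(N); X <- cbind(rnorm(N), rnorm(N), rnorm(N))
  dep <- mechanism_spec("A", c(-2.4, 0, 0),
                        list(c(-0.5, 0), c(-1.9, 0, 0, 2)))
  ind <- generate_indicators(y, X, id, visit, dep)
  r1 <- ind$r_x[, 1]
  rate_diff <- mean(ind$r_x[r1, 2]) - mean(ind$r_x[!r1, 2])
  expect_gt(rate_diff, 0.2)  # logistic(-1.9+2) - logistic(-1.9) ~ 0.39
  indep <- mechanism_spec("A", c(-2.4, 0, 0),
                          list(c(-0.5, 0), c(-1.9, 0, 0, 0)))
  ind0 <- generate_indicators(y, X, id, visit, indep)
  r1 <- ind0$r_x[, 1]
  expect_lt(abs(mean(ind0$r_x[r1, 2]) - mean(ind0$r_x[!r1, 2])), 0.02)
})
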