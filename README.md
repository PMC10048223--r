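# tweedieplmm

Bayesian Tweedie compound Poisson partial linear mixed models for
longitudinal semicontinuous data with nonignorable missing responses and
covariates.

## The problem

Longitudinal clinical scores (pain, disability) are often *semicontinuous*:
nonnegative, right-skewed, with a point mass at exactly zero. As follow-up
proceeds, both the outcome and covariates go missing, and the probability of
missingness can depend on the unobserved values themselves (missing not at
random). This package fits one joint Bayesian model for all three features,
for biostatisticians analysing cohort data of this shape and for
methodologists studying MNAR selection models.

## The model

Given a subject random effect, each outcome follows a Tweedie compound
Poisson distribution, Y<sub>ij</sub> | b<sub>i</sub> ~ Tw<sub>p</sub>(μ<sub>ij</sub>, φ) with
1 &lt; p &lt; 2, E(Y) = μ, Var(Y) = φμ<sup>p</sup>, and

  log μ<sub>ij</sub> = x<sub>ij</sub>ᵀβ + z<sub>ij</sub>ᵀb<sub>i</sub> + g(t<sub>ij</sub>),  b<sub>i</sub> ~ N<sub>r</sub>(0, Σ),

where g is a Bayesian P-spline (cubic B-splines, first-order random-walk
prior with locally adaptive weights). The Tweedie density's normalizing
constant is intractable on y &gt; 0, so inference augments each outcome with
its latent Poisson count U (Y is a Poisson-many sum of gammas) and works
with the tractable joint density of (Y, U).

Missingness of the response and of the leading ("missing-prone") covariates
is modelled by logistic selection models whose predictors include the
possibly missing values themselves — two variants are implemented (response
lag based, and response-in-every-logit) — together with sequential normal
models for the missing continuous covariates. Everything is estimated
jointly by an MH-within-Gibbs sampler that also imputes the missing values
and latent counts. See the methods vignette (`vignettes/methods.Rmd`) for
the full model, priors, and sampler details.

## Worked example

Simulate one dataset from the first study design (150 subjects, 4 visits,
variant-A missingness at its true coefficients) and fit it:

```r
library(tweedieplmm)

des <- sim_design("sim1")
dat <- simulate_dataset(des, seed = 42)
dat
#> Longitudinal semicontinuous data: 150 subjects, 600 subject-visits
#>   covariates: 3 fixed ( 2 missing-prone ), 1 random-effect column(s)
#>   missing: y 10.3%, x1 8.7%, x2 12.5%

fit <- tw_plmm(dat, des$mechanism, priors = prior_from_type("I", des),
               control = mcmc_control(iterations = 1000, burnin = 1000,
                                      seed = 7))
summary(fit)[c(1:6, 13, 16), ]
#>    parameter   mean    sd
#> 1      beta1  1.094 0.090
#> 2      beta2  0.879 0.078
#> 3      beta3 -0.908 0.085
#> 4          p  1.500 0.020
#> 5        phi  0.497 0.039
#> 6      Sigma  0.501 0.093
#> 13    phi_y1  0.075 0.067
#> 16   phi_x11  0.144 0.250
```

Posterior means sit near the generating values β = (1, 1, −1), p = 1.5,
φ = 0.5, Σ = 0.64; `phi_y1` and `phi_x11` are the selection slopes on the
(possibly unobserved) response and first covariate — their posteriors being
pulled toward the truths 0.1 is what joint MNAR modelling buys. The
posterior SD column quantifies per-parameter uncertainty from a single
dataset. The fitted smooth tracks the generating curve sin(2πt):

```r
spline_curve_estimate(fit, c(0.25, 0.50, 0.75))
#>      t   mean lower upper
#> 1 0.25  0.850  0.56  1.08
#> 2 0.50 -0.082 -0.50  0.32
#> 3 0.75 -1.153 -1.45 -0.88
```

(sin(2πt) at those points is 1, 0, −1 — each inside its 95% band.)

`run_replications()` wraps generate–fit–summarise into a replication study
and reports Bias / SD / RMS per parameter; `read_long_csv()` +
`data_schema()` ingest real long-format files, and `inst/cli/tweedieplmm.R`
exposes `simulate`, `fit` and `replicate` from the shell.

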