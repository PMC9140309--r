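# egug

Parametric survival modelling with the **exponentiated Gumbel-G (EGuG)
family** of lifetime distributions, and its three-shape-parameter special
case over the Nadarajah-Haghighi baseline (**EGuNH**). The package is for
statisticians and epidemiologists who fit flexible parametric models to
positive event data — waiting times, survival times, incidence counts —
and need the full toolkit around a custom family: distribution functions,
moments, quantile-based shape measures, actuarial risk measures,
maximum-likelihood inference, model adequacy statistics, and a Monte-Carlo
study of estimator quality.

## The model

For a baseline cdf Z(x; φ), the family cdf is

    F(x) = [ 1 − exp{ −(−log Z(x; φ))^(−1/σ) } ]^θ ,   θ, σ > 0,

obtained by passing the baseline through an exponentiated-Gumbel
transformer. Registered baselines: exponential, Weibull, Burr XII,
Nadarajah-Haghighi (NH), Rayleigh. With the NH baseline
Z = 1 − exp{1 − (1+λx)^α} this gives the EGuNH distribution, whose
quantile function is closed-form:

    Q(u) = ( [1 − log(1 − e^(−A))]^(1/α) − 1 ) / λ ,
    A    = [ −log(1 − u^(1/θ)) ]^(−σ),

so sampling (inversion), value at risk (VaR_q = Q(q)), expected shortfall
(ES_q = q⁻¹ ∫₀^q Q(u) du) and the Bowley/Moors/MacGillivray shape
measures are cheap and exact. Moments and inequality curves are computed
by adaptive quadrature. Fitting is multi-start quasi-Newton maximum
likelihood on log-parameters with an analytic score for EGuNH and
observed-information standard errors.

## Worked example

```r
library(egug)

# closed-form quartiles at (theta, sigma, alpha) = (2.1, 0.29, 1.5)
qegunh(c(0.25, 0.5, 0.75), theta = 2.1, sigma = 0.29, alpha = 1.5)
#> [1] 0.2552756 0.3101802 0.3607822      # prints as 0.255 / 0.310 / 0.361

# mean by quadrature at (2.1, 0.1, 1.5)
egunh_moment(1, 2.1, 0.1, 1.5)
#> [1] 0.2919823

# bundled earthquake waiting-time data (62 gaps in days)
d1 <- egug_dataset("D1")
round(descriptives(d1), 2)
#>        n     mean       sd      min      max skewness kurtosis
#>    62.00   437.21   399.93     9.00  1901.00     1.50     2.52

fit <- egug_fit(d1$values, "egunh")
fit
#> Maximum-likelihood fit: egunh
#>       estimate     se
#> theta   0.7155 0.4403
#> sigma   0.1151 0.0521
#> alpha   0.0594 0.0042
#> log-likelihood: -438.4139   n = 62   converged: TRUE

compare_models(d1$values, c("egunh", "nh", "exponential"))
#>         model neg_loglik aic bic a_star w_star d_star p_value rank_aic
#> 1 exponential        439 880 882  0.371 0.0539 0.0745   0.882        1
#> 2          nh        439 881 886  0.302 0.0357 0.0631   0.966        2
#> 3       egunh        438 883 889  0.306 0.0368 0.0634   0.965        3

# risk profile of a fitted loss distribution
egunh_risk_profile(6.5, 0.33, 1.35, levels = c(0.55, 0.75, 0.95))
#>      q   var    es
#> 1 0.55 0.445 0.386
#> 2 0.75 0.482 0.407
#> 3 0.95 0.548 0.428
```

Reading the output: the quartiles and the mean come straight from the
closed forms above; the D1 summary reproduces the data's published
descriptive statistics; the fit table gives the MLEs with
observed-information standard errors. On D1 all three models describe the
data adequately (high KS p-values) and AIC prefers the most parsimonious
one — the EGuNH fit attains the highest likelihood but not enough to pay
its parameter penalty on these 62 observations. The risk table pairs each
level q with its value at risk (the q-quantile) and expected shortfall
(the average quantile below q); ES is always below VaR.

A thin command-line interface wraps the same functions
(`inst/cli/egug`): subcommands `eval`, `fit`, `compare`, `simulate`,
`risk`, `data`.

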