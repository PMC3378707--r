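# censmix

Finite mixtures of linear mixed-effects models for **left-censored
longitudinal data** — model-based clustering of trajectories measured with
a lower limit of detection, such as repeated log10 viral-load measurements
in treatment studies.

## The model

Each individual $i$ with $n_i$ measurement occasions belongs to one of $G$
latent components with probabilities $\pi_1,\dots,\pi_G$. Within component
$g$,

$$Y_i = X_i \alpha_g + Z_i \beta_i + e_i, \qquad
\beta_i \sim N(0, \Psi_g), \quad e_i \sim N(0, \sigma^2_g I_{n_i}),$$

where $X_i$ is an intercept-plus-B-spline basis in time (so each
component's mean trajectory is a free smooth curve) and $Z_i$ carries a
random intercept. The response is observed as a pair $(q_{ij}, c_{ij})$:
when $c_{ij}=1$ the value is left-censored and $q_{ij}$ records the
detection limit, i.e. $y_{ij} \le q_{ij}$.

Estimation is maximum likelihood by an EM algorithm in which **both steps
are in closed form**. The E-step computes posterior memberships and the
conditional moments of censored responses and random effects using exact
Tallis-type formulas for the mean and covariance of a truncated
multivariate normal; only the multivariate normal distribution function is
evaluated numerically (deterministic quadrature). Model selection over the
number of components, spline flexibility and variance constraints uses the
BIC/AIC; standard errors come from the empirical information matrix built
from analytic per-individual scores; a parametric-bootstrap harness with
optimal component matching and the adjusted Rand index quantifies
estimation and clustering stability.

## A worked example

Simulate the package's reference two-group design (N = 120 individuals,
8 occasions, ~20% of observations below the detection limit), fit a
two-component model, and look at the results:

```r
library(censmix)

sim <- censmix_simulate(example_design(N = 120), seed = 42)
mean(sim$data$cens)
#> [1] 0.2

fit <- censmix_fit(sim$data, G = 2, df = 2,
                   control = censmix_control(n_starts = 2, seed = 1))
glance(fit)
#> # A tibble: 1 x 8
#>   logLik   AIC   BIC     k     N  nobs niter converged
#>    <dbl> <dbl> <dbl> <int> <int> <int> <int> <lgl>
#> 1  -654.  1330.  1361.    11   120   960    51 TRUE

tidy(fit)
#> # A tibble: 11 x 4
#>    block  component term        estimate
#>    <chr>      <int> <chr>          <dbl>
#>  1 pi             1 pi1            0.533
#>  2 alpha          1 (Intercept)    5.00
#>  3 alpha          1 bs1           -4.78
#>  4 alpha          1 bs2           -3.07
#>  5 alpha          2 (Intercept)    4.92
#>  6 alpha          2 bs1           -2.45
#>  7 alpha          2 bs2            0.552
#>  8 sigma2         1 sigma2_1       0.164
#>  9 sigma2         2 sigma2_2       0.180
#> 10 psi            1 psi_1          0.117
#> 11 psi            2 psi_2          0.142
```

Component 1 (weight 0.53) declines steeply and stays low — dipping under
the limit, which is why censoring-aware fitting matters — while component 2
declines and rebounds. The recovered weights, curves and variances match
the generating design (weights 0.55/0.45, variances 0.16). The
maximum-a-posteriori clustering recovers the true grouping exactly here:

```r
ari <- adjusted_rand(augment(fit)$.component, sim$truth$assignment)
ari
#> [1] 1
```

`autoplot(fit, band = TRUE)` draws the trajectories coloured by component
with fitted means and 95% pointwise bands; `censmix_select()` /
`censmix_two_stage()` fit the model grid and rank it by BIC;
`censmix_se()` and `censmix_band()` give standard errors and confidence
bands; `censmix_bootstrap()` runs the parametric bootstrap.

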