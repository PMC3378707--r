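---
title: "Finite mixtures of linear mixed models for left-censored longitudinal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite mixtures of linear mixed models for left-censored longitudinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal biomarker measurements — the motivating case is repeated
viral-load assays on log10 scale — often combine three features that defeat
the ordinary linear mixed model:

1. **Latent groups.** Patients may follow qualitatively different
   trajectories (e.g. sustained decline versus decline-and-rebound), and the
   grouping is not known in advance.
2. **Between-individual heterogeneity** within a group, naturally modelled
   by a random intercept.
3. **A lower limit of detection.** The assay cannot quantify low values;
   observations at or below the limit are reported *as the limit*, i.e. the
   response is left-censored.

`censmix` fits finite mixtures of Gaussian linear mixed models to such data.
Each individual $i$ belongs to one latent component $g \in \{1,\dots,G\}$
with probability $\pi_g$; within component $g$,

$$Y_i = X_i\alpha_g + Z_i\beta_i + e_i, \qquad
  \beta_i \sim N(0, \Psi_g), \quad e_i \sim N(0, \sigma^2_g I),$$

so that marginally $Y_i \mid g \sim N(X_i\alpha_g,\; V_{ig})$ with
$V_{ig} = Z_i\Psi_g Z_i^\top + \sigma^2_g I$. Membership is constant across
an individual's repeated measures: the mixture captures heterogeneity
*between* individuals. The fixed-effects design $X_i$ is an intercept plus a
B-spline basis in time, so the shape of each component's mean trajectory is
learnt from the data rather than assumed (e.g. no biexponential-decay
assumption). The observed data per occasion are a pair $(q_{ij}, c_{ij})$:
the recorded value and a censoring flag, with $c_{ij} = 1$ meaning
$y_{ij} \le q_{ij}$ (the recorded value is the detection limit).

## Estimation: EM with closed-form truncated-normal moments

Three kinds of information are missing: the component memberships, the
random effects, and the true values of the censored responses. The EM
algorithm handles all three at once. The E-step needs, per individual and
component,

* posterior membership probabilities
  $\tau_{ig} \propto \pi_g L_{ig}$, where $L_{ig}$ is the observed-data
  component likelihood — the Gaussian density of the uncensored coordinates
  times the conditional multivariate-normal probability that the censored
  block lies below its limits;
* the conditional mean and covariance of the censored block given the
  observed coordinates and the censoring event. Conditioning a Gaussian on
  observed coordinates is the standard formula, and the subsequent
  restriction to the rectangle $\{y_C \le q_C\}$ is a *truncated*
  multivariate normal whose first two moments have closed forms
  (Tallis-type): they require normal distribution functions of dimensions
  $d$, $d-1$ and $d-2$ only;
* the conditional moments of the random effects, propagated from the
  response moments through the linear identities
  $E[\beta \mid \cdot] = \Psi Z^\top V^{-1}(\hat y - \mu)$,
  $\mathrm{Cov}[\beta \mid \cdot] = \Psi - \Psi Z^\top V^{-1} Z \Psi
   + W^\top \Omega W$ with $W = V^{-1} Z \Psi$, and
  $\mathrm{Cov}[Y, \beta \mid \cdot] = \Omega W$.

The M-step is in closed form: $\pi_g$ averages the responsibilities;
$\alpha_g$ is a responsibility-weighted least-squares fit of
$\hat y_{ig} - Z_i \hat\beta_{ig}$ on $X_i$; $\Psi_g$ averages
$\hat\beta\hat\beta^\top + \mathrm{Cov}[\beta]$; and $\sigma^2_g$ uses the
expected residual sum of squares
$\lVert\hat y - X\alpha - Z\hat\beta\rVert^2 + \mathrm{tr}\,\Omega
 + \mathrm{tr}(Z\,\mathrm{Cov}[\beta]Z^\top)
 - 2\,\mathrm{tr}(\mathrm{Cov}[Y,\beta]Z^\top)$,
evaluated at the updated $\alpha_g$. Because the $\alpha$ update does not
involve $\sigma^2$, updating $\sigma^2$ at the new $\alpha$ is still an
exact joint maximiser, and the observed log-likelihood ascends at every
cycle — a property the test suite asserts directly on the iteration trace
rather than taking on faith. Under the optional equality constraints
(`equal_sigma`, `equal_psi`) the corresponding numerators and denominators
pool across components before normalising.

Convergence is declared when the relative change of the observed
log-likelihood falls below `tol` (default $10^{-6}$). Because EM only finds
local maxima, `n_starts` chains (default 5) are run from random hard
partitions of the individuals and the best final log-likelihood wins.

### Initialisation

Each chain partitions individuals uniformly into $G$ groups (redrawn until
every group has at least two members), imputes censored values at their
limits, sets random effects to zero, and runs one M-step on the hard
assignments. A literal zero-random-effects start would make $\Psi = 0$ an
absorbing state of the EM map (the E-step then keeps every
$\hat\beta = 0$), so the random-intercept variance is instead seeded from
the between-individual variance of mean residuals within each starting
group, floored at $0.1\,\hat\sigma^2$. Warm starts from a previous fit's
posterior probabilities are supported (`init_tau`), and the two-stage
selection uses them.

## Numerical design

**Normal probabilities.** The exported general-covariance routines
(`mvn_cdf()`, `tmvn_moments()`, `cond_trunc_moments()`) use exact
closed-form code in dimensions one and two — `pnorm` and a deterministic
Gauss–Legendre bivariate algorithm of the Drezner–Wesolowsky/Genz type
(absolute accuracy about $10^{-15}$, cross-checked against `mvtnorm` in the
tests) — the deterministic trivariate TVPACK routine of
`mvtnorm::pmvnorm()` at $d = 3$, and Genz–Bretz quasi-Monte-Carlo under a
fixed internal seed above that (the caller's RNG state is saved and
restored). Grid quadratures were rejected for $d \ge 3$ after they showed
relative errors near $1\%$ on strongly correlated problems; the QMC error
at the settings used is below $10^{-8}$ and every path is reproducible
bit-for-bit.

**Compound symmetry.** With a random intercept — the only random-effects
structure in the model grid — every $V_{ig}$ is compound-symmetric,
$\sigma^2 I + \psi J$. That family is closed under both Gaussian
conditioning and the Tallis recursion: conditioning on any coordinate keeps
compound symmetry with $\psi' = \psi\sigma^2/(\sigma^2 + \psi)$ and an
equal mean shift. The rectangle probability of a compound-symmetric
Gaussian is a one-dimensional integral over the shared factor, which the
EM hot path evaluates with a fixed 48-point Gauss–Hermite rule (exact
`pnorm`/bivariate shortcuts in dimensions one and two). The E-step
therefore needs no general MVN CDF at all; agreement between this
specialised path and the general-covariance routines is itself a test
(absolute agreement ~$10^{-6}$, limited by the general path's QMC
precision — the Gauss–Hermite rule is converged well below that). The
compound-symmetry kernel is compiled (Rcpp), with a line-for-line R
reference implementation kept in the package and asserted to agree to
machine precision; together these make the replicate studies below
affordable on one CPU.

**Floors and repairs.** Rectangle probabilities below $10^{-300}$ are
clamped before taking logs; a truncation-region mass below $10^{-12}$
triggers a fallback that imputes the censored values at their limits; a
non-PSD $\Psi$ update is eigenvalue-clipped at zero; a component whose
total responsibility falls below $10^{-6} N$ aborts its chain. All four
events are counted in an internal event log.

## Splines

The mean-trajectory basis is an explicit intercept plus `df` B-spline
columns (degree $\min(3, \mathrm{df})$, so flexibility beyond cubic comes
from knots). Interior knots sit at equally spaced *quantiles* of the
observed times rather than equally spaced times: measurement schedules in
treatment studies are heavily front-loaded, and quantile placement puts
flexibility where the data are. Boundary knots sit at the observed time
range, and evaluation outside it is an error by design — extrapolating a
free-knot spline silently is how nonsense trajectories get published. The
spline block omits the basis function that would be collinear with the
intercept; the underlying full basis satisfies the partition of unity,
which the tests assert.

## Model selection and inference

The grid crosses $G$ (1–5), `df` (1–5), random intercept presence, and the
two variance constraints; each cell gets the shared control and a seed
derived from the master seed and the cell index. Models are ranked by BIC
(recommended for choosing $G$) and AIC; non-converged cells are excluded
from the winners. In the BIC penalty $k\log n$, $n$ is the **number of
individuals**, not observations: individuals are the independent,
exchangeable units of the mixture. The alternative (total observations) is
recoverable from the reported table. The two-stage procedure first picks
$(G, \mathrm{df})$ by BIC among unrestricted-variance models, then compares
the four constraint variants at that $(G, \mathrm{df})$, warm-starting each
constrained EM from the stage-one posteriors.

Standard errors come from the empirical information matrix — the sum of
outer products of per-individual score vectors, avoiding second
derivatives. The scores are analytic, via Fisher's identity: the gradient
of the censored observed-data log-likelihood equals the conditional
expectation of the complete-data Gaussian gradient, which reuses the E-step
moments. Component weights are parameterised on the $(G-1)$-dimensional
free chart so the information is over an unconstrained parameter; equality
constraints collapse the corresponding score blocks by summation. A central
finite-difference oracle gates the analytic scores in the tests (relative
agreement $10^{-3}$ on censored problems). Pointwise confidence bands for a
component mean use $b(t)^\top \widehat{\mathrm{Cov}}(\alpha_g)\, b(t)$ with
the $\alpha_g$ block of the inverse information.

## The simulation harness

`censmix_simulate()` draws from the exact generative model: multinomial
component, Gaussian random intercept, Gaussian residuals, then left
censoring at the design's limit (`cens = 1`, value recorded at the limit).
The latent truth is returned out-of-band and never enters the fitted data.
`example_design()` is the reference study condition used throughout the
tests: $N$ individuals on the front-loaded 8-occasion schedule
$(0, 1, 2, 4, 8, 12, 20, 28)$, two components with weights $(0.55, 0.45)$ —
one declining curve that ends below the limit, one decline-and-rebound
curve — random-intercept and residual variances $0.16$ (SD $0.4$, log10
response units), and detection limit $2.53$, chosen analytically (via
`expected_censoring()`) so that 20% of observations are censored in
expectation. These values were fixed once, from the design of the study the
package emulates (well-separated trajectory groups, moderate censoring),
not tuned to test outcomes.

`censmix_bootstrap()` wraps the replicate loop: simulate, refit (optionally
across a grid of $G$), match estimated to generating components by optimal
assignment over the confusion matrix (exhaustive over permutations,
$G \le 5$; ties break lexicographically), and score the
maximum-a-posteriori clustering with the Hubert–Arabie adjusted Rand index.
Two single-cluster partitions are defined to agree perfectly (ARI 1), which
keeps the degenerate $G = 1$ path well-defined.

What the generator deliberately does *not* emulate: informative dropout,
assay-specific heteroscedasticity, non-Gaussian (e.g. $t$) residuals,
per-individual measurement schedules, or covariate effects on membership.
Passing tests on these simulations therefore demonstrate correctness of
the estimation machinery under the model's own assumptions, not robustness
to their violation.

## Problem sizes used in the checks

The replicate studies in the tests and in `scripts/acceptance.R` use sizes
chosen as sensible desk-scale versions of the emulated study: recovery and
BIC selection at $N = 200$ (20 bootstrap replicates over $G \in 1..3$),
censoring-awareness and band coverage at $N = 100$ (50 and 50 replicates in
the tests; 20 each in the acceptance script), EM chains with 2 random
starts and iteration caps of 200–300 for replicate fits. Single-fit checks
against classical references (ML mixed model, mixture-of-regressions EM)
use tight tolerances ($10^{-10}$) and generous iteration caps instead.

## Known limitations

* Only left censoring, only random intercepts, shared covariates and
  spline flexibility across components; the likelihood machinery
  (`tmvn_moments`) is structured for general rectangles and covariances,
  but the model surface does not expose them.
* EM convergence is slow near weakly separated components; the iteration
  caps used in replicate studies can leave such fits flagged
  non-converged, and selection then ignores them.
* The empirical information is an asymptotic device: with few individuals
  per component its inverse can be unstable (the pseudo-inverse fallback
  flags affected coordinates).
* Likelihood-ratio testing for the number of components is deliberately
  absent — the regularity conditions fail; use the BIC.
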