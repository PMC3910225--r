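---
title: "Modelling perceived-exertion trajectories: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceived-exertion trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exertraj)
```

## The problem

During a graded maximal cycle-ergometer test, a child reports a Borg CR10
rating of perceived leg exertion (0 = nothing at all, 10 = maximal) at every
1-minute work increment.  Work is normalized to the fraction of the
individual maximal work capacity (Wmax), so each subject contributes a short
trajectory of 6–12 ratings on work fractions $x \in (0, 1]$ ending at
$x = 1$.  Children differ strikingly in how these trajectories look: some
rise steeply from the first increment, some rise as a power function, and
many stay flat for a while — a *delay* — before ratings start climbing.
`exertraj` provides the models, estimation machinery and diagnostics to
describe these trajectories per subject, pooled across subjects, and as
shape-based clusters, together with a synthetic-cohort generator so every
method can be validated against known ground truth.

## Individual models

For subject $i$ with ratings $y_{ij}$ at work fractions $x_{ij}$,
$j = 1, \dots, n_i$, four families are available, all with
$\varepsilon_{ij} \sim N(0, \sigma_i^2)$:

* **P** (power): $y_{ij} = a_i + b_{2i}\, x_{ij}^{d_i}$ — the classic
  Stevens psychophysical stimulus–response form;
* **D** (delay): $y_{ij} = a_i + b_{1i}\, (x_{ij} - c_i \vee 0)$ — flat at
  the intercept until the changepoint $c_i$, linear afterwards;
* **PD** (power-delay): $y_{ij} = a_i + b_{2i}\, (x_{ij} - c_i \vee 0)^{d_i}$;
* **QD** (quadratic-delay):
  $y_{ij} = a_i + b_{1i}(x_{ij} - c_i \vee 0) + b_{2i}(x_{ij} - c_i \vee 0)^2$.

The delayed term $(x - c \vee 0)^d$ is defined as exactly **0 whenever
$x \le c$**, for every $d \ge 0$.  This pins down the $0^0$ corner at
$d = 0$ and preserves the intended "flat before the delay" semantics; for
$d > 0$ the curves are continuous at the changepoint.

The number of estimated coefficients is $k = 3, 3, 4, 4$ for P, D, PD, QD.
$\sigma^2$ is profiled out at its maximum-likelihood value
$\hat\sigma^2 = \mathrm{SSE}/n$ and is *not* counted in $k$.

### Estimation

Each family is **linear in $(a, b_1, b_2)$ once $(c, d)$ are fixed**, so
`fit_individual()` profiles the linear coefficients out exactly and runs a
box-constrained quasi-Newton search (`optim`, L-BFGS-B) only over the
nonlinear parameters.  Constraints:

* delay: $c \in [\min_j x_{ij} + \texttt{margin},\ \max_j x_{ij}]$ with
  margin $10^{-3}$ — the scientifically motivated constraint is the strict
  $c > \min_j x_{ij}$ (a delay below the first observation is
  unidentified), and optimizers need a closed box;
* exponent: $d \in [0, 10]$.  No upper bound is scientifically given;
  10 is far above any plausible psychophysical exponent and keeps the
  multistart stable.

The SSE surface is multimodal in $c$ (every gap between adjacent $x$ values
is a potential local optimum), so the search is **multistart**: 8 starts
over the $c$ box $\times$ 5 over the $d$ box, plus $d = 1$ and $d = 2$
starts that make nested-model solutions reachable.  Ties within the SSE
tolerance are broken toward smaller $c$, then smaller $d$, which makes
results reproducible when the profile is flat.

`grid_oracle_fit()` is an intentionally independent second route: an
exhaustive grid over $(c, d)$ with a closed-form least-squares solve at
every node.  It exists so the optimizer can be checked against brute force
(the test suite requires agreement on at least 95% of random subjects) and
plays no part in the primary fitting path.

### Model selection

`compute_criteria()` reports RMSE $= \sqrt{\mathrm{SSE}/n}$ and, with
$\log L$ the profile Gaussian log-likelihood,

$$\mathrm{AIC} = 2k - 2\log L, \qquad
  \mathrm{AICc} = \mathrm{AIC} + \frac{2k(k+1)}{n - k - 1}, \qquad
  \mathrm{BIC} = k \log n - 2\log L.$$

AICc is undefined (flagged `NA`) when $n \le k + 1$; a zero SSE sets a
degenerate-fit flag and an $+\infty$ log-likelihood sentinel rather than an
error.  We use the standard AIC/BIC definitions; the AICc correction term is
the classic small-sample penalty.  With 6–12 points per subject and
$k \in \{3, 4\}$, AICc penalizes the 4-coefficient families heavily — this
is intentional and mirrors how such sparse trajectories should be compared.

### The RMSE-difference diagnostic

`rmse_difference_analysis()` plots, per subject, the difference in RMSE
between two families against the estimated delay, overlaid with a loess
smoother (span 0.75, degree 1).  It answers whether the advantage of a
delay- or curvature-bearing family depends on how long the subject's delay
is.  Subjects whose ratings take fewer than three distinct values are
excluded: two rating levels cannot discriminate curvature from a step.  The
delay on the x-axis is taken from the QD fit by default (configurable); the
choice is immaterial for the qualitative pattern because delay estimates
across delay families track each other closely.

## Mixed-effects models

Pooling subjects, four Bayesian nonlinear mixed-effects variants are
available: MQD and MPD share one common delay $c$ across subjects, MQDV and
MPDV let the delay vary as $c_i = c + \gamma_i$ with
$\gamma_i \sim N(0, \nu^2)$ and the box constraint
$c_i \in [\min_j x_{ij}, \max_j x_{ij}]$.  All have a subject random
intercept $u_i \sim N(0, \tau^2)$ and residual $\varepsilon \sim
N(0, \sigma^2)$.

Priors are dispersed conjugate choices: $N(0, 10^3)$ for $a, b_1, b_2$;
$\mathrm{IG}(0.01, 0.01)$ for $\sigma^2, \tau^2, \nu^2$; uniform over the
observed-$x$ range for $c$; uniform $(0, 10]$ for $d$.

### Sampler

`fit_mixed()` runs a Gibbs-within-Metropolis scheme:

* conjugate Gaussian updates for the coefficient block and for each $u_i$;
* conjugate inverse-gamma updates for $\sigma^2, \tau^2, \nu^2$;
* random-walk Metropolis for $c$ and $d$ **with the coefficient block
  integrated out analytically** (the marginal likelihood is available in
  closed form via the matrix determinant lemma at $p \le 3$).  Collapsing
  removes the strong coupling between the changepoint and the slopes and is
  the main reason the chains converge comfortably within the standard run
  length;
* per-subject random-walk Metropolis for $\gamma_i$, with proposals outside
  the subject's observed-$x$ box rejected (this implements the truncated
  normal prescribed by both the normality assumption and the box
  constraint);
* for varying-delay variants, a recentring Gibbs move
  $\delta \sim N(\bar\gamma, \nu^2/m)$ (truncated so $c$ stays in the
  global box) shifts $c \leftarrow c + \delta$,
  $\gamma_i \leftarrow \gamma_i - \delta$, leaving every $c_i$ unchanged.
  Without it, $c$ and the mean of the $\gamma_i$ form a ridge the sampler
  random-walks along very slowly.

Proposal SDs are tuned toward 20–50% acceptance during the first half of
the convergence run and frozen afterwards, so the diagnostic half of every
chain is a fixed Markov kernel.

### Protocol and diagnostics

The estimation protocol is fixed-length: 3 chains, a 10,000-iteration
convergence run, then 1,000 further iterations thinned by 10, retaining
**300 posterior draws** pooled across chains.  Convergence is declared when
the Gelman–Rubin potential scale reduction factor (PSRF, computed on the
second half of each chain, classic between/within-variance form) is below
1.2 for every sampled parameter, including the random effects; otherwise
the result is returned with `converged = FALSE` and a warning — never
silently.  Two degenerate corners are defined explicitly: identical chains
give PSRF 1, constant-but-different chains give $\infty$.

Model comparison uses the **complete-likelihood DIC**: the deviance includes
the random-effect densities ($u_i$, and $\gamma_i$ where present), the
plug-in deviance is evaluated at the posterior means of all parameters and
random effects, and $\mathrm{DIC} = 2\bar D - D(\bar\theta)$ with
$p_D = \bar D - D(\bar\theta)$.  Several DIC constructions exist for mixed
models; the conditional-likelihood variant (random-effect densities
dropped) is exposed as an option.  Smaller is better; on cohorts with
genuinely heterogeneous delays the varying-delay variants win this
comparison essentially always, which is the qualitative behaviour the
method is designed to detect.

## Functional clustering

The shape-based grouping of trajectories proceeds in two steps.

1. **Representation.** Each trajectory is projected onto a common cubic
   B-spline basis with 5 equally spaced interior knots on $[0, 1]$
   (dimension 9).  The projection is penalized least squares with a
   *second-difference* coefficient penalty (weight $10^{-4}$).  A pure
   ridge penalty proved wrong here: basis functions supported below the
   first observed work fraction ($x$ starts at $1/n_i \ge 0.08$) receive
   essentially no data, their coefficients explode or collapse arbitrarily,
   and that noise dominates any subsequent clustering.  The difference
   penalty leaves constants and straight lines untouched (so flat and
   linear trajectories are represented exactly), extrapolates the
   unsupported boundary coefficients smoothly, and makes coefficients
   comparable across subjects with different numbers of points.
2. **Mixture clustering.** A Gaussian mixture (EM, diagonal covariance by
   default, full covariance optional with a diagonal fallback on
   singularity) on the coefficient vectors.  `K = "auto"` selects the
   number of clusters by BIC over 1–12, with two guards: component
   variances are floored at $10^{-3}$ (squared-rating units) so a single
   point cannot win the likelihood with a spike, and candidate solutions
   containing a hard-assigned singleton cluster are inadmissible (an
   outlier is not a pattern group).  Initialization is k-means under a
   fixed seed; labels are relabelled by decreasing cluster size and empty
   clusters compacted, so the output is deterministic and stable under
   subject reordering.

The clustering operates on basis coefficients of the *raw* trajectories;
clustering fitted model curves instead is possible by passing their
evaluations through the same representation.  On real cohorts of this kind
roughly nine shape groups have been described; we treat that as descriptive
of one dataset, not a target — the number of clusters is data-driven here.

## The synthetic cohort generator

No real cohort ships with the package, so `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, with ground
truth stored per subject:

* subjects draw an archetype (family + parameter distributions) by weight;
  the default suite has five shapes — steep linear, shallow linear,
  quadratic rise, delayed power rise, and a delayed sharp rise with plateau
  (negative curvature) — echoing the pattern groups seen in real pediatric
  data;
* delays centre near 40% of Wmax (the typical estimated individual delay),
  truncated away from the smallest observable work fraction;
* $n_i$ is uniform on 6–12; the work grid is $x_j = j/n_i$, equally spaced
  and ending exactly at Wmax $= 1$, which is what step-increment protocols
  produce after normalization;
* Gaussian rating noise with SD 0.3 by default (individual fit RMSEs of
  0.25–0.35 are typical of such data); ratings are clipped to $[0, 10]$
  and can optionally be snapped to the legal Borg values
  $\{0, 0.5, 1, 2, \dots, 10\}$;
* parameters/covariates and rating noise use **separate seed streams**, so
  changing the noise seed leaves the true parameters untouched — essential
  for clean recovery experiments.

What the generator does *not* emulate: censoring dynamics at the top of the
scale beyond simple clipping, non-monotone raters (they appear only through
noise), informative dropout before Wmax, and any physiological covariate
structure (heart rate, FEV1, ...).  A green test on synthetic data
therefore establishes correctness of the estimation machinery under the
stated model, not robustness to every behaviour real children produce.

`generate_mixed_cohort()` is the companion generator for the pooled models
(shared fixed effects, random intercepts, optionally random delays
truncated to each subject's observed-$x$ box).

## Numerical choices and edge cases

* Ratings are treated as continuous despite the discrete Borg scale, and no
  censoring correction is applied at 10 — matching standard practice, with
  truncation acknowledged as a limitation.
* A perfect fit (SSE $= 0$) is reported with a degenerate flag and infinite
  log-likelihood sentinel, not an exception.
* Rank-deficient design matrices (e.g. the delayed column vanishing when
  $c$ reaches $\max x$) fall back to minimum-norm least squares with
  dropped coefficients set to 0.
* Model-curve fixtures may exceed 10 slightly (a fitted curve is not a
  rating); `subject_trajectory(check_range = FALSE)` admits them while the
  reader and generator stay strict.
* The delay recovery bound (median $|\hat c - c| \le 0.05$ at
  $\sigma = 0.25$, $n_i = 12$) holds for populations at realistic parameter
  scales (slopes near 7, quadratic coefficients centred on 0).  With weak
  curvature and shallow slopes the changepoint is genuinely less
  identifiable — both the optimizer *and* the brute-force grid oracle show
  an attenuation bias there — so recovery experiments should state their
  population, as `recovery_experiment()` makes explicit.

## A small worked run

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_config(n_subjects = 40, seed = 1))
coh <- filter_min_points(coh, 6)$cohort

fits <- fit_cohort(coh)
summarize_fits(fits, coh)

rd <- rmse_difference_analysis(fits, coh)
plot(rd)

mix <- fit_mixed(coh, "MQDV", mcmc_config(seed = 1))
mix$posterior_summary

co <- represent_trajectories(coh)
cl <- cluster_trajectories(co, K = "auto", seed = 1)
describe_clusters(cl, coh)
```

The same stages run end-to-end, with everything persisted and a manifest
recording seeds and a configuration hash, via `run_pipeline()` or the
`exertraj_cli()` command-line entry point.

## Known limitations

* Individual fits carry no standard errors or intervals; uncertainty
  statements come from the Bayesian pooled models.
* The mixed-effects sampler is single-site Metropolis for $d$; on strongly
  ridged $(b_2, d)$ posteriors mixing for those two parameters is slower
  than for the rest (the PSRF check will say so).
* The functional clustering is one standard construction
  (spline coefficients + Gaussian mixture); it is a reimplementation
  decision, and other constructions could group borderline subjects
  differently.
* Dyspnea ratings, alternative rating scales, and heteroscedastic error
  models are out of scope.
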