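# exertraj

Modelling trajectories of perceived leg exertion during incremental
exercise, for biostatisticians and exercise-physiology researchers working
with Borg CR10 ratings collected on graded maximal ergometer tests —
especially in children and adolescents, whose stimulus–response curves are
far more heterogeneous than adults'.

Each subject contributes a short trajectory: ratings $y_{ij} \in [0, 10]$
at work fractions $x_{ij} \in (0, 1]$ of their own maximal work capacity
(Wmax).  The package provides:

* **Four per-subject model families** with Gaussian errors
  $\varepsilon_{ij} \sim N(0, \sigma_i^2)$:

  | family | mean structure | k |
  |---|---|---|
  | P (power) | $a + b_2 x^d$ | 3 |
  | D (delay) | $a + b_1 (x - c \vee 0)$ | 3 |
  | PD (power-delay) | $a + b_2 (x - c \vee 0)^d$ | 4 |
  | QD (quadratic-delay) | $a + b_1 (x - c \vee 0) + b_2 (x - c \vee 0)^2$ | 4 |

  The *delay* $c$ is the fraction of Wmax below which ratings stay flat at
  the intercept — a changepoint in the psychophysical stimulus–response
  function.  Fitting is profiled box-constrained least squares with
  multistart ($c > \min_j x_{ij}$, $d \ge 0$), plus RMSE / AICc / BIC model
  selection, per-subject family comparison, and the RMSE-difference-vs-delay
  diagnostic with a loess smoother.  An exhaustive grid-search oracle
  (`grid_oracle_fit`) provides an independent verification route.
* **Bayesian mixed-effects changepoint models** (MPD, MQD with a common
  delay; MPDV, MQDV with subject delays $c_i = c + \gamma_i$,
  $\gamma_i \sim N(0, \nu^2)$), estimated by a Gibbs-within-Metropolis
  sampler with collapsed changepoint updates; Gelman–Rubin PSRF
  diagnostics (threshold 1.2) and complete-likelihood DIC for model
  comparison.  Default protocol: 3 chains × 10,000 iterations, then 1,000
  more thinned by 10 → exactly 300 retained posterior draws.
* **Functional clustering** of trajectory shapes: penalized B-spline
  representation + Gaussian-mixture EM with BIC-selected K, plus
  cluster-composition tables by sex, age group and diagnosis.
* **A synthetic-cohort generator** with archetype mixtures (steep/shallow
  linear, quadratic rise, delayed power rise, plateau), stored ground
  truth, separate parameter/noise seed streams, and a parameter-recovery
  harness — so the whole pipeline is testable without any real data.

## Worked example

```r
library(exertraj)

coh  <- generate_cohort(cohort_config(n_subjects = 40, seed = 1))
coh  <- filter_min_points(coh, 6)$cohort      # keep subjects with >= 6 ratings
fits <- fit_cohort(coh)                        # all four families per subject
subset(summarize_fits(fits, coh),
       quantity %in% c("c", "d", "rmse") & family %in% c("P", "PD", "QD"))
```

```
   family group quantity  n median    q1    q3
3       P   all        d 40  2.219 1.591 2.803
4       P   all     rmse 40  0.308 0.254 0.445
15     PD   all        c 40  0.478 0.279 0.556
16     PD   all        d 40  0.823 0.482 1.144
17     PD   all     rmse 40  0.233 0.173 0.283
23     QD   all        c 40  0.399 0.247 0.490
24     QD   all     rmse 40  0.197 0.163 0.276
```

Read: on this synthetic cohort the median estimated delay in the
quadratic-delay model is ~0.40 (40% of Wmax); the simple power model needs
a median exponent ~2.2 to chase delayed rises, which drops below 1 once a
delay term absorbs the flat phase; and the delay-bearing families fit
better (median RMSE 0.20–0.23 vs 0.31 rating units).

```r
mix <- fit_mixed(coh, "MQD", mcmc_config(n_iterations = 2000, seed = 1))
mix
#> <mixed_fit> MQD: 300 retained draws (3 chains), max PSRF 1.013, DIC 1375.2 (pD 68.2)

cl <- cluster_trajectories(represent_trajectories(coh), K = "auto", seed = 1)
cl
#> <cluster_model> K=3 (diagonal covariance), sizes: 18/13/9, BIC 1485.4
```

The full pipeline (filter → individual fits → summaries → RMSE differences
→ optional mixed models → clustering, everything persisted with a seed- and
config-hash manifest) runs via `run_pipeline(pipeline_config(...))` or the
CLI:

```sh
Rscript -e 'exertraj::exertraj_cli()' simulate --out cohort.csv --n 100 --seed 1
Rscript -e 'exertraj::exertraj_cli()' fit --in cohort.csv --out fits.csv
Rscript -e 'exertraj::exertraj_cli()' run --config config.json
```

## Documentation

The methods vignette (`vignettes/exertraj-methods.Rmd`) describes the
models and their assumptions, the sampler, all numerical choices and
defaults, what the synthetic generator does and does not emulate, and known
limitations.
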