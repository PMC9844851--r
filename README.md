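# iemirt

Latent variable selection for multidimensional two-parameter logistic
(M2PL) item response models by an accelerated L1-penalized EM algorithm.

## The problem

A questionnaire of J dichotomous items measures K correlated latent traits
(personality factors, clinical constructs, abilities).  The M2PL model puts

    P(y_ij = 1 | theta_i) = plogis(a_j' theta_i + b_j),
    theta_i ~ N_K(0, Sigma),  diag(Sigma) = 1,

and the scientific question is *which items load on which traits* — the
support Lambda of the J x K loading matrix A.  Instead of factor rotation
plus an arbitrary cut-off, the loading matrix is estimated by maximizing
the L1-penalized marginal log-likelihood

    l(A, b, Sigma | Y) - eta * ||A||_1,

with a few anchor items pinned to single traits for identification, so
irrelevant loadings are shrunk to exactly zero and the structure is
selected automatically.  The penalty weight eta is tuned by BIC.

## The algorithm

The marginal likelihood is handled by EM with the latent distribution
discretized on a fixed quadrature grid of G points.  The M-step separates
into one weighted L1-penalized logistic regression per item plus a
covariance update under the unit-diagonal positive-definite constraint.
The package implements both M-step formulations:

* **EML1** (naive): each item regression runs on the N x G augmented
  pseudo-observations — faithful but expensive;
* **IEML1** (accelerated): the same objective regrouped onto 2 x G
  artificial observations weighted by the Bock–Aitkin expected counts
  f_g (expected sample size) and r_jg (expected positive responses),
  cutting the M-step from O(N x G) to O(2 x G).

The two are algebraically identical; the test suite verifies full fits
agree elementwise to 1e-13.  Item subproblems are solved by coordinate
descent with soft-thresholding (compiled, exact logistic curvature,
monotone safeguard); the covariance update is a projected gradient ascent
run to stationarity.  Weight diagnostics justify reduced grids (Grid7,
Grid5 on [-2.4, 2.4]) that cut G by an order of magnitude with near
identical selection accuracy.

## Worked example

Simulate the standard K = 3 design (40 items, nonzero loadings U(0.5, 2),
difficulties N(0, 1), latent correlations 0.1) and fit the BIC-tuned
IEML1 path on the fast 5-point grid:

```r
library(iemirt)

cfg   <- sim_config(N = 500, J = 40, K = 3, seed = replication_seed(1, 1))
model <- generate_true_model(cfg)
Y     <- generate_responses(model, 500, seed = replication_seed(1, 2))

path <- fit_path(Y, eta_grid(500, "coarse"), model$config, grid5(3))
sel  <- path$fits[[path$selected]]
sel$eta; sel$bic; sum(sel$Lambda)
correct_rate(sel$Lambda, model$Lambda, model$config)
c(sel$Sigma[1, 2], sel$Sigma[1, 3], sel$Sigma[2, 3])
```

This run (it is exactly what `scripts/acceptance.R --seed 1` executes)
prints:

```
  selected eta = 15 (BIC = 22693.75), 51 nonzero loadings
  structure correct rate vs truth: 0.9550
  estimated latent correlations: 0.162 0.091 0.108 (truth 0.1)
```

i.e. the BIC picks an interior penalty (eta = 0.03 N), the recovered
support matches the truth on 95.5% of the non-anchor entries, and the
latent correlations land near the generating value 0.1.

A thin command-line surface over the same functions lives at
`inst/cli/iemirt.R` (subcommands `simulate`, `fit`, `baselines`,
`diagnose-grid`, `evaluate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — simulates the K = 3
design under the given seed, runs the BIC-tuned IEML1 path, and prints the
selection summary — then writes the JSON report to `--out`.

## Layout

* `R/` — model core (likelihoods, penalized objective), quadrature and
  posterior tables, artificial data, M-step solvers, EM driver and tuning
  path, baselines (two-stage, EIFAthr/EIFAopt) and metrics (CR, FNR/FPR/
  precision, MSE), synthetic-data generators, I/O.
* `src/cd_logistic.cpp` — the weighted L1 logistic coordinate-descent
  solver.
* `vignettes/penalized-m2pl.Rmd` — the methods vignette: model,
  algorithm, numerical choices, design decisions, limitations.
* `tests/testthat/` — unit and property tests with independent
  brute-force oracles, plus `test-acceptance.R` (end-to-end criteria).
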