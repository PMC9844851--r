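---
title: "Latent variable selection in multidimensional 2PL models by accelerated penalized EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent variable selection in multidimensional 2PL models by accelerated penalized EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and the selection problem

A test of $J$ dichotomous items measures $K$ correlated latent traits of $N$
subjects.  The multidimensional two-parameter logistic (M2PL) model links the
response of subject $i$ to item $j$ through

$$P(y_{ij} = 1 \mid \boldsymbol\theta_i) =
  \frac{\exp(\mathbf a_j^\top \boldsymbol\theta_i + b_j)}
       {1 + \exp(\mathbf a_j^\top \boldsymbol\theta_i + b_j)},
\qquad \boldsymbol\theta_i \sim N_K(\mathbf 0, \Sigma),$$

with item discrimination (loading) vectors $\mathbf a_j$, difficulties $b_j$,
and a latent covariance $\Sigma$ constrained to a unit diagonal.  Which items
measure which traits is encoded by the support
$\Lambda = (\lambda_{jk}) = (I(a_{jk} \neq 0))$ of the loading matrix.  In
exploratory analyses this support is classically obtained by factor rotation
followed by an ad hoc cut-off; here it is *selected* by maximizing the
$L_1$-penalized marginal log-likelihood

$$\max_{A, \mathbf b, \Sigma}\;
  \ell(A, \mathbf b, \Sigma \mid Y) - \eta \lVert A \rVert_1,
\qquad \Sigma \succ 0,\; \operatorname{diag}(\Sigma) = \mathbf 1,$$

which shrinks irrelevant loadings to exactly zero.  Rotational indeterminacy
is resolved by *anchor items*: a small set of items declared, a priori, to
load on exactly one trait each (their remaining loadings are fixed zeros).
Scale is fixed by the unit diagonal of $\Sigma$.

## The EM algorithm and the artificial-data acceleration

The marginal likelihood integrates over $\boldsymbol\theta_i$; the package
follows the standard fixed-grid treatment: the latent distribution is
discretized on a $K$-ary Cartesian power grid (`build_grid()`, typically 11
points per dimension on $[-4, 4]$ or the reduced 7/5-point sets on
$[-2.4, 2.4]$), and the E-step computes each subject's posterior mass over
the grid (`posterior_table()`).  Identical response patterns share a
posterior, so the table is built over distinct patterns with multiplicities.

The surrogate to maximize splits into a $\Sigma$-part and $J$ independent
item parts.  The naive M-step (variant `"eml1"`) treats each item part as a
weighted penalized logistic regression on the $N \times G$ augmented
observations $(y_{ij}, \boldsymbol\theta^{(g)})$.  The accelerated M-step
(variant `"ieml1"`) regroups these by response value into the classical
Bock–Aitkin expected counts

$$f_g = \sum_i \tilde p(\boldsymbol\theta^{(g)} \mid \mathbf y_i), \qquad
  r_{jg} = \sum_i y_{ij}\, \tilde p(\boldsymbol\theta^{(g)} \mid \mathbf y_i),$$

which act as weights $w_j(1, g) = r_{jg}$ and $w_j(0, g) = f_g - r_{jg}$ on
only $2 \times G$ pseudo-observations (`artificial_weights()`).  The two
objectives are *algebraically identical* — only the summation is regrouped —
so the two variants must produce the same estimates up to floating-point
noise.  The test suite asserts this identity twice: symbolically (the two
`qj_value()` forms agree to $10^{-12}$ on random instances) and end-to-end
(full fits agree elementwise to $10^{-13}$).

Each item subproblem is solved by iteratively reweighted least squares with
coordinate-wise soft-thresholding (`src/cd_logistic.cpp`), using the exact
logistic curvature $w\,p(1-p)$ per pseudo-row and a step-halving safeguard
that makes the solver monotone from its warm start — which in turn makes the
whole EM surrogate ascent provable and testable (`ascent_slack`).
Coordinates are updated in fixed order, so runs are bitwise reproducible.
Zero coefficients are exact zeros (soft-thresholding), so the selected
support needs no post hoc thresholding.

The $\Sigma$-update maximizes
$Q_0(\Sigma) = -\tfrac N2\{K\log 2\pi + \log\det\Sigma +
\operatorname{tr}(\Sigma^{-1} S^*)\}$ over unit-diagonal positive-definite
matrices by projected gradient ascent with Armijo backtracking
(`update_covariance()`).  The projection symmetrizes, clips eigenvalues at
$10^{-6}$, and rescales to a unit diagonal; the line-search steps along the
*tangent* (diagonal-zeroed) gradient because, under the rescaling
retraction, the full gradient is not a descent direction.  The subproblem is
run to stationarity (projected gradient below `sigma_tol`) within each
M-step, reading the update as the argmax it is stated to be.

## Numerical choices

* **Log-space E-step.**  Products of up to $J = 40$ Bernoulli factors
  underflow double precision, so all per-row products are accumulated in
  logs and exponentiated after subtracting the row maximum.  Posterior rows
  therefore always sum to one; no `NaN` path exists.
* **Normalized prior mass.**  The marginal log-likelihood uses normalized
  grid weights $\varphi(\boldsymbol\theta^{(g)}\mid\Sigma)/\sum_{g'}
  \varphi(\boldsymbol\theta^{(g')}\mid\Sigma)$ — the exact likelihood of the
  grid-discretized latent model.  This makes the value of a zero-loading
  item exactly $\log \tfrac12$ per response, independent of the grid.  The
  posterior is unaffected (the normalizer cancels), and $Q_0$ keeps its
  closed form in the raw density.
* **Inner tolerances.**  The coordinate loop stops at a $10^{-14}$
  coefficient change and the IRLS loop at a $10^{-15}$ relative objective
  change.  These are deliberately much tighter than typical lasso defaults:
  the IEML1/EML1 agreement check at $10^{-13}$ needs both variants to carry
  solver error well below that level through a few dozen EM iterations.  At
  $2 \times G$ pseudo-observations the cost is negligible.
* **EM stopping rule.**  Largest elementwise change in $(A, \mathbf b,
  \Sigma)$ below $10^{-5}$ *and* relative surrogate change below $10^{-8}$,
  capped at 500 iterations.
* **Degenerate saddles.**  $A = 0$ (and, per trait, a zero column) is an
  exact stationary point of the EM map: the posterior equals the prior and
  every item score vanishes identically.  Two consequences are handled
  explicitly.  First, when all free loadings are zero and $(A, \mathbf b)$
  has stabilized, the fit stops: $\Sigma$ has dropped out of the likelihood
  and would otherwise chase grid-truncation drift to the iteration cap
  (flagged with a warning).  Second, `fit_path()` cold-starts every
  $\eta$ from the default initial values rather than warm-starting down the
  path: a collapsed solution is stationary at *every* smaller $\eta$, so a
  warm start can never revive a dead trait, and partially collapsed warm
  starts measurably drag the rest of the path into poorer optima.
  (`warm_start = TRUE` is available, guarded against fully degenerate
  seeds.)
* **Separation.**  If one pseudo-response class carries zero weight, the
  intercept MLE diverges; it is clipped at $\pm 30$ with a warning.
* **Sign indeterminacy.**  Anchors fix scale but not sign; after
  convergence, any trait whose anchor loading is negative has its loading
  column and covariance row/column reflected.
* **Ties.**  BIC ties along the path break toward the larger $\eta$ (the
  sparser model); coordinate updates use a fixed order, so there are no
  data-dependent tie-breaks.

## Tuning by BIC: judged on the refit, not the shrinkage

The penalty weight is chosen over the candidate grids
$(0.10, 0.09, \ldots, 0.01) \times N$ (simulation protocol) or
$(0.040, 0.038, \ldots, 0.002) \times N$ (questionnaire protocol),
`eta_grid()`.  The criterion is
$\mathrm{BIC} = -2\hat\ell + d \log N$ with $d$ counting the nonzero free
loadings, the $J$ difficulties, and the $K(K-1)/2$ free covariance entries
when $\Sigma$ is estimated (both counts are conventions and configurable in
`bic_m2pl()`).

A design choice that deserves its own paragraph: by default the likelihood
$\hat\ell$ entering the BIC of each candidate is evaluated at an
*unpenalized confirmatory refit* on that candidate's support
(`fit_path(..., bic = "refit")`, implemented via the `structure_zeros`
argument of `em_fit()`), not at the shrunk estimates themselves.  Plugging
in the shrunk estimates makes the BIC essentially monotone decreasing in
$\eta$ on realistic designs — every true loading regains shrinkage bias as
$\eta$ falls, a likelihood gain that scales with the *number of true
loadings* and dwarfs the $\log N$ price of the handful of tiny false
positives — so selection degenerates to the densest candidate.  Judged on
the refit, candidates whose support already contains the truth differ only
by the false positives' $\log N$ price, and the BIC minimum sits at an
interior $\eta$.  The plug-in version remains available
(`bic = "shrunk"`).

## The synthetic world

`sim_config()` / `generate_true_model()` / `generate_responses()` state the
simulation world used throughout the tests: $J = 40$ items, $K \in
\{3,4,5\}$ traits, nonzero loadings i.i.d. $U(0.5, 2)$, difficulties
$N(0,1)$, latent covariance with unit diagonal and all off-diagonals $0.1$,
anchors at items (1, 10, 19) / (1, 7, 13, 19) / (1, 5, 9, 13, 17).  The
reference designs' exact loading matrices live in an unpublished supplement;
the default `loading_pattern()` therefore generates a block-sparse stand-in:
items between consecutive anchors load on that anchor's trait, and the last
two non-anchor items of each block also load on the next trait, so the
selection problem contains genuine cross-loading items.  Any user-supplied
binary pattern respecting the anchors is accepted for exact reproduction.

What the generator does *not* emulate: guessing/slipping (3PL/4PL),
missing data, polytomous items, and local dependence.  A green recovery test
therefore establishes that the estimator recovers block-sparse M2PL
structure under correctly specified binary responses — not robustness to
model misspecification.

Per-replication seeds are derived from a master seed by fixed offsets
(`replication_seed()`), keeping every replication independently
reproducible and inside the 32-bit integer range.

## Reduced grids and the weight diagnostics

The cost of both E- and M-steps scales with $G = (\text{points per
dimension})^K$.  In the first E-step of a $K = 3$, $J = 40$ fit with the
11-point grid, sorting an item's $2 \times 1331$ artificial weights shows
a few hundred of them carrying nearly all of the total mass (about 95% in
the top 355), and their grid points confined to the central cube
$[-2.4, 2.4]^3$
(`weight_diagnostics()` reports the sorted weights, the cumulative-share
curve, and the smallest covering box).  This motivates the reduced `grid7()`
and `grid5()` sets, which the recovery tests show to match the full grid's
selection accuracy to within a few hundredths of CR at a fraction of the
cost.  A 3-point grid is implemented but warned against — it is too coarse
for the E-step expectation.

## Baselines and metrics

For comparison the package ships the competing estimators built from an
unpenalized constrained exploratory fit (`constrained_eifa()`, our own
$\eta = 0$ engine rather than an external IFA package — numerical parity
with any particular package is a non-goal): fixed hard thresholding
(`hard_threshold_estimate()`, anchors exempt), BIC-optimal thresholding
over $(0.30, 0.35, \ldots, 0.70)$ (`eifa_opt()`), and the two-stage method
(`two_stage_fit()`), which freezes the stage-1 covariance estimate inside
the penalized path.  Evaluation uses the field's metrics over the non-anchor
loading entries: the correct rate $\mathrm{CR} = \frac{1}{K(J-K)} \sum
I(\hat\lambda_{jk} = \lambda_{jk})$, FNR/FPR/precision
(`confusion_metrics()`, undefined ratios flagged, anchor rows excluded
consistently — the supplement defining the exact entry set is not public),
and entry-wise MSE across replications (`mse_report()`).

## A worked run

```{r}
library(iemirt)

cfg <- sim_config(N = 1000, J = 40, K = 3, seed = 11)
model <- generate_true_model(cfg)
Y <- generate_responses(model, N = 1000, seed = 12)

path <- fit_path(Y, eta_grid(1000, "coarse"), model$config, grid5(3))
sel <- path$fits[[path$selected]]
correct_rate(sel$Lambda, model$Lambda, model$config)
sel$Sigma

ts <- two_stage_fit(Y, eta_grid(1000, "coarse"), model$config, grid5(3))
mse_report(list(sel), model)$mean_Sigma_offdiag
mse_report(list(ts), model)$mean_Sigma_offdiag
```

## Known limitations

* The marginal problem is nonconvex; at moderate $\eta$ the EM map can park
  a whole trait at zero (a stationary saddle).  Cold starts per $\eta$
  mitigate but cannot exclude this; inspect `n_iter`, `converged` and the
  per-fit warnings along the path.
* Fixed rectangular grids inherit the usual truncation bias: posterior
  second moments are slightly attenuated near the grid boundary, so
  covariance estimates on the $[-2.4, 2.4]$ grids are mildly shrunk toward
  zero.
* Adaptive quadrature and Monte Carlo E-steps are out of scope by design:
  the $2 \times G$ regrouping requires one shared, fixed grid for all
  subjects.
* No missing-data handling: responses must be complete and coded 0/1.
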