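---
title: "Separating measurement and sampling bias in multisite functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating measurement and sampling bias in multisite functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcharmony)
```

## The problem

Resting-state functional-connectivity studies of psychiatric disorders must
pool scans from many imaging sites, because no single site can recruit
enough patients. Site differences then contaminate every downstream
analysis, and they are of two fundamentally different kinds:

* **measurement bias** — an engineering shift caused by the scanner and
  protocol (phase-encoding direction, manufacturer, coil, model). It is
  biologically meaningless and should be removed.
* **sampling bias** — a shift caused by *which participants* a site
  recruits (e.g. different depression subtypes dominating different
  clinics). It is biological signal about the site's subpopulation and
  should generally be preserved.

The two are confounded in an ordinary multisite sample: each site
contributes different participants scanned on a different machine. The key
to separating them is a **traveling-subject** dataset — the same healthy
participants scanned at every site — in which site differences can only be
measurement bias.

## The decomposition model

Connectivity is summarized per scan as the Fisher-z transformed Pearson
correlation between the time courses of every pair of atlas nodes; a
268-node atlas gives $268 \times 267 / 2 = 35{,}778$ edges. For each edge,
the package models the value of a scan as

$$y \;=\; \mathbf{x}_m^{\top}\mathbf{m}
  + \mathbf{x}_{s_{hc}}^{\top}\mathbf{s}_{hc}
  + \mathbf{x}_{s_{mdd}}^{\top}\mathbf{s}_{mdd}
  + \mathbf{x}_{s_{scz}}^{\top}\mathbf{s}_{scz}
  + \mathbf{x}_d^{\top}\mathbf{d}
  + \mathbf{x}_p^{\top}\mathbf{p}
  + \mathit{const} + e,$$

where $\mathbf{m}$ holds one measurement bias per site,
$\mathbf{s}_{hc}, \mathbf{s}_{mdd}, \mathbf{s}_{scz}$ one sampling bias
per site and diagnosis class, $\mathbf{d}$ the disorder factors (healthy
controls are the baseline, $d_{HC} = 0$), $\mathbf{p}$ the traveling
participants' factors, and $e \sim N(0, \gamma^{-1})$. All indicator
vectors use 1-of-K coding with an all-zero vector for non-membership:
multisite rows carry $\mathbf{m}$, one sampling block and $\mathbf{d}$
(their participant identity is noise); traveling rows carry $\mathbf{m}$
and $\mathbf{p}$ only. Both datasets are fitted *jointly*, which is what
makes $\mathbf{m}$ and the $\mathbf{s}$ blocks separable.

Identifiability requires hard constraints: each bias block sums to zero
over its sites, participant factors sum to zero over participants. These
are enforced exactly through the Karush-Kuhn-Tucker (KKT) linear system of
the equality-constrained problem, not through soft penalties. Because
within the multisite rows alone site indicators for $\mathbf{m}$ and the
$\mathbf{s}$ blocks are collinear, the design is ill-conditioned and the
loss includes an L2 penalty $\lambda \lVert w \rVert^2$ (the intercept is
excluded from the penalty — it estimates the grand mean and should not
shrink). One KKT factorization is shared by all edges, so fitting tens of
thousands of edges costs a single dense solve.

A diagnosis class observed at fewer than two sites cannot carry its own
sum-to-zero sampling block; its sampling bias is absorbed by its disorder
factor (in the emulated design this is the ASD class, which is sampled at
one site).

### Choosing the ridge weight

Without regularization the ill-conditioned design produces *spurious*
correlations between bias estimates: anticorrelation between measurement
bias and HC sampling bias, and correlation between HC sampling bias and
the patient sampling biases. `select_lambda()` refits the model over a
grid (default $0{-}20$) and minimizes the absolute mean of the three
between-bias correlation families over matched sites; a permutation mode
(site labels shuffled within dataset kind) produces the corresponding null
curve. The chosen $\lambda$ is always taken from the search, never
hard-coded.

```{r lambda, eval = FALSE}
study <- generate_study(n_edges = 500, seed = 1)
combined <- bind_datasets(study$multisite, study$traveling)
search <- select_lambda(combined, grid = 0:20)
dec <- fit_all_edges(combined, lambda = search$lambda)
```

## Harmonization methods

Four harmonizers share a fit/apply interface, so each can be fitted on one
dataset and applied to another:

* **traveling-subject** (`fit_traveling_subject`): subtracts the jointly
  estimated measurement bias $\hat{\mathbf{m}}$ only. Requires traveling
  coverage of every target site; the fit refuses to extrapolate.
* **GLM** (`fit_glm`): per-edge OLS on site indicators alone; subtracts
  the whole site difference. With sum-to-zero site coding the intercept is
  the grand mean, making the site terms directly comparable to
  $\hat{\mathbf{m}}$. Any disorder signal confounded with site is removed
  along with it.
* **adjusted GLM** (`fit_adjusted_glm`): site + diagnosis indicators
  (HC baseline); subtracts the site term only.
* **ComBat** (`fit_combat`): parametric empirical-Bayes location-and-scale
  adjustment with diagnosis covariates preserved. Edges are standardized
  by OLS estimates of grand mean, covariates and pooled variance; per-site
  additive and multiplicative effects are shrunk toward moment-matched
  priors (normal for the additive effect, inverse-gamma for the
  multiplicative) by iterating the conditional posterior means
  (tolerance $10^{-4}$, at most 100 iterations). The multiplicative term
  is indexed per site *and* edge, the standard formulation. The apply step
  is $(y - \widehat{const} - x_d^\top\hat d - \hat\gamma_{site})/\hat\delta_{site}
  + \widehat{const} + x_d^\top\hat d$.

The in-package ComBat exists because the fit/apply split across datasets
is essential to the cross-validated evaluation; on a single dataset it
reproduces the reference `sva::ComBat` output to float precision (this is
pinned by a test).

## Evaluating harmonization: twofold cross-validation

`run_cv_evaluation()` splits the multisite rows 50/50 within every site
and the traveling sessions 50/50 within every site-by-participant cell
(one seed governs both; odd counts round the extra row to fold 1). For
each direction, the traveling-subject model is fitted on fold 1 plus its
traveling half; the other models on fold 1 only. The fitted model is
applied to the testing dataset — fold 2 plus the *other* traveling half,
kept disjoint to avoid leaks — and the full decomposition is refitted on
the testing data. The residual measurement bias is summarized as the mean
across sites of the per-site SD of the bias magnitude distribution
(per-site values are also exposed, so a pooled summary can be formed
instead), and signal-to-noise is the ratio of that SD to the participant-
and disorder-factor SDs (the disorder SNR pools the available disorder
factors by their mean). Percentages reported by `reduction_and_snr()` are
relative to the unharmonized (`raw`) testing data, averaged over the two
fold directions.

Rows of the testing dataset whose site a model has never seen (the
traveling-only sites, for models fitted on multisite data) are passed
through unadjusted — the all-zero indicator convention of the model
equation.

## Sampling-bias population models

Is sampling bias just finite-sample noise, or do sites recruit from
genuinely different subpopulations? With per-site sample size $N_k$, the
across-edge variance of a site's sampling-bias vector has expectation
$\xi^2 / N_k$ if all sites draw from one population, and
$\xi^2/N_k + \sigma^2$ if site means themselves scatter with variance
$\sigma^2$. On the $\log_{10}$ scale:

$$\text{single population: } y_k = -x_k + 2\log_{10}\xi, \qquad
  \text{different subpopulations: } y_k = \log_{10}\!\big(\xi^2 10^{-x_k} + \sigma^2\big),$$

with $x_k = \log_{10} N_k$, $y_k = \log_{10} v_k$. The subpopulation curve
is the $\log_{10}$ of the variance law, so that at $\sigma = 0$ it reduces
exactly to the single-population line. `fit_population_model()` minimizes
squared residuals on the log scale by default (the scale on which both
curves are written and plotted); a raw-variance loss is selectable.
Because the log-scale objective has a flat basin at large $\sigma$, the
optimizer is a multi-start quasi-Newton search over
$(\log\xi, \log\sigma)$, which also enforces positivity smoothly.

Model comparison uses small-sample information criteria on the raw-scale
residuals $\varphi_k = v_k - \hat v_k$,

$$\mathrm{AICc} = \sum_k \ln \varphi_k^2 + 2q + \frac{2q(q+1)}{K-q-1},
\qquad \mathrm{BIC} = \sum_k \ln \varphi_k^2 + q \ln K,$$

with $q = 1$ or $2$ parameters and $K$ sites ($K = 6$ reproduces the
formulas for the emulated HC design; the implementation generalizes $K$).
`loso_cv_predict()` adds leave-one-site-out prediction of each held-out
site's variance from its $N_k$, comparing models by a one-tailed paired
Wilcoxon signed-rank test on absolute errors (direction fixed as "the
subpopulation model errs less"). This analysis is run on healthy controls;
patient classes are observed at too few sites for a six-point fit.

## Factor summaries

* `magnitude_moments()` — per level: mean, population SD (at ~35k edges
  the sample/population distinction is negligible), and signed cube root
  of the third central moment of the edge-wise distribution.
* `contribution_sizes()` — per (subject, edge) cell, each squared model
  term's share of the total squared signal (the intercept is excluded from
  the total); shares sum to one by construction, and a factor's
  contribution is its average share divided by its level count.
* `variance_comparisons()` — Ansari-Bradley dispersion tests over a
  level-pair grid (9 participants x 12 sites = 108 pairs in the emulated
  design), Bonferroni corrected — the only multiplicity correction used
  anywhere in the package.
* `bias_disorder_correlation()` — Pearson correlations between every
  site's measurement bias and every disorder factor, with a one-sample
  t test on the absolute correlations.
* `roi_projection()` — per-edge effects (median absolute value across
  levels, or the absolute disorder vector) averaged over the edges
  incident to each node, optionally z-scored within factor.
* `cluster_measurement_bias()` — hierarchical clustering of the sites'
  bias vectors at distance $1 - r$. Average linkage is the default and
  the criterion is configurable, since dendrogram shape depends on it;
  leaf ordering is left to `hclust` (merge heights, which carry the
  interpretation, are ordering-invariant).
* `site_effect_anova()` — per-edge one-way F tests of site, Bonferroni
  threshold $0.05/N$, computed with vectorized group sums (checked against
  `anova(lm(...))` in the tests).

## The preprocessing front end

`connectivity_pipeline()` turns ROI time series and rigid-body motion
parameters into an edge vector with a fixed stage order: scrubbing, then
nuisance regression, then band-pass filtering on the concatenated retained
volumes, then correlation. Framewise displacement is the sum of absolute
backward differences of the translations plus the rotations scaled by a
50 mm head radius (the Power convention; the radius is configurable since
conventions differ), with volumes above 0.5 mm deleted. The nuisance
design has 36 regressors: six motion parameters and three tissue means,
each with a backward-difference derivative (first row zero), and the
squares of all eighteen. The temporal filter is a first-order Butterworth
band-pass (0.01-0.08 Hz by default) applied forward and backward for zero
phase; the series is demeaned first, since DC lies outside the pass band
and otherwise excites start-up transients in the recursive filter. Fisher
z is capped at $\mathrm{atanh}(1 - 10^{-7})$ so degenerate $r = \pm 1$
stays finite. Scans whose removed-volume count exceeds the cohort mean
plus 3 SD are flagged for exclusion (`exclusion_check()`; the mirrored
retained-below reading is selectable, as the convention is ambiguous in
the field). Whether scrubbing should precede or follow filtering is
genuinely underdetermined; deletion-first is the documented default
because it keeps the filter from smearing spike volumes into neighbors.

## The synthetic study design

`generate_study()` draws data directly from the decomposition model with
known ground truth, emulating a realistic design: a unified-protocol
multisite sample (HC at six sites with 31/77/10/35/40/142 participants,
MDD at three, SCZ at three, ASD at one — 513 rows) and a twelve-site,
nine-participant traveling sample whose default schedule (three sessions
at nine sites, two at two sites, five three-session cycles at one site,
one participant one cycle short) totals 411 sessions.

Scale-setting defaults place simulations in the regime the estimator is
meant for: measurement-bias SD 0.0411, participant-factor SD 0.0662,
disorder SDs 0.0328/0.0377/0.0297 (MDD/SCZ/ASD), all in Fisher-z units.
Sampling bias is generated mechanistically from the subpopulation model:
site means $\beta_k \sim N(0, \sigma^2)$ with $\sigma = 0.02$ and
individual deviations at SD $\xi = 0.0662$ (the same scale as the
participant factor, since both are individual variation), giving realized
per-site sampling-bias SDs of about 0.021-0.029 over the default site
sizes. Scan-to-scan noise SD is 0.03, a value chosen (and marked
synthetic) so that factor recovery sits in a realistic regime — neither
trivial nor hopeless. Bias blocks are re-centered to sum to zero across
sites after drawing, matching the estimator's constraints so recovery is
unbiased rather than alias-shifted; the draws are pre-inflated by
$1/\sqrt{1 - 1/K}$ so the realized per-level SDs match the requested
scale after centering. The generator records the *realized* per-site
sampling biases (site means of the individual deviations), because that —
not the latent $\beta_k$ — is what the estimator targets.

What the generator does **not** emulate: spatial correlation among edges
(edges are independent Gaussians, as in the model itself), scanner
physics (phase-encoding distortion appears only as additive bias
structure), motion artifacts in the multisite values, and non-Gaussian
heavy tails. Passing tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness to
every property of real scanner data.

## Numerical choices and problem sizes

Constraints are satisfied to $10^{-6}$ or better (checked on every fit);
the KKT solution matches an independent null-space QP solver to $10^{-8}$
on random small instances. Residual variance is RSS/$n$ — degrees of
freedom are ill-defined under constraints plus ridge. The KKT system is
singular only when $\lambda = 0$ meets a rank-deficient design; that case
raises an explicit error advising $\lambda > 0$. Ridge shrinkage biases
recovered factor SDs slightly downward (about 2% at $\lambda = 1$ on the
default design), which is why scale-recovery checks use a light penalty.

The test suite and the acceptance script run the full design at reduced
edge counts (tens to a few thousand edges rather than 35,778): every
quantity checked is edge-wise or averages across edges, so the edge count
only sets Monte-Carlo precision, and the chosen sizes keep the whole
suite at a few minutes on one CPU.

## Known limitations

* Edges are modeled independently; hierarchical pooling across edges
  (ComBat-style priors inside the decomposition) is deliberately out of
  scope.
* The traveling-subject harmonizer cannot serve sites without traveling
  coverage, by design.
* The disorder-factor reading of the constraint $d_{HC} = 0$ is
  implemented as HC-baseline coding with one free coefficient per non-HC
  diagnosis; with patients of one class all at one site, that class's
  sampling bias is inseparable from its disorder factor.
* `exclusion_check()` and the scrub-versus-filter ordering implement
  documented defaults where field conventions are ambiguous; both are
  configurable.
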