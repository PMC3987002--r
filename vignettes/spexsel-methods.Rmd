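---
title: "Methods: spatial exposure modelling and NMIG variable selection"
author: "spexsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial exposure modelling and NMIG variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spexsel)
```

## The problem

Autoimmunity studies of small, geographically concentrated cohorts often
have a binary serological outcome (ANA positivity), a questionnaire panel
of personal covariates, and environmental chemical concentrations measured
at monitoring sites that do not coincide with where participants live.
`spexsel` implements a complete workflow for this setting:

1. **Distance-modified exposures.** Site concentrations are folded into
   per-participant exposures with inverse-distance weights, separately per
   residential address class (first/birth, longest-held, last/current —
   proxies for early, cumulative and recent exposure windows).
2. **Dimension reduction.** Correlated multi-chemical exposure panels are
   reduced by PCA on the correlation matrix, retaining the components that
   explain at least 80% of the variance.
3. **Variable selection.** A Bayesian logistic mixed model with a
   Normal-mixture-of-inverse-Gammas (NMIG) spike-and-slab prior selects
   among personal covariates and exposures (or PC scores), reporting
   posterior inclusion probabilities.
4. **Kriging validation.** Where a dense monitoring "strip" exists,
   chemicals are interpolated to addresses by Bayesian Kriging and the
   interpolation uncertainty is propagated into a two-stage
   measurement-error health model for the participants living within 1 km
   of the strip.

Every stage is exercised end-to-end on synthetic data with known truth,
because real residential coordinates in such cohorts are confidential.

## Distance-weighted exposures

Distances from addresses to sites use the spherical law of cosines with
mean Earth radius $R = 6371$ km; the arccosine argument is clipped to
$[-1, 1]$ to guard round-off at near-identical points. For a chemical
measured at sites $j = 1, \dots, J$ with concentrations $c_j$ at distances
$d_{ij}$ from participant $i$, the exposure is

$$x_i \;=\; \sum_j c_j \, d_{ij}^{-p}, \qquad p \in \{1, 2\},$$

the inverse-linear or inverse-quadratic weighted sum. The sum is the
literal reading of the per-site weighting form $c/d$ and $c/d^2$; because
the aggregation across sites admits a normalized alternative, the
inverse-distance-weighted *mean* is available via `normalize = TRUE`.
Distances below 0.1 km are clamped to 0.1 km so a participant living on a
sampling site cannot receive an infinite exposure. Columns are labelled
by chemical with a medium suffix ("S" soil, "W" groundwater, none for
strip metals).

## Correlation PCA

Chemicals are measured on very different scales (µg/kg vs µg/L), so PCA
uses the correlation matrix, computed by SVD of the standardized exposure
matrix (`prcomp`). Retention keeps the smallest $k$ whose cumulative
variance fraction reaches the threshold (default 0.80). Eigenvector signs
are arbitrary, so each loading column is flipped to make its
largest-magnitude element negative — a fixed convention that makes signed
loading reports reproducible; with predominantly positively correlated
exposure panels this typically renders first components all-negative.
The loading report lists chemicals with $|$loading$| \ge 0.30$ (the
display cutoff is configurable; some cutoff is needed to say a chemical
"did not load"). No rotation (varimax etc.) is applied. Missing exposure
entries are rejected rather than imputed: imputation policy belongs
upstream of the PCA.

## The NMIG spike-and-slab logistic mixed model

For outcome $y_i \sim \mathrm{Bern}(p_i)$,

$$\mathrm{logit}(p_i) = \mathbf{x}_i^\top \boldsymbol\beta + \gamma_i ,$$

with a per-participant random intercept $\gamma_i$. Selectable
coefficients carry the NMIG prior

$$\beta_j \mid \eta_j, \tau_j^2 \sim N(0, \tau_j^2 \eta_j), \quad
  \tau_j^2 \sim \Gamma^{-1}(a_\tau, b_\tau), \quad
  \eta_j = \begin{cases} 1 & \text{with probability } w \\
                         v_0 & \text{with probability } 1 - w \end{cases},
  \quad w \sim \mathrm{Beta}(a_w, b_w).$$

With $v_0$ small, $\eta_j = v_0$ collapses the coefficient variance to a
spike at zero and $\eta_j = 1$ leaves the diffuse slab; the posterior
frequency of the slab state is the term's *inclusion probability*.
Non-selectable coefficients (always-in terms and the model intercept) get
zero-mean Gaussian priors whose precisions have $\mathrm{Ga}(1, 5\times
10^{-5})$ priors, as does the random-intercept precision when the
intercept block is not itself selectable.

Defaults are $v_0 = 0.00025$, $a_\tau = 5$, $b_\tau = 25$,
$a_w = b_w = 1$ — the conventional settings for NMIG selection in
generalized additive mixed models; all are configurable because the
appropriate spike width is application-dependent.

**Sampling.** The Bernoulli-logit likelihood is augmented with exact
Polya-Gamma variables (a Devroye-type rejection sampler compiled in C++),
which makes every conditional update conjugate: Gaussian for
$\boldsymbol\beta$ and $\gamma$, Bernoulli for $\eta$ with the exact
density-ratio conditional (exposed as `conditional_eta_probability()`),
inverse-Gamma for $\tau^2$ (exposed as `draw_tau2_conditional()`), Beta
for $w$, Gamma for the remaining precisions. The sampler targets the
exact posterior; no Metropolis step or approximation is involved.

**Standardization.** All candidate columns are standardized to zero mean
and unit variance before selection, because the NMIG prior is
scale-sensitive; coefficients are reported on the standardized scale.

**Smooth terms.** A flexible effect $S(x)$ uses a first-order random-walk
smoother: the covariate is binned at quantile knots, the RW1 difference
penalty $K = D^\top D$ is eigen-decomposed, and the penalized subspace is
rescaled so block coefficients are exchangeable $N(0, \tau^2\eta)$. The
whole block shares one indicator $\eta$, so a smooth is selected in or
out as a unit; the penalty null space (the constant) is absorbed by the
model intercept.

**Random-intercept selection.** The intercept block may itself be
selectable (default), in which case its inclusion probability is reported
as `Rnd(id2)`; with one observation per participant the block indicator
is nearly absorbing — its conditional odds are a product over all
participants — so its chain mixes slowly and multi-chain summaries tend
to land near multiples of $1/\text{chains}$. This is a known property of
block-wise NMIG Gibbs samplers, worth keeping in mind when reading
random-intercept rows of selection tables. Fixed-effect indicators are
single-coefficient blocks and mix well.

**Classification.** A term is *included* when its mean inclusion
probability is at least 0.5 (ties included, since 0.5 is the minimum
value for inclusion), *reported* at 0.25, and an included linear term is
starred "well estimated" when its equal-tailed 95% credible interval
excludes zero.

**Defaults.** 3 chains of 10,000 iterations (5,000 burn-in, thin 5) with
consecutive seeds, monitored by split-$\hat R$ on the coefficients; the
examples and tests in this package use single short chains (2,000–4,000
iterations) because the standardized, low-dimensional designs mix in a
few hundred iterations.

## Bayesian Kriging and the two-stage model

Strip concentrations are modelled on the log scale (they are skewed and
nonnegative) as a Gaussian process with exponential covariance

$$\mathrm{Cov}(z_s, z_t) = \sigma^2 e^{-d_{st}/\phi} + \kappa\,
  \mathbf{1}\{s = t\},$$

the minimal standard choice when no covariance family is dictated by the
data. The mean has a conjugate Gaussian update; $(\log\sigma^2,
\log\phi, \log\kappa)$ move by random-walk Metropolis with weakly
informative log-normal priors centred on the empirical variance, half the
median inter-site distance, and a tenth of the empirical variance
respectively (spread 1.5 on the log scale) — these centre the sampler
without constraining the posterior at strip-like sample sizes (~110
sites). Predictions marginalize the conditional mean and variance over
the posterior draws by the law of total variance.

The validation cohort is the set of addresses inside the convex hull of
the strip sites or within 1 km of the hull boundary (the hull stands in
for the unpublished strip polygon; geometry is computed on a local
equirectangular projection, adequate at these extents).

Stage 2 is the same NMIG logistic model on the standardized predictive
means, with an additive measurement-error term in the linear predictor,
$\omega_i \sim N(0, v_i)$, where $v_i$ accumulates the stage-1 predictive
variances of the modelled chemicals on the standardized scale (plug-in
propagation; cross-chemical error correlation is ignored, and there is no
feedback from outcomes to the GP — the two stages are strictly
sequential). When every predictive sd is zero the $\omega$ update is
skipped entirely, so the fit collapses bit-for-bit to the plain
spike-and-slab fit on the means.

## The synthetic-data generator

The generator emulates the study conditions the pipeline was designed
around, with one master seed splitting into fixed per-stage streams:

- **80 participants** with target ANA prevalence **47.5%**; the
  intercept is calibrated by root-finding so the mean simulated outcome
  probability matches the target given effects and random intercepts.
- **Sparse irregular regional networks** (25 soil, 20 groundwater sites,
  uniform over a ~23 × 28 km coastal box) and a **dense 110-site strip**
  (a narrow jittered band across the middle of the region).
- **Log-normal chemical surfaces**: log-concentrations are Gaussian
  processes with exponential covariance (sill 1, range 8 km, nugget
  0.05) and exchangeable cross-chemical correlation 0.9 — high enough
  that one or two principal components carry most of the variance, as in
  real multi-metal panels. The cross-chemical factor is applied to the
  spatial-plus-nugget field, so the parameter is the marginal correlation
  of the full surfaces.
- **Addresses**: a base address uniform over the central 70% of the
  region (keeping most address-to-site distances within 15 km); the first
  address is the base, the longest-held jitters it by ~0.3 km and the
  last by ~1.5 km — residential moves of increasing recency, chosen in
  the absence of any formal mobility model.
- **Personal covariates**: counts (termite/insect treatments, paint
  work, fish meals) as Poisson, binaries (smoking, well water, gender,
  heater exposure) as Bernoulli, education near 12 years, age uniform on
  18–85. These marginals are pragmatic choices — no distributional claim
  about any real questionnaire panel is implied.

What the generator does **not** emulate: real Sea Island geography or
concentration magnitudes, informative residential mobility, correlation
between personal covariates and exposures, household clustering, or
missing data. Passing recovery tests therefore demonstrate that the
*methods* behave correctly under their own assumptions, not that the
pipeline would detect effects in any particular real cohort.

## Numerical choices

- Spatial covariance factorizations add a $10^{-8}\sigma^2$ ridge before
  Cholesky; duplicate coordinates are simulated once and copied so a zero
  nugget yields exactly identical values.
- Metropolis proposals whose covariance fails Cholesky are rejected; a
  singular covariance at the initial state (e.g. duplicated sites with
  the nugget fixed at zero) is an error, not a silent fallback.
- Exposure distances are clamped below at 0.1 km; predictive variances
  are floored at zero before taking square roots.
- The intercept calibration root-find runs on $[-40, 40]$ log-odds,
  tolerance $10^{-10}$.
- Ties at the 0.5 inclusion threshold classify as included.

## Problem sizes used in tests

The test suite and the acceptance script size their simulations to be
informative yet quick: selection recovery uses $n = 500$ participants
with 2 true effects among 10 candidates over 5 seeds; Kriging calibration
refits 10 replicate 110-site strips; the strip validation experiment uses
15 participants and 5 candidate metals (with near-independent surfaces,
since rank recovery among 0.9-correlated metals is not identifiable at
that sample size); the whole-cohort prevalence check uses $n = 2000$.
Single chains of 2,000–4,000 iterations are used throughout; split-$\hat R$
for such fits is routinely below 1.05.

## Known limitations

- The unnormalized exposure sum confounds concentration level with local
  site density; the normalized mean is provided but the two can rank
  participants differently.
- NMIG inclusion probabilities at very small $n$ (the strip subsamples)
  hover near the prior mean $a_w/(a_w + b_w) = 0.5$; rank order is more
  informative than the absolute probability there.
- The random-intercept inclusion indicator is nearly absorbing (see
  above).
- The Kriging range is weakly identified on an elongated strip whose
  short axis is comparable to the true range; posteriors are wide but
  calibrated.
- Plug-in measurement-error propagation understates stage-1 uncertainty
  relative to a joint model, though it preserves the widening of
  credible intervals with interpolation error.
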