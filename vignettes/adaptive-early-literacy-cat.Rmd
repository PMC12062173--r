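---
title: "Multidimensional 4PL calibration and adaptive testing with mcat4pl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional 4PL calibration and adaptive testing with mcat4pl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcat4pl)
```

## The measurement problem

Screening young children — here, preschoolers assessed on six early-literacy
scales (concepts of print, print awareness, word awareness, phonological
awareness, alphabet knowledge, early reading) — poses two difficulties that
shape everything in this package. First, attention is short: a fixed-form
test long enough to be reliable on six dimensions is too long to administer.
Second, responses are noisy in both directions: a child may guess a
four-option item correctly without the skill, and may miss an easy item
despite having the skill, through inattention or disengagement.
Computerized adaptive testing (CAT) addresses the first problem by selecting
each next item to be maximally informative at the child's current ability
estimate; the four-parameter logistic (4PL) response model addresses the
second.

## The response model

For item $j$ with loading (discrimination) vector $a_j$ over $D$ latent
dimensions, intercept $d_j$, lower asymptote $\chi_j$ and upper asymptote
$\gamma_j$, the probability of a correct response at trait vector $\theta$
is

$$P_j(\theta) = \chi_j + (\gamma_j - \chi_j)\,
  \frac{1}{1 + e^{-(a_j^\top \theta + d_j)}}.$$

The curve is the ordinary logistic compressed in the y-direction into
$[\chi_j, \gamma_j]$: $\chi_j$ captures guessing, $\gamma_j < 1$ captures
slipping/disengagement. Fixing $\chi_j = 0,\ \gamma_j = 1$ recovers the
2PL; freeing only $\chi_j$ gives the 3PL; the families are nested
(M2PL $\subset$ M3PL $\subset$ M4PL), which is what makes the model
comparison in `compareModels()` meaningful. We use the pure logistic link
without the historical 1.7 scaling constant. Internally the slope–intercept
parameterisation is canonical because it is the stable one for estimation;
the Reckase summaries MDISC $= \lVert a_j \rVert$ and MDIFF
$= -d_j / \lVert a_j \rVert$ are derived views (`mdisc()`, `mdiff()`).

The Fisher information of a single Bernoulli response is the rank-one
matrix

$$I_j(\theta) = \frac{\left[(\gamma_j-\chi_j)\,p^*(1-p^*)\right]^2}
  {P_j(1-P_j)}\; a_j a_j^\top,$$

with $p^*$ the inner logistic. Where $P_j$ degenerates to 0 or 1 the
information is taken as the zero matrix rather than an error, which keeps
adaptive selection total. A property test checks this expression against a
finite-difference computation of the expected negative Hessian.

## Calibration

`fitMirt()` maximises the marginal likelihood by EM. The latent density is
integrated on a fixed grid: a tensor product of equally spaced points with
normal weights for $D \le 3$ (61 points in one dimension, 21 and 11 per
axis in two and three), and a seeded quasi-Monte-Carlo rule (2000 standard
normal draws pushed through the Cholesky factor of the trait covariance)
for higher $D$, where tensor quadrature is infeasible — an eight-dimensional
bifactor model is exactly the situation this is for. Each M-step maximises
one item's expected complete-data log-likelihood under the confirmatory
loading pattern. Free asymptotes are estimated on the logit scale with weak
normal penalties (sd 3, centred at logit 0.15 and logit 0.95): the 4PL
asymptotes are notoriously ill-determined at screening-study sample sizes
and light regularisation keeps them in range without visibly moving the
likelihood. With `correlatedTraits = TRUE` the content-trait correlations
are updated each iteration from posterior moments (nuisance dimensions stay
orthogonal, with unit variances fixed for identification).

Because the 4PL likelihood is multimodal, estimation is repeated from
`nStarts` jittered starting points and the best marginal log-likelihood is
kept; the same seed always reproduces the same solution. Items with zero
response variance, or answered by fewer than `minResponses` respondents,
carry no usable information and are flagged for removal rather than
estimated.

Exploratory factor analysis is deliberately not implemented: structural
exploration that informs a loading pattern is treated as an input question,
and alternative structures (including bifactor refinements) are expressed
as confirmatory refits with different patterns.

## Goodness of fit

`fitIndices()` computes the limited-information M2 statistic from the $J$
univariate and $J(J-1)/2$ bivariate response margins:
$M_2 = N e^\top C e$ where $e$ is the residual margin vector, $\Xi$ the
multinomial asymptotic covariance of the sample margins (its entries are
model-implied joint moments up to order four, evaluated by quadrature),
$\Delta$ the Jacobian of the implied margins in the free parameters
(numerical, central differences), and
$C = \Xi^{-1} - \Xi^{-1}\Delta(\Delta^\top\Xi^{-1}\Delta)^{-1}
\Delta^\top\Xi^{-1}$. Degrees of freedom are
$df = J + J(J-1)/2 - q$ — exposed separately as `m2DegreesOfFreedom()`
because the arithmetic is useful on its own. RMSEA is
$\sqrt{\max((M_2-df)/(df\,N),\,0)}$ with confidence bounds from
noncentral-$\chi^2$ inversion. SRMSR is computed on residual
product-moment correlations of the binary responses — cheaper than
tetrachorics and monotone-equivalent for ranking models, which is all the
selection workflow needs; the routine is isolated so the residual metric
can be swapped. TLI and CFI are computed against an independence null with
free item margins evaluated on the same statistic. The $\Xi$ matrix is
quadratic in the number of margins, so `fitIndices()` is intended for
test-length banks (a few dozen items); on a large operational pool only
the df arithmetic is needed.

## Scoring

`mapEstimate()` returns the maximum a posteriori trait vector under a
multivariate-normal prior (by default the bank's trait correlation matrix),
found by BFGS with the analytic gradient. Per-dimension standard errors are
square roots of the diagonal of the inverse of prior precision plus the
*observed* information (negative Hessian of the log posterior) at the MAP —
standard MAP practice, with `information = "expected"` available for
comparison. Under the 4PL the observed matrix can fail to be positive
definite (wrong answers on easy items contribute positive curvature); in
that case the expected (Fisher) information is substituted automatically.
With unit-variance traits the conversions
$\mathrm{SEM} = \sqrt{1-\mathrm{Rel}}$ and
$\mathrm{Rel} = 1-\mathrm{SEM}^2$ tie precision to reliability:
reliabilities 0.75, 0.80, 0.85, 0.90 correspond to SEMs 0.500, 0.447,
0.387, 0.316. T-scores are the usual $T = 50 + 10\theta$. Nuisance
(bifactor) dimensions are estimated jointly but excluded from reporting.

## Item selection

Each candidate item is scored on
$M = P_0 + \sum_{\text{administered}} I_j(\hat\theta) + I_c(\hat\theta)$,
the prior precision plus accumulated plus candidate Fisher information at
the current MAP. The base rules maximise: **D** $\det M$ (volume of the
confidence ellipsoid), **T** $\mathrm{tr}\,M$, **A** $-\mathrm{tr}\,M^{-1}$
(average posterior variance), **E** the smallest eigenvalue of $M$, and
**W** $w^\top M w$ for a weight vector $w$ (default: equal weights on the
reported dimensions). The posterior-weighted variants TP/AP/WP/EP average
the same criterion over a fixed stencil of $2D+1$ quadrature points — the
MAP plus one posterior standard deviation in each axis direction — weighted
by the posterior density; AP, the operational default, is thus the
posterior-weighted A-criterion. In one dimension D, T, A and E all reduce
to maximum-information selection, which the tests verify. Because the
candidate term is rank-one, all criteria except E are evaluated with
rank-one updates ($\det$, trace and inverse-trace identities), so a full
session over a 177-item bank costs well under a second. Ties break to the
lowest bank index for reproducibility. No content balancing across scales
is enforced at the selection layer.

Difficulty adaptation — harder items after correct answers, easier after
incorrect — is emergent from information maximisation, not hard-coded, and
is checked in aggregate by a property test.

## Stopping

`stopRuleConfig()` encodes the staged rule, with thresholds stored at full
precision:

* items 1–49: stop once **all** reported dimensions have
  SEM $< \sqrt{0.15} = 0.387298334620742$ (reliability 0.85);
* from item 50: the threshold relaxes to
  $\sqrt{0.2} = 0.447213595499958$ (reliability 0.80);
* from item 60: additionally stop when
  $\sum_{f=1}^{6}(\mathrm{SEM}_f^{\max}-\mathrm{SEM}_f^{\min})^2 < 0.0005$
  over the last 10 items — per dimension that allows movement of only
  $\sqrt{0.0005/6} \approx 0.01$, i.e. the standard errors have stabilised
  and further items cannot meaningfully reduce them;
* a session with no items left always stops (`bank_exhausted`).

Item positions count the starting item, and the rule is evaluated after
each administration. Thresholds apply to all six content dimensions
simultaneously; per-dimension early release is deliberately not offered.
A threshold stop therefore *guarantees* the corresponding reliability floor
$1 - s^2$ on every reported dimension. Single-threshold runs (used
throughout the simulation studies) are expressed by `semThresholdStop()`,
which sets both stages to one value and disables the stability check; for
this reason the configuration accepts stage1 $\le$ stage2 rather than
requiring strict inequality.

Whether the stage boundaries at items 49/50/60 should be read as
before-or-after the item at exactly those positions is genuinely ambiguous;
the convention above (stage 1 *through* item 49, stability *from* item 60)
is documented as this package's reading, and the boundaries are
configurable.

## The synthetic bank

No calibrated early-literacy item parameters are public, so
`generateBank()` fabricates pools with the documented geometry of such a
bank, and every numeric claim in the tests runs on these synthetic pools:

* 177 items over the six scales (38/19/12/28/45/35 — approximating the
  published per-scale allocation after misfitting items were removed);
* MDIFF uniform on $[-2, 2]$ with the endpoints pinned per scale, so every
  pool spans the full band;
* MDISC lognormal, meanlog $\log 2.5$, sdlog 0.8, truncated to
  $[0.5, 12]$: roughly three quarters of items above 1.5 with a minority
  in 0.5–1.5 and a small very-high-discrimination tail;
* lower asymptotes uniform on $[0, 0.3]$ (four-option multiple choice),
  upper asymptotes on $[0.85, 1]$;
* content traits compound-symmetric with correlation 0.75; two bifactor
  nuisance dimensions, orthogonal to everything, attached to the first 20
  items of the first scale, each such item splitting its MDISC between its
  content axis and a nuisance axis;
* three starting items on the first scale at target difficulties
  $-1.5, -1.0, -0.5$ for age groups 4-and-under, 5, and 6-and-over —
  easy, and slightly harder for older children.

The trait correlation and the MDISC shape are the two quantities an
operational bank determines but a synthetic one must posit. They were
fixed, once, by requiring that the synthetic pool actually supports the
kind of screening the staged rule is designed for: under these defaults,
staged-rule sessions average about 32 items (median 27) with per-scale
terminal reliabilities averaging 0.88–0.94, and reaching reliability 0.80
on all six dimensions takes a few dozen items with a full-bank tail of
roughly 10–30% depending on the threshold — the regime a well-constructed
six-scale screening pool operates in. Weakly correlated traits or
uniformly modest discriminations make six-dimensional screening at these
reliabilities mathematically infeasible on 177 items, so those would not
be credible emulations: early-literacy skills are strongly interrelated,
and calibrated pools concentrate their most discriminating items where
most children are.

What the generator does *not* emulate: real item content; differential item
functioning by age; local dependence beyond the bifactor block;
misspecification of the response model itself (simulated responses are
drawn from exactly the 4PL that scoring assumes). Passing simulations
therefore demonstrate the internal consistency and efficiency of the
engine, not robustness to model misfit in field data.

## The simulation framework

`runCatSimulation()` runs one full session per simulee and aggregates item
counts (mean, SD, min, median, 75/80/85/90/95th percentiles, max, fraction
using the full bank) and terminal per-dimension reliabilities (mean, SD,
min, 5/25/50/75/95th percentiles, max). Percentiles use the nearest-rank
convention, matching discrete summary-table practice. Each simulee's
responses are pregenerated from their true trait vector under the run seed,
so two runs differing only in the stopping rule administer identical
prefixes — the stricter rule can never stop first, and paired comparisons
are exact. Identical inputs and seed give byte-identical summaries.

`startingItemStudy()` produces the per-session sum of squared terminal
SEMs over candidate starting items and stopping rules, and
`startingItemRegression()` fits the OLS with per-age-group dummy-coded
starting items (reference levels are an explicit input, since any choice is
a parameterisation, not a finding) and a looser-rule indicator, reporting
$b$, SE, $t$, $p$ and standardised $\beta$, most beneficial item first
within each age group.

## Worked example

```{r example, eval = FALSE}
bank <- generateBank(bankSpec(), seed = 1)
ses <- runSession(bank, ageGroup = "5", rule = "AP",
                  stopConfig = stopRuleConfig(),
                  trueTheta = rep(0.3, 8), seed = 42)
length(administeredItems(ses)); stopReason(ses)
est <- currentEstimate(ses)
classifyTrafficLight(tScores(est)[reportedDimensions(bank)])
```

A population-level evaluation at reliability 0.80:

```{r simulation, eval = FALSE}
simulees <- generateSimulees(100, rep(0, 8), traitCov(bank), seed = 2)
summ <- runCatSimulation(bank, simulees, rule = "AP",
                         stopConfig = semThresholdStop(sqrt(0.2)),
                         seed = 3)
summ
```

## Numerical choices and limitations

* MAP optimisation: BFGS, analytic gradient, relative tolerance `1e-10`,
  warm-started from the previous estimate within a session;
  non-convergence with a gradient norm above `1e-3` is an error.
* Probabilities are clamped to $[10^{-10}, 1-10^{-10}]$ inside likelihoods.
* EM convergence: absolute log-likelihood change below `tol` (default
  `1e-3`), at most `maxIter` (default 100) iterations.
* Problem sizes in the test suite — recovery at $N=1000, J=20$ in one
  dimension, 200-simulee reference simulations, M2 at $J \le 20$ — were
  chosen as the smallest at which the checked properties are stable.
* The M2 machinery assumes complete response data; with missingness the
  margins' multinomial covariance is undefined and the function refuses.
* Reliability is model-based ($1-\mathrm{SEM}^2$ under the fitted model),
  not a field test–retest quantity; the two coincide only insofar as the
  model holds.
* Exposure control and content balancing are out of scope at the selection
  layer.
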