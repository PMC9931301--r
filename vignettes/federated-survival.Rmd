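---
title: "Federated time-to-event analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated time-to-event analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedtte)
```

## The problem

Clinical time-to-event studies need sample sizes that single institutions
rarely have, while privacy law makes pooling subject-level records across
institutions difficult or impossible. `fedtte` implements the standard
time-to-event toolkit — Kaplan-Meier survival curves, Nelson-Aalen
cumulative hazards, the pairwise log-rank test, and Cox proportional
hazards regression — in a *federated* form: each site computes summary
statistics on its own data and only those summaries are combined. Two
privacy levels are offered on top of plain federation:

* **hybrid mode** routes every cross-site exchange through additive
  secret sharing, so the coordinating aggregator only ever sees global
  sums, never any site's local statistics; and
* **differential privacy** adds calibrated Laplace noise to released
  survival-curve counts, bounding what the published curve itself can
  reveal about any single subject.

The federation is simulated in one process with explicit message objects
and a who-saw-what audit log. This is deliberate: the statistical claims
and the information-flow claims are both about *what is exchanged*, which
the audit log captures exactly; a network transport is an orthogonal
extension point.

## Estimators from aggregated counts

For each time point $t_i$ of a shared timeline, site $k$ counts its
events $d_{ik}$, subjects at risk $n_{ik}$ and censorings $c_{ik}$. The
aggregator sums these over sites, and the federated estimators are the
usual ones applied to the totals:

$$S_{fed}(t) = \prod_{t_i \le t}\left[1 - \frac{\sum_k d_{ik}}{\sum_k n_{ik}}\right],
\qquad
H_{fed}(t) = \sum_{t_i \le t} \frac{\sum_k d_{ik}}{\sum_k n_{ik}}.$$

Because the counts are additive over sites, these are *algebraically
identical* to the centralized estimators on pooled data — the test suite
asserts equality to 1e-12 against `survival::survfit()` for every
partition of a cohort into 1, 3, 5 or 10 sites.

Conventions (where the literature leaves room):

* Censored subjects tied with an event time are kept in the risk set at
  that time (the standard Kaplan-Meier convention).
* Subjects with time 0 are retained.
* Timeline points with $n_i = 0$ contribute a factor of 1 (KM) or are
  skipped (NA).
* Greenwood pointwise intervals are available (`conf_int = TRUE`) but off
  by default; they are a documented extension, not part of the federated
  exchange.

Two timeline origins exist. `timeline_union()` uses the distinct observed
event times and reproduces the centralized estimator exactly.
`timeline_grid()` is a fixed, site-independent grid used in hybrid mode:
observations are snapped *up* to the covering grid point, so the set of
exchanged time points reveals nothing about any site's event times. When
the grid is at least as fine as the measurement resolution (e.g. daily
points for day-valued data) the snap is the identity and the estimates
are unchanged; coarser grids trade a quantified bias for fewer exchanged
coordinates.

## The log-rank statistic

For a pair of groups $A, B$ with per-group aggregated counts, the primary
statistic is the observed-vs-expected form

$$X^2 = \frac{(O_A - E_A)^2}{E_A} + \frac{(O_B - E_B)^2}{E_B},
\qquad
E_A = \sum_i n_{iA}\frac{d_i}{n_i},$$

referred to a $\chi^2_1$ upper tail. A pairwise comparison has one degree
of freedom; that is the only consistent reading and is our documented
choice. The classic hypergeometric-variance-weighted statistic
($U^2/V$, the form `survival::survdiff()` computes) is available as
`variant = "variance"`; the two coincide asymptotically for balanced
groups but differ in unbalanced designs, so they are kept clearly apart.
P-values across multiple pairs are raw; apply `stats::p.adjust()` if you
compare many groups.

## Additive secret sharing

Values live in the ring $\mathbb{Z}_{2^{64}}$ after fixed-point encoding
(scale $10^6$, i.e. six decimals preserved; negatives wrap around). Each
site splits its encoded vector into $K$ additive shares — $K-1$ uniform
random ring vectors plus the difference — keeps one and distributes the
rest; each site sums the shares it holds; the aggregator sums those
masked partial sums, which cancels every mask and reveals exactly the
global total. Any strict subset of shares is distributed independently of
the secret (tested with a chi-square uniformity check under two distinct
secrets). At least three sites are required: with two, a site could
subtract its own contribution from the announced total and read off its
partner's values.

Numerical design: R has no native 64-bit integer, so ring elements are
stored as two 32-bit limbs in doubles; every limb operation stays below
$2^{53}$ and is exact (verified against an independent base-$2^{16}$
big-integer oracle). Integer counts therefore aggregate *exactly*; real
vectors reconstruct within $K/10^6$ per entry. The encodable range is
capped so a $K$-party sum can neither wrap past the sign boundary nor
lose double precision — about $\pm 1.5\times10^9$ per entry at $K = 3$,
far beyond any statistic exchanged here. Shares are drawn from R's RNG
(seedable for reproducibility); a deployment across real institutions
would substitute a cryptographic RNG and encrypted transport, which is
exactly the pluggable-channel extension point the in-process simulator
stubs out.

## Federated Cox regression

The Breslow partial likelihood depends on data only through per-timeline
aggregates, which is what makes the federation exact:

* **Normalization.** Two rounds give the global covariate mean
  $m = \sum_k m_k n_k / \sum_k n_k$ and standard deviation (denominator
  $N - 1$); each site transforms to $(X - m)/\sigma$. This equals the
  pooled z-score exactly, and a constant covariate is rejected.
* **Initialization.** Per timeline point: global event counts $d_i$ and
  covariate sums over events $z_i$, aggregated once.
* **Iteration.** At the current $\beta$, each site returns the risk-set
  sums $s_0 = \sum_{l \in R_i} e^{\beta'z_l}$,
  $s_1 = \sum z_l e^{\beta'z_l}$, $s_2 = \sum z_l z_l' e^{\beta'z_l}$
  over $R_i = \{l: t_l \ge t_i\}$, computed in $O(np^2)$ via cumulative
  sums over time-sorted subjects. The aggregator forms the gradient
  $\sum_i [z_i - d_i s_{1i}/s_{0i}]$ and observed information
  $\sum_i d_i[s_{2i}/s_{0i} - (s_{1i}/s_{0i})(s_{1i}/s_{0i})']$ and takes
  a Newton-Raphson step.

Ties are handled with the Breslow approximation throughout — it is the
only tie convention expressible through these three sums, so Efron ties
are explicitly out of scope. The elastic-net penalty
$\tfrac12 p\,[(1-\alpha)\|\beta\|_2^2 + \alpha\|\beta\|_1]$ is applied on
the standardized scale; the L1 term is smoothed as
$\sqrt{\beta^2 + 10^{-8}}$ inside the gradient and Hessian so the plain
Newton loop remains valid for $\alpha > 0$. Safeguards: step-halving (up
to 10 times) whenever the penalized objective would decrease or
$e^{\beta'z}$ overflows; convergence when
$\|\Delta\beta\|_\infty < 10^{-7}$ (at most 50 iterations); a singular
information matrix raises an error suggesting a positive penalty. The
convergence check runs on the penalized objective.

Coefficients, standard errors (inverse of the final penalized
information) and 95% Wald intervals are back-transformed to the original
covariate scale ($\beta_{orig} = \beta_{std}/\sigma$; centering does not
affect a partial likelihood), so output is directly comparable to an
unstandardized centralized fit. With `penalty = 0` the federated fit
matches `survival::coxph(..., ties = "breslow")` to well below $10^{-6}$
for any partition of the data — split-invariance is the package's
headline property and is asserted across partitions in the test suite.

In hybrid mode the timeline is a fixed grid rather than the union of
event times, and every exchanged vector goes through a secret-sharing
round. A grid at the measurement resolution reproduces the plain fit (up
to the $10^{-6}$-scale fixed-point rounding); we evaluate the coarsened
setting at a weekly grid on day-valued data, where log hazard ratios stay
within 0.01 (standardized scale) of the plain fit on benchmark-sized
cohorts — close enough not to change any interpretation, while hiding
site event times.

## Differential privacy

A single subject changes each released count coordinate by at most 1
(asserted by brute force in the tests), so the count vectors have
sensitivity 1 and Laplace($1/\varepsilon$) noise per coordinate gives an
$\varepsilon$-DP release. Three presets are exposed: high
($\varepsilon = 0.75$), medium ($1$) and low ($3$); smaller
$\varepsilon$ means more privacy and more noise, and smaller cohorts are
hit harder at fixed $\varepsilon$ — both trends are asserted by
Monte-Carlo tests.

Two design points matter in practice:

* **Release grid.** Noise is paid per released coordinate, so counts are
  released on a coarse fixed grid (`dp_release_timeline()`, roughly 50
  bins over the follow-up) rather than per distinct event time. Binning
  both hides exact event times and keeps the per-bin noise small relative
  to the per-bin counts; releasing several hundred per-day coordinates
  instead would make the accumulated noise swamp the curve at small
  $\varepsilon$.
* **Post-processing.** Noisy at-risk counts are repaired to a
  non-increasing sequence by isotonic regression (pool-adjacent
  violators), then all vectors are rounded, clamped at zero and events
  capped by at-risk. PAVA is used rather than a running extremum because
  it is the least-squares monotone repair and adds no systematic drift.
  Post-processing is data-independent, so the $\varepsilon$ guarantee is
  untouched. Noise is added once, to the globally aggregated counts — the
  evaluation is independent of the federated computation, and per-site
  noise would change the $\varepsilon$ accounting.

The evaluation harness (`dp_evaluation_study()`) quantifies utility: draw
a DP count matrix, log-rank it against the non-DP counts, and report the
fraction of replicates that differ significantly at $\alpha = 0.05$.
Because that fraction varies noticeably with the particular cohort
realization, the harness averages over five independently generated
scale-matched cohorts with 200 DP draws each. On synthetic cohorts this
reproduces the expected pattern: at $\varepsilon = 3$ essentially no
replicate differs even for $n \approx 888$, while at
$\varepsilon = 0.75$ with $n \approx 137$ a few percent do — small
cohorts are the regime where high privacy starts to cost accuracy.
Composition across the three released vectors follows the cited
mechanism's own accounting and is inherited as such.

DP applies to the count-based outputs only (KM, NA, log-rank); the Cox
model releases no counts, and `study_config()` rejects a DP request for
it.

## The synthetic-data generator

All validation runs on generated cohorts with known ground truth. Event
times follow the proportional-hazards model
$h(t\,|\,z) = h_0(t)\,e^{\beta'z}$ by inverting the cumulative hazard:
$T = -\log(U)/(r e^{\beta'z})$ for an exponential baseline with rate $r$,
and $T = s(-\log U / e^{\beta'z})^{1/a}$ for a Weibull baseline with
shape $a$ and scale $s$. Censoring is independent (exponential or an
administrative cutoff), observed time is the minimum, and durations are
rounded *up* to a measurement resolution (default 1 day), producing the
tied integer-valued times of real clinical tables.

Defaults, chosen once as a realistic clinical regime on a day scale:
exponential baseline rate $1/365$ (median event time around eight
months), censoring rate $1/1200$ (roughly 25–30% censoring), standard
normal or Bernoulli(0.5) covariates. The benchmark-scale profiles match
the sample sizes of four classic survival datasets (137, 168, 432, 888
subjects, with 4–8 covariates) so that equivalence and DP experiments run
at realistic scales; a Weibull(1.2, 400) baseline with two groups and a
0.35 group log-hazard effect gives curves of a typical clinical shape.
Only the *scale* is matched — covariate distributions and effect sizes
are synthetic, so passing tests demonstrate the algorithms' agreement and
calibration at realistic problem sizes, not agreement with any published
analysis of the real datasets. Real data bring things the generator does
not emulate: covariate correlation and measurement error, informative
censoring, site heterogeneity in case mix, and non-proportional hazards.
The split-invariance results are algebraic identities and carry over
regardless; the DP utility fractions and coverage rates are specific to
the generated regime.

Validation problem sizes (and the package's own choices of scale): exact
federated equivalence is asserted on all four benchmark-scale cohorts ×
{3, 5, 10} sites; Cox confidence-interval coverage and bias on 500
replicates of $n = 500$ with two covariates; log-rank type-I error on 500
null replicates; the DP harness at 5 × 200 replicates per
($\varepsilon$, cohort) pair; secret-sharing reconstruction on 120
fuzzed rounds at $K \in \{3, 5, 10\}$.

## Known limitations

* No left truncation, interval censoring, competing risks, stratified or
  weighted log-rank variants, time-varying covariates or robust
  variances.
* Efron tie handling and federated baseline-hazard estimation are out of
  scope (the latter is never exchanged).
* Proportionality diagnostics (e.g. scaled Schoenfeld residuals) are not
  implemented.
* Covariate harmonization across sites is the study designers'
  responsibility: the package verifies column agreement and refuses
  mismatches rather than guessing a mapping.
* The secret-sharing scheme assumes honest-but-curious parties; there is
  no threshold reconstruction, dropout recovery or malicious-adversary
  security.
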