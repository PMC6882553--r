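---
title: "Methods: linking child-development instruments to one interval scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking child-development instruments to one interval scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Infants and toddlers are assessed with many different instruments —
milestone checklists, direct assessments, caregiver reports — each scored
on its own scale and standardised (if at all) against its own norming
population. Scores from different instruments, cohorts and countries are
therefore not directly comparable, which blocks any quantitative
comparison of early childhood development across settings. Yet the
instruments overlap heavily in content: most contain items tapping the
same underlying skills ("stacks two cubes", "builds a two-block tower").

`dscale` builds a single interval scale — the D-score — from such
heterogeneous item-level data. The chain is:

1. **Harmonise** all items to binary fail/pass and assemble a sparse
   child-round × item matrix (each child only sees the items of the
   instrument their cohort administered in that round).
2. **Link** instruments through *equate groups*: sets of same-skill items
   from different instruments whose difficulties are constrained equal in
   the model. Active equate groups are the mathematical bridges between
   instruments and cohorts.
3. **Fit** a unidimensional Rasch model by pairwise conditional
   likelihood, keeping only items that fit it.
4. **Anchor** the logit scale to D-score units through two milestones
   fixed at 20 and 40.
5. **Score** children by the expected a posteriori (EAP) method and
   convert D-scores to age-standardised DAZ via an LMS reference.
6. **Validate** the resulting metric (discriminant, concurrent,
   predictive validity).

Because no public item-level multi-cohort dataset exists for this design,
the package ships a synthetic-cohort generator with known truth; every
claim the test suite makes is a parameter-recovery or calibration claim
on that generator.

## The Rasch model and pairwise conditional estimation

The Rasch model gives child $n$ with ability $\theta_n$ probability
$P_{ni} = \operatorname{logistic}(\theta_n - \delta_i)$ of passing item
$i$ with difficulty $\delta_i$. When ability equals difficulty the pass
probability is exactly 50%; the model is unidimensional by design (that
is the claim being tested, not a nuisance).

Difficulties are estimated from *discordant pairs*. For two items both
observed on a child, conditional on exactly one being passed, the
probability that it is item $i$ is
$\pi_{ij} = \operatorname{logistic}(\delta_j - \delta_i)$ — the child's
ability cancels. With $n_{ij}$ the count of child-rounds passing $i$ and
failing $j$, the pairwise conditional log-likelihood is

$$\ell(\delta) = \sum_{i<j} n_{ij}\log\pi_{ij} + n_{ji}\log(1-\pi_{ij}),$$

a Bradley–Terry likelihood on the item "tournament". Equate-group
constraints are imposed by collapsing all members of an active group into
one cluster before estimation: their counts against outside items are
pooled and within-cluster pairs are excluded. The solution is normalised
to mean zero over *clusters* (not items), so instruments with many items
do not dominate the origin; the origin is irrelevant after anchoring
anyway.

**Optimisation.** The likelihood is concave with a translation
invariance. We run minorise–maximise (MM) fixed-point iterations as a
warm start and finish with damped Newton steps; the Hessian is a weighted
graph Laplacian, regularised along the constant direction. Convergence is
declared when the largest difficulty change is below `tol` (default
`1e-8`, `max_iter` 2000 total iterations). One-sided zero counts receive
a smoothing constant (0.05) on both sides so the maximiser is finite.
Estimation requires the cluster-level comparison graph to be strongly
connected; `connectivity_check()` reports linked components beforehand
and the model builder proceeds on the largest component with a warning if
the bank is disconnected.

## Fit statistics, retention and the activation screen

Infit (information-weighted) and outfit (unweighted) mean-square
residuals are computed per item against EAP abilities estimated under a
flat prior (a design choice: the estimator of $\theta$ used inside fit
statistics is not dictated by the model; EAP is stable for the sparse
designs this package targets). The retention rule is deliberately strict:
an independent item survives only if *both* statistics are below 1;
active-equate members always survive. Estimation, scoring and retention
alternate until the retained set is stable (capped at
`max_retention_iter`, default 5).

Candidate equate groups are screened before activation. A group is
activated only if, when its constraint alone is released (all other
active groups keeping the scale identified), its members' freely
estimated difficulties span less than `activation_range` (0.5 logits),
and no member's constrained infit/outfit exceeds `activation_fit_max`
(1.2). Groups whose release would disconnect the comparison graph cannot
be screened this way and stay active — they are load-bearing. The
activation list can be overridden by configuration, because choosing
bridges is partly a judgment call about content equivalence, not a purely
statistical one. Groups containing an anchor milestone are never
deactivated, and anchor items are exempt from retention and DIF removal:
they define the metric.

Screening note: an earlier formulation estimated member difficulties
per cohort conditional on estimated abilities; per-cohort estimation
error propagated into the free difficulties and produced 1–2 logit
spreads on data generated without any difference. The constraint-release
formulation avoids conditioning on estimated abilities entirely.

## Differential item functioning

Items administered in several countries are pooled into one difficulty
only if children of equal ability have equal pass probability everywhere.
The screen re-estimates each item's difficulty within each group by a
one-dimensional pairwise refit (all other difficulties fixed at the
pooled estimates) and flags the item when the largest pairwise gap
exceeds 0.5 logits *and* a Wald test rejects at 5%. Two calibration
details matter:

* the Wald standard error is cluster-robust over child-rounds — pairwise
  contributions sharing a child are correlated, and the naive information
  overstates precision several-fold;
* a group enters the comparison only with at least `dif_min_n` pairwise
  wins *and* losses for the item; raw response counts are not enough,
  because an item with almost no discordances yields a skewed refit with
  an invalid Wald interval.

Flagged items are excluded by default (configurable to keep them
group-specific).

## Anchoring and EAP scoring

The logit scale is mapped to D-score units by the unique increasing
linear transform that places "lifts head to 45 degrees in prone position"
at 20 and "sits in stable position without support" at 40. The slope $a$
(D units per logit) carries the unit change: pass probability on the D
metric is $\operatorname{logistic}((\theta_D - \delta_D)/a)$, so the
fitted model is preserved exactly — no re-estimation in D units. With
anchors 10 logits apart, $a = 2$ and an ability 5 D above an item's
difficulty passes with probability $\operatorname{logistic}(2.5) \approx
92\%$; a 10-unit gap spans the "very likely to fail" to "very likely to
pass" range.

EAP scoring evaluates prior × likelihood on an equally spaced quadrature
grid (601 nodes over prior mean ± 15 D for a single child; the batch
scorer uses one shared grid at the same 0.05 D node spacing, which is
numerically equivalent and vectorises). The D-score is the posterior
mean, the reported SEM its posterior SD; a child-round with no scoreable
responses returns the prior unchanged. The default prior is built in two
passes: a flat pass (normal, SD 50, grid spanning the difficulty range)
followed by a normal prior centred on a median curve smoothed against
$\sqrt{\text{age}}$ with SD 5 D — stabilising children seen on very few
items without overwhelming the data.

## The LMS age reference and DAZ

The age-conditional distribution of D-scores is modelled by the LMS
(Box–Cox) family: at age $t$, $z = ((y/M(t))^{L(t)} - 1)/(L(t)S(t))$ is
standard normal, with median $M$, coefficient of variation $S$ and
Box–Cox power $L$. No LMS fitter is available among the package's
dependencies, so the penalized-likelihood backfitting algorithm is
implemented directly: each cycle takes a Fisher-scoring step per curve
(analytic Box–Cox-normal scores, with the $L \to 0$ limit handled) and
smooths the working variate with a fixed-df smoothing spline. Defaults:
effective df 3 (L), 5 (M), 3 (S); age smoothed on a square-root axis to
stabilise infancy curvature; a +1 D offset applied before the fit (the
Box–Cox form needs positive values near age zero) and inverted on
output. With $L$ fixed at 1 the model reduces exactly to a normal
heteroscedastic fit, which the tests exploit as an algebraic check.
`daz()` and `daz_inverse()` interpolate the monthly curves linearly and
round-trip to numerical precision; ages outside the reference support
are refused rather than extrapolated.

## Validity analyses

* **Discriminant**: mean DAZ compared across low birth weight (< 2.5 kg),
  stunting (height-for-age z < −2) and four maternal-education
  categories, per cohort-round; Welch t-tests for the binary factors
  (cell SDs are visibly unequal in real data; pooled-variance available
  by option) and one-way ANOVA F for education; cells under 10
  observations are excluded and marked.
* **Concurrent**: Pearson correlation of DAZ with age-standardised
  instrument scores. Internal standardisation is a rank-based
  inverse-normal transform (Blom offset) within sliding 3-month age
  windows, widened with a warning when thin — invariant to any monotone
  rescoring of the instrument.
* **Predictive**: DAZ in 12-month age bins at Time 1 against outcomes at
  least 2 years later, split into middle childhood (>4–9 y) and
  adolescence (>9–18 y); bins under 10 pairs suppressed.
* Correlations are classified low / moderate / strong / very strong at
  the conventional 0.20 / 0.40 / 0.60 / 0.80 bounds, closed on the left.
* **Item-subset simulation**: every child-round is scored with the full
  retained pool and with a subset, emulating a shorter instrument; the
  correlation of the two D-score vectors and the SEM inflation quantify
  the precision cost.

## The synthetic-cohort generator

The generator emulates the structure of a multi-country longitudinal
study at a size the test suite can fit in minutes: 5 cohorts × 500
children, 1–3 measurement rounds each, 4 instruments × 40 items with
staggered difficulty ranges (8–40, 24–54, 40–70, 58–82 D), and 6
cross-instrument equate groups, two of which are the anchor milestones.
Latent ability is a monotone median curve $11\sqrt{t}$ (D at age $t$
months — about 11 D at 1 month, 76 D at 48 months, head-lift near 3
months, stable sitting near 13 months) plus a stable individual effect
(SD 5 D) plus covariate shifts (−0.4 SD for low birth weight, −0.3 SD
for stunting, +0.15 SD per maternal-education step; shifts are centred
within cohort so the median child sits on the curve). The true slope is
2 D per logit. Responses are Bernoulli draws from the Rasch model;
each child answers only their round's instrument, reproducing planned
missingness. Two instruments expose native raw scoring (0/5/10 and
0/1/2 schemes) to exercise the recoding layer; Time 2 outcomes mix the
standardised latent ability with noise to hit a target correlation
(default 0.3).

Instrument ranges and round ages were fixed so that every item — in
particular every equate-group member — keeps at least 10 observations in
its minority response category under the generating model; a member
silently removed by the sparse filter would otherwise cost its group its
bridge role.

What the generator does *not* emulate: multidimensionality, local item
dependence, real DIF structure (unless injected), informative
missingness, rater effects, or floor/ceiling artefacts of real
instruments. Passing recovery tests on this generator therefore shows
the machinery is correct and calibrated under its own assumptions — not
that any real instrument pair can be equated.

## Numerical and design choices, in brief

* Sparse-item filter: an item needs ≥ 10 observations in its least
  populated category (pooled across cohorts); boundary (exactly 10) is
  retained.
* Pairwise estimation: MM + damped Newton, tol `1e-8`, smoothing 0.05 on
  one-sided zeros, mean-zero over clusters.
* Fit-statistic abilities: flat-prior EAP on the logit scale.
* DIF: threshold 0.5 logits, $\alpha$ 0.05, cluster-robust SE, min 30
  wins and losses per group.
* Quadrature: 0.05 D node spacing, span ± 15 D around the prior mean
  (flat pass: difficulty range ± 15).
* LMS: df (3, 5, 3), square-root age axis, +1 D offset, 50 backfit
  cycles max.
* Problem sizes in the test suite (500 children per cohort for the
  end-to-end fit, 5 000 scores for reference calibration, 1 000 null
  replicates for test calibration) were chosen as the smallest sizes at
  which the targeted tolerances are comfortably identifiable.

## Known limitations

* The pairwise pseudo-likelihood discards concordant information; it is
  consistent but not fully efficient, and its naive information matrix
  understates variance (hence the robust SEs in the DIF screen; the
  difficulty estimates themselves are reported without standard errors).
* Activation screening is heuristic by necessity; the 0.5-logit range
  and 1.2 fit cutoffs are defaults, not laws, and the activation list is
  overridable.
* The LMS backfitting uses diagonal expected information (no L–M–S
  cross-terms); adequate at these smoothing levels but slower-converging
  than a full Newton.
* `internal_standardize` is O(n²) in the worst case; fine at cohort
  sizes, not meant for biobank-scale inputs.
* D-scores near the Box–Cox boundary rely on the configured offset; very
  negative scores (possible under a flat prior with all-fail patterns at
  young ages) should be screened before reference fitting.
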