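---
title: "Comparing symptom networks across groups with moderated network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing symptom networks across groups with moderated network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Item-level symptom data — here nine depression items (PHQ-9), seven
generalised-anxiety items (GAD-7) and four work/social functioning items
(WSAS 2–5; the ability-to-work item is excluded because it is routinely
not applicable outside employment) — can differ between population groups
in two distinct ways:

* **intercepts**: a group's adjusted mean level of a symptom, controlling
  for age, gender and all other symptoms; and
* **partial associations (edges)**: the conditional association between
  two symptoms given all other symptoms and the covariates — the
  network's "co-occurrence" structure.

`mnmcompare` estimates both kinds of group difference for *every* pair of
groups (up to the 11-group, 55-pair design typical of UK
ethnicity-coded service data), and attaches permutation-based empirical
p-values.

## The model

For node $s$ with z-scored score $y_s$, group factor $g$ (reference
group $r$), and covariates age ($z$-scored) and gender (0/1), each
nodewise regression is

$$
y_s = \beta_{0s} + \sum_{t \neq s} \beta_{st}\, y_t
    + \sum_{g \neq r} \gamma_{sg}\, \mathbb{1}[G = g]
    + \sum_{t \neq s}\sum_{g \neq r} \delta_{stg}\, y_t\, \mathbb{1}[G = g]
    + \eta_1\, \mathrm{age} + \eta_2\, \mathrm{gender} + \varepsilon_s .
$$

All 20 regressions together form the moderated network (the disjoint
pseudolikelihood / nodewise approach): $\beta_{st}$ are the reference
group's directed edge weights, $\gamma_{sg}$ the group intercept
differences and $\delta_{stg}$ the group edge differences. Every node is
treated as a continuous Gaussian conditional — the simplest specification
under which the nodewise fits are exactly linear regressions.

Each regression is fit by the LASSO over a decreasing penalty path, and
the path point is selected by the Extended Bayesian Information Criterion

$$
\mathrm{EBIC}_\gamma = n \log(\mathrm{RSS}/n) + d \log n + 2\gamma d \log p,
$$

with $d$ the number of nonzero coefficients and $p$ the number of
candidate predictors. Ties are broken toward the larger penalty (the
sparser model). The EBIC is evaluated on the penalised fit's residual sum
of squares, matching the convention of the estimation software this
design follows.

An unordered edge $(s,t)$ has two directed estimates ($t$ in $s$'s
regression and vice versa). The **AND-rule** declares the edge present
only when both are nonzero, with value their arithmetic mean; an OR-rule
variant is available. "Nonzero" means magnitude above $10^{-10}$,
guarding against floating-point dust after path selection.

## All pairwise contrasts by reference rotation

A single fit only contrasts each group against the reference. The package
therefore refits the model once per group (`rotate_references()`). For a
pair $(a, b)$ this yields two direct estimates of every difference: $b$'s
dummy/interaction coefficients in the fit with reference $a$, and the
sign-flipped $a$ coefficients in the fit with reference $b$. A genuine
difference is declared only when *both* estimates are nonzero (the
AND-rule again, at rotation level), and the combined estimate is their
mean, oriented as group $b$ minus group $a$.

Two properties anchor the implementation and are enforced by tests:

* at zero penalty the two rotation estimates are *identical* (linear
  reparameterization invariance), which requires reporting dummy and
  interaction coefficients on their natural column scale rather than
  per-column standardized units (column SDs differ between rotations when
  group sizes are unequal). Items and age are z-scored cohort-wide;
  column standardization is applied only *inside* the penalised fit so
  the L1 penalty stays scale-equitable, and coefficients are reported
  back on the design-column scale (the `glmnet` convention);
* `contrast(a, b)` and `contrast(b, a)` are exact sign-flips of each
  other.

Significant differences are summarised per group pair as proportions: out
of 20 symptoms for intercepts, and out of the 380 *ordered* co-occurrence
slots ($20 \times 19$) for edges. A detected edge difference is an
unordered object here, so it occupies two ordered slots and the
proportion is identical under the unordered convention ($2k/380 =
k/190$); both counts are emitted. Percent differences for heatmaps use
the symmetric form $200(x - y)/(|x| + |y|)$ — the standard symmetric
percent difference with exactly the $[-200, 200]$ range, clamped at the
endpoints against one-ulp overshoot, and defined as 0 when both estimates
are 0. Values of magnitude $\ge 100$ mean one group's estimate is near
zero relative to the other (presence vs absence of an edge).

## Permutation inference

The null hypothesis "no group differences at all" is simulated by
shuffling group labels across persons (covariates stay attached to their
rows, so covariate–group structure is broken while remaining adjusted for
in each refit) and refitting the full rotation ensemble $B$ times
(default $B = 100$). Empirical p-values use add-one smoothing,

$$
p = \frac{1 + \#\{|T^{(b)}| \ge |T_{\mathrm{obs}}|\}}{B + 1},
$$

which is valid at finite $B$, counts ties as extreme, bottoms out at
$1/(B+1)$, and returns $p = 1$ whenever the observed combined estimate is
0 (undetected contrasts). P-values are computed for every individual
parameter and for the aggregate per-pair counts of detected differences;
no multiple-testing correction is applied to individual p-values — the
aggregate comparison is the primary inferential surface, and the default
significance call for reporting is the *conjunction* of the AND-rule flag
and $p < \alpha$ (each criterion is also reported separately).

A chi-square goodness-of-fit test asks whether estimated edge counts are
uniform across groups: each group's edge count is averaged over the $G$
rotated fits (the single-fit alternative is available by passing one fit),
the expectation is total$/G$, and $\mathrm{df} = G - 1$. Uniform
expectation is the only reading compatible with that df.

## The synthetic-cohort generator

Because the service data this methodology targets are not publicly
deposited, the generator (`build_truth()` + `sample_cohort()`) emulates
their statistical structure with known ground truth:

* group-specific item means (base means near instrument midpoints — 1.6
  for the 0–3 items, 4 for the 0–8 items — plus planted shifts in item-SD
  units);
* group-specific sparse partial-association networks (base density 0.15
  of the 190 item pairs, weights 0.1–0.25 with random signs, plus planted
  edge shifts);
* linear age and gender effects on item means (slopes uniform in
  $\pm 0.15$); age uniform on [18, 80], gender Bernoulli(0.65), echoing a
  predominantly female service population;
* optional (default on) ordinal realism: scores rounded and clipped to
  their instrument ranges;
* optionally unbalanced group sizes, echoing the two-orders-of-magnitude
  spread (≈65,000 vs ≈2,700) of the motivating cohort.

Positive definiteness of every group's implied precision matrix is
enforced by one deterministic diagonal ridge shared across groups (until
the minimum eigenvalue exceeds 0.05); realized partials are then the
configured values divided by a common factor $1 + \mathrm{ridge}$, and
the stored truth and planted registry always hold the realized values.
Configurations needing a ridge above 1 are rejected as infeasible.

One planted shift on a group moves it away from *every* other group, so
the full oracle of implied pairwise differences
(`planted_differences()`) is a superset of the designated planted slots
(`$planted_registry`); recovery is always scored against the full oracle.

What the generator does **not** emulate: the empirical marginal
distributions of real instrument items beyond rounding (no
item-response-theory measurement model, no copula), missing-data
mechanisms (cohorts are complete-case by construction), or moment
matching to any published descriptive table. Passing recovery and
calibration tests therefore demonstrates correctness of the estimator and
inference machinery under the assumed Gaussian-conditional structure, not
robustness to real-data ordinality or missingness.

## Numerical choices

* Penalty path: $\lambda_{\max}$ is the largest absolute standardized
  predictor–response inner product divided by $n$; 50 log-spaced values
  down to $\lambda_{\max}/1000$.
* EBIC $\gamma = 0.25$, the customary default of the estimator family
  this follows; $\gamma = 0$ recovers BIC. All coefficients are
  penalised by default (covariates can be unpenalised via a setting).
* A path value of exactly 0 is solved as the unpenalised least-squares
  problem by QR — the LASSO solution at zero penalty — so the
  zero-penalty oracle identities hold to machine-level accuracy.
* Degenerate inputs: constant design columns are left at zero when
  standardizing; groups with fewer than 2 members, non-positive-definite
  truths, zero total edge counts (chi-square) and empty post-filter
  cohorts are rejected with informative errors.
* Sub-seeds derive from the master seed by fixed offsets (cohort $+1$,
  truth $+2$, permutation $b$: $+7919b$, all modulo $2^{31} - 19$), so
  every stage and every permutation is independently reproducible.

## Detection characteristics and known limitations

The AND-rule composition is deliberately conservative, and markedly more
so for edge differences than for intercept differences. An intercept
difference is one dummy coefficient per rotation; an edge difference must
survive selection in **four** regressions (two directions × two
rotations). Moreover, in the rotation whose reference *is* the shifted
group, a single edge difference must be represented by $G - 1$ separate
interaction coefficients, multiplying its EBIC cost: a 0.2 partial
shift carried by one group of 2,000 yields a likelihood gain close to the
selection cost of those coefficients, so that rotation frequently
selects none of them and the AND-rule then discards the difference. In
the packaged calibration scenarios (G = 4, n = 2,000/group; see
`scripts/acceptance.R` and the test suite) intercept shifts of 0.4 SD
are recovered with sensitivity 1.0 and specificity ≈ 1.0, while
0.2-partial edge shifts are detected far less often — the same asymmetry
(many intercept differences, few edge differences) that motivates
interpreting edge findings at the aggregate level. False-positive
behaviour is excellent: on null cohorts the proportion of parameters
with $p < 0.05$ and the per-pair detected counts are essentially zero.

Problem sizes used in the packaged validation were chosen to make the
statistical behaviour visible at desk scale: null calibration at
G = 4, n = 1,000/group, B = 50 permutations; recovery at G = 4,
n = 2,000/group; closed-form oracles at n = 200–400. Larger runs change
precision, not structure.

Other limitations: no categorical or count node families; no three-way
symptom interactions; no cross-validated penalty selection; no bootstrap
stability analysis (the permutation machinery tests group differences,
not parameter stability); heatmap matrices are exported for plotting
rather than reproducing any particular published figure style.
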