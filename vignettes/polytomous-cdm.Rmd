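---
title: "Cognitive diagnosis with polytomous attributes: models, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive diagnosis with polytomous attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical cognitive diagnosis models (CDMs) classify examinees as masters
or non-masters of each skill ("attribute") measured by a test.  In many
instructional settings a binary split is too coarse: a student may be
unable to compare fractions, able to compare two fractions, or able to
order several — three ordered mastery levels of one attribute.  `spcdm`
models binary item responses driven by such *polytomous* attributes, each
attribute $k$ taking levels $0, 1, \dots, M_k - 1$, with possibly unequal
$M_k$ across attributes.

A test of $J$ items is described by a polytomous Q-matrix: entry $q_{jk}$
is the level of attribute $k$ that item $j$ requires (0 = not required).
The $C = \prod_k M_k$ full level patterns are the *latent classes*.  An
item cannot distinguish classes that agree on its required attributes;
the equivalence classes of this relation are the item's *latent groups*,
and the item response function assigns one success probability per group.

## The saturated model and its special cases

Let $\alpha^*_{lj}$ denote latent group $l$ of item $j$.  The saturated
model gives every group its own success probability via a linear predictor
on a chosen link scale,

$$ f\!\left(P_j(\alpha^*_{lj})\right) = \delta_{j0}
   + \sum_{k} \sum_{m\ge 1} \delta_{jkm}\, I(\alpha_k \ge m)
   + \text{interaction terms}, $$

with $f$ the identity, logit, or log link.  The package codes main effects
as *cumulative step indicators* $I(\alpha_k \ge m)$, so $\delta_{jkm}$ is
the increment earned by reaching level $m$ from $m-1$; steps between
adjacent levels may differ.  Interaction columns are indexed by an
attribute subset and one step level per member, which yields exactly
$\prod_{k:\,q_{jk}>0} M_k$ columns — a square, invertible design, so the
saturated parameter vector and the group probability vector are in
one-to-one correspondence (the parameter count depends only on the
*maximum* levels of the required attributes, not the required levels).
Dummy coding $I(\alpha_k = m)$ spans the same saturated space; the coding
choice only matters for the semantics of reduced models, and the
cumulative convention matches the reading of the additive model in which
each mastered step independently raises the success probability.

Reduced models are column subsets (or collapsings) of this design:

| kind | columns | parameters |
|---|---|---|
| `saturated` | all | $\prod M_k$ |
| `pgdina` | G-DINA design on collapsed indicators $d_k = I(\alpha_k \ge q_{jk})$ | $2^{K^*_j}$ |
| `fam` (fully additive) | intercept + all step columns | $1 + \sum (M_k - 1)$ |
| `min-fam` | steps with $m \ge q_{jk}$ | $1 + \sum (M_k - q_{jk})$ |
| `max-fam` | steps with $m \le q_{jk}$ | $1 + \sum q_{jk}$ |
| `conjunctive` | intercept + $I(\text{all } d_k = 1)$ | 2 |
| `disjunctive` | intercept + $I(\text{any } d_k = 1)$ | 2 |

With all $M_k = 2$ these reduce exactly to the dichotomous G-DINA, DINA,
DINO and additive CDMs.  The `pgdina` collapse embodies the
specific-attribute-level-mastery assumption: an item splits each required
attribute only into at-or-above versus below its required level.  The
additive column set under the logit or log link gives the logit-additive
and log-additive models (the polytomous analogues of compensatory
logistic and non-compensatory multiplicative models).  An optional
equal-steps constraint merges each attribute's step columns into one,
forcing a common step size.

## Estimation

Parameters are estimated by marginal maximum likelihood with an EM
algorithm over the latent classes.  The E-step computes class posteriors
$P(c \mid \mathbf{x}_i) \propto \pi_c \prod_j P_{jc}^{x_{ij}} (1 -
P_{jc})^{1 - x_{ij}}$ (log-sum-exp, with probabilities floored at
$10^{-10}$ *inside likelihoods only* — reported estimates are unfloored)
and aggregates expected per-group sample sizes $N_{jl}$ and correct counts
$R_{jl}$.  The M-step is $\hat P_{jl} = R_{jl} / N_{jl}$ for saturated
items and a design-matrix weighted Bernoulli maximization (BFGS with a
quadratic box penalty keeping probabilities in $[\varepsilon,
1-\varepsilon]$, $\varepsilon = 10^{-4}$) for reduced models.  The class
proportions $\pi$ are estimated as a saturated multinomial (mean
posterior) by default; `fix_pi_uniform` holds them at the generating
uniform distribution for exact-replication experiments.

**Monotonicity.**  When `monotone = TRUE` (the default, matching the
simulation protocol; real-data analyses may switch it off) the M-step
enforces non-decreasing success probabilities along the latent-group
partial order (one level up on one required attribute).  For saturated
items this is a weighted adjacent-violator pooling over the partial
order; for reduced models a quadratic penalty on violations.  Pooling on
a partial order is not always the exact constrained maximizer, so every
item update is *ascent-guarded*: it is accepted only if it improves that
item's complete-data likelihood, otherwise the previous value is kept.
This makes the algorithm a generalized EM, and the marginal log-likelihood
trace is non-decreasing by construction (asserted in the tests at
tolerance $10^{-8}$).

**Numerical choices.**  Convergence requires both the maximum absolute
change in any group probability below `tol_p` ($10^{-4}$) and the relative
log-likelihood change below `tol_ll` ($10^{-7}$), capped at 2000
iterations.  Initial group probabilities are linearly spaced from 0.2 to
0.8 along each item's monotone group order with a small seeded
perturbation ($\pm 0.05$, `init_seed`) to avoid symmetric stationary
points; warm starts are supported (`init_probs`, `init_pi`), and
refitting from a solution converges immediately.  Latent groups with
expected size below $10^{-3}$ keep their previous value.  MAP ties break
to the lowest pattern index for determinism.

Standard errors use the empirical cross-product of per-examinee
incomplete-data scores (via Fisher's identity), per item block; singular
blocks — e.g. an empty latent group of a saturated item — are flagged
unavailable rather than given fabricated values.  Model comparison uses
deviance, AIC and BIC with the parameter count equal to the summed item
design columns plus the $C - 1$ free class proportions.  Whether
structural parameters belong in the count is a convention; including them
is consistent across models with a common attribute space and therefore
does not affect model orderings, which is what the comparison is for.

## What the simulation engine emulates

The generator mirrors a three-level-attribute Monte Carlo design:
attribute patterns drawn uniformly over all $\prod M_k$ classes; item
quality controlled by guessing $g$ and slip $s$ with $s = g$ (high
$g = .05$, moderate $.10$, low $.15$); main-effect sizes averaging .16 /
.15 / .13 and interaction effects .10 / .08 / .07 for the three quality
levels.  Because per-parameter generating values are published only as
class means, the package uses a deterministic scheme: every main effect
gets its class mean, every interaction its class mean, then all
non-intercept effects are rescaled by a common factor so the most capable
group's probability is exactly $1 - s$.  Item quality is thus controlled
exactly and reproducibly; the cost is that generated items have equal
steps within an effect class, which real calibrations would not.

Sample sizes default to $N \in \{1000, 2000\}$ with test lengths
$J \in \{26, 52\}$ and $K \in \{3, 5\}$ three-level attributes.  The
26-item Q-matrix is built by the `balanced` template: two single-attribute
items for every attribute level (the coverage heuristic required for
identifiability), then two- and three-attribute items cycling through
level combinations; the 52-item form duplicates it row for row.
Replication seeds derive from one root seed by a fixed splitting rule
(`seed * 1009 + condition * 100003 + generator * 101 + rep * 7919`, mod
$2^{31} - 19$), so studies are exactly reproducible.

Passing tests under this generator show that the estimator recovers the
data-generating process it assumes — uniform classes, items exactly at
their quality endpoints, no misfit between the Q-matrix and behaviour.
They do not establish robustness to correlated or skewed attribute
distributions, Q-matrix misspecification, or missing responses, none of
which the generator produces.

## Evaluation metrics

Recovery is summarized by per-item bias (mean over groups of the
replication-averaged error) and RMSE.  Two RMSE conventions are
implemented because the literature uses both: `per_rep` (default), the
across-replication root-mean-square error averaged over groups, measures
the sampling variability of a single calibration; `mean_estimate`, the
RMS across groups of the replication-*averaged* error, measures the
residual systematic error of the estimator and shrinks with the number of
replications.  Published recovery tables whose RMSEs fall well below the
single-replication binomial noise floor are reporting the second
quantity, and the package's replication checks therefore use
`mean_estimate` there.

Classification accuracy is PCA (percent of correctly classified
attribute levels, per attribute) and PCV (percent of exactly matched
whole vectors); PCV $\le \min_k$ PCA$_k$ always.  MAP classification is
used for these summaries (EAP marginals are available).  Fitted models on
the same data are compared by the posterior-weighted RMSD per item,
$\mathrm{RMSD}_j = \sqrt{\sum_l w_{jl}\, (\hat P^{(m)}_{jl} - \hat
P^{(m')}_{jl})^2}$, where $w_{jl}$ is the reference (saturated) fit's
expected posterior mass of group $l$ divided by $N$.

## Problem sizes used in the bundled checks

The package's replication checks run the four high-quality,
three-attribute true-model conditions ($J \in \{26,52\} \times N \in
\{1000, 2000\}$) at 25 replications, plus a 6-replication
misspecification study (additive model under-fitted to saturated data and
vice versa); these sizes keep a full check run in a few minutes on one
core while leaving Monte-Carlo error well below the effects being tested.
A known limitation is that no transcribed reference Q-matrix is bundled
(`make_qmatrix(template = "paper")` errors unless one is supplied), so
the `balanced` template stands in; with it the 26-item conditions carry
limited information — even classification with the *true* parameters
attains only ≈ 89% PCA / 72% PCV there — which should be kept in mind
when comparing 26-item results across studies that used a different
design matrix.  Other known limitations: no polytomous responses, no missing
data, no higher-order or correlated attribute structure, and
cross-item-block standard errors are out of scope.
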