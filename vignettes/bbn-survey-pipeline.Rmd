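---
title: "Modeling sleep, physical activity and self-reported stroke with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sleep, physical activity and self-reported stroke with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokebbn)
```

## The model

`strokebbn` analyses categorical health-survey data with discrete Bayesian
belief networks. A network is a directed acyclic graph over the survey
variables together with one conditional probability table (CPT) per
variable; the joint distribution factorizes as

$$P(x_1,\dots,x_V) = \prod_{v=1}^{V} P(x_v \mid \mathrm{pa}(x_v)).$$

Two structure classes are learnt. *Naive Bayes* (NB) makes the outcome
(self-reported stroke) the sole parent of every covariate. The
*tree-augmented naive Bayes* (TAN) relaxes the NB independence assumption
by adding a spanning tree of covariate–covariate edges, found by the
Chow–Liu construction: every covariate pair $(X_i, X_j)$ is weighted by its
conditional mutual information given the outcome $C$,

$$I(X_i; X_j \mid C) = \sum_c \hat p(c)\, I(X_i; X_j \mid C = c),$$

and the maximum-weight spanning tree is oriented outward from the
lexicographically first covariate. Each covariate then has at most two
parents (the outcome plus one covariate), which keeps exact inference
linear in the number of variables while capturing the strongest pairwise
dependence among correlates.

Model choice between NB and TAN uses a minimum-description-length (MDL)
score: the data code length $\sum_i w_i(-\log_2 P(x_i))$ in bits plus the
BIC-style parameter cost $(K/2)\log_2 N$, where
$K = \sum_v (r_v - 1)\prod_{p\in\mathrm{pa}(v)} r_p$. Commercial tools
attach additional structure-coding terms to their MDL; those differ by
model-independent constants and bounded structure terms, so *rankings* of
candidate structures — the only thing the pipeline consumes — are
comparable, while absolute scores are not.

CPT rows are estimated with Laplace smoothing,
$(\text{count} + \alpha)/(\text{total} + \alpha r)$, default
$\alpha = 1$. With a 3% outcome prevalence and covariates of up to seven
states, rare-class rows are sparse; $\alpha = 0$ would produce zero cells
that break log-loss scoring and imputation.

## Observational inference: dynamic vs fixed

Given evidence $e$ (for example a sleep duration and an activity
regimen), *dynamic* inference is ordinary conditioning,
$P(C \mid e)$, computed exactly by variable elimination; every other
covariate updates with the evidence, so the answer includes whatever the
evidence indirectly implies about age, health status and the rest.

*Fixed-probability* inference is the package's confounding control. With
$Z$ the variables outside the target and the evidence, it standardizes
over the baseline joint of $Z$:

$$P_{\text{fixed}}(C \mid e) = \sum_z P(Z = z)\, P(C \mid e, Z = z),$$

restricted and renormalized to the $z$ compatible with the evidence. This
is a deliberate interpretation: the originating tool's "fixing" of
probability distributions is proprietary and not publicly specified, and
we operationalize its stated purpose — holding the distribution of the
other correlates at the baseline while the evidence varies — as covariate
standardization over the *joint* baseline of the fixed set (not the
product of its marginals, so covariate–covariate dependence is
respected). When the fixed set's state space has at most $10^6$
configurations the sum is enumerated exactly; otherwise $z$ is
forward-sampled from the baseline network (seeded; default $10^5$
samples), the conditional averaged, and samples with
$P(e, z) = 0$ skipped and counted in the diagnostics. Standardized
responses are typically attenuated relative to conditioning when the
evidence is positively confounded with the outcome, which is why the
profile tables default to the more conservative fixed mode.

## Validation metrics

Classification uses the exact posterior of the outcome given all
covariates. Four test-set summaries are reported as percentages:

* **precision** — share of records whose MAP prediction is correct;
* **reliability** — truth-weighted mean of per-class predictive values,
  $\sum_k (n_k/n)\,\mathrm{PPV}_k$. This is an interpretation of a tool
  term: the natural "prediction-weighted PPV" reading collapses
  algebraically to precision, so it cannot be what a tool reporting the
  two numbers separately computes; truth-weighting preserves the contrast;
* **ROC index** — area under the ROC curve of the positive-class scores,
  computed by midranks (ties averaged), invariant under monotone score
  transforms;
* **lift index** — area under the model's cumulative-gains curve divided
  by the ideal ranking's area, another interpretation chosen so that a
  near-perfect ranking scores near 100.

The association screen reports, per covariate: mutual information with the
outcome in bits; *normalized* MI as a share of the outcome's maximum
entropy $\log_2 r_C$ (for a binary outcome this is just $100 \times$ MI);
*relative* MI as a share of the outcome's realized entropy; Pearson
correlation on the canonical integer state codes (which is why ordered
covariates must list their states in natural order — negative correlations
are meaningful only under ordinal coding); and a G-test p-value with
$G = 2N\ln(2)\,I$ on $(r_X-1)(r_C-1)$ degrees of freedom. Back-calculation
of the two non-zero printed p-values in the published correlate table is
consistent with $N$ being the learning-set size (231,111), which the
package therefore uses in its identity checks.

## The synthetic survey generator

No survey microdata ships with the package. The generator builds a TAN
ground truth over the 34-correlate schema (cardinalities recovered from
the published degrees of freedom, states = df + 1) plus the binary stroke
target and samples records ancestrally:

* the target is a root whose marginal equals the configured prevalence
  (default 0.0307) *exactly*, by construction;
* the covariate tree is a seeded random attachment tree (each feature
  joins a uniformly chosen earlier one). This is not uniform over labeled
  trees, which is irrelevant here: recovery experiments only need a known,
  reproducible tree;
* dependence strength is parameterized as total-variation distance
  between CPT rows. A row is shifted toward a direction state $k$ by
  exactly $d$ in total variation via
  $p' = (1-\lambda)p + \lambda e_k,\ \lambda = d/(1 - p_k)$; direction
  states differ across conditioning states so rows are distinguishable.
  Defaults (target effect 0.15, tree effect 0.25 TV) give adjacent-pair
  conditional MIs comfortably above the sampling noise at the sample
  sizes used in the tests, so skeleton recovery is well-posed;
* missingness is MCAR per variable (default 2%, the outcome exempt). The
  source study reports no missingness mechanism or rates; 2% is a
  conventional order of magnitude for well-fielded interview items and is
  fully configurable. Only MCAR is implemented.

The `jshape_sleep` option calibrates the sleep CPT from the published
composition of cases — sleep given no stroke ≈ (29.0%, 62.3%, 8.7%) and
given stroke (30.4%, 48.9%, 20.7%) — which makes the posterior
P(stroke | sleep) J-shaped: average < short < long. In this mode the sleep
variable deliberately stands *outside* the covariate tree (outcome parent
only): its likelihood ratio then multiplies the posterior odds identically
under any covariate profile, so the J-shaped ordering provably holds
within every age–sex–activity stratum, not merely marginally. With sleep
inside the tree, sleep-conditioned child CPTs can reverse the ordering in
some strata for some seeds, which would make a qualitative invariant
seed-dependent.

What passing tests on this generator do **not** show: real NHIS marginals
(only the target prevalence and cardinalities are matched), informative
missingness, survey-design effects (weights are carried through all
counting but no NHIS-specific calibration is attempted), or measurement
error in self-reports.

## Imputation

Missing cells are filled with their exact posterior-mode state given the
record's observed cells. Records are grouped by missingness pattern; each
pattern's joint completions are enumerated and evaluated vectorized over
the pattern's records (only CPT families touching a missing variable are
re-evaluated per completion). A record whose completion space exceeds
`max_combos` (default $10^4$) falls back to deterministic iterative
conditional modes, and all-missing records are filled from the prior
marginal modes; both cases are counted in the diagnostics attribute.
Multiple passes re-fit the CPTs on completed data and re-impute the
original holes, approximating an EM sweep; one pass is the default and is
what the pipeline uses before its final refit.

## Numerical and design choices

* CPT rows are stored in linear space; all record-level likelihoods are
  accumulated in $\log_2$ space, so 35-variable products do not
  underflow.
* CPT row order follows `expand.grid()`: the first parent varies fastest.
* Chow–Liu ties are broken lexicographically (edge weights sorted by
  decreasing weight, then by variable names) and the tree root is the
  lexicographically first feature, so learning is deterministic.
* Sleep reports round half-hours up and smaller remainders down (6h45 →
  7h, 6h05 → 6h). The source text also mentions *dropping* sub-half-hour
  reports, contradicting its own worked example; rounding down is the
  default and a `strict_drop` flag restores the dropping behavior.
* Whole-hour sleep bins make "long > 8 h" and "long ≥ 9 h" identical; the
  stored bin edge is ≥ 9.
* Activity-duration boundary minutes belong to the bin whose printed
  label contains them ("10–30" includes 10 and 30; "31–60" includes 60).
* Every random operation takes an explicit seed and restores the caller's
  RNG stream; the pipeline derives stage seeds from one master seed and
  logs them.
* The train/test split takes `floor(n × fraction)` test records, so the
  288,888-record design splits to exactly 231,111 / 57,777.

## Problem sizes used in the checks

The automated checks run at sizes chosen to make their statistical
contracts sharp while staying desk-scale: skeleton recovery uses 20
replicates of 8 features at $n = 50{,}000$; model selection 20 replicates
at $n = 20{,}000$; imputation $n = 50{,}000$ at 10% MCAR; the end-to-end
pipeline $n = 100{,}000$ over the full 35-variable schema. Parameter
recovery (max CPT error < 0.01) runs at $n = 200{,}000$ on a *balanced*
generator (binary features, prevalence 0.5): at a 3% prevalence the
rare-class rows would have so few effective observations that the 0.01
bound is unreachable by any estimator — a sampling floor, not an
implementation property.

## Limitations

The fixed-mode standardization is one defensible reading of a proprietary
procedure; reliability and lift index are likewise documented
interpretations. The headline published validation numbers (precision
95.84/96.24/96.09%, reliability 95.46/95.19%, ROC 86.46/86.21%, lift
99.52%, and the per-profile prevalence table) were produced on the actual
288,888-record NHIS extract, which is not distributable here; the package
reproduces the *method* and its in-table arithmetic identities, and
demonstrates the qualitative phenomena (J-shaped sleep effect,
fixed-below-dynamic attenuation, 36-profile enumeration) on synthetic
data. Continuous nodes, temporal networks, general DAG search, soft
evidence and MNAR missingness are out of scope.
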