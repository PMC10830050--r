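---
title: "Methods: audience segmentation with response-style correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audience segmentation with response-style correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audseg)
```

# The analysis model

`audseg` implements a complete attitudinal audience-segmentation pipeline
for Likert-type survey data. The underlying measurement model is a linear
factor model: respondent $r$ holds a vector of latent attitude factor
values $f_r$, and item $i$ (belonging to one factor, with signed loading
$a_i$) is answered as a discretized version of $a_i f_{r}$ plus noise.
Segments are groups of respondents sharing a common factor centroid. Two
response *styles* sit on top of this content model:

* **straight-lining** — a respondent gives one constant answer across the
  attitude blocks (inattention); and
* **acquiescence** — a respondent's answers are shifted toward the
  agreement pole of the scale across the agree/disagree batteries,
  regardless of item content, most strongly in some blocks. Blocks where a
  constant or uniformly-high answer is a *reasonable* response (life
  satisfaction, behaviour frequency) are exempt from both the screening
  rules and the style model.

The pipeline runs: screening → dual-mode standardization → factor scoring
→ hybrid segmentation → profiling → predictive validation.

## Screening (`qc_screen`)

Respondent-level means and sample variances (denominator $n-1$) are
computed per item block. A respondent is removed when

* variance $\le$ `var_eps` in at least `min_invariant_blocks` non-exempt
  blocks, or over all non-exempt items pooled (invariant respondents); or
* some non-exempt block is simultaneously low-variability and
  high-mean (block mean $\ge$ `high_mean_quantile`): agreement with
  essentially every statement in a battery that contains reverse-keyed
  items is a style signature, not an attitude.

No canonical numeric thresholds exist for these rules, so the defaults are
deliberately conservative analyst choices, all exposed in configuration:
`var_eps = 0` (strictly invariant only), `min_invariant_blocks = 3`,
`high_mean_quantile` = scale maximum $-$ 0.25. With integer Likert codes,
`var_eps = 0` means literal constancy, which keeps the false-flag rate on
attentive respondents essentially nil while catching every straight-liner
(they are constant in *all* non-exempt blocks). Elapsed-time ("speeder")
filtering is deliberately out of scope: it is a fieldwork-level remedy and
does not address acquiescence.

## Dual-mode standardization (`standardize_responses`)

Items of ordinary blocks are z-scaled by question (column mean 0, sample sd
1). Items of the designated acquiescence-prone blocks are instead scaled
*within respondent* (ipsative): centered on the respondent's own mean over
those items and divided by the respondent's own sd. This removes the
respondent-specific location (and spread) of scale use — the algebraic
signature of acquiescence — while preserving the within-person pattern of
agreement, which is where the attitudinal signal lives provided the blocks
contain reverse-keyed items. Respondent-level scaling is exactly invariant
to adding any constant to a respondent's raw answers; the test suite
asserts this identity directly.

Which blocks are designated is a *required* configuration decision (the
default questionnaire designates its two concern batteries): the remedy
only makes sense for blocks where scale-usage heterogeneity is evident,
and it sacrifices the between-person location information of those blocks.
After the dual-mode pass, question-mode columns are exactly (0, 1) by
construction; respondent-mode columns are only approximately so, and
`standardization_diagnostics()` reports how close they come. Missing
values are excluded pairwise; no imputation is performed.

## Factors (`score_factors`, `cronbach_alpha`, `fit_efa`)

Factor scores are signed-loading weighted sums of standardized items,
renormalized to unit sd; a negative loading reverse-codes its item.
Cross-loading items may appear in several factors — the factors feed a
cluster analysis, not a structural model, so shared variance between
factors is acceptable. Reliability is Cronbach's alpha computed after
flipping negatively-keyed items, with 0.7 as the adequacy threshold;
`refine_to_reliable()` performs a greedy single-item drop/add search that
stops at the first model reaching the threshold. Exploratory factor
analysis uses iterated principal-axis extraction (communalities start at
squared multiple correlations) with oblimin rotation by default — attitude
factors are expected to correlate — or varimax; both the extraction and
rotation are implemented in the package and verified by simulation
recovery (mean Tucker congruence against a known loading structure).
Second-order ("meta") factors are available for compressing a large,
partly redundant factor set before clustering; the default pipeline scores
the ten shipped factor definitions directly, since the final rebuild
procedure works from a fixed reliable factor set.

## Hybrid segmentation (`build_segments` and friends)

The default path is: mark the `central_fraction` (default 2%) most neutral
respondents (smallest radius in factor space, ties broken by respondent
id); run stability-checked k-means on the remainder; append the central
group as its own segment (people without a strong or distinctive point of
view are a meaningful audience, not waste); then apply **one**
nearest-centroid reassignment pass over all respondents and segments —
exactly one iteration of k-means from the fitted centroids, which is
verified against a textbook oracle. Euclidean distance is used throughout,
and assignment ties break to the lowest segment index for reproducibility.

Stability is the mean pairwise adjusted Rand index across `n_runs`
(default 20) clustering runs; each run takes the best of `nstart`
(default 5) random initialisations so that the score reflects structural
ambiguity in the data rather than single-start initialisation luck. The
number of clusters `k` is a configuration decision, not an automatic
choice: segmentation quality is judged by stability and interpretability.
The historical audit-trail operations — MDS embedding of respondents or
centroids (`embed_mds`, classical Torgerson scaling), polar sectoring into
36 half-open sectors (`polar_sector_segments`), and reinstatement of a
lost segment from a designated seed set (`reinstate_segment`) — are
shipped as explicit workflow steps rather than being baked into the
default path, because the seed set is a judgment input that cannot be
derived from the data alone.

Booster-sample respondents (over-sampled subgroups) are held out of the
clustering and allocated afterwards by quadratic discriminant analysis:
one Gaussian per segment with its own covariance, priors equal to segment
frequencies. A numerically singular class covariance is ridge-regularized
($\lambda I$, escalating from $10^{-6}$) with a warning. The in-package
implementation exists because regularization is needed for degenerate
classes; it is cross-checked against an established QDA implementation on
well-conditioned data in the test suite.

**Rebuild matching.** Rebuilding a segmentation from a refined factor set
can never reproduce it exactly — tiny perturbations move borderline
respondents between adjacent segments. The package therefore estimates a
*move threshold* by bootstrap: resampling respondents with replacement,
recomputing centroids, and recording each respondent's potential
improvement (distance to its assigned centroid minus distance to the
nearest centroid) under the resampled geometry. The threshold is the 95th
percentile of that null distribution, and `rebuild_match_rate()` counts a
respondent as matched when the labels agree *or* the improvement from the
old label to the new one is within the threshold. On noiseless,
well-separated data the threshold collapses to zero, and it is monotone in
the requested quantile; both properties are asserted. The "improvement
under resampled centroids" definition of the bootstrap null is an
interpretation — a simple respondent-resampling bootstrap is
underspecified — and is documented here as the package's choice.

## Profiling (`build_profile_table`)

Variable-by-segment tables carry a percentage (or mean), a base size, and
a significance-letter string per cell. Columns are lettered a, b, c, … in
fixed segment order; column $j$'s string lists every column with a
*smaller* statistic whose pairwise test against $j$ is significant at the
0.05 level — so the smallest cell in a row never carries a letter.
Percentages use the pooled two-proportion z test, means the Welch
(unpooled) t test with Welch–Satterthwaite degrees of freedom: segment
variances cannot be assumed equal, and Welch is the safer default where
the pooled/unpooled choice is not dictated. No multiple-testing correction
is applied, per market-research convention — the tables are pattern
summaries, not confirmatory tests, and the per-comparison level is part of
the convention being reproduced. When weights are supplied, statistics are
weighted and tests run on Kish effective base sizes
($(\sum w)^2 / \sum w^2$), switchable off.

## Predictive validation (`fit_type3_anova`, `fit_logistic_wald`)

A summative 0–5 protective-behaviour score (masking, distancing, crowd
avoidance, handwashing, ventilation) is regressed on the segment factor
plus demographics with sum-to-zero contrasts; marginal (Type III) sums of
squares per term are assembled into the full Unianova-style table
(Corrected Model, Intercept, terms, Error, Total, Corrected Total) with
partial eta-squared $SS_{term}/(SS_{term}+SS_{error})$, $R^2$, and
adjusted $R^2$ computed from unrounded mean squares. Demographic coding
follows the conventional single-df treatment of ordinal covariates: gender
as a binary term, ethnicity as a multi-level factor (4 df at five levels),
education, income and age as numeric single-df terms. Binary outcomes
(vaccine refusal) use maximum-likelihood logistic regression with
coefficient-block Wald chi-squares, so a seven-level segment variable gets
a single 6-df test; complete separation is detected and flagged. The
combined demographic effect size is reported as the *sum* of the
demographic Type III SS against the error SS — a joint-term refit is the
alternative definition; the two differ only through predictor
non-orthogonality, and the summed version is the one the table itself
supports. Rank-deficient fits raise an error naming the aliased
coefficients rather than silently dropping terms.

# The synthetic-survey generator

No shareable microdata exists for surveys of this kind, so the generator
*is* the benchmark. Its defaults define the package's reference study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_respondents` | 5,525 | a national-survey-scale sample |
| `n_segments` | 7 | distinct attitudinal segments |
| `mixing_proportions` | (14, 14, 13, 13, 15, 21, 15)/105 | published rounded segment shares, normalised to a simplex |
| `central_fraction` | 0.02 | neutral respondents at the grand centroid |
| `noise_sd` | 0.40 | within-segment factor spread and item noise (sd, standardized units); places the nearest centroid pair about four within-segment sd apart, i.e. a stable, recoverable segmentation |
| `acquiescence_fraction` | 0.15 | roughly one cluster's worth of acquiescers |
| `acquiescence_shift` | 2 scale points | strong agreement lean on the two designated blocks |
| `acquiescence_secondary_shift` | 1 scale point | milder lean on every other attitude block; behaviour/satisfaction blocks unaffected |
| `straightliner_fraction` | 0.05 | inattentive respondents |
| `likert_levels` | 5 | agree/disagree scale |

The questionnaire design has 118 items in 12 thematic blocks measuring ten
factors (22, 35, 14, 12, 4, 6, 5, 6, 3, 5 items, plus six filler items),
every attitude block containing reverse-keyed items. The 7 × 10 factor
centroid matrix is **illustrative**: no published per-segment factor means
exist, so the centroids were designed once to match the qualitative
segment portraits (e.g. a dismissive low-trust segment, a
high-concern/low-wellbeing segment, a moderate "pragmatic" segment distinct
from the neutral core) and are not estimates of any real population.
Demographics (age, gender, ethnicity, social grade) follow published
segment-by-demographic margins; education and income gradients are
invented. Outcome rates follow the published segment-by-outcome
percentages where available (vaccination status, masking, handwashing,
distancing) and graded illustrative values for the two remaining
behaviours.

Generation draws a segment per respondent, factor values centroid +
$N(0, \sigma^2)$, item values $a_i f + N(0, \sigma^2)$, then discretizes
each item with equal-width bins over its mean $\pm 3$ sd, clipped — a
simple monotone map that reproduces floor/ceiling effects. Acquiescence is
injected *after* discretization as an integer shift clipped at the scale
maximum (the saturation behaviour of a real agree-with-everything
respondent); straight-liners repeat their first non-exempt answer. One
master seed drives deterministic per-stage substreams, so every stage is
individually reproducible.

**What passing the synthetic benchmark does and does not show.** It shows
the pipeline's internal consistency: segments that exist by construction
are recovered (the suite requires adjusted Rand index ≥ 0.8 at the default
conditions, tending to 1 as noise vanishes), the screening rules catch
injected straight-liners without flagging attentive respondents, and
ipsative standardization strictly improves recovery on acquiescence-biased
data in at least 9 of 10 paired seeds. It does not show that real
populations contain seven (or any) well-separated segments, that real
acquiescence is an additive shift, or that real factor structures match
the shipped design. Real data also carry mode effects, item non-response
patterns, weighting complexities and measurement non-invariance across
cultural groups that the generator deliberately omits.

# Numerical and scale choices

* Sample ($n-1$) variances and sds everywhere, for consistency between
  screening and standardization.
* Constant columns z-scale to 0 with a warning (configurable hard error);
  constant respondent rows ipsatively scale to 0 and are flagged.
* Distance ties in assignment break to the lowest segment index; radius
  ties in central excision break by respondent id.
* The principal-axis loop regularizes a singular correlation matrix by an
  escalating ridge and errors (with the iteration count) if it fails to
  converge within 200 iterations at tolerance $10^{-6}$.
* Oblimin rotation uses gradient projection on the oblique manifold
  (quartimin criterion), with loading-sign columns normalised so each
  factor's largest loading is positive.
* Problem sizes in the test suite are chosen to make the statistical
  assertions decisive at conventional Monte-Carlo bounds: the shared
  default-conditions population uses $n = 5{,}000$; the paired
  acquiescence comparison uses $n = 2{,}000$ per arm over ten seeds; oracle
  equivalence sweeps 50 random instances per operation.

# Known limitations

* The acquiescence model is purely location-shift; IRT-style style factors
  or multiplicative extremity styles are out of scope, matching the
  ipsative remedy implemented here.
* Ipsative scaling of a nearly one-directionally keyed block would destroy
  its attitudinal signal; the remedy presumes mixed-keyed batteries, and
  the default design guarantees them.
* `k` is not chosen automatically, by design: the method treats the number
  of segments as an interpretability judgment.
* The profile tables' letter tests are per-comparison and descriptive;
  with hundreds of cells some letters are expected by chance.
* Quota weighting to population margins is reduced to optional
  per-respondent weights; no design-based variance estimation is
  performed.
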