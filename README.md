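# audseg

Audience segmentation of Likert-type survey data with response-style
correction.

## The problem

Public-health communicators segment a population into attitudinally
homogeneous groups so messages and channels can be tailored to each group.
The standard recipe — score respondents on a set of attitude factors, run
k-means, profile the clusters — breaks down on real survey data in three
ways that this package addresses head on:

* **Inattentive respondents.** Straight-liners (the same answer to every
  item) and other low-variability respondents blur every cluster boundary.
  `audseg` screens them out with per-block variance rules on the blocks
  where a constant answer is *not* a reasonable response.
* **Acquiescence (courtesy) bias.** Some respondents agree with almost
  every statement, even mutually contradictory ones — a response *style*,
  not a response *content*, and one that differs systematically across
  cultural groups. Left uncorrected it manufactures a spurious
  "agrees-with-everything" cluster. `audseg` removes it by ipsative
  (respondent-level) standardization of the affected item blocks: each
  respondent's answers are centered on their own mean and scaled by their
  own spread, so only the *pattern* of agreement survives. For a row of
  answers `x_i`, the corrected value is `(x_i - mean(x)) / sd(x)`, which is
  exactly invariant to any additive shift of that respondent's scale use.
* **Judgment-laden clustering.** Real segmentations are built iteratively:
  k-means stability checks across many runs, a multidimensional-scaling
  map, removal (and later reinstatement) of a neutral central group,
  nearest-centroid refinement, a bootstrap-derived threshold that keeps
  borderline respondents from counting as disagreements when a
  segmentation is rebuilt from refined factors, and quadratic discriminant
  allocation of over-sampled booster respondents. Each of those steps is a
  tested, reusable function here.

Factors are scored as signed-loading sums of standardized items
(`score = sum_i w_i z_i`, negative loadings reverse-code their items),
with Cronbach's alpha (threshold 0.7) as the reliability gate and a greedy
item-swap refiner for scales that fall short. Predictive validity of a
segmentation is assessed with a Type III ANOVA of a summative
protective-behaviour score on the segment factor plus demographics —
partial eta-squared per term, `SS_term / (SS_term + SS_error)` — and a
logistic regression with per-term Wald chi-squares for a binary outcome
such as vaccine refusal.

Because real survey microdata of this kind is rarely shareable, the package
ships a synthetic-survey generator (`generate_population()`) with known
latent segments, response styles, demographics and outcome rates, used by
the test suite to verify that the whole pipeline recovers ground truth.

## Worked example

```r
library(audseg)
res <- run_pipeline(list(seed = 42, synth = list(n_respondents = 2000)))
print(res)
```

```
<pipeline_result>
  respondents analysed: 1799 (201 removed in screening)
  factors scored: 10
  segments: segment_1, ..., segment_7, central
  k-means stability (mean pairwise ARI): 0.975
  QDA training accuracy: 0.979
  recovery ARI vs ground truth: 0.85
  segment eta2 = 0.348, combined demographics eta2 = 0.007
```

Reading: of 2,000 simulated respondents, 201 were removed by the
variability screen (straight-liners and extreme acquiescers); the ten
shipped attitude factors were scored; k-means with a 2% central-group
excision produced seven attitudinal segments plus the neutral core, with
near-identical partitions across 20 clustering runs (mean pairwise adjusted
Rand index 0.975); booster-sample respondents were allocated by QDA at
97.9% training accuracy; the recovered segments agree with the generator's
ground truth at ARI 0.85; and the single segment variable explains far more
of the protective-behaviour score (partial eta-squared 0.348) than all
demographic terms combined (0.007).

The validation stage prints the full Unianova-style table:

```r
print(res$validation$glm_table)
```

```
          source        ss   df      ms       F         p partial_eta2
 Corrected Model  1178.716   15  78.581  77.477 9.69e-182        0.395
       Intercept   558.788    1 558.788 550.939 2.18e-106        0.236
        Segments   963.462    7 137.637 135.704 2.28e-160        0.348
          gender     5.428    1   5.428   5.352  2.08e-02        0.003
             ...
           Error  1808.402 1783   1.014
R Squared = 0.395 (Adjusted R Squared = 0.390)
```

Segment profile tables with market-research significance letters (pooled
two-proportion z tests for percentages, Welch t tests for means, alpha =
0.05 per comparison, letters a, b, c, ... in fixed column order; the
smallest cell in a row never carries a letter) are in `res$profile`.

## Layout

* `R/` — synthetic generator, screening, standardization, factor tools
  (EFA by principal-axis factoring with oblimin/varimax rotation, alpha,
  meta-factors, reliability refinement), segmentation engine, profiling,
  validation, pipeline orchestration.
* `vignettes/segmentation-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, and what the synthetic benchmark does
  and does not show.
* `tests/testthat/` — unit, property and acceptance suites.
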