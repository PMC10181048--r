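---
title: "Ranking genotypes by distance to an ideal genotype: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking genotypes by distance to an ideal genotype: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siig)
```

## The selection problem

A breeding trial delivers a genotype × trait table whose columns live in
incompatible units: day counts, centimetres, grams, kilograms per hectare.
Classical weighted selection indices (Smith–Hazel and descendants) need
economic weights or genetic covariances that are rarely available early in a
programme. The index implemented here takes a different route, borrowed
from ideal-point multi-criteria decision analysis: construct a hypothetical
*ideal genotype* that attains the best observed value of every trait and a
*non-ideal genotype* that attains the worst, and score each real genotype by
its relative closeness to the ideal.

## The model

For the trait matrix $x_{ij}$ ($i = 1..n$ genotypes, $j = 1..m$ traits):

$$r_{ij} = \frac{x_{ij}}{\sqrt{\sum_{i=1}^{n} x_{ij}^2}}, \qquad
d_i^{+} = \sqrt{\sum_j (r_{ij} - r_j^{+})^2}, \qquad
d_i^{-} = \sqrt{\sum_j (r_{ij} - r_j^{-})^2},$$

$$\mathrm{SIIG}_i = \frac{d_i^{-}}{d_i^{+} + d_i^{-}} \in [0, 1],$$

where $r_j^{+}$ and $r_j^{-}$ are the per-trait directed extrema of the
normalized column: the maximum and minimum for a *benefit* trait, swapped
for a *cost* trait. The vector normalization divides each column by its
Euclidean norm, so units cancel and no trait dominates by scale alone; it
does not centre the data, so a genotype's relative standing within a trait
is preserved. A genotype attaining the directed extremum of every trait has
$d^{+} = 0$ and scores exactly 1; the all-worst genotype scores 0.

Two structural identities follow and are enforced by the test suite:
multiplying any trait column by a positive constant leaves every score
unchanged (to 1e-12), and flipping the orientation of every trait swaps the
two profiles, mapping each score $s$ to $1 - s$.

### Assumptions and what the index is not

The index is purely phenotypic and relative to the trial at hand: the
"ideal" is the best *observed* value, not a target ideotype, so scores are
not comparable across trials. All traits enter unweighted — equal
importance is an explicit modelling choice, not an omission. The index does
not model genotype × environment interaction, heritability, or breeding
values; it ranks whatever table it is given (raw means, adjusted means, or
per-environment values).

## Parameters that matter

* **Trait directions.** The one genuinely scientific input. The
  `"warm-barley"` preset encodes selection logic for warm, short-season
  environments: days to heading (DHE) and maturity (DMA) are costs (early
  material escapes terminal heat), plant height (PLH) is a cost (lodging
  risk under irrigation), while grain-filling period (GFP, days), thousand-
  kernel weight (TKW, g) and yield (YLD, kg/ha) are benefits. Any named
  vector or config file overrides it.
* **Group breakpoints** (`siig_groups`, default `0.7, 0.6, 0.5, 0.4`). Bins
  are closed on the lower bound — a score of exactly 0.70 belongs to group 1
  — matching the convention that "≥ 0.7" defines the top class. Groups 1–2
  (score ≥ 0.6) are the conventional superior set, also available directly
  via `threshold_select(fit, tau = 0.6)` with an inclusive comparison.
* **Rank tie policy** (`ties`). `"first"` (default) breaks ties by input
  order, giving a strict 1..n permutation like published ranking tables;
  `"average"` is appropriate when ranks feed a correlation.

## Numerical choices and degenerate inputs

* All accumulation is in double precision; column norms use plain
  summation, which is ample for trial-scale $n$ (compensated summation
  would matter only far beyond thousands of genotypes).
* An all-zero trait column has no defined normalization and is an error
  naming the trait; missing or non-finite cells are errors naming the
  genotype and trait.
* If every genotype is identical on every trait, the ideal and non-ideal
  profiles coincide, $d^{+} + d^{-} = 0$, and the score is indeterminate;
  the package scores such genotypes 0.5 with a warning instead of failing,
  since they are simultaneously ideal and non-ideal.
* Negative trait values are permitted by the algebra (the norm is still
  defined) but are agronomically suspect, so they warn rather than error.
* The correlation report uses the exact t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ df, two-sided — the standard test
  behind trait-association heat maps; stars are `*` for p < 0.05 and `**`
  for p < 0.01, with no multiple-testing correction (deliberately, to match
  common practice in trial reports; treat stars as descriptive).

## Design decisions where the method description was open

* **The normalization radical.** Some statements of the index typeset the
  normalizer as $\sum x^2$ without the square root. Only the
  root-sum-of-squares reading keeps the score inside $[0,1]$ and makes it
  unit-invariant, so that is what is implemented.
* **Unweighted only.** A weighted variant is easy to bolt on but would
  reintroduce exactly the weight-elicitation problem the index avoids; v1
  exposes no weights.
* **Grouping of empty classes.** When no genotype reaches the top bin the
  empty group is reported with count 0 rather than renumbering the rest, so
  group labels mean the same thing across environments; `drop_empty = TRUE`
  gives the compact display.

## The bundled trial and its quirks

The package ships the summary tables of a 111-genotype barley trial grown
in four warm-climate environments of Iran (Ahvaz, Gonbad, Zabol, Darab):
per-environment yields with per-environment index values, and
across-environment trait means with the published overall index. Values are
transcribed as printed (3 decimals for scores, whole kg/ha for yields).
Two transcription-level facts matter for reuse:

* The printed GFP means can differ from `DMA - DHE` by one day because GFP
  was recorded in three of the four environments, so its mean averages a
  different environment subset. The fixture test asserts agreement within
  one day, and `derive_gfp()` computes the exact difference for single-trial
  data.
* Recomputing the index from the *printed* (rounded) trait means cannot
  reproduce the published scores exactly: the package obtains 0.720 for the
  top genotype against a published 0.726, with Spearman agreement 0.999
  across all 111 genotypes. The acceptance tests therefore check the top
  genotype within ±0.05 and rank agreement at ρ ≥ 0.95 rather than exact
  equality.

## What the synthetic generator emulates — and what it does not

`simulate_traits()` draws genotype trait vectors from a multivariate normal
with per-trait means and SDs defaulting to the bundled trial's grand means
(DHE 101.8 d, DMA 135.7 d, GFP 32.5 d, PLH 84.6 cm, TKW 38.4 g,
YLD 3750 kg/ha) and the empirical dispersions of its genotype means
(2.5, 2.0, 1.7, 6.2, 3.4, 450 in the same order). The default correlation
structure carries the trial's association signs: yield positively
correlated with grain-filling period (0.3), negatively with maturity
(−0.3) and heading (−0.2), and heading–maturity coupling (0.6); all other
pairs independent. These defaults were fixed once from the trial summaries
and are not tuned.

The generator reproduces first and second moments and supports a *planted
winner*: one genotype overwritten with the directed extremum of every trait
pushed a further 3 SD, guaranteeing strict dominance so the recovery test
(`winner` ranked 1 with score exactly 1) is deterministic. It does **not**
emulate genotype × environment interaction, non-Gaussian trait shapes,
integer day counts (unless `round_days = TRUE`), or any REML-recoverable
variance structure — so a green simulation test establishes that the index
machinery is correct on data with the trial's moments, not that the index
will behave identically on real multi-environment data.

## Known limitations

* Scores depend on the genotype set: adding or removing a genotype can move
  every profile and hence every score. This is inherent to observed-extrema
  ideal points.
* Ties in printed-precision scores make published rank columns
  order-dependent; the package's `"first"` policy is stable but need not
  match how any particular table broke its ties.
* Per-environment trait tables of the bundled trial were never published,
  so per-environment group trait means cannot be recomputed from the
  fixtures and are excluded from the tests.
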