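---
title: "Matching respondents of the Q53 questionnaire: measures, evaluation and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching respondents of the Q53 questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(q53match)
```

## The problem

People living with a rare disease typically spend years with symptoms before a
diagnosis is established, and even after diagnosis rarely meet anyone with
comparable experiences. A patient-matching service can connect such people by
comparing their answers to a standardized questionnaire. `q53match` implements
the numeric core of such a service for the Q53 instrument: 53 items in 7
thematic categories, each answered on the coded scale 1 = No, 2 = Slightly no,
3 = Slightly yes, 4 = Yes, 5 = Do not know.

Each respondent is a 53-dimensional vector of codes P. Matching is plain
k-nearest-neighbor search: for a query, compute a distance to every other
respondent and keep the k smallest (default k = 10, a list long enough to give
the searching user choice without overwhelming them). The scientific question
the evaluation harness answers is *which distance works*: 24 candidate
measures from eight families of the classical distance/similarity taxonomy
are compared on equal footing.

## The 24 measures

`list_measures()` returns the registry: Manhattan, Euclidean and Minkowski
(Lp family); Sørensen, Gower, Canberra, Lorentzian (L1 family); Wave Hedges,
Czekanowski, Tanimoto, Jaccard, Dice (intersection family); cosine (inner
product family); Bhattacharyya, Hellinger, Squared-Chord (fidelity /
squared-chord family); Neyman, Probabilistic Symmetric, Clark, Additive
Symmetric (squared-L2 family); Jeffreys, Jensen difference (Shannon entropy
family); Kumar-Johnson and Avg (combined). All formulas act on the raw codes,
whose entries are at least 1, so every denominator, square root and logarithm
is well defined.

Three deliberate quirks are preserved because they are part of the measure
set under study rather than bugs to fix:

* **Cosine is a similarity but is minimized as-is.** The matcher always
  minimizes the configured value, so "best" cosine matches are the *least*
  similar respondents. The evaluation reproduces the consequence: cosine falls
  at or below the random benchmark. A corrected `cosine_distance()`
  (1 − cosine) exists under its own name but is not one of the 24.
* **Probability-distribution measures run on raw codes.** Bhattacharyya,
  Hellinger, Squared-Chord and the entropy family are defined on probability
  distributions; applied to raw codes they behave anomalously (e.g. the
  Bhattacharyya self-distance is −log ΣP ≠ 0). A `normalize = TRUE` switch
  rescales vectors to unit sum, but it is off by default because the registry
  documents the measures as used, not as intended.
* **"Do not know" = 5 enters arithmetic literally**, placing it beyond "Yes"
  on the scale. `impute_dont_know()` can recode it to the 1–4 midpoint (2.5)
  as a preprocessing step; also off by default.

Useful structural facts, all property-tested: Neyman is the only asymmetric
measure (its denominator is the query); Manhattan, Gower and Minkowski with
exponent p = 1 are positive multiples of one another and therefore rank
candidates identically, as do Sørensen and Czekanowski — which is why those
rows of any accordance table coincide; and Manhattan/2 ≤ Avg ≤ Manhattan,
since the Chebyshev term is at most the Manhattan sum.

Minkowski's exponent defaults to p = 1 precisely so that the registry
reproduces the observed rank-equivalence of the Minkowski, Manhattan and
Gower rows; it is configurable (`exponent`).

## Ties and determinism

Distances on integer codes tie often (Manhattan distances are integers).
The default tie rule is stable-by-input-order: fully deterministic and
auditable, at the cost of a documented dependence on row order among exactly
tied candidates. A seeded random tie rule is available for sensitivity
checks. Distances are never rounded before ranking; all arithmetic is double
precision with no internal tolerances.

## Matching accordance and the random benchmark

Evaluation is leave-one-out: each respondent in turn is matched against the
remaining n − 1. For each of six properties — gender, age, latency (years
with symptoms before diagnosis), disease group, diagnostic system, exact
diagnosis — the *accordance* of a match list is the fraction of its k matches
agreeing with the query, among matches whose value is known. A measure's
table row is the per-property mean over all queries with known value, in
percent.

Two properties are continuous and need an equality rule. Exact-year equality
would make accordance on age nearly unattainable, so age is compared in
decade bins (0–9, …, 80–89, covering the cohort's 0–87 range) and latency in
the bins <1, 1–2, 3–5, 6–10, >10 years; both are configurable
(`property_specs()`). Unknown values (the `"unknown"` token, unknown latency)
are excluded from both numerator and denominator rather than counted as
disagreement; a query whose own value is unknown contributes nothing for that
property. The diagnostic system keeps `"unknown"` as a regular category — the
subgroup without an established diagnosis is itself a meaningful matching
target.

The negative benchmark draws, for every query, k distinct non-self
respondents uniformly at random (100 replicates per query by default,
averaged; the number of replicates is a design choice, not given by the study
design). Its analytic expectation for a categorical property with category
sizes $n_c$, $u$ unknown values and cohort size $n$ is

$$E = \sum_c \frac{n_c}{n-u}\cdot\frac{n_c-1}{n-1-u} \times 100,$$

independent of k; `expected_random_accordance()` computes it and the test
suite checks the Monte-Carlo benchmark against it. Per property, the
best-scoring measure is flagged as the positive benchmark (ties jointly).

## Significance testing and a calibration caveat

`compare_rows()` tests whether two rows differ on one property. Three methods
are implemented because the correct choice is subtle:

* **Label permutation (default).** Property labels are permuted over
  respondents while every row's neighbor sets stay fixed, and the difference
  of mean accordances is recomputed per permutation (10,000 by default,
  seeded). For the benchmark row the analytic expectation above is used; it
  depends only on category counts and is therefore invariant under
  permutation. Under the null "answers carry no information about this
  property" the labels are exchangeable with respect to the answer-derived
  neighbor graph, so this test is exact.
* **Paired sign-flip permutation.** Flips signs of per-query accordance
  differences (exhaustive enumeration up to 12 informative queries, otherwise
  Monte-Carlo). This is the natural first idea for paired leave-one-out data,
  but its independence assumption is violated: per-query accordances are
  positively cross-correlated because queries share neighbors (if two
  respondents are mutual nearest neighbors and share a diagnosis, both their
  accordances rise together). The sign-flip null understates the variance of
  the mean difference and the test is mildly anti-conservative. It remains
  available (`method = "permutation"`) for comparison and for inputs without
  stored neighbor structure.
* **Pooled two-proportion z-test** (`method = "z"`): fastest, ignores both
  pairing and dependence; a rough screen only.

The calibration property is tested end to end: on a synthetic cohort whose
answers carry no diagnostic signal (cluster strength 0, below), every
measure's exact-diagnosis accordance must sit within 3 standard errors of the
analytic random expectation, and the default test must not reject above its
nominal 5% rate across independent realizations of the benchmark and
permutation draws.

## The synthetic cohort generator

The real 973-respondent data set behind the published accordance table is not
deposited, so the generator stands in for it. It emulates the *printed*
composition exactly — 759 rare-disease, 126 chronic-disease, 27
psychosomatic, 27 healthy, 34 unknown-diagnosis respondents; 702 female, 271
male; ages 0–87 with mean 39.4 — and a diagnosis-driven answer structure:

* Diagnostic-system counts and gender counts are allocated exactly (largest-
  remainder apportionment for other cohort sizes), because they are reported
  facts about the study population, not distributional parameters.
* Each exact diagnosis (default: 20 rare-disease diagnoses spread over the
  groups neuromuscular, autoimmune, metabolic, pulmonary, other; 5
  chronic-disease diagnoses; one label each for psychosomatic, healthy,
  unknown) owns a prototype answer vector drawn uniformly from codes 1–4.
  Respondents draw their diagnosis uniformly within their system — the real
  per-diagnosis sample sizes are unpublished, so uniformity is an explicit,
  arbitrary default.
* Each answer copies the prototype with probability `cluster_strength`,
  otherwise is uniform on 1–4; afterwards it is replaced by code 5 with
  probability `dontknow_rate` (default 0.05). "Do not know" never appears in
  prototypes — it is noise, not signal, mirroring its non-ordinal semantics.
  The default `cluster_strength` of 0.6 encodes a moderate assumption — that
  same-diagnosis respondents share many but not all experiences; strength 0
  (no signal) and 1 (clones) bracket it and are the calibration and
  forced-success conditions of the test suite.
* Ages are normal(39.4, 18) truncated to [0, 87] by resampling and rounded;
  latency is gamma (shape 2) with mean 8 years for rare diseases — the
  field's typical diagnostic delay — 2 for chronic disease, 4 for
  psychosomatic, 0 for healthy, unknown for the unknown group. The age SD and
  latency means are not printed in the study description and were chosen once
  as plausible for such a cohort.

What the generator does *not* emulate: real Q53 answer distributions, item
correlations within categories, severity gradients, or any clinical
plausibility of individual profiles. Passing tests on synthetic cohorts
therefore demonstrate the correctness and calibration of the machinery — not
that any particular measure would win on real data. In particular, the
published absolute accordance percentages are not reproducible without the
original data; what the suite reproduces is the qualitative pattern: with
diagnosis-driven structure present, distance measures beat random matching
significantly while minimized cosine does not.

## The embedding

`embed_cohort()` projects the 53-dimensional answer vectors to 2D with an
exact (O(n²)) t-SNE — Gaussian input affinities with per-point bandwidths
bisected to a target perplexity (default 30, clamped to (n−1)/3), Student-t
output kernel, early exaggeration, momentum gradient descent — written
in-package and deterministic under its seed. Its role is diagnostic: colored
by diagnostic system it shows whether any group forms a separable cluster
(with strongly clustered synthetic data, a distinct healthy profile separates
visibly; with weak structure nothing does, which is exactly why nearest
neighbors are used here for matching rather than classification).

## Problem sizes and numerical choices

The test suite exercises the full 973-respondent scale where the scale
matters (composition fidelity, calibration, the qualitative benchmark
pattern, pipeline determinism) and small fixtures (n = 10–60) everywhere
else; the k-NN oracle comparison uses 100 random cohorts of n = 50 at k = 10
across all 24 measures. Formula agreement is asserted to 1e-9 relative
tolerance against direct scalar evaluation; permutation p-values use the
add-one estimator; accordance means ignore undefined queries (`NA`) rather
than imputing them.

## Known limitations

* Brute-force O(n·d) scans per query: right for cohorts of a few thousand,
  not for millions (no spatial indexing by design — auditability first).
* Respondents with identical answer vectors are not deduplicated; whether the
  original evaluation did is unknown.
* The sign-flip test's anti-conservatism grows with k/n (more shared
  neighbors); use the default label-permutation method for inference.
* The generator's latent-prototype model makes within-diagnosis answer
  correlation uniform across items, which real questionnaires will not obey.
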