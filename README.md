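# q53match

Patient-similarity matching for the Q53 questionnaire: k-nearest-neighbor
search under 24 distance/similarity measures, with a leave-one-out
"matching accordance" evaluation harness.

## The problem

People with rare diseases typically wait years for a diagnosis and rarely
meet anyone with comparable experiences. A matching service can connect them
by comparing answers to a standardized questionnaire — here the Q53
instrument: 53 items in 7 categories, answered on the coded scale
1 = No, 2 = Slightly no, 3 = Slightly yes, 4 = Yes, 5 = Do not know.

Matching is k-nearest-neighbor search over the 53-dimensional code vectors
(default k = 10). Which distance to use is an empirical question: this
package implements 24 candidate measures from eight families of the
classical distance taxonomy — Minkowski (Manhattan, Euclidean, Minkowski),
L1 (Sørensen, Gower, Canberra, Lorentzian), intersection (Wave Hedges,
Czekanowski, Tanimoto, Jaccard, Dice), inner product (cosine),
fidelity/squared-chord (Bhattacharyya, Hellinger, Squared-Chord), squared L2
(Neyman, Probabilistic Symmetric, Clark, Additive Symmetric), Shannon
entropy (Jeffreys, Jensen difference) and combined (Kumar–Johnson, Avg) —
and evaluates each by leave-one-out cross-validation: every respondent is
matched against the remaining n − 1, and the *accordance* of a measure on a
property is the mean fraction of a query's k matches sharing that property
(gender, age decade, latency bin, disease group, diagnostic system, exact
diagnosis):

```
accordance(measure, property) = mean over queries of
    (# of the k matches agreeing on the property) / (# with known value)
```

Every measure is compared against a pseudorandom-matching negative benchmark
(k random matches per query), whose expectation has the closed form
`sum_c n_c/(n-u) * (n_c-1)/(n-1-u)` over property categories of size `n_c`
(`u` unknown values). Significance uses a label-permutation test by default:
property labels are permuted over respondents while the neighbor graph stays
fixed, which is exact for the null "answers carry no information about the
property" (see the methods vignette for why the naive paired sign-flip test
is anti-conservative here; it is available as an alternative).

The study data set behind the original evaluation (973 respondents) is not
public, so the package includes a synthetic cohort generator that reproduces
its printed composition exactly — 759 rare-disease, 126 chronic-disease, 27
psychosomatic, 27 healthy, 34 unknown-diagnosis respondents; 702 female /
271 male; ages 0–87 with mean 39.4 — with a tunable diagnosis-driven answer
structure (`cluster_strength` from 0 = no signal to 1 = per-diagnosis
clones).

## Worked example

```r
library(q53match)

cfg <- synthetic_config(
  composition = c(RD = 60, CD = 15, psychosomatic = 5, healthy = 5, unknown = 5),
  cluster_strength = 0.6)
cohort <- generate_cohort(cfg, seed = 42)

find_matches(cohort, "R0001", match_config("Manhattan", k = 5))
#>   query_id rank match_id distance
#> 1    R0001    1    R0051       33
#> 2    R0001    2    R0042       35
#> 3    R0001    3    R0021       38
#> 4    R0001    4    R0047       43
#> 5    R0001    5    R0006       57

tab <- build_table(cohort, measures = c("Manhattan", "Euclidean", "Cosine", "Jeffreys"),
                   k = 5, bench = benchmark_config(replicates = 50, seed = 42),
                   seed = 42, n_perm = 2000)
tab
#> Leave-one-out matching accordance (percent), k = 5, n = 90
#>
#>    measure                  family gender  age latency disease_group
#>  Manhattan            Lp Minkowski   60.2 17.1    23.7          60.9
#>  Euclidean            Lp Minkowski   59.8 17.3    22.7          45.4
#>     Cosine           Inner product   55.1 15.1    18.1           9.8
#>   Jeffreys         Shannon entropy   59.3 19.1    21.6          47.9
#>     random (Pseudo)random sampling   58.7 15.7    19.4          16.6
#>  diagnostic_system exact_diagnosis
#>               79.3            52.8
#>               71.8            36.2
#>               46.2             0.2
#>               74.0            38.7
#>               47.8             4.5
```

Reading the table: the five rows are mean accordance in percent per property.
With a moderate diagnosis-driven answer structure, Manhattan's matches share
the exact diagnosis 52.8% of the time against 4.5% under random matching
(the analytic expectation, `expected_random_accordance(cohort,
"exact_diagnosis")`, is also 4.5) — and the label-permutation p-value in
`tab$comparisons` for Manhattan vs the negative benchmark is 0.0005. Cosine,
a similarity coefficient that the matcher minimizes as-is, selects maximally
*dissimilar* respondents and lands at 0.2%, below the random benchmark — a
deliberate reproduction of how this measure set behaves.

A command-line wrapper covers the whole pipeline
(`generate`, `match`, `evaluate`, `compare`, `embed`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "q53match", package = "q53match"))')
Rscript "$CLI" generate --seed 7 --out cohort.csv
Rscript "$CLI" evaluate --cohort cohort.csv --all-measures --k 10 \
        --bench-reps 100 --seed 7 --out table.csv --pvals pvals.csv
Rscript "$CLI" embed --cohort cohort.csv --seed 7 --out coords.csv
```

All stochastic behavior flows from `--seed`; each run writes its resolved
configuration next to its output (`<out>.config.json`).

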