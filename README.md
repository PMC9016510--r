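# pcgcluster

Unsupervised random-forest clustering of pharmacy-based cost group (PCG)
profiles from health-insurance claims.

## The problem

Health insurers hold no diagnoses, but they do hold drug claims. Translating a
year of prescriptions (ATC code + defined daily dose) into **pharmacy-based
cost groups** gives every insured person a vector of 34 binary
chronic-condition flags, and a person with two or more PCGs is operationally
**multimorbid**. Simple PCG counts, however, flatten very different patients
onto the same number. `pcgcluster` segments an insured population (aged ≥ 50)
by the *pattern* of PCG co-occurrence instead, using only the 34 flags as
clustering input, and then profiles the segments with the cost and
health-care-use columns that were deliberately kept out of the clustering.

## The method

For a clusterable sample `X` (n patients × 34 binary flags):

1. **Synthetic reference (Addcl1).** Build `X'` of the same size by sampling
   each column independently from its empirical distribution: marginals are
   preserved, dependence is destroyed.
2. **Forest dissimilarity.** Train a random forest to classify
   `original vs synthetic`. The proximity of two points is the number of
   trees in whose same terminal leaf they land. To stabilize forest noise, 10
   forests are trained and their proximity matrices averaged;
   `D = 1 − P̄ / n_trees` is the dissimilarity. The mean **out-of-bag (OOB)
   misclassification error** of the ensemble measures how much dependence
   structure the data holds (≈ 0.5 ⇒ none).
3. **MDS.** `D` (original + synthetic points) is projected to 2-D by metric
   stress majorization (SMACOF); quality is reported as normalized stress-1,
   `sqrt( Σ_{i<j} (d̂_ij − d_ij)² / Σ_{i<j} d_ij² )`.
4. **HDBSCAN.** After dropping the synthetic rows, density clusters are
   extracted from the 2-D coordinates via the condensed cluster hierarchy
   (λ = 1/distance) with excess-of-mass selection; sparse points get label
   `−1`, and each cluster carries a persistence score.

Before any of this, three "single" groups are set aside: patients with no
PCGs, patients whose PCGs are all hypertension-related, and patients whose
PCGs are all mental-disease-related; patients confined to one other single
disease category are excluded from clustering but kept for audit. Detected
clusters are profiled into a descriptive table (age, sex, deductible,
gatekeeping, PCG count, multimorbid share, costs, utilization) and named by
transparent rules (complex high-cost high-need / slightly complex / oldest at
high risk / one costly disease).

Because real claims data are proprietary, the package includes a synthetic
cohort generator whose default population reproduces the published
descriptive table of an 18,732-person Swiss claims cohort (archetype sizes,
mean PCG counts, multimorbid shares, cost and utilization levels), plus a
planted-archetype benchmark for recovery experiments. The shipped 34-PCG
taxonomy is a synthetic stand-in (`inst/extdata/default_taxonomy_synthetic.csv`)
and can be replaced by any 34-PCG / 15-category mapping via `read_taxonomy()`.

## Worked example

```r
library(pcgcluster)

coh <- generate_cohort(planted_cohort_spec(n_patients = 900), seed = 201)
pipe <- run_full_pipeline(coh,
                          forest_cfg = forest_config(n_forests = 10, n_trees = 150),
                          mds_n_init = 2, seed = 301)
pipe
#> <pcg_pipeline>
#>   partition: no_pcg=4, hypertension_only=52, mental_only=55, other_single=98,
#>              clusterable=691, not_sampled=0
#>   oob_mean=0.059  stress=0.384  clusters=3
#>   persistence: 4.003 2.462 7.465
recovery_ari(pipe, coh)
#> [1] 0.7491513
```

Reading the output: the forests separate original from synthetic rows almost
perfectly (OOB 0.059), i.e. the planted cohort is highly structured — the
opposite extreme from a structureless cohort, where the same number sits at
~0.5. The 2-D projection keeps the distances to stress 0.384, and HDBSCAN
finds three persistent clusters among the 691 clusterable patients; the
adjusted Rand index of 0.75 against the generator's hidden archetype labels
scores the recovery. Profiling then reproduces a descriptive table per label:

```r
prof <- profile_clusters(coh, pipe)
prof[, c("label_name", "n", "pcg_count_mean", "multimorbid_share", "total_cost_mean")]
name_clusters(prof)
autoplot(pipe)                        # MDS scatter colored by cluster
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pcgcluster.R generate --seed 1 --out run/
Rscript inst/cli/pcgcluster.R cluster  --seed 1 --out run/
Rscript inst/cli/pcgcluster.R profile  --seed 1 --out run/
```

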