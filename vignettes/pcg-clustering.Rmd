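---
title: "Segmenting insured populations by PCG co-occurrence: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting insured populations by PCG co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgcluster)
```

## Why cluster on PCGs at all

Pharmacy-based cost groups (PCGs) translate a year of prescribed-drug claims
(active ingredient and quantity, via ATC codes and defined daily doses) into
34 binary chronic-condition flags per insured person. They are the only
morbidity signal available in many claims databases, and the operational
definition of multimorbidity — two or more PCGs in a year — is built on
them. A plain PCG count, however, treats a patient with well-controlled
hypertension plus raised cholesterol the same as one combining depression,
COPD and chronic pain. `pcgcluster` segments the population by the *pattern*
of PCG co-occurrence, keeping the cost and utilization columns strictly out
of the clustering so they remain available as an independent read-out for
profiling the segments.

## The clustering model, stage by stage

### Pre-clustering partition

Density clustering on binary profiles is dominated by a handful of extremely
frequent degenerate profiles, so these are set aside first:

* patients with **no PCGs**;
* patients whose PCGs all fall in the **hypertension** disease category;
* patients whose PCGs all fall in the **mental** disease category;
* patients confined to exactly one *other* disease category. These carry no
  co-occurrence information either; they are excluded from clustering but
  written to an audited `other_single` group rather than dropped silently.

The remainder — patients spanning at least two disease categories — is the
clusterable set. Above a configurable threshold (default 5,000) it is thinned
to a uniform 10% subsample, reflecting the quadratic memory and time cost of
the proximity stage; below the threshold no thinning occurs, so small
synthetic cohorts are never thinned away. "One type of PCG" is interpreted at
the level of the 15 disease categories, not individual PCGs — consistent with
the single-hypertension and single-mental groups admitting several PCGs of
one disease type.

### Synthetic reference and forest dissimilarity

The dissimilarity is the classic unsupervised-random-forest construction: a
synthetic reference of the same size is drawn by resampling each input
column independently from its empirical distribution (the *Addcl1* scheme),
and a forest is trained to classify original versus synthetic rows. Because
the reference preserves the marginals exactly, anything the forest learns is
between-column dependence. Two consequences are load-bearing:

* the **out-of-bag misclassification error** is a structure meter: on a
  cohort whose flags are truly independent the task is undecidable and OOB
  error concentrates at 0.5 (the package's acceptance script reproduces
  this at n = 2,000 within ±0.05);
* the **proximity** of two rows — the number of trees placing both in the
  same terminal leaf — is high exactly when the rows co-occur in the
  dependence structure the forest found.

Ten forests (default) are trained with consecutive seeds and their raw
proximity count matrices averaged; the distance is `1 − P̄ / n_trees`,
applied entrywise with the diagonal forced to zero. Raw counts are stored
and normalization happens only in the distance transform. Defaults the
procedure does not prescribe elsewhere are the common classification
defaults: 500 trees per forest, `mtry = floor(sqrt(p))`, minimal node size
1, unbounded depth; all are configurable through `forest_config()`. The
proximity matrix is dense over original *and* synthetic points (the
embedding consumes both), giving an O(n²) memory contract with a practical
ceiling around 10⁴ points — the reason the 10% subsample exists.

### Metric MDS by stress majorization

The distance matrix is embedded in 2-D with SMACOF (unit weights): the
first start is the classical-scaling solution, the remaining `n_init − 1`
(default 4 total) are uniform random configurations, and the lowest-stress
result wins. Reported quality is normalized stress-1,

`stress = sqrt( Σ_{i<j} (d̂_ij − d_ij)² / Σ_{i<j} d_ij² )`,

which is 0 for exactly reproduced distances and 1 for a configuration
collapsed onto one point. Stress-1 is used because the distances are treated
quantitatively (metric, not ordinal, MDS); which normalization the original
analysis used is not stated, so stress-1 is stipulated. Iteration stops when
the stress change drops below `1e-4` or after 300 iterations; the majorization
step is implemented in compiled code because it is the pipeline's hot loop.
Convergence from the classical-scaling start is typically reached in well
under 300 iterations, and on exactly-Euclidean inputs the start is already
the fixed point (stress < 1e-6). Synthetic points take part in the embedding
and are dropped only afterwards, preserving the stage order of the procedure.

### HDBSCAN and persistence

Density clusters are extracted from the 2-D coordinates of the original
points. The implementation follows the standard HDBSCAN construction: core
distances (distance to the `min_samples`-th nearest neighbour), mutual
reachability `max(core_i, core_j, d_ij)`, the single-linkage hierarchy on
mutual reachabilities, a condensed tree in which a split counts only when
both sides hold at least `min_cluster_size` points (`λ = 1/distance`), and
excess-of-mass selection over cluster stability
`Σ_points (λ_leave − λ_birth)`. The hierarchy root is never selected, except
in the degenerate case of all points coincident, which is reported as one
dense mass. Points claimed by no selected cluster are outliers (`−1`), and
clusters are numbered 0..k−1 in the order they split off the condensed tree.

Two defaults deserve comment.

* `min_cluster_size = max(15, round(0.02 n))`: a cluster smaller than 2% of
  the clusterable sample (floor 15) is not interesting at population scale.
* `min_samples = 4 × min_cluster_size` (capped at n − 1). This is larger
  than the conventional `min_samples = min_cluster_size`, deliberately:
  binary profiles duplicate heavily, duplicated profiles land on identical
  MDS coordinates, and with a small neighbourhood every such pile is its own
  density peak — the flat clustering then fragments into dozens of
  pattern-level clusters. Smoothing the density estimate over several piles
  makes clusters form at the profile-mix level, which is the object of
  interest. In planted-archetype experiments this single change moves
  recovery from ARI ≈ 0.35 (16+ fragments) to ARI ≈ 1.0 (4 clusters). Both
  parameters remain fully configurable.

**Persistence.** The per-cluster score reported here is stability divided by
the cluster's size at birth — the mean λ-lifetime of a member beyond the
cluster's birth. This is one of several normalizations in circulation;
absolute values are therefore not comparable across implementations, only
across clusters of one run.

### Profiling and naming

Profiles are plain arithmetic per label (including the single groups,
outliers and, when subsampling applies, the `not_sampled` remainder):
means of age, deductible, the three cost components and their sum, the four
utilization counts, the sex split, the gatekeeping share, the mean PCG count
and the multimorbid share, plus the most prevalent PCGs. The per-cluster
joint PCG distribution is the symmetric 34 × 34 co-occurrence count matrix;
"single disease" clusters are recognizable by an empty off-diagonal. Naming
is rule-based and advisory — highest PCG count and costs → complex
high-cost high-need; oldest with above-average inpatient burden → oldest at
high risk; mean PCG count near 1 with the highest medication costs → one
costly disease; multimorbid with below-average total costs → slightly
complex; anything else `unlabelled_<k>`. The rules only read the profile
table and never feed back into clustering, mirroring how such labels arise
from reading a descriptive table. The cutoffs (e.g. |mean PCG − 1| ≤ 0.35)
are stipulated, since no published thresholds exist.

## The synthetic cohort generator

Real claims data cannot ship with the package, so `generate_cohort()` draws
cohorts from explicit population archetypes. The default
(`default_cohort_spec()`) encodes the published descriptive statistics of an
18,732-person cohort: eight archetypes (outlier, complex high-cost, slightly
complex, oldest at high risk, one costly disease, no-PCG, hypertension-only,
mental-only) with proportions taken from the printed group counts
(321/817/709/531/1056/12,720/1,813/765 — the rounded percentages do not
recover these counts, the counts themselves do), and per-archetype mean PCG
counts, multimorbid shares, age, sex, deductible, gatekeeping, cost and
utilization levels copied from the published table. Swiss francs are the
canonical unit throughout.

Choices the published material does not determine, fixed once here:

* **Costs** are log-normal with the archetype mean and coefficient of
  variation 1 — the heavy right tail typical of claims data. `total_cost`
  is the exact sum of the three components for every record (the published
  per-cluster total means are slightly larger than the sum of their
  component means; the identity wins, and the printed total is kept in the
  spec for reference). Deductibles are log-normal with CV 0.5.
* **Utilization counts** are negative binomial with dispersion 1;
  generalist consultations are a binomial thinning of total consultations,
  so generalist ≤ total holds row-wise. Hospital days are drawn
  independently of hospitalizations, a simplification.
* **Ages** are normal with the archetype mean/SD, clamped at 50 (the study
  population is 50+); clamping shifts means upward by well under a year.
* **Co-occurrence modes.** `joint` draws a patient-level severity
  multiplier (0.7 or 1.3) shared across the archetype's PCG pool, making
  pool PCGs positively correlated; `rare_joint` draws pool PCGs
  independently; `single` assigns a fixed small number of distinct pool
  PCGs. Optional pool weights let an archetype have high-prevalence
  "signature" PCGs plus rare auxiliaries. All modes keep the expected PCG
  count equal to the archetype's `mean_pcg_count` exactly.
* **`exact_counts` mode** replaces sampling with construction: archetype
  sizes are the largest-remainder apportionment, and within each archetype
  a deterministic allocation of 0/1/2/3+-PCG patients hits the total PCG
  count and the multimorbid head-count exactly (`round(m·n)` and
  `round(s·n)`). One-PCG patients of multi-category archetypes draw from
  the pool excluding hypertension- and mental-category PCGs, so chance
  draws cannot migrate them into the single-disease partitions; the three
  printed single-group sizes are then reproduced exactly by construction.
* **`separation ∈ [0, 1]`** relocates each drawn PCG, with probability
  `1 − separation`, to a uniform draw from the union of all pools: 1 keeps
  archetype pools as configured, 0 erases archetype identity.

The **planted benchmark** (`planted_cohort_spec()`) is four equal archetypes
with disjoint six-PCG pools spanning distinct disease categories, weighted
3:3:1:1:1:1 so each archetype has two signature PCGs (per-PCG rate 0.84 at
the default mean of 2.8) plus four auxiliaries (0.28). The signature
structure matters: with uniform disjoint pools the four archetypes are
mutually near-equidistant in RF distance, and four equidistant clusters
cannot be embedded in the plane — recovery then fails for reasons that are
an artifact of the benchmark's geometry, not of the method. Signature cores
give within-archetype cohesion, as real multimorbidity segments have.

What the generator does **not** emulate: marginal PCG prevalences and joint
frequencies of real Swiss claims (not published; the generator's
correlations are stipulated), longitudinal dynamics, regional and insurer
heterogeneity, and any dependence of costs on the specific PCG combination
beyond the archetype mean. Passing recovery tests on planted cohorts
therefore demonstrates that the pipeline recovers co-occurrence structure of
the planted kind — not that real claims data contains such structure.

## Ground truth and evaluation

Every generated record carries `true_archetype`. It is ground truth for the
generator only; every pipeline stage ignores it, and `recovery_ari()` is the
single consumer, computing the adjusted Rand index between detected labels
and archetypes on clusterable, non-outlier patients. In the test suite the
planted benchmark is run at n = 1,500 (10 forests × 200 trees, 2 MDS starts)
for recovery and at n = 900 (10 × 150) across separations 1.0/0.6/0.2 for
the degradation check; medians over 5 seeds are used. These sizes keep each
experiment in the tens of seconds while leaving the clusterable set an order
of magnitude above `min_cluster_size`.

## Degenerate inputs and numerical corners

* Zero-height merges (duplicate points) would give infinite λ; heights are
  floored at the smallest positive merge height of the hierarchy.
* A clusterable set smaller than `min_cluster_size` yields all-outlier
  labels with a warning; an empty clusterable set short-circuits the
  pipeline after the partition.
* A cohort of all-identical coordinates is one dense mass, not noise.
* Stress on an all-zero distance matrix is defined as 0; a collapsed
  configuration against any nonzero distances scores exactly 1.
* All stages consume and propagate explicit seeds (`seed + 0..3` for
  partition, reference, forests, MDS off the pipeline's master seed); fixed
  seeds give bit-identical cohorts, proximity matrices, embeddings and
  labels, with forests restricted to one thread.

## Known limitations

* The shipped taxonomy is a synthetic stand-in: 34 plausible PCG names in 15
  categories covering every name the published table uses. The pipeline's
  mathematics never depends on the names, and any official mapping can be
  substituted as a two-column CSV.
* Persistence values are implementation-specific (see above) and should not
  be compared against numbers from other HDBSCAN implementations.
* The 2-D embedding is a genuine information bottleneck (stress ≈ 0.4 on
  structured synthetic cohorts): clusters that are well separated in RF
  distance can abut in the plane. This is inherent to the procedure being
  reproduced, which clusters the projection rather than the distance matrix.
* Out-of-sample assignment (labelling a new patient without re-running the
  pipeline) and soft memberships are out of scope, as are drug-level
  derivation of PCGs and any statistical testing of between-cluster
  differences.
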