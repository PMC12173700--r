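---
title: "Edge-wise permutation contrasts for paired structural and functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-wise permutation contrasts for paired structural and functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectomediff)
library(dplyr)
```

## The analysis problem

Case-control connectome studies ask where, in a node-by-node connectivity
matrix, two groups differ. `connectomediff` implements an edge-wise variant
of the Network Based Statistic for cohorts carrying two connectivity
modalities per subject on a shared parcellation:

* **structural** connectomes — streamline counts between parcel pairs from
  probabilistic tractography (nonnegative, sparse after thresholding);
* **functional** connectomes — Pearson correlations between parcel-average
  resting-state time courses (dense, in `[-1, 1]`).

Instead of the classical cluster-extent NBS statistic, every edge is
compared between groups with a Mann-Whitney rank test and then referred to
*its own* permutation null, so the raw (not binarised) connectivity enters
the test and no cluster-forming assumption is needed. Downstream stages
summarise the surviving edges as subnetworks, test whether the structural
and functional subnetworks implicate the same nodes more often than group
labels predict, and correlate connectivity of the implicated edges with
clinical scores.

## The statistical procedure

### Quality control

* Streamline-count edges below 10 counts are removed (`apply_dmri_threshold()`;
  a count of exactly 10 is kept — the threshold is read as the minimum
  retained value). Raw directional count matrices are symmetrised by the
  mean of the two directions first (`symmetrize()`), since all analyses are
  over unordered node pairs.
* Correlation edges with `|r| <= 0.05` are removed (strict inequality
  retained, matching the rule "absolute value of r > 0.05"), then the
  surviving correlations are variance-stabilised with Fisher's
  `z = atanh(r)` (`fisher_z_transform()`), in that order.
* Subjects whose motion summary (mean relative RMS displacement, mm)
  exceeds the sample mean by more than one standard deviation are excluded
  per modality (`motion_exclude()`). The rule is one-sided (only high
  movers are implausible) and computed on the pooled sample by default;
  both choices are exposed (`sidedness`, `scope`) because conventions vary
  and the underlying convention in the source analyses is ambiguous.

### Edge-wise contrast

For each unordered pair `(i, j)` the two groups' connectivity vectors are
compared with a Mann-Whitney test using midranks for ties. `U` is the
group-A rank sum minus `nA(nA+1)/2`; the normal approximation uses the
tie-corrected variance and a continuity correction,

$$ z = \frac{U - n_A n_B / 2 \mp 1/2}
          {\sqrt{\tfrac{n_A n_B}{12}\bigl[(N+1) -
           \tfrac{\sum_t (t^3 - t)}{N(N-1)}\bigr]}} , $$

with two-sided `p = 2\Phi(-|z|)`. Edges with `p < 0.001` (the candidate
threshold `alpha`) enter the permutation stage: group labels are reassigned
uniformly at random `G = 10{,}000` times with group sizes preserved, the
`|z|` statistic is recomputed under every relabeling, and the permutation p
is the plain proportion of null values at least as large as the observed
one. Effect sizes are Rosenthal's `r = |z|/\sqrt{N}`.

Numerical and design choices worth knowing:

* **One shared schedule across edges.** Because midranks per edge are
  invariant under relabeling, the whole null reduces to one matrix product
  (relabeling indicator times rank matrix); a per-edge schedule would cost
  the same statistically and thousands of times more computationally.
* **Structurally absent edges** (zero in every subject of both groups) are
  skipped — a thresholded-away connection is missing data, not a tie.
* **`perm_p = 0` is possible** under the plain-proportion convention; the
  `(count+1)/(G+1)` estimator is available behind `add_one = TRUE`.
* **Permutation significance cut**: the final cut on the permutation p is
  not fixed by the procedure's description anywhere authoritative; the
  default is `p_crit = 0.05`, exposed in the configuration.
* **Small-sample approximation quality.** Against full enumeration of all
  labelings, `U` agrees exactly at any size, and for groups of at least 3
  the approximate two-sided p is within 0.05 of the exact value at every
  possible `U`. At 2v2 and 2v3 the worst-case error at the extreme `U` is
  0.088 and 0.051 respectively — inherent to the continuity-corrected
  normal approximation, and irrelevant at study scale (tens per group).

### Subnetworks, centrality, hubs

Significant edges form the difference graph; its connected components
(sorted by node count, then edge count, then smallest member id) are the
reported subnetworks. Within each subnetwork, eigenvector centrality is the
leading eigenvector of the **binary** adjacency of significant edges
(weights are not used by default; a weighted variant would change reported
magnitudes and is left as an option for `eigenvector_centrality()` callers
who pass a weighted adjacency), computed by power iteration from the
uniform vector with a diagonal shift `A + I` — the shift leaves
eigenvectors unchanged while making the spectrum positive, which suppresses
the period-2 oscillation bipartite components would otherwise exhibit.
Centralities are nonnegative and Euclidean-normalised per subnetwork, which
reproduces the magnitude range conventionally reported (max-norm would
force a 1.0 in every subnetwork). A node is a hub when its centrality
strictly exceeds the subnetwork mean plus one sample SD (n-1 denominator;
equal centralities therefore yield no hubs).

### Structural-functional overlap

The observed statistic is the set of nodes shared by the largest structural
and the largest functional subnetwork. Its null: permute group labels
within each modality (sizes preserved, independently per modality, because
the post-QC subject sets differ between modalities; a shared-relabeling
mode exists for identical subject sets), re-run the edge-wise scan at
`alpha`, intersect the largest components, and record the member node ids.
Each observed node's p is its appearance fraction over `G` iterations, and
Benjamini-Hochberg correction is applied over the observed intersect (the
family actually tested; correcting over all atlas nodes would be needlessly
conservative given that only observed nodes can be reported). The inner
scans use the candidate graph directly — nesting the per-edge permutation
stage inside the node-identity null would require `G^2` relabelings for no
change in the intersect statistic, which is defined by the sparse candidate
matrices.

### Clinical correlations

Pearson correlations between each clinical score (CAARMS total, SPI-A
total, GAF, BACS total) and the connectivity of significant edges incident
to the intersect nodes, within the case group (the reported degrees of
freedom in comparable analyses imply case-only correlations; `group = NULL`
analyses everyone). "Edges incident to an intersect node" has a broader
reading — every tested pair touching the node — available via
`scope = "all-incident"`; neither reading is asserted as canonical. The
permutation FDR stage permutes the score across subjects `G = 1,000` times
and compares each edge's `|r|` with its own null (per-edge, the default)
or with the per-iteration maximum over edges (`null = "max"`, strong
familywise control); BH is then applied within each score's family, since
the procedure this follows applies both corrections. Missing scores are
dropped pairwise.

### Cohort description statistics

`cohort_summary_stats()` reproduces demographic-table conventions: Welch's
t with a **pooled-SD** Cohen's d (that pairing, though internally
inconsistent, is what the summary tables it mirrors use — and it reproduces
their printed values exactly), Mann-Whitney with Rosenthal's r, and
chi-squared or Fisher's exact (point-probability, two-sided) with the phi
coefficient `|ad - bc| / \sqrt{(a{+}b)(c{+}d)(a{+}c)(b{+}d)}`.

## The synthetic cohort generator

No subject-level data are distributable for the class of study this
package targets, so `simulate_cohort()` generates cohorts with known ground
truth; every downstream stage is validated against planted effects.

* **Structure**: a connected random backbone (spanning tree plus
  independent extras, expected density 0.2) carries negative-binomial
  streamline counts, mean 150 and dispersion (`size`) 2 per edge —
  probabilistic tractography counts on retained edges are large and
  heavily overdispersed, which a Poisson model would understate. Planted
  edges multiply the case-group mean by `(1 + delta)` ("hyper") or its
  inverse ("hypo").
* **Function**: each subject's matrix is the sample correlation of 150
  multivariate-normal time points from a 6-block community covariance
  (within 0.3, between 0.05). Case-group effects are added to the *latent*
  correlations (`±delta`) and the matrix is projected to the nearest
  positive-definite correlation matrix by eigenvalue clipping at `1e-4` —
  planting on the latent scale makes finite-length sampling noise
  realistic rather than assumed away. The effect knob is therefore split
  by modality (`effect_delta_dmri`, `effect_delta_rsfmri`): one number
  cannot be simultaneously a count multiplier and a correlation increment.
* **Motion**: gamma baseline (mean 0.2 mm, SD 0.04 mm, the scale of
  typical mean relative RMS summaries) with a configurable fraction of
  subjects at 10x baseline; outlier ids are recorded.
* **Clinical scores**: `beta *` (mean connectivity over a designated
  planted-edge subset) `+ N(0, sd)`, with the designation recorded so
  correlation recovery can be scored.
* **Scale**: 60 parcels and 30 subjects per group by default — 1,770 node
  pairs keep full permutation runs interactive while exercising every code
  path; the full 333-parcel scale is supported but not the default. One
  master seed fans out to per-stage child seeds so any stage can be rerun
  independently.

What the generator does **not** emulate: fibre geometry, haemodynamics,
scanner artefacts beyond the motion scalar, spatial autocorrelation of
parcels, or site effects. Passing recovery tests therefore demonstrate
statistical correctness of the pipeline, not robustness to every nuisance
structure of real imaging data.

For recovery experiments the planted design
(`planted_overlap_design()`) places a connected path-plus-chord subnetwork
per modality sharing a fixed node subset, with `delta = 9` (a tenfold count
change, at dispersion 6) and a 0.4 correlation shift — pilot-calibrated so
that every planted edge is detectable at `p < 10^{-6}` parametrically,
which is the regime in which full recall is the correct expectation.

## A worked run

```{r, eval = FALSE}
design <- planted_overlap_design(60, n_overlap = 4, n_extra = 3, seed = 5)
cfg <- sim_config(n_parcels = 60,
                  planted_edges_dmri = design$planted_edges_dmri,
                  planted_edges_rsfmri = design$planted_edges_rsfmri,
                  overlap_nodes = design$overlap_nodes,
                  effect_delta_dmri = 9, count_dispersion = 6,
                  effect_delta_rsfmri = 0.4,
                  clinical_beta = 0.05, clinical_noise_sd = 0.5, seed = 11)
sim <- simulate_cohort(cfg)

res <- run_pipeline(sim$cohort,
                    pipeline_config(contrast = list(permutations = 500),
                                    overlap = list(permutations = 300),
                                    clinical = list(permutations = 300),
                                    seed = 3))
res
glance(res)
tidy(res$overlap)
autoplot(res$contrasts$dmri)
plot_subnetwork(res$subnetworks$dmri, 1)
```

## Known limitations

* The permutation stage's final significance level, the BH family for the
  overlap test, the motion-rule sidedness/grouping, and the clinical edge
  family all have ambiguous conventions in the literature this follows;
  each is a documented default with the alternative exposed as an option.
* The node-identity overlap null conditions on the candidate threshold
  `alpha`; very different `alpha` choices change both the observed
  intersect and its null in ways that are not comparable across runs.
* Eigenvector centrality is only computed within connected subnetworks
  (it is not identifiable across disconnected pieces); singleton
  components are assigned centrality 1 and no hub status.
* Validation problem sizes (60 parcels, 30 per group, 500-iteration
  permutation checks, 12-cohort calibration batches) were chosen so the
  whole validation suite runs interactively; all scale parameters are
  configuration, not constants.
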