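# patternsurv

Survival stratification of cancer cohorts by the expression **patterns** —
not the expression levels — of small panels of functionally related
transcripts.

## The problem and who this is for

Most prognostic expression signatures key on how *much* of certain
transcripts a tumor makes. A complementary signal lives in the *relative
pattern* a small gene panel assumes within each tumor: two tumors can have
very different overall expression magnitude yet the same internal pattern,
and cohorts often split into a handful of such pattern groups with markedly
different overall survival. `patternsurv` packages that analysis for
computational oncologists and biostatisticians working with bulk RNA-seq
cohorts (tumor × gene matrices stored as log2(FPKM-UQ + 1), plus a
phenotype table with overall-survival time and event status).

## The method

For a panel of *n* genes, each tumor's panel-restricted expression profile
is a vector in ℝⁿ. The cohort mean vector is subtracted and each centered
vector is rescaled to unit Euclidean norm, placing every tumor on the unit
(n−1)-sphere — magnitude is gone, only pattern remains. The pipeline then:

1. **Embeds** the sphere vectors in 3-D with exact t-SNE, sweeping
   perplexity {5,…,30} × learning rate {0.1, 1, 10, 100}, each run for at
   least 2500 iterations and until the layout stabilizes.
2. **Decides discernibility**: a density-gap partition (single linkage on
   mutual-reachability distances, silhouette-scored) operationalizes
   "obviously distinguishable clusters"; cohorts with no discernible
   structure are *rejected*, not forced.
3. **Assigns clusters** with a K-component Gaussian mixture fitted under
   eight configurations — {full, diagonal} covariance × {shared, unshared}
   × {±5%-of-bounding-radius input perturbation} — keeping the fit whose
   labels best preserve the unity of the discernible clusters (adjusted
   Rand index).
4. **Compares survival** with Kaplan-Meier curves and Mantel-Haenszel
   log-rank tests, reporting the most disparate cluster pair (plus a
   Bonferroni-adjusted column).
5. **Ranks driver transcripts** with a 100-tree random forest's
   out-of-bag permutation importance (prominent ⇔ importance > 1).
6. **Refines**: re-analyzes one cluster with a second panel (sequential
   t-SNE), crosses clusters with whole-transcriptome hierarchical
   ("dendro") partitions, tests subtype enrichment (Fisher exact /
   chi-square), and re-examines stage-restricted subsets under the
   original labels.

A synthetic-cohort generator (`simulate_cohort()`) plants known
directional clusters, exponential survival with cluster-specific hazards,
uniform censoring, nested second-panel structure, subtype enrichment and a
correlated background block — so every stage is testable against ground
truth.

## Worked example

```r
library(patternsurv)

spec <- cohort_spec(
  n_samples = 300,
  panels = list(list(name = "panelA", n_genes = 20, K = 3,
                     theta = pi / 2, sigma = 0.1, amplitude = 2)),
  hazards = log(2) / c(1000, 700, 400),
  censor_horizon = 3000, seed = 1)
cohort <- simulate_cohort(spec)

vectors <- center_and_project(
  subset_to_panel(cohort$expression, cohort$panels$panels[["panelA"]]),
  panel_name = "panelA")
embedding <- run_tsne(vectors, embedding_params(perplexity = 20, seed = 1,
                                                n_iter_max = 3000))
found <- count_discernible_clusters(embedding)
solution <- assign_clusters(embedding, found$K, found$labels, seed = 1)
compare_clusters(solution, cohort$phenotype)
rank_drivers(vectors, solution$labels, seed = 1)
```

Output (verbatim):

```
<embedding> 300 samples in 3-D (perplexity 20, lr 100, 3000 iterations, KL 0.6767)
<cluster_solution> K = 3 (full, unshared) unity 1; sizes: 100/100/100
<survival_report> 3 cluster(s)
  cluster 1: n = 100, median 652 days
  cluster 2: n = 100, median 677 days
  cluster 3: n = 100, median 315 days
  most disparate pair 2 vs 3: p = 3.36e-05
<importance_table> 20 genes, 100 trees, OOB error 0.00178
  panelA_g02: 7 *
  panelA_g03: 1.1 *
  ...
```

Reading it: the three planted pattern clusters are recovered exactly
(adjusted Rand index 1 against the generator's labels; all eight mixture
configurations agree, so the tie-break returns full/unshared/unperturbed).
The poor-prognosis cluster (planted median 400 days; Kaplan-Meier median
315 under ~40% censoring) separates from the best cluster at p = 3×10⁻⁵,
and the forest flags the two transcripts carrying most of the
between-cluster pattern signal (importance > 1, starred).

## Command line

```sh
Rscript inst/cli/pattern-surv simulate --out cohort_dir --seed 3 --n 300 --k 3
Rscript inst/cli/pattern-surv run-all --config cfg.yaml --out results_dir
```

(After installation the launcher also lives at
`system.file("cli", "pattern-surv", package = "patternsurv")`.)

## Panels fixture

`inst/extdata/panels_synthetic_12x212.gmt` is a **synthetic stand-in**
panel registry: 12 cancer-pathway panels over 212 unique NCBI Gene IDs
(221 listed, 9 shared between the purine and pyrimidine panels, panel
sizes 6–30). Gene memberships are plausible but not a transcription of any
published supplement; the registry-level counts are what the tests assert.
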