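# Refinement and integration of cluster solutions: sequential re-analysis of
# one cluster with a second panel, whole-transcriptome hierarchical
# partitions ("dendro" groups), cluster x partition survival
# cross-stratification, categorical enrichment and covariate-restricted
# re-analysis.

#' Sequentially refine one cluster with a second pathway panel
#'
#' Restricts the cohort to the samples of `cluster_id` in the first-panel
#' solution, rebuilds pattern vectors for `panel2` within that subset (fresh
#' subset mean -- each cluster is treated as a new cohort), re-runs the
#' embedding sweep, mixture assignment and survival comparison, and reports
#' whether the sub-split is survival-significant. First-panel labels are
#' never modified.
#'
#' @param expression Full-cohort [expression_matrix()].
#' @param pheno A [phenotype_table()].
#' @param panel1_solution `cluster_solution` for the first panel.
#' @param panel2 A [pathway_panel()].
#' @param cluster_id Cluster to refine.
#' @param seed Integer seed.
#' @param min_subset Minimum subset size; smaller clusters are skipped with
#'   a warning (default 20).
#' @param grid,silhouette_min,base_params Passed to [sweep_and_select()].
#' @param allow_missing Passed to [subset_to_panel()].
#' @return List with `status` ("refined", "rejected" when no discernible
#'   sub-split exists, or "skipped"), and when refined: `solution`,
#'   `survival`, `sweep`.
#' @export
sequential_refine <- function(expression, pheno, panel1_solution, panel2,
                              cluster_id, seed = 1L, min_subset = 20L,
                              grid = default_sweep_grid(),
                              silhouette_min = 0.35,
                              base_params = embedding_params(),
                              allow_missing = FALSE) {
  stopifnot(inherits(panel1_solution, "cluster_solution"))
  ids <- panel1_solution$sample_ids[panel1_solution$labels == cluster_id]
  if (length(ids) == 0L) {
    stop("cluster ", cluster_id, " not present in the panel-1 solution")
  }
  if (length(ids) < min_subset) {
    warning("cluster ", cluster_id, " has ", length(ids),
            " samples (< ", min_subset, "); skipping refinement")
    return(list(status = "skipped", n = length(ids)))
  }
  sub <- expression_matrix(
    expression$values[ids, , drop = FALSE],
    scale = expression$scale
  )
  subm <- subset_to_panel(sub, panel2, allow_missing = allow_missing)
  v <- center_and_project(subm, panel_name = panel2$name)
  sweep <- sweep_and_select(v, grid = grid, seed = seed,
                            silhouette_min = silhouette_min,
                            base_params = base_params)
  if (sweep$status == "rejected") {
    return(list(status = "rejected", n = length(ids), sweep = sweep))
  }
  sol <- assign_clusters(sweep$embedding, sweep$K, sweep$labels,
                         seed = derive_seed(seed, 9L))
  surv <- compare_clusters(sol, pheno)
  list(status = "refined", n = length(ids), solution = sol,
       survival = surv, sweep = sweep,
       significant = !is.na(surv$headline_p) && surv$headline_p < 0.05)
}

#' Hierarchical partition of samples from a wide expression matrix
#'
#' Average-linkage agglomerative clustering of samples on the
#' 1 - Pearson-correlation distance between expression profiles, cut into
#' `k_groups` ("dendro" groups), as an in-package substitute for published
#' whole-transcriptome dendrograms.
#'
#' @param m An [expression_matrix()] (typically the whole-transcriptome or
#'   background block).
#' @param k_groups Number of groups to cut the tree into.
#' @return Object of class `sample_partition`: named vector of group labels
#'   `"Dendro1"`, ... keyed by sample ID.
#' @export
hierarchical_partition <- function(m, k_groups) {
  stopifnot(inherits(m, "expression_matrix"), k_groups >= 1L,
            k_groups <= length(m$sample_ids))
  sds <- apply(m$values, 1L, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant-expression sample(s), correlation undefined: ",
         paste(m$sample_ids[sds < 1e-12], collapse = ", "))
  }
  if (k_groups == length(m$sample_ids)) {
    groups <- paste0("Dendro", seq_along(m$sample_ids))
  } else {
    d <- stats::as.dist(1 - stats::cor(t(m$values)))
    hc <- stats::hclust(d, method = "average")
    groups <- paste0("Dendro", stats::cutree(hc, k = k_groups))
  }
  structure(stats::setNames(groups, m$sample_ids), class = "sample_partition")
}

#' Read a two-column partition TSV (sample_id, group)
#'
#' @param path TSV file with header.
#' @return A `sample_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("partition TSV needs sample_id and group columns")
  structure(stats::setNames(as.character(df[[2]]), as.character(df[[1]])),
            class = "sample_partition")
}

#' Cross-stratify clusters against an external partition
#'
#' Within each cluster, compares survival between partition groups
#' (log-rank) and vice versa; emits the cluster x group contingency table.
#' Cells below `min_group_size` are excluded from the within-stratum tests;
#' strata collapsing to a single group are skipped.
#'
#' @param solution A `cluster_solution`.
#' @param partition A `sample_partition` (or named character vector).
#' @param pheno A [phenotype_table()].
#' @param min_group_size Minimum per-group size inside a stratum.
#' @return List with `contingency`, `within_cluster` (data frame of
#'   log-rank results per cluster), `within_group` (per partition group).
#' @export
cross_stratify <- function(solution, partition, pheno, min_group_size = 5L) {
  stopifnot(inherits(solution, "cluster_solution"))
  ids <- intersect(solution$sample_ids, names(partition))
  ids <- intersect(ids, pheno$sample_id)
  if (length(ids) == 0L) stop("no samples shared by solution and partition")
  lab <- solution$labels[match(ids, solution$sample_ids)]
  grp <- as.character(partition[ids])
  ph <- pheno[match(ids, pheno$sample_id), ]

  contingency <- table(cluster = lab, group = grp)

  test_within <- function(strat, other) {
    out <- data.frame(stratum = character(0), chi_square = numeric(0),
                      p_value = numeric(0), n = integer(0))
    for (s in sort(unique(strat))) {
      sel <- strat == s
      sizes <- table(other[sel])
      keep_groups <- names(sizes)[sizes >= min_group_size]
      use <- sel & other %in% keep_groups
      if (length(unique(other[use])) < 2L || sum(ph$os_event[use]) == 0) next
      lr <- logrank(ph$os_time[use], ph$os_event[use], other[use])
      out <- rbind(out, data.frame(stratum = as.character(s),
                                   chi_square = lr$chi_square,
                                   p_value = lr$p_value, n = sum(use)))
    }
    out
  }
  list(contingency = contingency,
       within_cluster = test_within(lab, grp),
       within_group = test_within(grp, as.character(lab)))
}

#' Enrichment of a focal category within each cluster
#'
#' Per cluster, a 2x2 table (in/out of cluster x in/out of the focal group)
#' tested with a two-sided Fisher exact test plus odds ratio; additionally
#' an overall 2xK chi-square testing whether the focal group is randomly
#' distributed across clusters (expected counts from the cohort's cluster
#' proportions).
#'
#' @param solution A `cluster_solution`.
#' @param partition Named character vector (or `sample_partition`) of
#'   category labels.
#' @param focal_group The category of interest (must be present).
#' @return List with `per_cluster` (data frame: cluster, counts, odds ratio,
#'   Fisher p) and `overall` (chi-square statistic, df, p).
#' @export
enrichment <- function(solution, partition, focal_group) {
  stopifnot(inherits(solution, "cluster_solution"))
  ids <- intersect(solution$sample_ids, names(partition))
  if (length(ids) == 0L) stop("no samples shared by solution and partition")
  lab <- solution$labels[match(ids, solution$sample_ids)]
  focal <- as.character(partition[ids]) == as.character(focal_group)
  if (!any(focal)) stop("focal group '", focal_group, "' not present")

  clusters <- sort(unique(lab))
  per <- data.frame(cluster = clusters, n_cluster = NA_integer_,
                    n_focal_in = NA_integer_, odds_ratio = NA_real_,
                    p_fisher = NA_real_)
  for (i in seq_along(clusters)) {
    k <- clusters[i]
    a <- sum(lab == k & focal)
    b <- sum(lab == k & !focal)
    c <- sum(lab != k & focal)
    d <- sum(lab != k & !focal)
    tab <- matrix(c(a, b, c, d), 2L, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    per$n_cluster[i] <- a + b
    per$n_focal_in[i] <- a
    # sample odds ratio (ad/bc), 0 allowed at the boundary
    per$odds_ratio[i] <- if (b * c == 0 && a * d == 0) NA_real_
                         else (a * d) / max(b * c, .Machine$double.xmin)
    per$p_fisher[i] <- ft$p.value
  }
  counts <- table(factor(lab, levels = clusters), focal)
  suppressWarnings(ch <- stats::chisq.test(counts, correct = FALSE))
  list(per_cluster = per,
       overall = list(chi_square = unname(ch$statistic),
                      df = unname(ch$parameter),
                      p_value = unname(ch$p.value)))
}

#' Restrict a phenotype table to one covariate value
#'
#' Returns the matching sample IDs; downstream survival analyses run on the
#' subset while retaining the full-cohort cluster labels (advanced-stage
#' tumors are located within the original clusters, not re-embedded).
#'
#' @param pheno A [phenotype_table()].
#' @param column Covariate column name.
#' @param value Covariate value to keep.
#' @return Character vector of sample IDs.
#' @export
filter_by_covariate <- function(pheno, column, value) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (!column %in% colnames(pheno)) {
    stop("unknown phenotype column: ", column)
  }
  ids <- pheno$sample_id[pheno[[column]] == value]
  if (length(ids) == 0L) stop("no samples with ", column, " == ", value)
  ids
}

#' Subset a cluster solution to given samples, keeping labels
#'
#' @param solution A `cluster_solution`.
#' @param sample_ids Samples to keep (order preserved).
#' @return A `cluster_solution` restricted to those samples.
#' @export
subset_solution <- function(solution, sample_ids) {
  stopifnot(inherits(solution, "cluster_solution"))
  idx <- match(sample_ids, solution$sample_ids)
  if (anyNA(idx)) {
    stop("sample(s) absent from solution: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  out <- solution
  out$sample_ids <- solution$sample_ids[idx]
  out$labels <- solution$labels[idx]
  out$posteriors <- solution$posteriors[idx, , drop = FALSE]
  out
}
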