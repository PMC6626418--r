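bg_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_spec(
        n_samples = 120L, n_background_genes = 90L, background_blocks = 3L,
        background_overlap = 1.0, seed = 17L))
    }
    cache
  }
})

test_that("hierarchical partition recovers planted correlated blocks", {
  co <- bg_cohort()
  bg_genes <- grep("^bg_", co$expression$gene_ids, value = TRUE)
  m <- expression_matrix(co$expression$values[, bg_genes],
                         scale = co$expression$scale)
  part <- hierarchical_partition(m, 3L)
  expect_gte(adjusted_rand_index(as.integer(factor(part)),
                                 co$truth$block_labels), 0.9)

  expect_true(all(hierarchical_partition(m, 1L) == "Dendro1"))
  singletons <- hierarchical_partition(m, length(m$sample_ids))
  expect_equal(length(unique(singletons)), length(m$sample_ids))
})

test_that("constant-expression samples make correlation distances fail loudly", {
  vals <- matrix(stats::runif(30, 1, 5), 6,
                 dimnames = list(sprintf("s%d", 1:6), sprintf("g%d", 1:5)))
  vals[2, ] <- 3
  m <- expression_matrix(vals, scale = "fpkm_uq")
  expect_error(hierarchical_partition(m, 2L), "s2")
})

test_that("cross-stratification tables conserve margins and find planted splits", {
  co <- bg_cohort()
  truth <- co$truth$panel_labels$panelA
  sol <- make_solution(co$expression$sample_ids, truth)
  part <- structure(stats::setNames(co$phenotype$dendro,
                                    co$phenotype$sample_id),
                    class = "sample_partition")
  res <- cross_stratify(sol, part, co$phenotype)
  expect_equal(sum(res$contingency), 120L)
  expect_equal(unname(rowSums(res$contingency)), unname(table(truth)),
               ignore_attr = TRUE)

  # partition identical to the clusters: within-stratum tests degenerate
  same <- structure(stats::setNames(paste0("Dendro", truth),
                                    co$expression$sample_ids),
                    class = "sample_partition")
  res2 <- cross_stratify(sol, same, co$phenotype)
  expect_equal(nrow(res2$within_cluster), 0L)

  expect_error(cross_stratify(sol, structure(stats::setNames("x", "zz"),
                                             class = "sample_partition"),
                              co$phenotype), "no samples shared")
})

test_that("partition-dependent hazards are detected only where planted", {
  # survival keyed to the partition inside cluster 1 only
  set.seed(33)
  n <- 240
  ids <- sprintf("s%03d", 1:n)
  cl <- rep(1:2, each = n / 2)
  grp <- rep(c("DendroA", "DendroB"), n / 2)
  lambda <- ifelse(cl == 1 & grp == "DendroA", log(2) / 250, log(2) / 1000)
  time <- stats::rexp(n, lambda)
  pheno <- phenotype_table(data.frame(sample_id = ids, os_time = time,
                                      os_event = 1))
  res <- cross_stratify(make_solution(ids, cl),
                        structure(stats::setNames(grp, ids),
                                  class = "sample_partition"),
                        pheno)
  wc <- res$within_cluster
  expect_lt(wc$p_value[wc$stratum == "1"], 0.01)
  expect_gt(wc$p_value[wc$stratum == "2"], 0.01)
})

test_that("Fisher enrichment matches the enumeration oracle", {
  ids <- sprintf("s%02d", 1:20)
  lab <- rep(1:2, each = 10)
  part <- stats::setNames(rep(c("T", "O"), each = 10), ids)
  res <- enrichment(make_solution(ids, lab), part, "T")
  row1 <- res$per_cluster[res$per_cluster$cluster == 1, ]
  expect_equal(row1$p_fisher, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(row1$n_focal_in, 10L)

  for (seed in 1:20) {
    set.seed(seed)
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0) next
    expect_equal(stats::fisher.test(matrix(c(a, b, c, d), 2,
                                           byrow = TRUE))$p.value,
                 fisher_oracle(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("proportional and boundary enrichment cases behave", {
  ids <- sprintf("s%03d", 1:200)
  lab <- rep(1:4, each = 50)
  # exactly proportional focal group: 15 of 50 in every cluster
  part <- stats::setNames(rep(c(rep("T", 15), rep("O", 35)), 4), ids)
  res <- enrichment(make_solution(ids, lab), part, "T")
  expect_equal(res$overall$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$overall$p_value, 1)
  expect_equal(res$per_cluster$odds_ratio, rep(1, 4), tolerance = 1e-12)
  expect_true(all(res$per_cluster$p_fisher == 1))

  # focal group absent from cluster 1 but present elsewhere: OR 0, finite p
  part2 <- stats::setNames(c(rep("O", 50), rep("T", 150)), ids)
  res2 <- enrichment(make_solution(ids, lab), part2, "T")
  row1 <- res2$per_cluster[1, ]
  expect_equal(row1$odds_ratio, 0)
  expect_true(is.finite(row1$p_fisher))
})

test_that("covariate filtering keeps full-cohort labels", {
  co <- bg_cohort()
  spec_stage <- cohort_spec(n_samples = 120L, seed = 23L,
                            stage_probs = c(I = 0.4, II = 0.3, IV = 0.3))
  cs <- simulate_cohort(spec_stage)
  ids <- filter_by_covariate(cs$phenotype, "stage", "IV")
  expect_true(all(cs$phenotype$stage[match(ids, cs$phenotype$sample_id)] ==
                    "IV"))
  expect_error(filter_by_covariate(cs$phenotype, "nope", "IV"),
               "unknown phenotype column")
  expect_error(filter_by_covariate(cs$phenotype, "stage", "V"), "no samples")

  sol <- make_solution(cs$expression$sample_ids, cs$truth$panel_labels$panelA)
  sub <- subset_solution(sol, ids)
  expect_identical(sub$labels,
                   sol$labels[match(ids, sol$sample_ids)])
  expect_error(subset_solution(sol, "ghost"), "absent from solution")
})

test_that("stage assigned independently of clusters is not enriched", {
  hits <- 0L
  for (seed in 1:20) {
    cs <- simulate_cohort(cohort_spec(
      n_samples = 200L, seed = 300L + seed,
      stage_probs = c(I = 0.4, II = 0.3, IV = 0.3)))
    sol <- make_solution(cs$expression$sample_ids,
                         cs$truth$panel_labels$panelA)
    part <- stats::setNames(cs$phenotype$stage, cs$phenotype$sample_id)
    res <- enrichment(sol, part, "IV")
    if (res$overall$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L) # >= 90% of null replicates
})

test_that("sequential refinement honors guards and planted nesting", {
  spec <- cohort_spec(
    n_samples = 260L,
    panels = list(
      list(name = "p1", n_genes = 12L, K = 2L, theta = pi / 2, sigma = 0.1),
      list(name = "p2", n_genes = 12L, K = 3L, theta = pi / 2, sigma = 0.1)
    ),
    hazards = log(2) / c(1000, 400, 700), censor_horizon = 6000,
    nesting = list("1" = c(1L, 2L)), seed = 91L)
  co <- nested_refinement_cohort(spec)
  sol1 <- make_solution(co$expression$sample_ids, co$truth$panel_labels$p1)
  panel2 <- co$panels$panels[["p2"]]
  grid1 <- data.frame(perplexity = 15, learning_rate = 100)

  ref <- sequential_refine(co$expression, co$phenotype, sol1, panel2,
                           cluster_id = 1L, seed = 5L, grid = grid1,
                           base_params = fast_params())
  expect_identical(ref$status, "refined")
  expect_equal(ref$solution$K, 2L)
  expect_true(ref$significant)
  # upstream labels untouched
  expect_identical(sol1$labels, co$truth$panel_labels$p1)

  rej <- sequential_refine(co$expression, co$phenotype, sol1, panel2,
                           cluster_id = 2L, seed = 5L, grid = grid1,
                           base_params = fast_params())
  expect_identical(rej$status, "rejected")

  lab_small <- co$truth$panel_labels$p1
  lab_small[lab_small == 2][-(1:10)] <- 1L
  sol_small <- make_solution(co$expression$sample_ids, lab_small)
  expect_warning(
    sk <- sequential_refine(co$expression, co$phenotype, sol_small, panel2,
                            cluster_id = 2L, grid = grid1,
                            base_params = fast_params()),
    "skipping")
  expect_identical(sk$status, "skipped")
})
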