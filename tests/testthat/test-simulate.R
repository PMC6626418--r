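test_that("identical seeds reproduce the cohort exactly", {
  spec <- cohort_spec(n_samples = 60L, seed = 11L,
                      n_background_genes = 30L,
                      stage_probs = c(I = 0.5, IV = 0.5))
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(as.data.frame(a$phenotype), as.data.frame(b$phenotype))
  expect_identical(a$truth, b$truth)
})

test_that("K = 1 collapses to a single trivially recoverable cluster", {
  spec <- cohort_spec(n_samples = 30L,
                      panels = list(list(name = "p", n_genes = 10L, K = 1L,
                                         theta = pi / 2, sigma = 0.1)),
                      hazards = log(2) / 800, seed = 2L)
  co <- simulate_cohort(spec)
  truth <- co$truth$panel_labels$p
  expect_true(all(truth == 1L))
  expect_equal(adjusted_rand_index(truth, rep(1L, 30)), 1)
})

test_that("pattern directions respect the pairwise-angle contract", {
  set.seed(5)
  dirs <- patternsurv:::pattern_directions(10, 4, pi / 2)
  expect_equal(unname(rowSums(dirs^2)), rep(1, 4), tolerance = 1e-9)
  ang <- acos(pmin(1, tcrossprod(dirs)[upper.tri(diag(4))]))
  expect_true(all(ang >= pi / 2 - 1e-9))
  # infeasible: more near-orthogonal directions than dimensions
  expect_error(patternsurv:::pattern_directions(2, 5, pi / 2), "cannot place")
})

test_that("uncensored event times follow the planted exponentials", {
  # near-infinite horizon => os_time is the raw event time
  spec <- cohort_spec(n_samples = 2000L,
                      panels = list(list(name = "p", n_genes = 6L, K = 2L,
                                         theta = pi / 2, sigma = 0.2)),
                      hazards = c(log(2) / 1000, log(2) / 500),
                      censor_horizon = 1e9, seed = 31L)
  co <- simulate_cohort(spec)
  truth <- co$truth$panel_labels$p
  expect_true(all(co$phenotype$os_event == 1))
  for (k in 1:2) {
    t_k <- co$phenotype$os_time[truth == k]
    ks <- stats::ks.test(t_k, "pexp", rate = spec$hazards[k])
    expect_gt(ks$p.value, 0.01)
    expect_equal(stats::median(t_k), log(2) / spec$hazards[k],
                 tolerance = 0.15) # median of ~1000 exponential draws

  }
})

test_that("censoring fraction decreases as the horizon grows", {
  fractions <- vapply(c(800, 2000, 6000), function(h) {
    spec <- cohort_spec(n_samples = 400L, censor_horizon = h, seed = 7L)
    mean(simulate_cohort(spec)$phenotype$os_event == 0)
  }, numeric(1))
  expect_true(all(diff(fractions) < 0))
})

test_that("nested cohorts refine panel-1 clusters and key hazards to panel 2", {
  spec <- cohort_spec(
    n_samples = 200L,
    panels = list(
      list(name = "p1", n_genes = 12L, K = 2L, theta = pi / 2, sigma = 0.1),
      list(name = "p2", n_genes = 12L, K = 3L, theta = pi / 2, sigma = 0.1)
    ),
    hazards = log(2) / c(1000, 500, 800),
    nesting = list("1" = c(1L, 2L)), seed = 13L)
  co <- nested_refinement_cohort(spec)
  l1 <- co$truth$panel_labels$p1
  l2 <- co$truth$panel_labels$p2
  # each panel-2 cluster sits inside exactly one panel-1 cluster
  expect_true(all(vapply(split(l1, l2), function(x) length(unique(x)),
                         integer(1)) == 1L))
  expect_setequal(unique(l2[l1 == 1]), c(1L, 2L))
  expect_length(unique(l2[l1 == 2]), 1L)
  # hazards follow the panel-2 labels
  expect_equal(co$truth$lambda, spec$hazards[l2])

  expect_error(
    simulate_cohort(cohort_spec(
      panels = spec$panels, hazards = spec$hazards,
      nesting = list("9" = c(1L, 2L)), seed = 1L)),
    "unknown panel-1 cluster")
})

test_that("empty nesting is identical to the plain generator", {
  spec <- cohort_spec(n_samples = 50L, seed = 3L, nesting = list())
  a <- nested_refinement_cohort(spec)
  b <- simulate_cohort(cohort_spec(n_samples = 50L, seed = 3L))
  expect_identical(a$expression$values, b$expression$values)
})

test_that("background blocks align with clusters at the requested rate", {
  spec <- cohort_spec(n_samples = 600L, n_background_genes = 60L,
                      background_blocks = 3L, background_overlap = 0.8,
                      seed = 21L)
  co <- simulate_cohort(spec)
  l1 <- co$truth$panel_labels$panelA
  aligned <- mean(co$truth$block_labels == ((l1 - 1L) %% 3L) + 1L)
  expect_gt(aligned, 0.75) # 0.8 planted plus chance alignment of the rest
  expect_true(all(co$phenotype$dendro %in% paste0("Dendro", 1:3)))
})
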