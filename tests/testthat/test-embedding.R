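test_that("t-SNE is deterministic given the seed and guards its inputs", {
  co <- reference_cohort()
  v <- center_and_project(subset_to_panel(co$expression,
                                          co$panels$panels[[1]]))
  e1 <- run_tsne(v, fast_params(seed = 5))
  e2 <- run_tsne(v, fast_params(seed = 5))
  expect_identical(e1$coords, e2$coords)
  e3 <- run_tsne(v, fast_params(seed = 6))
  expect_false(identical(e1$coords, e3$coords))
  expect_gte(e1$iterations, 400L)
  expect_true(is.finite(e1$kl_divergence))

  # guard: n must exceed 3 * perplexity
  small <- subset_vectors(v, v$sample_ids[1:50])
  expect_error(run_tsne(small, fast_params(perplexity = 30)),
               "reduce the perplexity")
})

test_that("planted directional clusters stay separated in the embedding", {
  co <- reference_cohort()
  v <- center_and_project(subset_to_panel(co$expression,
                                          co$panels$panels[[1]]))
  emb <- run_tsne(v, fast_params(seed = 2))
  sil <- silhouette_score(emb$coords, co$truth$panel_labels$p)
  expect_gte(sil, 0.7)
})

test_that("an unrelated t-SNE implementation sees the same planted structure", {
  # cross-check oracle: Rtsne (independent code base) embeds the same
  # pattern vectors; both implementations should separate the planted
  # clusters cleanly
  skip_if_not_installed("Rtsne")
  co <- reference_cohort()
  v <- center_and_project(subset_to_panel(co$expression,
                                          co$panels$panels[[1]]))
  truth <- co$truth$panel_labels$p
  set.seed(123)
  ref <- Rtsne::Rtsne(v$vectors, dims = 3, perplexity = 15, theta = 0,
                      max_iter = 700, pca = FALSE)
  expect_gte(silhouette_score(ref$Y, truth), 0.7)
  ours <- run_tsne(v, fast_params(seed = 123))
  expect_gte(silhouette_score(ours$coords, truth), 0.7)
})

test_that("count_discernible_clusters reads blob geometry correctly", {
  # all points inside a tiny ball: one indiscernible mass
  set.seed(1)
  tight <- matrix(rnorm(300, 0, 1e-3), 100, 3)
  cd <- count_discernible_clusters(tight)
  expect_equal(cd$K, 1L)
  expect_false(cd$discernible)

  # three blobs, centroid separation >= 10x the within-blob sd
  blobs <- make_blobs(150, 3, sep = 10, sd = 1, seed = 4)
  cd3 <- count_discernible_clusters(blobs$coords)
  expect_equal(cd3$K, 3L)
  expect_true(cd3$discernible)
  expect_equal(adjusted_rand_index(cd3$labels, blobs$labels), 1)

  # two blobs plus 5% uniform background noise: noise attaches to a blob
  b2 <- make_blobs(190, 2, sep = 12, sd = 1, seed = 9)
  set.seed(10)
  noise <- matrix(runif(30, -15, 15), 10, 3)
  coords <- rbind(b2$coords, noise)
  cdn <- count_discernible_clusters(coords)
  expect_equal(cdn$K, 2L)
  expect_length(cdn$labels, 200L)
  expect_equal(adjusted_rand_index(cdn$labels[1:190], b2$labels), 1)
})

test_that("sweep selects on planted structure and rejects noise", {
  co <- reference_cohort()
  v <- center_and_project(subset_to_panel(co$expression,
                                          co$panels$panels[[1]]))
  grid1 <- data.frame(perplexity = 15, learning_rate = 100)
  sel <- sweep_and_select(v, grid = grid1, seed = 8,
                          base_params = fast_params())
  expect_identical(sel$status, "selected")
  expect_equal(sel$K, 3L)
  expect_equal(nrow(sel$sweep_record), 1L)
  expect_length(sel$validation_K, 3L)

  # isotropic noise: no grid point yields discernible clusters
  set.seed(77)
  noise <- matrix(rnorm(120 * 10), 120, 10)
  noise <- noise / sqrt(rowSums(noise^2))
  rownames(noise) <- sprintf("n%03d", 1:120)
  vn <- structure(list(sample_ids = rownames(noise), vectors = noise,
                       panel_name = "noise", n = 10L),
                  class = "pattern_vectors")
  rej <- sweep_and_select(vn, grid = grid1, seed = 8,
                          base_params = fast_params())
  expect_identical(rej$status, "rejected")
})

test_that("hold-out label transfer matches its oracles", {
  co <- reference_cohort()
  v <- center_and_project(subset_to_panel(co$expression,
                                          co$panels$panels[[1]]))
  truth <- co$truth$panel_labels$p

  # perfectly separated planted clusters transfer almost perfectly
  res <- holdout_confirm(v, truth, seed = 3)
  expect_gte(res$agreement, 0.95)
  expect_gt(res$n_test, 0)

  # shuffled labels transfer at about the majority-class frequency
  set.seed(6)
  agree_null <- mean(vapply(1:20, function(s) {
    holdout_confirm(v, sample(truth), seed = s)$agreement
  }, numeric(1)))
  expect_equal(agree_null, max(table(truth)) / length(truth),
               tolerance = 0.15)

  # K = 1 is trivially consistent
  expect_equal(holdout_confirm(v, rep(1L, length(truth)))$agreement, 1.0)

  # micro-clusters are excluded with a warning
  lab <- truth
  lab[1:2] <- 99L
  expect_warning(holdout_confirm(v, lab, seed = 1), "< 4 members")
})

test_that("derived seeds stay positive 32-bit integers", {
  s <- vapply(1:500, function(i) patternsurv:::derive_seed(123456L, i),
              integer(1))
  expect_true(all(s >= 1L))
  expect_true(all(s <= 2147483647L))
  expect_gt(length(unique(s)), 490L)
})
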