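test_that("bounding sphere handles degenerate and exact cases", {
  one <- matrix(c(1, 2, 3), 1)
  bs <- bounding_sphere(one)
  expect_equal(bs$radius, 0)
  expect_equal(bs$center, c(1, 2, 3))

  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  bs2 <- bounding_sphere(two)
  expect_equal(bs2$center, c(1, 0, 0))
  expect_equal(bs2$radius, 1)
})

test_that("Ritter radius is within 5% of the exact minimal sphere", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  bs <- bounding_sphere(cube)
  exact <- welzl_oracle(cube)
  expect_equal(exact$radius, sqrt(3) / 2, tolerance = 1e-9)
  expect_lte(bs$radius, exact$radius * 1.05)
  expect_gte(bs$radius, exact$radius - 1e-9)

  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(rnorm(8 * 3), 8, 3)
    bs <- bounding_sphere(pts)
    exact <- welzl_oracle(pts)
    expect_lte(bs$radius, exact$radius * 1.05)
    expect_gte(bs$radius, exact$radius - 1e-9)
  }
})

test_that("perturbation is bounded, seeded and a no-op at radius 0", {
  set.seed(2)
  pts <- matrix(rnorm(60), 20, 3)
  r <- bounding_sphere(pts)$radius
  p1 <- perturb_coords(pts, r, seed = 4)
  p2 <- perturb_coords(pts, r, seed = 4)
  expect_identical(p1, p2)
  disp <- sqrt(rowSums((p1 - pts)^2))
  expect_true(all(disp <= 0.05 * r + 1e-12))
  expect_true(any(disp > 0))
  expect_identical(perturb_coords(pts, 0, seed = 1), pts)
})

test_that("mixture fitting covers K = 1 and all eight configurations", {
  sol1 <- fit_mixture(make_blobs(40, 1, seed = 1)$coords, 1L)
  expect_true(all(sol1$labels == 1L))
  expect_true(all(sol1$posteriors == 1))

  blobs <- make_blobs(120, 2, sep = 20, sd = 1, seed = 3)
  cfgs <- mixture_configs()
  expect_equal(nrow(cfgs), 8L)
  for (i in seq_len(nrow(cfgs))) {
    sol <- fit_mixture(blobs$coords, 2L, config = as.list(cfgs[i, ]),
                       seed = 5L)
    expect_equal(adjusted_rand_index(sol$labels, blobs$labels), 1,
                 info = paste("config", i))
    expect_equal(rowSums(sol$posteriors), rep(1, 120), tolerance = 1e-9)
    expect_equal(sol$labels, max.col(sol$posteriors, "first"))
  }
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
  a <- rep(1:3, each = 20)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, ((a %% 3) + 1)), 1) # relabelled
  set.seed(8)
  null_ari <- replicate(50, adjusted_rand_index(a, sample(a)))
  expect_lt(abs(mean(null_ari)), 0.05)
})

test_that("assign_clusters preserves unity and applies the tie-break", {
  blobs <- make_blobs(150, 3, sep = 20, sd = 1, seed = 6)
  sol <- assign_clusters(blobs$coords, 3L, blobs$labels, seed = 2)
  expect_equal(sol$unity_score, 1)
  expect_true(all(sol$config_record$unity_score == 1))
  # tie-break: first configuration in the fixed order
  expect_identical(sol$config$covariance, "full")
  expect_false(sol$config$shared)
  expect_false(sol$config$perturb_input)
  expect_equal(adjusted_rand_index(sol$labels, blobs$labels), 1)

  solK1 <- assign_clusters(blobs$coords, 1L, rep(1L, 150), seed = 2)
  expect_equal(solK1$unity_score, 1.0)
  expect_true(all(solK1$labels == 1L))
})

test_that("full-covariance assignment is rotation invariant", {
  blobs <- make_blobs(90, 3, sep = 15, sd = 1, seed = 12)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  sol_a <- assign_clusters(blobs$coords, 3L, blobs$labels, seed = 4)
  sol_b <- assign_clusters(blobs$coords %*% rot, 3L, blobs$labels, seed = 4)
  expect_equal(adjusted_rand_index(sol_a$labels, sol_b$labels), 1)
})

test_that("full covariance wins on strongly anisotropic clusters", {
  # two parallel elongated clusters (10:1 anisotropy), separated along the
  # short axis: axis-aligned-diagonal fits can split the long axis instead
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80
    dir_long <- c(1, 1, 0) / sqrt(2)
    base <- outer(rnorm(n, 0, 10), dir_long)
    off <- outer(rnorm(n, 0, 1), c(1, -1, 0) / sqrt(2))
    shift <- rep(c(-3, 3), each = n / 2)
    coords <- base + off + cbind(0, 0, shift) + matrix(rnorm(3 * n, 0, 1), n)
    labels <- rep(1:2, each = n / 2)
    rec <- assign_clusters(coords, 2L, labels, seed = seed)$config_record
    full_best <- max(rec$unity_score[rec$covariance == "full"])
    diag_best <- max(rec$unity_score[rec$covariance == "diagonal"])
    if (full_best >= diag_best) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
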