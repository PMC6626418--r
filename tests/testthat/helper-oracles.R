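# Independent oracles. Each is deliberately written from the definition of
# the quantity it checks (or delegates to an unrelated, established
# implementation), never by calling the package code path under test.

# Direct product-limit computation straight from the estimator's definition
# (vectorized, unlike the package's sequential accumulation): at each
# distinct event time t, S(t) multiplies in (1 - d_t / n_t) with d_t the
# deaths at t and n_t the number still at risk.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  d <- vapply(ts, function(t) sum(time == t & event == 1), numeric(1))
  n_at <- vapply(ts, function(t) sum(time >= t), numeric(1))
  # sequential double-precision products (cumprod would accumulate in
  # extended precision and differ in the last bit)
  unlist(Reduce(`*`, 1 - d / n_at, accumulate = TRUE))
}

# Exhaustive-permutation p value for the two-group log-rank statistic on a
# micro-cohort: every assignment of nA subjects to group A is enumerated and
# the observed chi-square is ranked among the permutation distribution. The
# statistic itself comes from survival::survdiff (an implementation
# unrelated to the package's).
perm_logrank_oracle <- function(time, event, group) {
  n <- length(time)
  idx_a <- which(group == sort(unique(group))[1])
  nA <- length(idx_a)
  chisq_of <- function(g) {
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }
  obs <- chisq_of(group)
  combos <- utils::combn(n, nA)
  stats <- apply(combos, 2L, function(sel) {
    g <- rep("B", n)
    g[sel] <- "A"
    if (sum(event[g == "A"]) + sum(event[g == "B"]) == 0) return(NA_real_)
    chisq_of(g)
  })
  mean(stats >= obs - 1e-12, na.rm = TRUE)
}

# Two-sided Fisher exact p by direct hypergeometric enumeration over every
# table with the observed margins: sum the probabilities of all tables no
# more probable than the observed one.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact minimal enclosing sphere by exhaustive search over support sets:
# every pair (diametral sphere) and every circumsphere of 3..(d+1)-point
# subsets is tried; the smallest sphere covering all points wins. Only
# usable for small n; kept as the oracle for the Ritter approximation.
welzl_oracle <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  d <- ncol(pts)
  best <- list(radius = Inf, center = NULL)
  covers <- function(center, radius) {
    all(sqrt(rowSums((pts - matrix(center, n, d, byrow = TRUE))^2)) <=
          radius + 1e-9)
  }
  consider <- function(center, radius) {
    if (!is.null(center) && radius < best$radius && covers(center, radius)) {
      best <<- list(radius = radius, center = center)
    }
  }
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      center <- (pts[i, ] + pts[j, ]) / 2
      consider(center, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
    }
  }
  # circumsphere of an m-point support set: the center lies in the points'
  # affine hull, center = p1 + t(A) y with A the rows (p_k - p1); the
  # equidistance conditions give (A t(A)) y = rhs - A p1.
  for (m in 3:min(n, d + 1)) {
    for (sel in utils::combn(n, m, simplify = FALSE)) {
      p1 <- pts[sel[1], ]
      A <- t(vapply(sel[-1], function(k) pts[k, ] - p1, numeric(d)))
      rhs <- vapply(sel[-1], function(k) {
        (sum(pts[k, ]^2) - sum(p1^2)) / 2
      }, numeric(1))
      y <- tryCatch(solve(A %*% t(A), rhs - A %*% p1),
                    error = function(e) NULL)
      if (!is.null(y)) {
        center <- p1 + drop(t(A) %*% y)
        consider(center, sqrt(sum((center - p1)^2)))
      }
    }
  }
  best
}

# Well-separated isotropic Gaussian blobs in `dim` dimensions; `sep` is the
# guaranteed minimum pairwise distance between blob centers.
make_blobs <- function(n, K, sep = 10, sd = 1, dim = 3, seed = 1) {
  set.seed(seed)
  labels <- sample(rep_len(seq_len(K), n))
  repeat {
    centers <- matrix(rnorm(K * dim), K, dim)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    if (K == 1L || min(dist(centers)) >= sep) break
  }
  coords <- centers[labels, , drop = FALSE] + matrix(rnorm(n * dim, 0, sd),
                                                     n, dim)
  rownames(coords) <- sprintf("S%03d", seq_len(n))
  list(coords = coords, labels = labels)
}

# Minimal cluster_solution wrapper around known labels (used to test
# downstream stages in isolation from the embedding stages).
make_solution <- function(sample_ids, labels) {
  K <- max(labels)
  post <- matrix(0, length(labels), K)
  post[cbind(seq_along(labels), labels)] <- 1
  structure(list(sample_ids = sample_ids, labels = as.integer(labels),
                 posteriors = post, K = K,
                 config = list(covariance = "full", shared = FALSE,
                               perturb_input = FALSE),
                 unity_score = 1, seed = 0L),
            class = "cluster_solution")
}

# Short-iteration embedding parameters for unit tests that exercise
# behavior, not the production iteration contract.
fast_params <- function(perplexity = 15, seed = 1L) {
  embedding_params(perplexity = perplexity, learning_rate = 100, seed = seed,
                   n_iter_min = 400L, n_iter_max = 700L)
}

# Small reference cohort shared by several test files (cached per session).
reference_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(
        n_samples = 150L,
        panels = list(list(name = "p", n_genes = 15L, K = 3L, theta = pi / 2,
                           sigma = 0.1, amplitude = 2)),
        hazards = log(2) / c(1000, 700, 400), censor_horizon = 3000,
        seed = 42L
      )
      cache <<- simulate_cohort(spec)
    }
    cache
  }
})
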