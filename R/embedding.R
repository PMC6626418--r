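# 3-D t-SNE of pattern vectors plus the "obviously distinguishable clusters"
# decision. The visual criterion -- dense point collections separated by
# clearly empty regions -- is operationalized as a density-gap partition:
# single linkage on mutual-reachability distances, candidate cuts scored by
# mean silhouette, small components treated as noise and attached to the
# nearest dense group. An embedding is discernible iff the best partition has
# K >= 2 and silhouette >= `silhouette_min`.

#' t-SNE embedding parameters
#'
#' @param perplexity Effective neighborhood size. Sweep mode uses 5..30.
#' @param learning_rate Gradient-descent step size. Sweep mode uses
#'   0.1, 1, 10, 100.
#' @param seed Integer seed; the embedding is deterministic given the seed.
#' @param n_iter_min Minimum number of iterations before the stabilization
#'   check may stop the run.
#' @param n_iter_max Hard iteration cap.
#' @param stabilization_tol Windowed mean per-point displacement (normalized
#'   by the layout's bounding radius) below which the run is stable.
#' @param stabilization_window Window length (iterations) for the check.
#' @param dim Output dimensionality; 3 throughout this package.
#' @return Object of class `embedding_params`.
#' @export
embedding_params <- function(perplexity = 20, learning_rate = 100,
                             seed = 1L, n_iter_min = 2500L,
                             n_iter_max = 50000L,
                             stabilization_tol = 1e-4,
                             stabilization_window = 50L, dim = 3L) {
  stopifnot(perplexity > 0, learning_rate > 0, n_iter_min >= 1L,
            n_iter_max >= n_iter_min, stabilization_tol > 0,
            stabilization_window >= 1L)
  structure(list(perplexity = perplexity, learning_rate = learning_rate,
                 seed = as.integer(seed), n_iter_min = as.integer(n_iter_min),
                 n_iter_max = as.integer(n_iter_max),
                 stabilization_tol = stabilization_tol,
                 stabilization_window = as.integer(stabilization_window),
                 dim = as.integer(dim)),
            class = "embedding_params")
}

#' Run exact t-SNE on pattern vectors
#'
#' Runs at least `n_iter_min` iterations, then continues until the windowed
#' mean per-point displacement stabilizes (or `n_iter_max` is reached).
#'
#' @param v A `pattern_vectors` object (see [center_and_project()]).
#' @param params An [embedding_params()].
#' @return Object of class `embedding`: `sample_ids`, `coords` (samples x 3),
#'   `params`, `kl_divergence`, `iterations`.
#' @export
run_tsne <- function(v, params = embedding_params()) {
  stopifnot(inherits(v, "pattern_vectors"), inherits(params, "embedding_params"))
  n <- nrow(v$vectors)
  if (n <= 3 * params$perplexity) {
    stop("need n_samples > 3 * perplexity (n = ", n, ", perplexity = ",
         params$perplexity, "); reduce the perplexity")
  }
  res <- .tsne_cpp(v$vectors, params$perplexity, params$learning_rate,
                   params$seed, dim = params$dim,
                   iter_min = params$n_iter_min,
                   iter_max = params$n_iter_max,
                   stab_window = params$stabilization_window,
                   stab_tol = params$stabilization_tol)
  coords <- res$Y
  rownames(coords) <- v$sample_ids
  structure(list(sample_ids = v$sample_ids, coords = coords,
                 params = params, kl_divergence = res$kl_divergence,
                 iterations = res$iterations),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding> ", length(x$sample_ids), " samples in ",
      ncol(x$coords), "-D (perplexity ", x$params$perplexity,
      ", lr ", x$params$learning_rate, ", ", x$iterations,
      " iterations, KL ", signif(x$kl_divergence, 4), ")\n", sep = "")
  invisible(x)
}

#' Mean silhouette width of a labelled point set
#'
#' @param coords Numeric matrix of points.
#' @param labels Integer labels.
#' @return Mean silhouette width, or `NA` when fewer than 2 groups.
#' @export
silhouette_score <- function(coords, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

# Density-gap reference partition of a 3-D layout. Returns labels (1..K),
# K and the silhouette of the partition. `k_max` caps the number of candidate
# cuts considered.
density_partition <- function(coords, min_cluster_size = NULL, k_max = 10L) {
  n <- nrow(coords)
  if (is.null(min_cluster_size)) min_cluster_size <- max(5L, ceiling(0.02 * n))
  d <- as.matrix(stats::dist(coords))
  if (max(d) < 1e-12) {
    return(list(labels = rep(1L, n), K = 1L, silhouette = NA_real_))
  }
  min_pts <- min(min_cluster_size, n - 1L)
  core <- apply(d, 1L, function(r) sort(r)[min_pts + 1L])
  mreach <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")

  best <- list(labels = rep(1L, n), K = 1L, silhouette = NA_real_)
  best_sil <- -Inf
  for (k in 2:min(k_max, n - 1L)) {
    raw <- stats::cutree(hc, k = k)
    sizes <- table(raw)
    dense <- as.integer(names(sizes)[sizes >= min_cluster_size])
    if (length(dense) < 2L) next
    labels <- attach_noise(raw, dense, d)
    if (length(unique(labels)) < 2L) next
    s <- silhouette_score(coords, labels)
    if (!is.na(s) && s > best_sil) {
      best_sil <- s
      best <- list(labels = labels, K = length(unique(labels)), silhouette = s)
    }
  }
  best
}

# Noise points (members of components below the size threshold) adopt the
# label of their nearest point inside a dense component.
attach_noise <- function(raw, dense, d) {
  labels <- match(raw, dense) # NA for noise
  noise <- which(is.na(labels))
  core_idx <- which(!is.na(labels))
  for (i in noise) {
    labels[i] <- labels[core_idx[which.min(d[i, core_idx])]]
  }
  as.integer(labels)
}

#' Count obviously distinguishable clusters in an embedding
#'
#' @param e An `embedding` (or a bare coordinate matrix).
#' @param silhouette_min Validity threshold below which the layout is not
#'   considered discernibly clustered (default 0.35).
#' @param min_cluster_size Dense-group size threshold; defaults to
#'   `max(5, ceiling(0.02 * n))`.
#' @return List with `K`, `discernible` flag, `labels` (the density
#'   reference partition) and `silhouette`.
#' @export
count_discernible_clusters <- function(e, silhouette_min = 0.35,
                                       min_cluster_size = NULL) {
  coords <- if (inherits(e, "embedding")) e$coords else as.matrix(e)
  part <- density_partition(coords, min_cluster_size)
  disc <- part$K >= 2L && !is.na(part$silhouette) &&
    part$silhouette >= silhouette_min
  if (!disc && part$K >= 2L) {
    # below-threshold structure is reported as a single indiscernible mass
    part <- list(labels = rep(1L, nrow(coords)), K = 1L,
                 silhouette = part$silhouette)
  }
  list(K = part$K, discernible = disc, labels = part$labels,
       silhouette = part$silhouette)
}

#' Default sweep grid
#'
#' Perplexities 5..30 crossed with learning rates 0.1, 1, 10, 100.
#' @return Data frame with columns `perplexity`, `learning_rate`.
#' @export
default_sweep_grid <- function() {
  expand.grid(perplexity = c(5, 10, 15, 20, 25, 30),
              learning_rate = c(0.1, 1, 10, 100))
}

#' Sweep t-SNE parameters and select a discernible embedding
#'
#' Evaluates every grid point, keeps those whose embedding shows obviously
#' distinguishable clusters, selects the one with the highest silhouette,
#' then validates it by re-running with `n_validation` fresh seeds and
#' requiring the selected K to recur in at least two thirds of those runs.
#' Cohorts for which no grid point yields discernible clusters are rejected
#' (a value, not an error), mirroring cohorts set aside from further
#' analysis.
#'
#' @param v A `pattern_vectors` object.
#' @param grid Data frame with `perplexity` and `learning_rate` columns.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param silhouette_min Discernibility threshold (see
#'   [count_discernible_clusters()]).
#' @param n_validation Number of fresh-seed validation runs.
#' @param base_params An [embedding_params()] supplying iteration and
#'   stabilization settings for every run.
#' @return List with `status` ("selected" or "rejected"); when selected also
#'   `embedding`, `K`, `labels`, `silhouette`, `params` and `sweep_record`
#'   (one row per grid point).
#' @export
sweep_and_select <- function(v, grid = default_sweep_grid(), seed = 1L,
                             silhouette_min = 0.35, n_validation = 3L,
                             base_params = embedding_params()) {
  stopifnot(nrow(grid) >= 1L)
  record <- grid
  record$K <- NA_integer_
  record$discernible <- FALSE
  record$silhouette <- NA_real_
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- base_params
    p$perplexity <- grid$perplexity[i]
    p$learning_rate <- grid$learning_rate[i]
    p$seed <- derive_seed(seed, i)
    if (nrow(v$vectors) <= 3 * p$perplexity) next # infeasible grid point
    emb <- run_tsne(v, p)
    cd <- count_discernible_clusters(emb, silhouette_min)
    record$K[i] <- cd$K
    record$discernible[i] <- cd$discernible
    record$silhouette[i] <- cd$silhouette
    runs[[i]] <- list(embedding = emb, cd = cd, params = p)
  }
  ok <- which(record$discernible)
  if (length(ok) == 0L) {
    return(list(status = "rejected", sweep_record = record))
  }
  best <- ok[which.max(record$silhouette[ok])]
  sel <- runs[[best]]

  # validation by multiple runs: the selected K must recur
  k_runs <- integer(n_validation)
  for (j in seq_len(n_validation)) {
    p <- sel$params
    p$seed <- derive_seed(seed, nrow(grid) + j)
    cd <- count_discernible_clusters(run_tsne(v, p), silhouette_min)
    k_runs[j] <- cd$K
  }
  if (sum(k_runs == sel$cd$K) < ceiling(2 * n_validation / 3)) {
    return(list(status = "rejected", sweep_record = record,
                validation_K = k_runs))
  }
  list(status = "selected", embedding = sel$embedding, K = sel$cd$K,
       labels = sel$cd$labels, silhouette = sel$cd$silhouette,
       params = sel$params, sweep_record = record, validation_K = k_runs)
}

#' Hold-out consistency check of a cluster labelling
#'
#' Simplified stand-in for a parametric embedding: a stratified 75% training
#' subset is drawn; each held-out sample receives the label of its nearest
#' training sample in pattern-vector space, and the fraction of transferred
#' labels agreeing with the full-cohort labels is reported. Clusters with
#' fewer than 4 members are excluded with a warning.
#'
#' @param v A `pattern_vectors` object.
#' @param labels Integer cluster labels from the full-cohort solution.
#' @param seed Integer seed for the stratified split.
#' @param train_fraction Training fraction (default 0.75).
#' @return List with `agreement` (fraction in `[0, 1]`), `n_test` and the
#'   held-out `test_ids`.
#' @export
holdout_confirm <- function(v, labels, seed = 1L, train_fraction = 0.75) {
  stopifnot(inherits(v, "pattern_vectors"),
            length(labels) == length(v$sample_ids))
  labels <- as.integer(labels)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < 4L])
  if (length(small)) {
    warning("excluding cluster(s) with < 4 members: ",
            paste(small, collapse = ", "))
  }
  keep <- !(labels %in% small)
  if (length(unique(labels[keep])) < 2L) {
    return(list(agreement = 1.0, n_test = 0L, test_ids = character(0)))
  }
  set.seed(seed)
  idx <- which(keep)
  train <- unlist(lapply(split(idx, labels[idx]), function(ii) {
    n_tr <- max(1L, floor(train_fraction * length(ii)))
    if (length(ii) == 1L) ii else sample(ii, n_tr)
  }), use.names = FALSE)
  test <- setdiff(idx, train)
  if (length(test) == 0L) {
    return(list(agreement = 1.0, n_test = 0L, test_ids = character(0)))
  }
  xt <- v$vectors[train, , drop = FALSE]
  xs <- v$vectors[test, , drop = FALSE]
  # nearest training neighbor in input space
  cross <- outer(rowSums(xs^2), rep(1, nrow(xt))) -
    2 * xs %*% t(xt) + outer(rep(1, nrow(xs)), rowSums(xt^2))
  nn <- apply(cross, 1L, which.min)
  transferred <- labels[train][nn]
  list(agreement = mean(transferred == labels[test]),
       n_test = length(test), test_ids = v$sample_ids[test])
}

# Per-stage / per-run seed derivation: keeps derived seeds positive and
# below 2^31 while remaining a pure function of (master seed, counter).
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
               2147483647) + 1L
}
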