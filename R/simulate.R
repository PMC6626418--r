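# Synthetic cohorts with planted structure. The generator emulates the data
# model the pipeline assumes: a log2(FPKM-UQ + 1) matrix whose per-panel
# centered/normalized vectors fall into K well-separated directional
# clusters; exponential survival with cluster-specific hazards plus uniform
# censoring; optional subtype enrichment, nested second-panel structure and
# a correlated background gene block partially aligned with the clusters.

#' Specification of a synthetic cohort
#'
#' Defaults describe the reference world used throughout the test suite:
#' 400 tumors, one 20-gene panel with three orthogonal pattern directions,
#' log2-scale noise sd 0.1, cluster median survivals 1000/750/500 days and a
#' 3000-day uniform censoring horizon (~40% censoring, in the range typical
#' of archival tumor cohorts).
#'
#' @param n_samples Number of tumors.
#' @param panels List of per-panel settings; each element is a list with
#'   `name`, and either `panel` (a [pathway_panel()]) or `n_genes`; plus
#'   `K` (clusters), `theta` (minimum pairwise angle between pattern
#'   directions, radians, in (0, pi]), `sigma` (log2-scale noise sd) and
#'   `amplitude` (log2 units of directional signal).
#' @param hazards Per-cluster exponential rates (1/days), keyed to the first
#'   panel's clusters (or to second-panel clusters when `nesting` is set).
#' @param censor_horizon Upper bound of the uniform censoring time (days).
#' @param subtype_enrichment Optional named list mapping a panel-1 cluster
#'   (as character) to `list(label =, prob =)`; other samples carry the
#'   focal label with `subtype_background_prob`.
#' @param subtype_background_prob Baseline probability of each focal label
#'   outside its enriched cluster.
#' @param nesting Optional named list mapping a panel-1 cluster (character)
#'   to the vector of panel-2 cluster ids that subdivide it.
#' @param n_background_genes,background_blocks,background_overlap Size and
#'   block count of the "whole-transcriptome" background, and the
#'   probability that a sample's block follows its panel-1 cluster.
#' @param stage_probs Optional named probability vector for an independent
#'   categorical `stage` covariate (e.g. `c(I = .3, II = .3, III = .2, IV = .2)`).
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 400L,
                        panels = list(list(name = "panelA", n_genes = 20L,
                                           K = 3L, theta = pi / 2,
                                           sigma = 0.1, amplitude = 2)),
                        hazards = log(2) / c(1000, 750, 500),
                        censor_horizon = 3000,
                        subtype_enrichment = NULL,
                        subtype_background_prob = 0.05,
                        nesting = NULL,
                        n_background_genes = 0L,
                        background_blocks = 3L,
                        background_overlap = 0.8,
                        stage_probs = NULL,
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), panels = panels,
               hazards = hazards, censor_horizon = censor_horizon,
               subtype_enrichment = subtype_enrichment,
               subtype_background_prob = subtype_background_prob,
               nesting = nesting,
               n_background_genes = as.integer(n_background_genes),
               background_blocks = as.integer(background_blocks),
               background_overlap = background_overlap,
               stage_probs = stage_probs, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_samples >= 2L, length(spec$panels) >= 1L)
  for (p in spec$panels) {
    if (is.null(p$K) || p$K < 1L) stop("panel K_clusters must be >= 1")
    th <- if (is.null(p$theta)) pi / 2 else p$theta
    if (th <= 0 || th > pi) stop("theta must lie in (0, pi]")
    if (is.null(p$sigma) || p$sigma <= 0) stop("sigma must be > 0")
  }
  if (any(spec$hazards <= 0)) stop("hazard rates must be > 0")
  if (spec$censor_horizon <= 0) stop("censor_horizon must be > 0")
  if (!is.null(spec$stage_probs) &&
      abs(sum(spec$stage_probs) - 1) > 1e-8) {
    stop("stage_probs must sum to 1")
  }
  invisible(spec)
}

# K unit directions in R^n with pairwise angle >= theta. Greedy rejection
# sampling; deterministic fallback to the canonical basis when it applies.
pattern_directions <- function(n, K, theta, max_tries = 2000L) {
  if (K == 1L) return(matrix(c(1, rep(0, n - 1L)), nrow = 1L))
  dirs <- matrix(0, K, n)
  k <- 0L
  tries <- 0L
  while (k < K && tries < max_tries) {
    cand <- stats::rnorm(n)
    cand <- cand / sqrt(sum(cand^2))
    ok <- k == 0L ||
      all(acos(pmin(1, pmax(-1, dirs[seq_len(k), , drop = FALSE] %*% cand))) >= theta)
    if (ok) {
      k <- k + 1L
      dirs[k, ] <- cand
    }
    tries <- tries + 1L
  }
  if (k == K) return(dirs)
  if (n >= K && theta <= pi / 2 + 1e-12) {
    # canonical axes are mutually orthogonal (angle pi/2)
    return(diag(1, K, n))
  }
  stop("cannot place ", K, " directions with pairwise angle >= ",
       signif(theta, 3), " in dimension ", n)
}

# One panel's log2 expression block given per-sample labels.
panel_block <- function(labels, n_genes, dirs, sigma, amplitude, gene_ids) {
  n <- length(labels)
  baseline <- stats::runif(n_genes, 6, 12)  # per-gene log2 baseline, drawn once
  signal <- amplitude * dirs[labels, , drop = FALSE]
  noise <- matrix(stats::rnorm(n * n_genes, 0, sigma), n, n_genes)
  vals <- sweep(signal + noise, 2L, baseline, "+")
  vals[vals < 0] <- 0  # log2p1 storage is non-negative; baseline makes this rare
  colnames(vals) <- gene_ids
  vals
}

#' Simulate a cohort with planted pattern clusters and survival structure
#'
#' @param spec A [cohort_spec()].
#' @return List with `expression` (an [expression_matrix()], scale
#'   `"log2p1"`), `phenotype` (a [phenotype_table()]), `truth` (per-panel
#'   true labels, subtype and block labels, true per-sample hazard) and
#'   `panels` (a [panel_registry()] covering the simulated panels).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  # --- panel-1 cluster labels (balanced multinomial) -----------------------
  K1 <- spec$panels[[1]]$K
  labels1 <- sample(rep_len(seq_len(K1), n))

  # --- optional nesting: panel-2 labels refine panel-1 labels --------------
  nesting <- spec$nesting
  labels2 <- NULL
  if (!is.null(nesting) && length(spec$panels) >= 2L) {
    if (!all(names(nesting) %in% as.character(seq_len(K1)))) {
      stop("nesting references unknown panel-1 cluster(s): ",
           paste(setdiff(names(nesting), as.character(seq_len(K1))),
                 collapse = ", "))
    }
    used <- unlist(nesting)
    next_label <- if (length(used)) max(used) + 1L else 1L
    labels2 <- integer(n)
    for (c1 in seq_len(K1)) {
      idx <- which(labels1 == c1)
      key <- as.character(c1)
      if (key %in% names(nesting)) {
        subs <- nesting[[key]]
        labels2[idx] <- sample(rep_len(subs, length(idx)))
      } else {
        labels2[idx] <- next_label
        next_label <- next_label + 1L
      }
    }
    K2_needed <- max(labels2)
    if (spec$panels[[2]]$K != K2_needed) {
      stop("panel 2 declares K = ", spec$panels[[2]]$K, " but nesting implies ",
           K2_needed, " clusters")
    }
  }

  # --- expression blocks, one per panel ------------------------------------
  truth_labels <- list()
  blocks <- list()
  registry_panels <- list()
  for (i in seq_along(spec$panels)) {
    p <- spec$panels[[i]]
    name <- if (is.null(p$name)) paste0("panel", i) else p$name
    if (!is.null(p$panel)) {
      gene_ids <- p$panel$gene_ids
      registry_panels[[i]] <- p$panel
    } else {
      gene_ids <- sprintf("%s_g%02d", name, seq_len(p$n_genes))
      registry_panels[[i]] <- pathway_panel(name, gene_ids,
                                            source = "synthetic")
    }
    n_genes <- length(gene_ids)
    theta <- if (is.null(p$theta)) pi / 2 else p$theta
    amplitude <- if (is.null(p$amplitude)) 2 else p$amplitude
    lab <- if (i == 1L) labels1
           else if (i == 2L && !is.null(labels2)) labels2
           else sample(rep_len(seq_len(p$K), n))
    dirs <- pattern_directions(n_genes, p$K, theta)
    blocks[[i]] <- panel_block(lab, n_genes, dirs, p$sigma, amplitude, gene_ids)
    truth_labels[[name]] <- lab
  }

  # --- background "whole transcriptome" block ------------------------------
  block_labels <- NULL
  if (spec$n_background_genes > 0L) {
    B <- spec$background_blocks
    aligned <- stats::runif(n) < spec$background_overlap
    block_labels <- ifelse(aligned, ((labels1 - 1L) %% B) + 1L,
                           sample.int(B, n, replace = TRUE))
    gene_block <- rep_len(seq_len(B), spec$n_background_genes)
    gene_ids <- sprintf("bg_g%04d", seq_len(spec$n_background_genes))
    baseline <- stats::runif(spec$n_background_genes, 6, 12)
    member <- outer(block_labels, gene_block, "==")
    vals <- sweep(2 * member +
                    matrix(stats::rnorm(n * spec$n_background_genes, 0, 0.5),
                           n, spec$n_background_genes),
                  2L, baseline, "+")
    vals[vals < 0] <- 0
    colnames(vals) <- gene_ids
    blocks[[length(blocks) + 1L]] <- vals
  }

  values <- do.call(cbind, blocks)
  rownames(values) <- sample_ids
  expr <- expression_matrix(values, scale = "log2p1")

  # --- survival: exponential event times, uniform censoring ----------------
  hazard_labels <- if (!is.null(labels2)) labels2 else labels1
  if (max(hazard_labels) > length(spec$hazards)) {
    stop("hazards must supply one rate per cluster (need ",
         max(hazard_labels), ")")
  }
  lambda <- spec$hazards[hazard_labels]
  t_event <- stats::rexp(n, rate = lambda)
  t_cens <- stats::runif(n, 0, spec$censor_horizon)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.numeric(t_event <= t_cens)

  # --- subtype labels ------------------------------------------------------
  pheno <- data.frame(sample_id = sample_ids, os_time = os_time,
                      os_event = os_event, stringsAsFactors = FALSE)
  subtype <- NULL
  if (!is.null(spec$subtype_enrichment)) {
    subtype <- rep("Other", n)
    for (key in names(spec$subtype_enrichment)) {
      ent <- spec$subtype_enrichment[[key]]
      k <- as.integer(key)
      in_k <- labels1 == k
      take <- stats::runif(n) < ifelse(in_k, ent$prob,
                                       spec$subtype_background_prob)
      subtype[take] <- ent$label
    }
    pheno$subtype <- subtype
  }
  if (!is.null(spec$stage_probs)) {
    pheno$stage <- sample(names(spec$stage_probs), n, replace = TRUE,
                          prob = spec$stage_probs)
  }
  if (!is.null(block_labels)) {
    pheno$dendro <- paste0("Dendro", block_labels)
  }

  list(
    expression = expr,
    phenotype = phenotype_table(pheno),
    truth = list(panel_labels = truth_labels, subtype = subtype,
                 block_labels = block_labels, lambda = lambda),
    panels = panel_registry(registry_panels)
  )
}

#' Simulate a cohort whose second panel refines the first panel's clusters
#'
#' Thin wrapper over [simulate_cohort()] that requires a `nesting` map and at
#' least two panels: the second panel's clusters subdivide the designated
#' first-panel clusters and the survival hazards are keyed to the
#' second-panel labels, so a sequential analysis has a planted split to find.
#'
#' @param spec A [cohort_spec()] with `nesting` set and >= 2 panels.
#' @return Same structure as [simulate_cohort()].
#' @export
nested_refinement_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(spec$nesting) || length(spec$nesting) == 0L) {
    return(simulate_cohort(spec))
  }
  if (length(spec$panels) < 2L) {
    stop("nesting requires two panels in the spec")
  }
  simulate_cohort(spec)
}

#' Write a simulated cohort to disk
#'
#' Emits the expression TSV, phenotype TSV, panel GMT and a ground-truth TSV
#' under `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_phenotype(cohort$phenotype, file.path(dir, "phenotype.tsv"))
  write_panels(cohort$panels, file.path(dir, "panels.gmt"))
  truth <- data.frame(sample_id = cohort$expression$sample_ids,
                      stringsAsFactors = FALSE)
  for (nm in names(cohort$truth$panel_labels)) {
    truth[[paste0("label_", nm)]] <- cohort$truth$panel_labels[[nm]]
  }
  truth$lambda <- cohort$truth$lambda
  if (!is.null(cohort$truth$block_labels)) {
    truth$block <- cohort$truth$block_labels
  }
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
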