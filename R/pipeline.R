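# End-to-end orchestration: one structured config drives panel selection,
# pattern-space construction, the t-SNE sweep, mixture assignment, survival
# comparison and driver ranking, with per-stage seeds derived from a single
# master seed and a JSON run report.

#' Default run configuration
#'
#' @param expression,phenotype,panels File paths (TSV, TSV, GMT).
#' @param panel Name of the panel to analyze.
#' @param scale Stored scale of the expression TSV.
#' @param transpose Expression TSV is genes x samples.
#' @param work_on_log_scale If `TRUE` the pattern vectors are built on the
#'   stored log2 scale; if `FALSE` (archive-data default) the log transform
#'   is inverted to raw FPKM-UQ first.
#' @param allow_missing Drop panel genes absent from the matrix (with a
#'   warning) instead of erroring.
#' @param perplexities,learning_rates Sweep grid.
#' @param silhouette_min,min_group_size,prominence Decision thresholds.
#' @param n_iter_min,n_iter_max t-SNE iteration window.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out Output directory (created on demand), or `NULL` for in-memory
#'   operation.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(expression, phenotype, panels, panel,
                       scale = "log2p1", transpose = FALSE,
                       work_on_log_scale = TRUE, allow_missing = FALSE,
                       perplexities = c(5, 10, 15, 20, 25, 30),
                       learning_rates = c(0.1, 1, 10, 100),
                       silhouette_min = 0.35, min_group_size = 5L,
                       prominence = 1, n_iter_min = 2500L,
                       n_iter_max = 50000L, seed = 1L, out = NULL) {
  structure(list(expression = expression, phenotype = phenotype,
                 panels = panels, panel = panel, scale = scale,
                 transpose = isTRUE(transpose),
                 work_on_log_scale = isTRUE(work_on_log_scale),
                 allow_missing = isTRUE(allow_missing),
                 perplexities = perplexities,
                 learning_rates = learning_rates,
                 silhouette_min = silhouette_min,
                 min_group_size = as.integer(min_group_size),
                 prominence = prominence,
                 n_iter_min = as.integer(n_iter_min),
                 n_iter_max = as.integer(n_iter_max),
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(run_config, raw)
}

#' Validate a run configuration
#'
#' Checks paths, ranges and enum values; returns every problem found, not
#' just the first.
#'
#' @param config A `run_config`.
#' @return Character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  for (f in c("expression", "phenotype", "panels")) {
    p <- config[[f]]
    if (is.null(p) || !is.character(p) || !nzchar(p)) {
      add(paste0("missing path: ", f))
    } else if (!file.exists(p)) {
      add(paste0(f, " file not found: ", p))
    }
  }
  if (!config$scale %in% c("log2p1", "fpkm_uq")) {
    add(paste0("scale must be log2p1 or fpkm_uq, got: ", config$scale))
  }
  if (any(config$perplexities < 5 | config$perplexities > 30)) {
    add("sweep perplexities must lie in [5, 30]")
  }
  if (!all(config$learning_rates %in% c(0.1, 1, 10, 100))) {
    add("sweep learning rates must be among 0.1, 1, 10, 100")
  }
  if (config$silhouette_min < 0 || config$silhouette_min > 1) {
    add("silhouette_min must lie in [0, 1]")
  }
  if (config$min_group_size < 1) add("min_group_size must be >= 1")
  if (config$n_iter_min < 1 || config$n_iter_max < config$n_iter_min) {
    add("need 1 <= n_iter_min <= n_iter_max")
  }
  if (!is.finite(config$seed)) add("seed must be an integer")
  errs
}

# Small deterministic content hash (modular polynomial rolling hash over the
# serialized object); recorded in reports so identical configs are
# recognizable.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Run the full pipeline from a configuration
#'
#' Stages, in order: read inputs, restrict to the panel, build pattern
#' vectors (optionally after inverting the log transform), sweep and select
#' a t-SNE embedding, assign clusters with the eight-configuration mixture
#' search, compare cluster survival, rank driver transcripts. When the sweep
#' finds no discernible clusters the run stops after the embedding stage
#' with status `"rejected"`. All randomness derives from `config$seed`.
#'
#' @param config A `run_config` (see also [read_run_config()]).
#' @return A `run_report` list; when `config$out` is set, artifacts
#'   (coords, labels, KM curves, importance, `report.json`) are written
#'   there too.
#' @export
run_all <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))

  registry <- read_panels(config$panels)
  if (!config$panel %in% names(registry$panels)) {
    stop("panel '", config$panel, "' not in registry")
  }
  panel <- registry$panels[[config$panel]]
  expr <- read_expression(config$expression, scale = config$scale,
                          transpose = config$transpose)
  pheno <- read_phenotype(config$phenotype)

  sub <- subset_to_panel(expr, panel, allow_missing = config$allow_missing)
  if (!config$work_on_log_scale && sub$scale == "log2p1") {
    sub <- invert_log_transform(sub)
  }
  vectors <- center_and_project(sub, panel_name = panel$name)

  grid <- expand.grid(perplexity = config$perplexities,
                      learning_rate = config$learning_rates)
  base_params <- embedding_params(n_iter_min = config$n_iter_min,
                                  n_iter_max = config$n_iter_max)
  sweep <- sweep_and_select(vectors, grid = grid,
                            seed = derive_seed(config$seed, 1L),
                            silhouette_min = config$silhouette_min,
                            base_params = base_params)

  # hash the analysis-relevant settings; where the artifacts land is not
  # part of the run's scientific identity
  report <- list(package_version = as.character(utils::packageVersion("patternsurv")),
                 config_hash = config_hash(unclass(config)[setdiff(names(config), "out")]),
                 panel = panel$name, n_samples = length(vectors$sample_ids),
                 n_genes = vectors$n, status = sweep$status)

  if (sweep$status == "rejected") {
    report$sweep_record <- sweep$sweep_record
    return(finish_run(report, config, vectors, sweep, NULL, NULL, NULL))
  }

  solution <- assign_clusters(sweep$embedding, sweep$K, sweep$labels,
                              seed = derive_seed(config$seed, 2L))
  surv <- compare_clusters(solution, pheno,
                           min_group_size = config$min_group_size)
  drivers <- rank_drivers(vectors, solution$labels,
                          seed = derive_seed(config$seed, 3L),
                          prominence_threshold = config$prominence)

  report$K <- sweep$K
  report$tsne_params <- list(perplexity = sweep$params$perplexity,
                             learning_rate = sweep$params$learning_rate,
                             iterations = sweep$embedding$iterations)
  report$silhouette <- sweep$silhouette
  report$mixture_config <- solution$config
  report$unity_score <- solution$unity_score
  report$headline_p <- surv$headline_p
  report$most_disparate_pair <- surv$most_disparate_pair
  report$median_survival <- lapply(surv$curves, function(cv) {
    list(median = cv$median, censored = cv$median_censored, n = cv$n)
  })
  report$prominent_drivers <- drivers$gene_id[drivers$prominent]
  report$top_drivers <- top_drivers(drivers, min(5L, nrow(drivers)))

  finish_run(report, config, vectors, sweep, solution, surv, drivers)
}

finish_run <- function(report, config, vectors, sweep, solution, surv,
                       drivers) {
  out <- config$out
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sweep$embedding)) {
      coords <- data.frame(sample_id = sweep$embedding$sample_ids,
                           sweep$embedding$coords)
      colnames(coords) <- c("sample_id", "x", "y", "z")
      utils::write.table(coords, file.path(out, "coords.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(solution)) {
      utils::write.table(
        data.frame(sample_id = solution$sample_ids, cluster = solution$labels),
        file.path(out, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    if (!is.null(drivers)) {
      ord <- order(-drivers$importance)
      utils::write.table(as.data.frame(drivers)[ord, ],
                         file.path(out, "importance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  structure(list(report = report, vectors = vectors, sweep = sweep,
                 solution = solution, survival = surv, drivers = drivers),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("<run_report> panel ", r$panel, ", ", r$n_samples, " samples, status ",
      r$status, "\n", sep = "")
  if (identical(r$status, "selected")) {
    cat("  K = ", r$K, " (perplexity ", r$tsne_params$perplexity,
        ", lr ", r$tsne_params$learning_rate, "), unity ",
        signif(r$unity_score, 3), "\n", sep = "")
    if (!is.null(r$headline_p) && !is.na(r$headline_p)) {
      cat("  headline log-rank p = ", signif(r$headline_p, 3),
          " (clusters ", r$most_disparate_pair[1], " vs ",
          r$most_disparate_pair[2], ")\n", sep = "")
    }
    if (length(r$prominent_drivers)) {
      cat("  prominent drivers: ", paste(r$prominent_drivers, collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
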