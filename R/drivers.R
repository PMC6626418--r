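# Driver-transcript identification: which panel genes most determine the
# cluster structure. A 100-tree bagged classification forest predicts the
# cluster labels from the pattern-vector coordinates (every predictor
# considered at every split); importance is the out-of-bag permutation
# importance normalized as mean per-tree error increase divided by its
# standard deviation across trees, so the fixed prominence threshold
# (importance > 1) is comparable across cohorts.

#' Rank panel genes by random-forest permutation importance
#'
#' @param v A `pattern_vectors` object (the clusters being explained were
#'   built from these coordinates, so they are also the predictors).
#' @param labels Integer cluster labels with at least 2 classes, every class
#'   having at least 2 members.
#' @param seed Integer seed; the forest is deterministic given it.
#' @param n_trees Number of trees (default 100).
#' @param prominence_threshold Importance above which a gene is flagged
#'   prominent (default 1).
#' @return Object of class `importance_table`: data frame with `gene_id`,
#'   `importance`, `prominent`, ordered as the panel; attributes `n_trees`,
#'   `seed`, `oob_error`.
#' @export
rank_drivers <- function(v, labels, seed = 1L, n_trees = 100L,
                         prominence_threshold = 1) {
  stopifnot(inherits(v, "pattern_vectors"),
            length(labels) == length(v$sample_ids))
  labels <- as.integer(factor(labels))
  K <- max(labels)
  if (K < 2L) stop("driver ranking needs K >= 2 clusters")
  if (any(tabulate(labels, K) < 2L)) {
    stop("every cluster needs >= 2 members for out-of-bag estimation")
  }
  fit <- .forest_importance_cpp(v$vectors, labels, as.integer(n_trees),
                                as.integer(seed))
  tab <- data.frame(gene_id = colnames(v$vectors),
                    importance = as.numeric(fit$importance),
                    stringsAsFactors = FALSE)
  tab$prominent <- tab$importance > prominence_threshold
  structure(tab, class = c("importance_table", "data.frame"),
            n_trees = as.integer(n_trees), seed = as.integer(seed),
            oob_error = mean(fit$oob_error),
            prominence_threshold = prominence_threshold)
}

#' Top-k driver genes
#'
#' Highest-importance genes; ties (and the all-zero case) resolve to panel
#' order. `k` beyond the panel size is clipped with a warning.
#'
#' @param table An `importance_table` from [rank_drivers()].
#' @param k Number of genes wanted.
#' @return Character vector of gene IDs.
#' @export
top_drivers <- function(table, k) {
  stopifnot(inherits(table, "importance_table"), k >= 1L)
  if (k > nrow(table)) {
    warning("k = ", k, " exceeds panel size ", nrow(table), "; clipped")
    k <- nrow(table)
  }
  ord <- order(-table$importance, seq_len(nrow(table))) # stable: panel order
  table$gene_id[ord][seq_len(k)]
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> ", nrow(x), " genes, ", attr(x, "n_trees"),
      " trees, OOB error ", signif(attr(x, "oob_error"), 3), "\n", sep = "")
  ord <- order(-x$importance)
  top <- utils::head(ord, 5L)
  for (i in top) {
    cat("  ", x$gene_id[i], ": ", signif(x$importance[i], 3),
        if (x$prominent[i]) " *" else "", "\n", sep = "")
  }
  invisible(x)
}
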