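# Pattern space: each sample's panel-restricted expression profile is a point
# in R^n (n = panel size). Subtracting the cohort mean vector and rescaling
# every centered vector to unit Euclidean norm projects the cohort onto the
# unit (n-1)-sphere, so that downstream stages see relative expression
# *patterns*, not absolute levels.

#' Invert the log2(x + 1) storage transform
#'
#' Archive exports store expression as log2(FPKM-UQ + 1); this recovers the
#' raw FPKM-UQ values (v -> 2^v - 1).
#'
#' @param m An [expression_matrix()] with scale `"log2p1"`.
#' @return An [expression_matrix()] with scale `"fpkm_uq"`.
#' @export
invert_log_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "log2p1") {
    stop("matrix scale is '", m$scale, "'; refusing to invert twice")
  }
  expression_matrix(2^m$values - 1, sample_ids = m$sample_ids,
                    gene_ids = m$gene_ids, scale = "fpkm_uq")
}

#' Center a cohort and project onto the unit hypersphere
#'
#' Subtracts the unweighted cohort mean vector from every sample's expression
#' vector, then divides each centered vector by its Euclidean norm. Centering
#' uses the mean of the samples actually present, so re-running on a subset
#' (sequential refinement) re-centers within that subset.
#'
#' @param m An [expression_matrix()] with at least 2 samples and 1 gene.
#'   Either scale is accepted; which scale feeds the projection is the
#'   caller's modelling choice (see the package vignette).
#' @return Object of class `pattern_vectors`: fields `sample_ids`, `vectors`
#'   (samples x n, unit rows), `panel_name`, `n`.
#' @param panel_name Optional label carried through to downstream reports.
#' @export
center_and_project <- function(m, panel_name = NA_character_) {
  stopifnot(inherits(m, "expression_matrix"))
  x <- m$values
  if (nrow(x) < 2L) stop("need >= 2 samples to center a cohort")
  centered <- sweep(x, 2L, colMeans(x), "-")
  norms <- sqrt(rowSums(centered^2))
  bad <- norms < 1e-12
  if (any(bad)) {
    stop("sample(s) identical to the cohort mean (zero centered vector): ",
         paste(m$sample_ids[bad], collapse = ", "))
  }
  vectors <- centered / norms
  dimnames(vectors) <- list(m$sample_ids, m$gene_ids)
  structure(list(sample_ids = m$sample_ids, vectors = vectors,
                 panel_name = panel_name, n = ncol(x)),
            class = "pattern_vectors")
}

#' @export
print.pattern_vectors <- function(x, ...) {
  cat("<pattern_vectors> ", length(x$sample_ids), " samples on the ",
      x$n - 1L, "-sphere", sep = "")
  if (!is.na(x$panel_name)) cat(" [", x$panel_name, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Write pattern vectors as TSV (audit dump)
#'
#' @param v A `pattern_vectors` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(v, path) {
  stopifnot(inherits(v, "pattern_vectors"))
  df <- data.frame(sample_id = v$sample_ids,
                   format(v$vectors, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(v$vectors))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset pattern-vector rows by sample
#'
#' Row selection only; it does NOT re-center. Use [center_and_project()] on a
#' subsetted expression matrix when a fresh cohort mean is wanted.
#'
#' @param v A `pattern_vectors` object.
#' @param sample_ids Samples to keep.
#' @return A `pattern_vectors` object.
#' @export
subset_vectors <- function(v, sample_ids) {
  stopifnot(inherits(v, "pattern_vectors"))
  missing <- setdiff(sample_ids, v$sample_ids)
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  }
  structure(list(sample_ids = as.character(sample_ids),
                 vectors = v$vectors[sample_ids, , drop = FALSE],
                 panel_name = v$panel_name, n = v$n),
            class = "pattern_vectors")
}
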