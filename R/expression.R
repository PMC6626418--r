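# Expression matrices are stored samples x genes with a declared scale:
#   log2p1  -- log2(FPKM-UQ + 1), the archive export convention
#   fpkm_uq -- raw upper-quartile-normalized FPKM
# Both scales are non-negative; values must be finite.

#' Expression matrix container
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param sample_ids,gene_ids Unique identifiers; default to dimnames.
#' @param scale One of `"log2p1"` or `"fpkm_uq"`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              scale = c("log2p1", "fpkm_uq")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample_ids and gene_ids are required (or set dimnames)")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("negative values not allowed under scale ", scale)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", length(x$sample_ids), " samples x ",
      length(x$gene_ids), " genes [", x$scale, "]\n", sep = "")
  invisible(x)
}

#' Read a TSV expression matrix
#'
#' Default layout: first column sample IDs, header gene IDs. Archive-style
#' exports are genes-by-samples; pass `transpose = TRUE` for those.
#'
#' @param path TSV file.
#' @param scale Declared scale of the stored values.
#' @param transpose If `TRUE`, the file is genes x samples.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("log2p1", "fpkm_uq"),
                            transpose = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs an ID column plus data columns")
  ids <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1]))
  if (anyNA(num)) stop("non-numeric cell(s) in expression TSV: ", path)
  if (transpose) num <- t(num)
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] in the samples-by-genes layout; values are
#' written with full precision so a read/write round trip is exact.
#'
#' @param m An [expression_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(sample_id = m$sample_ids,
                   format(m$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("sample_id", m$gene_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to a panel's genes
#'
#' Output columns follow the panel's order regardless of input order.
#'
#' @param m An [expression_matrix()].
#' @param panel A [pathway_panel()].
#' @param allow_missing If `TRUE`, panel genes absent from `m` are dropped
#'   with a warning; if `FALSE` (default) they are an error.
#' @return An [expression_matrix()] with columns in panel order.
#' @export
subset_to_panel <- function(m, panel, allow_missing = FALSE) {
  stopifnot(inherits(m, "expression_matrix"), inherits(panel, "pathway_panel"))
  present <- panel$gene_ids %in% m$gene_ids
  if (!any(present)) {
    stop("panel '", panel$name, "': no panel genes present in the matrix")
  }
  if (!all(present)) {
    missing <- panel$gene_ids[!present]
    if (!allow_missing) {
      stop("panel '", panel$name, "': missing genes: ",
           paste(missing, collapse = ", "),
           " (use allow_missing = TRUE to drop)")
    }
    warning("panel '", panel$name, "': dropping ", length(missing),
            " absent gene(s): ", paste(missing, collapse = ", "))
  }
  keep <- panel$gene_ids[present]
  expression_matrix(m$values[, keep, drop = FALSE],
                    sample_ids = m$sample_ids, gene_ids = keep,
                    scale = m$scale)
}

#' Phenotype table container
#'
#' One row per sample: overall-survival time in days, event indicator
#' (1 = death observed, 0 = right-censored) and arbitrary categorical
#' covariates (stage, subtype, external partition labels, ...).
#'
#' @param df Data frame with columns `sample_id`, `os_time`, `os_event` plus
#'   optional covariate columns.
#' @return Object of class `phenotype_table` (a validated data frame).
#' @export
phenotype_table <- function(df) {
  req <- c("sample_id", "os_time", "os_event")
  if (!all(req %in% colnames(df))) {
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.numeric(df$os_event)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in phenotype table")
  if (anyNA(df$os_time) || any(df$os_time < 0)) {
    stop("os_time must be numeric and non-negative")
  }
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a phenotype TSV
#'
#' @param path TSV with required columns `sample_id`, `os_time`, `os_event`
#'   and any number of extra categorical columns.
#' @return A [phenotype_table()].
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Write a phenotype table as TSV
#'
#' @param pheno A [phenotype_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype_table"))
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
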