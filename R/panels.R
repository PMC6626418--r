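#' Pathway panel
#'
#' A named set of NCBI Gene IDs defining the n-dimensional pattern space for
#' one pathway. Gene identity is exact ID string match; no symbol aliasing.
#'
#' @param name Short panel name, unique within a registry.
#' @param gene_ids Character vector of NCBI Gene IDs (coerced to character).
#'   Duplicates within the panel are collapsed with a warning.
#' @param source Free-text provenance.
#' @return An object of class `pathway_panel` with fields `name`, `gene_ids`,
#'   `source`.
#' @export
pathway_panel <- function(name, gene_ids, source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) {
    stop("panel '", name, "': gene_ids must be non-empty")
  }
  if (anyDuplicated(gene_ids)) {
    warning("panel '", name, "': duplicate gene IDs collapsed")
    gene_ids <- unique(gene_ids)
  }
  structure(
    list(name = name, gene_ids = gene_ids, source = as.character(source)),
    class = "pathway_panel"
  )
}

#' @export
print.pathway_panel <- function(x, ...) {
  cat("<pathway_panel> ", x$name, ": ", length(x$gene_ids), " genes\n", sep = "")
  invisible(x)
}

#' Panel registry
#'
#' @param panels List of [pathway_panel()] objects with unique names.
#' @return An object of class `panel_registry`.
#' @export
panel_registry <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1L)
  ok <- vapply(panels, inherits, logical(1), "pathway_panel")
  if (!all(ok)) stop("all elements must be pathway_panel objects")
  nms <- vapply(panels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate panel names in registry: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(panels) <- nms
  structure(list(panels = panels), class = "panel_registry")
}

#' @export
print.panel_registry <- function(x, ...) {
  sizes <- vapply(x$panels, function(p) length(p$gene_ids), integer(1))
  cat("<panel_registry> ", length(x$panels), " panels, ",
      length(unique(unlist(lapply(x$panels, `[[`, "gene_ids")))),
      " unique genes (", sum(sizes), " listed)\n", sep = "")
  invisible(x)
}

#' Read gene panels from a GMT file
#'
#' Each line: panel name, description, then one or more gene IDs, all
#' tab-separated (standard gene-set interchange format).
#'
#' @param path Path to a GMT file.
#' @return A [panel_registry()].
#' @export
read_panels <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT format error: file is empty: ", path)
  panels <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT format error: line needs name, description and >= 1 gene ID")
    }
    pathway_panel(fields[1], fields[-(1:2)], source = fields[2])
  })
  panel_registry(panels)
}

#' Write gene panels to a GMT file
#'
#' @param registry A [panel_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panels <- function(registry, path) {
  stopifnot(inherits(registry, "panel_registry"))
  lines <- vapply(registry$panels, function(p) {
    src <- if (nzchar(p$source)) p$source else "NA"
    paste(c(p$name, src, p$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Number of genes shared by two panels
#'
#' Exact NCBI Gene ID string intersection.
#'
#' @param a,b [pathway_panel()] objects.
#' @return Integer count `|a$gene_ids` intersected with `b$gene_ids|`.
#' @export
panel_overlap <- function(a, b) {
  stopifnot(inherits(a, "pathway_panel"), inherits(b, "pathway_panel"))
  length(intersect(a$gene_ids, b$gene_ids))
}

#' Registry-wide gene counts
#'
#' @param registry A [panel_registry()].
#' @return List with `n_panels`, `n_listed` (sum of panel sizes) and
#'   `n_unique` (size of the union of all panels).
#' @export
registry_counts <- function(registry) {
  stopifnot(inherits(registry, "panel_registry"))
  sizes <- vapply(registry$panels, function(p) length(p$gene_ids), integer(1))
  list(
    n_panels = length(registry$panels),
    n_listed = sum(sizes),
    n_unique = length(unique(unlist(lapply(registry$panels, `[[`, "gene_ids"))))
  )
}
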