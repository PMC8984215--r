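#' Cells-by-genes expression matrix container
#'
#' Lightweight S3 container used throughout the package: a (sparse) numeric
#' matrix with cells in rows and genes in columns, plus cell identifiers,
#' gene symbols, a per-cell metadata table, and a layer tag recording what
#' the values represent.
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, cells x genes.
#' @param cell_ids character vector of unique cell identifiers (one per row).
#' @param gene_symbols character vector of gene symbols (one per column);
#'   symbols are upper-cased and duplicates are made unique by suffixing.
#' @param cell_meta optional data.frame of per-cell metadata (donor, cluster,
#'   state, ...). Row order matches `cell_ids`.
#' @param layer one of `"raw_counts"`, `"normalized"`, `"lognorm"`,
#'   `"residual"`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, cell_ids, gene_symbols,
                              cell_meta = NULL,
                              layer = c("raw_counts", "normalized",
                                        "lognorm", "residual")) {
  layer <- match.arg(layer)
  values <- as_csparse(values)
  cell_ids <- as.character(cell_ids)
  gene_symbols <- toupper(as.character(gene_symbols))
  if (nrow(values) != length(cell_ids))
    stop_integrity("number of rows (", nrow(values),
                   ") does not match number of cell ids (", length(cell_ids), ")")
  if (ncol(values) != length(gene_symbols))
    stop_integrity("number of columns (", ncol(values),
                   ") does not match number of gene symbols (",
                   length(gene_symbols), ")")
  if (anyDuplicated(cell_ids))
    stop_validation("cell ids must be unique")
  if (anyDuplicated(gene_symbols)) {
    dup <- duplicated(gene_symbols)
    warning(sum(dup), " duplicate gene symbol(s) made unique by suffixing")
    gene_symbols <- make.unique(gene_symbols, sep = "-")
  }
  if (layer == "raw_counts") {
    v <- values@x
    if (length(v) && (any(v < 0) || any(abs(v - round(v)) > 1e-8)))
      stop_validation("raw_counts layer must be non-negative and integral")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stop_integrity("cell_meta has ", nrow(cell_meta), " rows for ",
                     length(cell_ids), " cells")
    rownames(cell_meta) <- cell_ids
  }
  dimnames(values) <- list(cell_ids, gene_symbols)
  structure(list(values = values, cell_ids = cell_ids,
                 gene_symbols = gene_symbols, cell_meta = cell_meta,
                 layer = layer),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (ncol(x$cell_meta))
    cat("  cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix by cells and/or genes
#'
#' @param x an `expr_matrix`.
#' @param cells,genes index vectors (integer, logical or character) selecting
#'   cells / genes; `NULL` keeps all.
#' @return An `expr_matrix` on the same layer.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  ci <- if (is.null(cells)) seq_len(nrow(x$values)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(x$values)) else genes
  if (is.character(ci)) ci <- match(ci, x$cell_ids)
  if (is.character(gi)) gi <- match(toupper(gi), x$gene_symbols)
  if (anyNA(ci) || anyNA(gi)) stop_validation("unknown cell or gene in subset")
  em <- expression_matrix(x$values[ci, gi, drop = FALSE],
                          x$cell_ids[ci], x$gene_symbols[gi],
                          cell_meta = x$cell_meta[ci, , drop = FALSE],
                          layer = x$layer)
  em
}

# Replace values keeping ids/meta; used when a transform changes the layer.
set_layer <- function(x, values, layer) {
  expression_matrix(values, x$cell_ids, x$gene_symbols,
                    cell_meta = x$cell_meta, layer = layer)
}
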