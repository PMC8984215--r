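#' Read a Matrix Market expression matrix with sidecar files
#'
#' Reads the common droplet-sequencing trio: `matrix.mtx` plus
#' `features.tsv` (gene symbols) and `barcodes.tsv` (cell ids). Both on-disk
#' orientations (genes-in-rows, the CellRanger convention, or cells-in-rows)
#' are accepted; the orientation is inferred from the sidecar lengths and the
#' returned matrix is always cells x genes.
#'
#' @param path directory containing `matrix.mtx`, `features.tsv` and
#'   `barcodes.tsv` (also accepts `genes.tsv` for features).
#' @return An [expression_matrix()] with layer `"raw_counts"`.
#' @export
read_expression_matrix <- function(path) {
  if (!dir.exists(path)) stop_integrity("directory not found: ", path)
  mtx <- file.path(path, "matrix.mtx")
  feat <- file.path(path, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
  bc <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feat, bc)) if (!file.exists(f))
    stop_integrity("missing file: ", basename(f), " in ", path)
  m <- Matrix::readMM(mtx)
  genes <- read.table(feat, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.table(bc, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  nr <- nrow(m); nc <- ncol(m)
  if (nr == length(genes) && nc == length(cells)) {
    if (nr == nc && length(genes) == length(cells))
      stop_integrity("square matrix with equal sidecar lengths: ",
                     "orientation is ambiguous")
    m <- Matrix::t(m)
  } else if (nr == length(cells) && nc == length(genes)) {
    # already cells x genes
  } else {
    stop_integrity("matrix is ", nr, " x ", nc, " but sidecars list ",
                   length(cells), " cells and ", length(genes), " genes")
  }
  expression_matrix(m, cells, genes, layer = "raw_counts")
}

#' Write an expression matrix as Matrix Market plus sidecars
#'
#' Writes `matrix.mtx` in the genes-in-rows convention, with `features.tsv`
#' and `barcodes.tsv`, so the output is readable by standard droplet-data
#' tooling and by [read_expression_matrix()].
#'
#' @param x an `expr_matrix`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$values), file.path(path, "matrix.mtx"))
  writeLines(x$gene_symbols, file.path(path, "features.tsv"))
  writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a marker dictionary from a YAML file
#'
#' The file maps label names to lists of marker gene symbols, e.g.
#' `Fibroblast: [LUM, PDGFRA, COL1A1, SFRP2, CCL19]`. Label order is
#' preserved and symbols are upper-cased.
#'
#' @param path YAML file.
#' @return A named list of character vectors, class `marker_dict`.
#' @export
read_marker_dictionary <- function(path) {
  if (!file.exists(path)) stop_integrity("marker file not found: ", path)
  raw <- yaml::read_yaml(path)
  marker_dictionary(raw)
}

#' Construct a marker dictionary
#'
#' @param x named list: label name -> character vector of gene symbols.
#' @return `x` validated and upper-cased, class `marker_dict`.
#' @export
marker_dictionary <- function(x) {
  if (!length(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop_validation("marker dictionary needs non-empty label names")
  out <- lapply(x, function(g) {
    g <- toupper(as.character(unlist(g)))
    if (!length(g)) stop_validation("a label has an empty gene list")
    unique(g)
  })
  structure(out, class = "marker_dict")
}

#' @export
print.marker_dict <- function(x, ...) {
  cat("<marker_dict>", length(x), "labels\n")
  for (nm in names(x))
    cat(" ", nm, ":", paste(head(x[[nm]], 8), collapse = ", "),
        if (length(x[[nm]]) > 8) "..." else "", "\n")
  invisible(x)
}

#' Write per-cell annotations as TSV
#'
#' One row per cell; first column `cell_id`, then the metadata columns in
#' their stored order.
#'
#' @param x an `expr_matrix` with non-empty `cell_meta`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!ncol(x$cell_meta)) stop_validation("cell_meta is empty; nothing to write")
  df <- cbind(cell_id = x$cell_ids, x$cell_meta)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell annotations written by [write_annotations()]
#'
#' @param path TSV file with a `cell_id` column.
#' @return data.frame with `cell_id` as the first column.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_integrity("annotation file not found: ", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
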