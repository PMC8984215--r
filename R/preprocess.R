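#' Discard genes with low total counts
#'
#' Keeps genes whose total count across cells is at least `min_counts`
#' (a gene with total exactly `min_counts` is kept: only genes with *fewer*
#' counts are discarded). Gene order is preserved.
#'
#' @param x an [expression_matrix()] on the `raw_counts` layer.
#' @param min_counts minimum total count, default 30.
#' @return Filtered `expr_matrix`.
#' @export
filter_genes_min_counts <- function(x, min_counts = 30) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "raw_counts")
    stop_validation("gene filtering applies to the raw_counts layer")
  keep <- Matrix::colSums(x$values) >= min_counts
  if (!any(keep))
    stop_validation("all genes removed at min_counts = ", min_counts)
  out <- subset_cells(x, genes = which(keep))
  attr(out, "gene_rel_rate") <- attr(x, "gene_rel_rate")[keep]
  out
}

#' Normalize counts per cell
#'
#' Scales every cell's counts so its total equals the target: the median of
#' the per-cell totals by default, or a fixed number. Zero-count cells
#' cannot be scaled and are excluded with a warning.
#'
#' @param x an `expr_matrix` on the `raw_counts` layer.
#' @param target `"median"` or a positive number.
#' @return An `expr_matrix` on the `normalized` layer.
#' @export
normalize_per_cell <- function(x, target = "median") {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "raw_counts")
    stop_validation("normalization applies to the raw_counts layer")
  totals <- Matrix::rowSums(x$values)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-count cell(s) excluded")
    x <- subset_cells(x, cells = which(totals > 0))
    totals <- totals[totals > 0]
  }
  tgt <- if (identical(target, "median")) median(totals) else {
    stopifnot(is.numeric(target), target > 0)
    target
  }
  v <- Matrix::Diagonal(x = tgt / totals) %*% x$values
  set_layer(x, v, "normalized")
}

#' Log-transform normalized expression
#'
#' Elementwise `log(1 + x)`.
#'
#' @param x an `expr_matrix` on the `normalized` layer.
#' @return An `expr_matrix` on the `lognorm` layer.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "normalized")
    stop_validation("log transform applies to the normalized layer (got ",
                    x$layer, ")")
  v <- x$values
  v@x <- log1p(v@x)
  set_layer(x, v, "lognorm")
}

#' Principal component embedding
#'
#' Centered PCA of log-normalized expression. The sign of every component
#' is fixed so that its largest-magnitude loading is positive, making the
#' embedding deterministic.
#'
#' @param x an `expr_matrix` on the `lognorm` or `residual` layer, or a
#'   plain numeric matrix.
#' @param n_pcs number of components, default 30.
#' @param genes optional gene subset (e.g. from [select_features()]).
#' @return cells x `n_pcs` numeric matrix of scores.
#' @export
compute_pca <- function(x, n_pcs = 30, genes = NULL) {
  m <- if (inherits(x, "expr_matrix")) {
    if (!x$layer %in% c("lognorm", "residual"))
      stop_validation("PCA expects the lognorm or residual layer (got ",
                      x$layer, ")")
    if (!is.null(genes)) x <- subset_cells(x, genes = genes)
    as.matrix(x$values)
  } else as.matrix(x)
  if (n_pcs >= min(dim(m)))
    stop_validation("n_pcs (", n_pcs, ") must be smaller than min(cells, genes)")
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- if (inherits(x, "expr_matrix")) x$cell_ids else rownames(m)
  attr(scores, "sdev") <- pc$sdev
  scores
}

#' Select highly variable genes
#'
#' Default method ranks genes by variance-to-mean dispersion of the
#' log-normalized values and keeps the top `n_features`; `external` accepts
#' a pre-computed gene vector, the hook for plugging in an external feature
#' selector.
#'
#' @param x an `expr_matrix` on the `lognorm` layer.
#' @param n_features number of genes to keep.
#' @param method `"dispersion"` or `"external"`.
#' @param external_genes gene symbols when `method = "external"`.
#' @return Character vector of selected gene symbols.
#' @export
select_features <- function(x, n_features, method = c("dispersion", "external"),
                            external_genes = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  if (method == "external") {
    genes <- toupper(external_genes)
    if (!all(genes %in% x$gene_symbols))
      stop_validation("external gene(s) not present")
    return(genes)
  }
  if (x$layer != "lognorm")
    stop_validation("feature selection expects the lognorm layer")
  if (n_features > ncol(x$values))
    stop_validation("n_features exceeds gene count")
  m <- x$values
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colMeans(m^2)
  v <- (ex2 - mu^2) * nrow(m) / max(1, nrow(m) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, seq_along(disp))
  sel <- ord[seq_len(n_features)]
  x$gene_symbols[sort(sel)]
}

#' Exact k-nearest-neighbour graph
#'
#' Brute-force exact kNN on an embedding, with cosine (default) or
#' Euclidean metric. Self is excluded; distance ties are broken by lower
#' cell index. Computed block-wise so memory stays bounded for large n.
#'
#' @param embedding cells x d numeric matrix.
#' @param k number of neighbours, default 15.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return A `knn_graph`: list with `neighbors` (n x k integer matrix),
#'   `k`, `metric`.
#' @export
build_knn_graph <- function(embedding, k = 15, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(embedding)
  n <- nrow(m)
  if (k >= n) stop_validation("k must be smaller than the number of cells")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- m / nrm
  }
  sq <- rowSums(m^2)
  nb <- matrix(0L, n, k)
  block <- max(1L, min(n, as.integer(2^25 / n)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    # squared Euclidean distances; on unit-normalized rows this is a
    # monotone transform of cosine distance, so neighbour order is identical
    d2 <- outer(sq[idx], sq, `+`) - 2 * tcrossprod(m[idx, , drop = FALSE], m)
    for (r in seq_along(idx)) {
      i <- idx[r]
      d <- d2[r, ]
      d[i] <- Inf
      ord <- order(d, seq_len(n))
      nb[i, ] <- ord[seq_len(k)]
    }
  }
  structure(list(neighbors = nb, k = as.integer(k), metric = metric),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph> %d cells, k = %d, metric = %s\n",
              nrow(x$neighbors), x$k, x$metric))
  invisible(x)
}

#' Cluster a kNN graph by community detection
#'
#' Builds an undirected graph from the kNN adjacency (union of directed
#' edges) and runs Leiden community detection at the given resolution.
#' Cluster ids are dense character labels `"0", "1", ...` ordered by
#' decreasing size; the result is deterministic given `seed`.
#'
#' @param graph a `knn_graph`.
#' @param resolution Leiden resolution parameter, default 1.
#' @param seed integer seed.
#' @return A `cluster_assignment`: list with `cluster` (character vector per
#'   cell) and `n_clusters`.
#' @export
cluster_graph <- function(graph, resolution = 1.0, seed = 1L) {
  stopifnot(inherits(graph, "knn_graph"))
  n <- nrow(graph$neighbors)
  from <- rep(seq_len(n), graph$k)
  to <- as.vector(graph$neighbors)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    igraph::membership(cl)
  })
  sizes <- table(memb)
  new_id <- setNames(seq_along(sizes) - 1L,
                     names(sort(sizes, decreasing = TRUE)))
  lab <- as.character(new_id[as.character(memb)])
  structure(list(cluster = lab, n_clusters = length(sizes)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", length(x$cluster), "cells in", x$n_clusters,
      "clusters\n")
  print(table(x$cluster))
  invisible(x)
}

#' Flag a sample lacking expression of a required marker
#'
#' Implements the sample-exclusion rule: a sample is flagged for exclusion
#' when the fraction of its cells expressing the marker (count > 0) falls
#' below `min_expressing_fraction`. A marker absent from the matrix counts
#' as expressed in no cell (flag raised, with a warning).
#'
#' @param x an `expr_matrix` on the `raw_counts` layer.
#' @param marker gene symbol, e.g. `"SFRP2"`.
#' @param min_expressing_fraction minimum expressing-cell fraction.
#' @return Logical: `TRUE` when the sample should be excluded.
#' @export
flag_sample_marker_absence <- function(x, marker, min_expressing_fraction = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "raw_counts")
    stop_validation("marker absence check uses the raw_counts layer")
  gi <- match(toupper(marker), x$gene_symbols)
  if (is.na(gi)) {
    warning("marker ", marker, " absent from matrix; treating as unexpressed")
    frac <- 0
  } else {
    frac <- sum(x$values[, gi] > 0) / nrow(x$values)
  }
  frac < min_expressing_fraction
}

#' Run the standard preprocessing cycle
#'
#' Convenience composition of the stages a droplet pipeline repeats:
#' gene filtering, per-cell normalization, log transform, optional feature
#' selection, PCA, kNN graph and graph clustering.
#'
#' @param x an `expr_matrix` on the `raw_counts` layer.
#' @param config a [pipeline_config()].
#' @param n_features optional number of variable genes for PCA.
#' @return List with `normalized`, `lognorm` (both `expr_matrix`),
#'   `embedding`, `graph`, `clusters`.
#' @export
preprocess_cycle <- function(x, config = pipeline_config(), n_features = NULL) {
  filt <- filter_genes_min_counts(x, config$min_gene_counts)
  norm <- normalize_per_cell(filt, config$normalization_target)
  logn <- log_transform(norm)
  genes <- if (!is.null(n_features))
    select_features(logn, n_features) else NULL
  emb <- compute_pca(logn, n_pcs = min(config$n_pcs, min(dim(logn)) - 1),
                     genes = genes)
  graph <- build_knn_graph(emb, k = config$knn_k, metric = config$knn_metric)
  clusters <- cluster_graph(graph, resolution = config$clustering_resolution,
                            seed = derive_seed(config$random_seed, "cluster"))
  list(normalized = norm, lognorm = logn, embedding = emb, graph = graph,
       clusters = clusters)
}
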