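#' kNN-smooth expression of selected genes
#'
#' Replaces each cell's value for each gene by the sum of that gene's
#' values over the cell's k nearest neighbours divided by k (the neighbour
#' mean; self excluded per the graph contract, unless the graph was built
#' otherwise). Smoothing denoises sparse genes and sharpens locally
#' enriched expression before rank normalization.
#'
#' @param x an [expression_matrix()]; any layer (the matching chain uses
#'   `normalized` by default, see [match_populations()]).
#' @param graph a `knn_graph` over the same cells.
#' @param genes gene symbols to smooth; genes missing from the matrix are
#'   dropped with a warning (error if none remain).
#' @return Dense cells x genes matrix of smoothed values.
#' @export
knn_smooth <- function(x, graph, genes) {
  stopifnot(inherits(x, "expr_matrix"), inherits(graph, "knn_graph"))
  n <- nrow(x$values)
  if (nrow(graph$neighbors) != n)
    stop_integrity("graph has ", nrow(graph$neighbors), " cells, matrix has ", n)
  genes <- toupper(genes)
  present <- genes %in% x$gene_symbols
  if (!all(present)) {
    if (!any(present))
      stop_validation("none of the requested genes are in the matrix")
    warning("dropping ", sum(!present), " gene(s) not in matrix: ",
            paste(genes[!present], collapse = ", "))
    genes <- genes[present]
  }
  gi <- match(genes, x$gene_symbols)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), graph$k),
    j = as.vector(graph$neighbors),
    x = 1, dims = c(n, n))
  sm <- as.matrix(adj %*% x$values[, gi, drop = FALSE]) / graph$k
  dimnames(sm) <- list(x$cell_ids, genes)
  sm
}

#' Rank-normalize a matrix column-wise
#'
#' Per gene, values across cells are replaced by their ascending rank
#' (ties receive the average rank) divided by the number of cells, giving
#' values in (0, 1]: the unique top-expressing cell gets exactly 1, the
#' lowest gets about 1/n.
#'
#' @param m numeric matrix (cells x genes), e.g. from [knn_smooth()].
#' @return Matrix of the same shape with values in (0, 1].
#' @export
rank_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop_validation("rank normalization needs >= 2 cells")
  apply(m, 2, function(v) rank(v, ties.method = "average") / length(v))
}

#' Per-cell label scores for a marker dictionary
#'
#' For every label, the marker genes are kNN-smoothed, rank-normalized and
#' averaged across genes, giving each cell one score in (0, 1] per label.
#'
#' @param x an `expr_matrix`.
#' @param graph a `knn_graph`.
#' @param markers a `marker_dict` (or named list of gene vectors).
#' @return A `cell_label_scores`: list with `scores` (cells x labels matrix)
#'   and `label_names`.
#' @export
cell_label_scores <- function(x, graph, markers) {
  if (!inherits(markers, "marker_dict")) markers <- marker_dictionary(markers)
  out <- matrix(NA_real_, nrow(x$values), length(markers),
                dimnames = list(x$cell_ids, names(markers)))
  for (lab in names(markers)) {
    genes <- markers[[lab]][markers[[lab]] %in% x$gene_symbols]
    if (!length(genes))
      stop_validation("label '", lab, "' has no marker genes in the matrix")
    dropped <- setdiff(markers[[lab]], genes)
    if (length(dropped))
      warning("label '", lab, "': dropping absent marker(s) ",
              paste(dropped, collapse = ", "))
    sm <- knn_smooth(x, graph, genes)
    rn <- rank_normalize(sm)
    out[, lab] <- rowMeans(rn)
  }
  structure(list(scores = out, label_names = names(markers),
                 cell_ids = x$cell_ids),
            class = "cell_label_scores")
}

#' Aggregate cell scores to cluster-level scores at a percentile
#'
#' For each cluster and label, takes the given percentile (linear
#' interpolation between closest ranks) of the member cells' scores,
#' assigning one number per cluster and label.
#'
#' @param cell_scores a `cell_label_scores`.
#' @param clusters a `cluster_assignment` or character vector per cell.
#' @param percentile percentile in (0, 100], default 70.
#' @return A `cluster_label_scores`: list with `scores` (clusters x labels),
#'   `cluster_ids`, `label_names`, `percentile`.
#' @export
cluster_label_scores <- function(cell_scores, clusters, percentile = 70) {
  stopifnot(inherits(cell_scores, "cell_label_scores"))
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.character(clusters)
  if (length(cl) != nrow(cell_scores$scores))
    stop_integrity("cluster vector length does not match number of cells")
  if (anyNA(cl)) stop_validation("every cell must be clustered")
  ids <- sort(unique(cl))
  s <- matrix(NA_real_, length(ids), length(cell_scores$label_names),
              dimnames = list(ids, cell_scores$label_names))
  for (k in ids) {
    rows <- cell_scores$scores[cl == k, , drop = FALSE]
    if (!nrow(rows)) stop_validation("empty cluster ", k)
    s[k, ] <- apply(rows, 2, percentile_interp, p = percentile)
  }
  structure(list(scores = s, cluster_ids = ids,
                 label_names = cell_scores$label_names,
                 percentile = percentile),
            class = "cluster_label_scores")
}

#' Assign labels to clusters from aggregated scores
#'
#' Each cluster receives the label with its highest score. With
#' `use_intermediate`, labels whose score is within `intermediate_threshold`
#' of the best are merged into a composite name joined by `/` in
#' descending-score order (ties alphabetical). With `min_score` set, a
#' cluster whose best score falls below it receives `fallback_label`
#' instead.
#'
#' @param scores a `cluster_label_scores`.
#' @param intermediate_threshold maximum score gap for merging, default 0.05.
#' @param use_intermediate merge near-ties into composite labels?
#' @param min_score optional minimum best score.
#' @param fallback_label label used below `min_score`.
#' @return Named character vector: cluster id -> label.
#' @export
assign_labels <- function(scores, intermediate_threshold = 0.05,
                          use_intermediate = TRUE, min_score = NULL,
                          fallback_label = NULL) {
  stopifnot(inherits(scores, "cluster_label_scores"))
  if (!is.null(min_score) && is.null(fallback_label))
    stop_validation("min_score requires a fallback_label")
  s <- scores$scores
  out <- character(nrow(s))
  names(out) <- scores$cluster_ids
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    best <- max(row)
    if (!is.null(min_score) && best < min_score) {
      out[i] <- fallback_label
      next
    }
    if (use_intermediate) {
      in_band <- which(best - row <= intermediate_threshold)
      ord <- in_band[order(-row[in_band], scores$label_names[in_band])]
      out[i] <- paste(scores$label_names[ord], collapse = "/")
    } else {
      out[i] <- scores$label_names[which.max(row)]
    }
  }
  out
}

#' Match clusters to marker-defined populations
#'
#' The full population-matching chain: per-label kNN smoothing, rank
#' normalization and gene averaging ([cell_label_scores()]), percentile
#' aggregation per cluster ([cluster_label_scores()]) and label assignment
#' with optional intermediate-state merging and minimum-score fallback
#' ([assign_labels()]).
#'
#' @param x an `expr_matrix`; the `normalized` layer is the recommended
#'   input (cross-cell ranks of raw counts leak per-cell depth).
#' @param graph a `knn_graph`.
#' @param markers a `marker_dict`.
#' @param clusters a `cluster_assignment` or per-cell character vector.
#' @param percentile aggregation percentile, default 70.
#' @param intermediate_threshold score gap for composite labels, default 0.05.
#' @param use_intermediate merge near-ties?
#' @param min_score,fallback_label optional minimum-score fallback.
#' @return A `population_match`: list with `assignment` (cluster -> label),
#'   `cluster_scores`, `cell_scores`, `cell_labels` (per-cell label via its
#'   cluster).
#' @export
match_populations <- function(x, graph, markers, clusters, percentile = 70,
                              intermediate_threshold = 0.05,
                              use_intermediate = TRUE, min_score = NULL,
                              fallback_label = NULL) {
  cs <- cell_label_scores(x, graph, markers)
  ks <- cluster_label_scores(cs, clusters, percentile)
  asg <- assign_labels(ks, intermediate_threshold = intermediate_threshold,
                       use_intermediate = use_intermediate,
                       min_score = min_score, fallback_label = fallback_label)
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.character(clusters)
  structure(list(assignment = asg, cluster_scores = ks, cell_scores = cs,
                 cell_labels = unname(asg[cl])),
            class = "population_match")
}

#' @export
print.population_match <- function(x, ...) {
  cat("<population_match>\n")
  print(data.frame(cluster = names(x$assignment), label = unname(x$assignment),
                   best_score = apply(x$cluster_scores$scores, 1, max),
                   row.names = NULL))
  invisible(x)
}
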