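#' Consensus gene-signature definition
#'
#' A named gene list with its provenance (the source lists it was distilled
#' from and any manual additions) and a classification threshold with a
#' fallback label for clusters scoring below it.
#'
#' @param name signature name, e.g. `"Stress"`.
#' @param genes character vector of gene symbols.
#' @param threshold classification threshold in [0, 1].
#' @param fallback_label label for clusters below threshold.
#' @param source_lists named list of the source gene lists (provenance).
#' @param manual_additions genes added by hand to the consensus.
#' @param min_list_membership consensus rule used (provenance).
#' @return A `signature_def` object.
#' @export
signature_definition <- function(name, genes, threshold, fallback_label,
                                 source_lists = list(),
                                 manual_additions = character(),
                                 min_list_membership = NA_integer_) {
  genes <- unique(toupper(genes))
  if (!length(genes)) stop_validation("signature has no genes")
  if (threshold < 0 || threshold > 1)
    stop_validation("threshold must be in [0, 1]")
  structure(list(name = name, genes = genes, threshold = threshold,
                 fallback_label = fallback_label,
                 source_lists = source_lists,
                 manual_additions = toupper(manual_additions),
                 min_list_membership = min_list_membership),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("<signature_def> %s: %d genes, threshold %.2f (fallback '%s')\n",
              x$name, length(x$genes), x$threshold, x$fallback_label))
  invisible(x)
}

#' Build a consensus signature from multiple source gene lists
#'
#' Genes appearing in at least `min_list_membership` of the source lists
#' form the consensus (the default, 3, selects genes appearing in more than
#' two lists); manually curated genes can then be added to obtain a more
#' robust list. Output gene order is sorted, so the result is independent
#' of input order.
#'
#' @param source_lists named list: source name -> character gene vector.
#' @param min_list_membership minimum number of lists a gene must appear in.
#' @param manual_additions genes appended regardless of membership count.
#' @param name,threshold,fallback_label passed to [signature_definition()].
#' @return A `signature_def`.
#' @export
build_signature <- function(source_lists, min_list_membership = 3,
                            manual_additions = character(),
                            name = "Signature", threshold = 0.5,
                            fallback_label = "Normal") {
  if (!length(source_lists)) stop_validation("need at least one source list")
  lists <- lapply(source_lists, function(g) unique(toupper(g)))
  counts <- table(unlist(lists, use.names = FALSE))
  consensus <- sort(names(counts)[counts >= min_list_membership])
  genes <- sort(unique(c(consensus, toupper(manual_additions))))
  if (!length(genes))
    stop_validation("consensus is empty at min_list_membership = ",
                    min_list_membership, " and no manual additions given")
  signature_definition(name = name, genes = genes, threshold = threshold,
                       fallback_label = fallback_label,
                       source_lists = lists,
                       manual_additions = manual_additions,
                       min_list_membership = min_list_membership)
}

#' Score cells for a gene signature
#'
#' Runs the population-matching scoring chain with a single label (the
#' signature): kNN smoothing, rank normalization and averaging over the
#' signature genes. Identical to [cell_label_scores()] with one label.
#'
#' @param x an `expr_matrix`.
#' @param graph a `knn_graph`.
#' @param sig a `signature_def`.
#' @return Named numeric vector of per-cell scores in (0, 1].
#' @export
score_cells_for_signature <- function(x, graph, sig) {
  stopifnot(inherits(sig, "signature_def"))
  md <- marker_dictionary(setNames(list(sig$genes), sig$name))
  cs <- cell_label_scores(x, graph, md)
  setNames(cs$scores[, 1], x$cell_ids)
}

#' Classify clusters against a signature
#'
#' A cluster receives the signature's name when the percentile-aggregated
#' signature score of its cells is at least the signature threshold, and
#' the fallback label when the score is strictly lower.
#'
#' @param x an `expr_matrix`.
#' @param graph a `knn_graph`.
#' @param clusters a `cluster_assignment` or per-cell character vector.
#' @param sig a `signature_def` (e.g. [stress_signature()]).
#' @param percentile aggregation percentile, default 70.
#' @return A data.frame with `cluster`, `score`, `label`.
#' @export
classify_clusters <- function(x, graph, clusters, sig, percentile = 70) {
  stopifnot(inherits(sig, "signature_def"))
  md <- marker_dictionary(setNames(list(sig$genes), sig$name))
  cs <- cell_label_scores(x, graph, md)
  ks <- cluster_label_scores(cs, clusters, percentile)
  sc <- ks$scores[, 1]
  data.frame(cluster = ks$cluster_ids, score = unname(sc),
             label = ifelse(sc >= sig$threshold, sig$name, sig$fallback_label),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-sum differential expression between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum test on log-normalized values,
#' log2 fold change of group means, Benjamini-Hochberg adjusted p-values.
#' Rows are sorted by increasing p (ties by decreasing absolute fold
#' change).
#'
#' @param x an `expr_matrix` on the `lognorm` layer.
#' @param group_a,group_b cell selections (indices, logical or cell ids),
#'   each of size >= 2 and disjoint.
#' @return data.frame with `gene`, `statistic`, `lfc`, `p`, `p_adj`.
#' @export
differential_expression <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "lognorm")
    stop_validation("differential expression expects the lognorm layer")
  ia <- if (is.character(group_a)) match(group_a, x$cell_ids) else
    which(seq_len(nrow(x$values)) %in% seq_len(nrow(x$values))[group_a])
  ib <- if (is.character(group_b)) match(group_b, x$cell_ids) else
    which(seq_len(nrow(x$values)) %in% seq_len(nrow(x$values))[group_b])
  if (length(ia) < 2 || length(ib) < 2)
    stop_validation("both groups need at least 2 cells")
  if (length(intersect(ia, ib)))
    stop_validation("groups overlap")
  ma <- as.matrix(x$values[ia, , drop = FALSE])
  mb <- as.matrix(x$values[ib, , drop = FALSE])
  na <- length(ia); nb <- length(ib)
  res <- vapply(seq_len(ncol(ma)), function(j) {
    a <- ma[, j]; b <- mb[, j]
    r <- rank(c(a, b))
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U
    # normal approximation with tie correction, as wilcox.test does
    ties <- table(r)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 *
      (na + nb + 1 - sum(ties^3 - ties) / ((na + nb) * (na + nb - 1)))
    z <- if (sig2 > 0) (w - mu) / sqrt(sig2) else 0
    p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    c(z, log2((mean(a) + 1e-9) / (mean(b) + 1e-9)), p)
  }, numeric(3))
  df <- data.frame(gene = x$gene_symbols, statistic = res[1, ],
                   lfc = res[2, ], p = pmin(1, res[3, ]),
                   stringsAsFactors = FALSE)
  df$p_adj <- p.adjust(df$p, method = "BH")
  df[order(df$p, -abs(df$lfc)), , drop = FALSE]
}
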