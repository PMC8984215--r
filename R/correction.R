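#' Regress per-cell covariates out of expression
#'
#' Per gene, ordinary least squares of the log-normalized expression on the
#' covariates plus an intercept; values are replaced by the residuals with
#' the intercept (gene mean structure) retained, so only the covariates'
#' linear contribution is removed. Constant covariates are dropped with a
#' warning; if all are dropped the matrix is returned unchanged.
#'
#' @param x an `expr_matrix` on the `lognorm` layer.
#' @param covariates numeric vector, matrix or data.frame of per-cell
#'   scores (e.g. from [score_cells_for_signature()]).
#' @return An `expr_matrix` on the `residual` layer.
#' @export
regress_out_scores <- function(x, covariates) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$layer %in% c("lognorm", "residual"))
    stop_validation("regression expects the lognorm (or residual) layer")
  z <- as.matrix(covariates)
  if (nrow(z) != nrow(x$values))
    stop_integrity("covariates have ", nrow(z), " rows for ",
                   nrow(x$values), " cells")
  if (!all(is.finite(z))) stop_validation("covariates must be finite")
  keep <- apply(z, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant covariate(s) dropped")
    z <- z[, keep, drop = FALSE]
  }
  if (!ncol(z)) {
    warning("no usable covariates; returning values unchanged")
    return(set_layer(x, x$values, "residual"))
  }
  zc <- scale(z, center = TRUE, scale = FALSE)
  m <- as.matrix(x$values)
  # OLS with intercept: residual = X - Zc (Zc' Zc)^-1 Zc' X, gene means kept
  beta <- solve(crossprod(zc), crossprod(zc, m))
  res <- m - zc %*% beta
  set_layer(x, res, "residual")
}

#' Merge two expression matrices by rows
#'
#' Row-concatenates two matrices on their common gene set (intersection,
#' with a warning when genes are lost); the subset of origin is recorded in
#' `cell_meta$subset_origin` and duplicate cell ids are suffixed.
#'
#' @param a,b `expr_matrix` objects on the same layer.
#' @param names_ab length-2 character: origin tags, default `c("a", "b")`.
#' @return A merged `expr_matrix`.
#' @export
merge_subsets <- function(a, b, names_ab = c("a", "b")) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  if (a$layer != b$layer)
    stop_validation("cannot merge layers ", a$layer, " and ", b$layer)
  common <- intersect(a$gene_symbols, b$gene_symbols)
  if (!length(common)) stop_validation("gene sets are disjoint")
  if (length(common) < length(a$gene_symbols) ||
      length(common) < length(b$gene_symbols))
    warning("merging on ", length(common), " common genes")
  a2 <- subset_cells(a, genes = common)
  b2 <- subset_cells(b, genes = common)
  ids <- c(a2$cell_ids, b2$cell_ids)
  if (anyDuplicated(ids)) {
    warning("duplicate cell ids suffixed")
    ids <- make.unique(ids, sep = "-")
  }
  meta_cols <- union(names(a2$cell_meta), names(b2$cell_meta))
  meta <- data.frame(
    subset_origin = rep(names_ab, c(nrow(a2$values), nrow(b2$values))),
    stringsAsFactors = FALSE)
  for (cc in meta_cols) {
    va <- if (cc %in% names(a2$cell_meta)) a2$cell_meta[[cc]] else
      rep(NA, nrow(a2$values))
    vb <- if (cc %in% names(b2$cell_meta)) b2$cell_meta[[cc]] else
      rep(NA, nrow(b2$values))
    meta[[cc]] <- c(va, vb)
  }
  expression_matrix(rbind(a2$values, b2$values), ids, common,
                    cell_meta = meta, layer = a$layer)
}

#' kNN mixing score between two states
#'
#' For every cell, the fraction of its k nearest neighbours carrying the
#' opposite state label is computed; the mean over cells is divided by its
#' expectation under random mixing, 2 f (1 - f) for state fraction f, and
#' truncated to [0, 1]. A score of 1 means the two states are fully
#' intermingled in the embedding; 0 means fully separated.
#'
#' @param embedding cells x d numeric matrix (e.g. PCA scores).
#' @param state_labels per-cell labels with exactly two distinct values.
#' @param k number of neighbours, default 15.
#' @param metric kNN metric, default `"euclidean"` (embeddings are already
#'   scale-comparable).
#' @return A number in [0, 1].
#' @export
knn_mixing_score <- function(embedding, state_labels, k = 15,
                             metric = "euclidean") {
  lab <- as.character(state_labels)
  states <- unique(lab)
  if (length(states) != 2)
    stop_validation("need exactly two states, got ", length(states))
  g <- build_knn_graph(embedding, k = k, metric = metric)
  is_b <- lab == states[2]
  opp <- vapply(seq_len(nrow(g$neighbors)), function(i)
    mean(is_b[g$neighbors[i, ]] != is_b[i]), numeric(1))
  f <- mean(is_b)
  expected <- 2 * f * (1 - f)
  min(1, max(0, mean(opp) / expected))
}

#' Pre/post-correction integration experiment
#'
#' Reproduces the recoverability contrast for one state program: the cells
#' of that state plus the normal cells are pooled, preprocessed, scored for
#' the signature, and embedded; the mixing between the two states is
#' measured before and after regressing the signature score out of
#' expression. An additive state integrates with normal cells after
#' correction; a destructive one does not.
#'
#' @param x an `expr_matrix` on the `raw_counts` layer containing normal
#'   and state cells.
#' @param states per-cell state labels (e.g. ground truth or
#'   classification); cells labeled `normal_label` or `state_name` are used.
#' @param sig a `signature_def` for the state's gene program.
#' @param state_name state label to test, e.g. `"stress"`.
#' @param normal_label label of unaffected cells, default `"normal"`.
#' @param config a [pipeline_config()].
#' @return A `correction_report`: list with `mixing_pre`, `mixing_post`,
#'   `n_state`, `n_normal`, `state_name`.
#' @export
correction_experiment <- function(x, states, sig, state_name,
                                  normal_label = "normal",
                                  config = pipeline_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(sig, "signature_def"))
  states <- as.character(states)
  sel <- which(states %in% c(state_name, normal_label))
  if (!any(states[sel] == state_name) || !any(states[sel] == normal_label))
    stop_validation("need both '", state_name, "' and '", normal_label,
                    "' cells")
  sub <- subset_cells(x, cells = sel)
  lab <- states[sel]

  filt <- filter_genes_min_counts(sub, config$min_gene_counts)
  norm <- normalize_per_cell(filt, config$normalization_target)
  logn <- log_transform(norm)
  n_pcs <- min(config$n_pcs, min(dim(logn)) - 1)
  emb_pre <- compute_pca(logn, n_pcs = n_pcs)
  graph <- build_knn_graph(emb_pre, k = config$knn_k,
                           metric = config$knn_metric)
  mix_pre <- knn_mixing_score(emb_pre, lab == state_name, k = config$knn_k)

  score <- score_cells_for_signature(norm, graph, sig)
  resid <- regress_out_scores(logn, score)
  emb_post <- compute_pca(resid, n_pcs = n_pcs)
  mix_post <- knn_mixing_score(emb_post, lab == state_name, k = config$knn_k)

  structure(list(state_name = state_name, mixing_pre = mix_pre,
                 mixing_post = mix_post,
                 n_state = sum(lab == state_name),
                 n_normal = sum(lab == normal_label)),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("<correction_report> %s vs normal (%d + %d cells)\n",
              x$state_name, x$n_state, x$n_normal))
  cat(sprintf("  kNN mixing: %.3f before correction, %.3f after\n",
              x$mixing_pre, x$mixing_post))
  invisible(x)
}
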