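# Independent brute-force reimplementation of the matching chain, written
# with explicit loops, sort-based ranks and manual percentile interpolation.
# Deliberately shares no code with the package internals.

oracle_smooth <- function(values, neighbors, gene_idx) {
  n <- nrow(values)
  out <- matrix(0, n, length(gene_idx))
  for (i in seq_len(n)) {
    for (j in seq_along(gene_idx)) {
      s <- 0
      for (nb in neighbors[i, ]) s <- s + values[nb, gene_idx[j]]
      out[i, j] <- s / ncol(neighbors)
    }
  }
  out
}

oracle_rank_normalize <- function(m) {
  n <- nrow(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ord <- order(v)
    rk <- numeric(n)
    i <- 1
    while (i <= n) {
      k <- i
      while (k < n && v[ord[k + 1]] == v[ord[i]]) k <- k + 1
      avg <- mean(i:k)
      for (t in i:k) rk[ord[t]] <- avg
      i <- k + 1
    }
    out[, j] <- rk / n
  }
  out
}

oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100
  lo <- floor(h)
  if (lo + 1 >= length(x)) return(x[length(x)])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Full chain: per-label smoothing -> rank -> gene mean -> per-cluster
# percentile -> assignment with intermediate merging / min-score fallback.
oracle_match <- function(values, neighbors, markers, gene_symbols, clusters,
                         percentile = 70, intermediate_threshold = 0.05,
                         use_intermediate = TRUE, min_score = NULL,
                         fallback_label = NULL) {
  labels <- names(markers)
  cell_scores <- matrix(NA_real_, nrow(values), length(labels))
  for (li in seq_along(labels)) {
    gi <- match(markers[[li]], gene_symbols)
    gi <- gi[!is.na(gi)]
    rn <- oracle_rank_normalize(oracle_smooth(values, neighbors, gi))
    cell_scores[, li] <- rowMeans(rn)
  }
  ids <- sort(unique(clusters))
  cl_scores <- matrix(NA_real_, length(ids), length(labels),
                      dimnames = list(ids, labels))
  for (ki in seq_along(ids)) {
    for (li in seq_along(labels)) {
      cl_scores[ki, li] <-
        oracle_percentile(cell_scores[clusters == ids[ki], li], percentile)
    }
  }
  assignment <- character(length(ids))
  for (ki in seq_along(ids)) {
    row <- cl_scores[ki, ]
    best <- max(row)
    if (!is.null(min_score) && best < min_score) {
      assignment[ki] <- fallback_label
    } else if (use_intermediate) {
      inb <- which(best - row <= intermediate_threshold)
      inb <- inb[order(-row[inb], labels[inb])]
      assignment[ki] <- paste(labels[inb], collapse = "/")
    } else {
      assignment[ki] <- labels[which.max(row)]
    }
  }
  list(cell_scores = cell_scores, cluster_scores = cl_scores,
       assignment = stats::setNames(assignment, ids))
}

# Brute-force exact kNN by full sorting of pairwise distances.
oracle_knn <- function(emb, k, metric) {
  n <- nrow(emb)
  if (metric == "cosine") {
    for (i in seq_len(n)) {
      nv <- sqrt(sum(emb[i, ]^2))
      if (nv > 0) emb[i, ] <- emb[i, ] / nv
    }
  }
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum((emb[i, ] - emb[j, ])^2)
    d[i] <- Inf
    nb[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  nb
}
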