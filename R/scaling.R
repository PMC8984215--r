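#' Time the standard pipeline over a ladder of cell counts
#'
#' Generates one superset dataset at the largest ladder value, then for each
#' cell count and replicate subsamples cells and times the standard stage
#' list: quality-control gene filter, normalization + log transform, PCA,
#' kNN graph, clustering, and one-vs-rest rank-sum differential expression
#' across the clusters. Wall-clock seconds per stage and in total are
#' recorded.
#'
#' @param spec a [generator_spec()]; its `n_cells` is overridden by
#'   `max(cell_ladder)`.
#' @param cell_ladder ascending integer vector of cell counts.
#' @param replicates timed runs per cell count, default 3.
#' @param config a [pipeline_config()].
#' @return A `timing_table` data.frame with columns `n_cells`, `replicate`,
#'   `seconds` and one `stage_*` column per stage.
#' @export
time_pipeline <- function(spec, cell_ladder, replicates = 3,
                          config = pipeline_config()) {
  stopifnot(inherits(spec, "generator_spec"))
  cell_ladder <- as.integer(cell_ladder)
  if (is.unsorted(cell_ladder, strictly = TRUE))
    stop_validation("cell_ladder must be strictly ascending")
  spec$n_cells <- max(cell_ladder)
  gen <- generate_counts(spec)
  super <- gen$matrix
  stages <- c("filter", "normalize_log", "pca", "knn", "cluster", "deg")
  rows <- vector("list", length(cell_ladder) * replicates)
  r <- 0L
  for (n in cell_ladder) {
    for (rep_i in seq_len(replicates)) {
      seed <- derive_seed(spec$random_seed, paste0("bench", n, "_", rep_i))
      cells <- with_seed(seed, sort(sample(nrow(super$values), n)))
      sub <- subset_cells(super, cells = cells)
      t_stage <- setNames(numeric(length(stages)), stages)
      tic <- function(expr) {
        t0 <- proc.time()[["elapsed"]]
        v <- force(expr)
        list(v = v, s = proc.time()[["elapsed"]] - t0)
      }
      s1 <- tic(filter_genes_min_counts(sub, config$min_gene_counts))
      t_stage["filter"] <- s1$s
      s2 <- tic(log_transform(normalize_per_cell(s1$v,
                                                 config$normalization_target)))
      t_stage["normalize_log"] <- s2$s
      s3 <- tic(compute_pca(s2$v, n_pcs = min(config$n_pcs,
                                              min(dim(s2$v)) - 1)))
      t_stage["pca"] <- s3$s
      s4 <- tic(build_knn_graph(s3$v, k = config$knn_k,
                                metric = config$knn_metric))
      t_stage["knn"] <- s4$s
      s5 <- tic(cluster_graph(s4$v, resolution = config$clustering_resolution,
                              seed = seed))
      t_stage["cluster"] <- s5$s
      s6 <- tic({
        cl <- s5$v$cluster
        for (k in unique(cl))
          if (sum(cl == k) >= 2 && sum(cl != k) >= 2)
            differential_expression(s2$v, which(cl == k), which(cl != k))
        NULL
      })
      t_stage["deg"] <- s6$s
      r <- r + 1L
      rows[[r]] <- c(list(n_cells = n, replicate = rep_i,
                          seconds = sum(t_stage)), as.list(t_stage))
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out)[-(1:3)] <- paste0("stage_", stages)
  class(out) <- c("timing_table", "data.frame")
  out
}

#' Fit a two-regime log-log runtime scaling model
#'
#' Ordinary least squares of `log2(seconds)` on `log2(n_cells)`, fitted
#' separately below and above a split point. The per-doubling runtime
#' factor of each regime is `2^slope`. With `split_at = "auto"` every gap
#' between consecutive distinct cell counts is tried (requiring at least
#' two distinct counts per side) and the split minimizing the summed
#' residual sum of squares is kept; when no split improves materially on a
#' single regression (relative RSS reduction below `degenerate_tol`), a
#' single-regime fit is reported and both slopes coincide.
#'
#' @param table a `timing_table` (or data.frame with `n_cells`, `seconds`).
#' @param split_at `"auto"` or a cell count; points with `n_cells <=
#'   split_at` form the low regime.
#' @param degenerate_tol relative RSS-improvement threshold below which the
#'   two-regime fit collapses to one, default 0.05.
#' @return A `scaling_fit` with components `low_slope`, `high_slope`,
#'   `doubling_factors`, `split_point` (geometric midpoint of the bracketing
#'   cell counts; `NA` for a single regime), `regimes` (1 or 2), and the
#'   fitted `lm` objects. Methods: `print`, `coef`, `predict`.
#' @export
fit_piecewise_scaling <- function(table, split_at = "auto",
                                  degenerate_tol = 0.05) {
  df <- as.data.frame(table)
  stopifnot(all(c("n_cells", "seconds") %in% names(df)))
  if (any(df$seconds <= 0)) stop_validation("seconds must be positive")
  df$lx <- log2(df$n_cells)
  df$ly <- log2(df$seconds)
  ns <- sort(unique(df$n_cells))

  fit_one <- function(d) lm(ly ~ lx, data = d)
  rss <- function(f) sum(stats::residuals(f)^2)
  split_fit <- function(s) {
    lo <- df[df$n_cells <= s, , drop = FALSE]
    hi <- df[df$n_cells > s, , drop = FALSE]
    if (length(unique(lo$n_cells)) < 2)
      stop_validation("fewer than 2 distinct cell counts in the low regime")
    if (length(unique(hi$n_cells)) < 2)
      stop_validation("fewer than 2 distinct cell counts in the high regime")
    list(lo = fit_one(lo), hi = fit_one(hi))
  }

  single <- fit_one(df)
  if (identical(split_at, "auto")) {
    if (length(ns) < 4) stop_validation("auto split needs >= 4 distinct counts")
    cand <- ns[2:(length(ns) - 2)]    # >= 2 distinct counts on each side
    fits <- lapply(cand, split_fit)
    tot <- vapply(fits, function(f) rss(f$lo) + rss(f$hi), numeric(1))
    best <- which.min(tot)
    # an (almost) exact single power law: nothing for a split to explain
    improvement <- if (rss(single) > 1e-12)
      (rss(single) - tot[best]) / rss(single) else 0
    if (improvement <= degenerate_tol) {
      sl <- unname(coef(single)[2])
      return(structure(list(low_slope = sl, high_slope = sl,
                            doubling_factors = c(low = 2^sl, high = 2^sl),
                            split_point = NA_real_, regimes = 1L,
                            fits = list(single = single), data = df),
                       class = "scaling_fit"))
    }
    s <- cand[best]
    split_point <- sqrt(s * ns[match(s, ns) + 1])  # geometric midpoint
    f <- fits[[best]]
  } else {
    s <- split_at
    below <- ns[ns <= s]; above <- ns[ns > s]
    split_point <- if (length(below) && length(above))
      sqrt(max(below) * min(above)) else as.numeric(s)
    f <- split_fit(s)
  }
  lo_sl <- unname(coef(f$lo)[2])
  hi_sl <- unname(coef(f$hi)[2])
  structure(list(low_slope = lo_sl, high_slope = hi_sl,
                 doubling_factors = c(low = 2^lo_sl, high = 2^hi_sl),
                 split_point = split_point, regimes = 2L,
                 fits = f, data = df),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  if (x$regimes == 1L) {
    cat(sprintf(
      "<scaling_fit> single regime: slope %.3f (x%.3f runtime per doubling)\n",
      x$low_slope, x$doubling_factors[["low"]]))
  } else {
    cat(sprintf(
      "<scaling_fit> two regimes, split at ~%.0f cells\n  low:  slope %.3f (x%.3f per doubling)\n  high: slope %.3f (x%.3f per doubling)\n",
      x$split_point, x$low_slope, x$doubling_factors[["low"]],
      x$high_slope, x$doubling_factors[["high"]]))
  }
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(low_slope = object$low_slope, high_slope = object$high_slope,
    split_point = object$split_point)
}

#' Predicted runtimes from a scaling fit
#'
#' @param object a `scaling_fit`.
#' @param n_cells cell counts to predict at.
#' @param ... unused.
#' @return Numeric vector of predicted seconds.
#' @export
predict.scaling_fit <- function(object, n_cells, ...) {
  lx <- log2(n_cells)
  if (object$regimes == 1L) {
    ly <- stats::predict(object$fits$single, data.frame(lx = lx))
  } else {
    lo <- n_cells <= object$split_point
    ly <- numeric(length(lx))
    if (any(lo))
      ly[lo] <- stats::predict(object$fits$lo, data.frame(lx = lx[lo]))
    if (any(!lo))
      ly[!lo] <- stats::predict(object$fits$hi, data.frame(lx = lx[!lo]))
  }
  setNames(2^ly, n_cells)
}
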