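# Shared fixtures built in code at test time.

# A tiny dense expression matrix wrapped in the package container.
toy_matrix <- function(values, layer = "raw_counts", ids = NULL,
                       genes = NULL) {
  n <- nrow(values); g <- ncol(values)
  expression_matrix(values,
                    ids %||% sprintf("c%02d", seq_len(n)),
                    genes %||% sprintf("G%02d", seq_len(g)),
                    layer = layer)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small instance for oracle-equivalence checks.
random_instance <- function(seed, max_cells = 50, max_genes = 20) {
  set.seed(seed)
  n <- sample(10:max_cells, 1)
  g <- sample(6:max_genes, 1)
  k <- sample(2:min(8, n - 1), 1)
  values <- matrix(rpois(n * g, lambda = 3), n, g)
  em <- toy_matrix(values)
  graph <- build_knn_graph(matrix(rnorm(n * 3), n, 3), k = k,
                           metric = "euclidean")
  n_lab <- sample(2:3, 1)
  markers <- lapply(seq_len(n_lab), function(i)
    em$gene_symbols[sample(g, sample(2:4, 1))])
  names(markers) <- paste0("L", seq_len(n_lab))
  clusters <- as.character(sample(0:2, n, replace = TRUE))
  list(em = em, graph = graph, markers = markers, clusters = clusters)
}

# A fast two-population generator spec for unit tests.
small_spec <- function(seed = 1, n_cells = 400, n_genes = 150) {
  generator_spec(
    n_cells = n_cells, n_genes = n_genes,
    populations = list(
      list(name = "P1", proportion = 0.5,
           marker_genes = c("MK1", "MK2", "MK3"), marker_fold_change = 8),
      list(name = "P2", proportion = 0.5,
           marker_genes = c("MK4", "MK5", "MK6"), marker_fold_change = 8)),
    random_seed = seed)
}
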