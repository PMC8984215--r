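test_that("gene filter keeps totals at the boundary and preserves order", {
  v <- matrix(0L, 3, 3)
  v[, 1] <- c(10L, 10L, 9L)   # total 29
  v[, 2] <- c(10L, 10L, 10L)  # total 30
  v[, 3] <- c(50L, 25L, 25L)  # total 100
  em <- toy_matrix(v, genes = c("LOW", "EDGE", "HIGH"))
  out <- filter_genes_min_counts(em, 30)
  expect_identical(out$gene_symbols, c("EDGE", "HIGH"))

  expect_identical(filter_genes_min_counts(em, 0)$gene_symbols,
                   em$gene_symbols)
  low <- toy_matrix(matrix(5L, 3, 3))
  expect_error(filter_genes_min_counts(low, 30),
               class = "popmatch_validation_error")
})

test_that("per-cell normalization hits the median target and drops empty cells", {
  v <- matrix(0, 3, 2)
  v[1, ] <- c(60, 40); v[2, ] <- c(150, 50); v[3, ] <- c(100, 200)
  em <- toy_matrix(v)
  out <- normalize_per_cell(em)
  expect_equal(unname(Matrix::rowSums(out$values)), c(200, 200, 200))
  expect_identical(out$layer, "normalized")

  # already equal totals: identity
  v2 <- rbind(c(3, 7), c(5, 5))
  out2 <- normalize_per_cell(toy_matrix(v2))
  expect_equal(as.matrix(out2$values), v2, ignore_attr = TRUE)

  v3 <- rbind(c(5, 5), c(0, 0), c(2, 8))
  expect_warning(out3 <- normalize_per_cell(toy_matrix(v3)), "zero-count")
  expect_equal(nrow(out3$values), 2L)
})

test_that("log transform is log1p and enforces the layer contract", {
  v <- matrix(c(0, exp(1) - 1, 3, 9), 2, 2)
  em <- toy_matrix(matrix(0L, 2, 2), genes = c("G1", "G2"))
  em$values <- methods::as(Matrix::Matrix(v, sparse = TRUE), "CsparseMatrix")
  em$layer <- "normalized"
  out <- log_transform(em)
  expect_equal(as.matrix(out$values)[1, 1], 0)
  expect_equal(as.matrix(out$values)[2, 1], 1)
  expect_identical(out$layer, "lognorm")
  # per-gene rank order unchanged
  expect_identical(order(as.matrix(out$values)[, 2]), order(v[, 2]))
  expect_error(log_transform(out), class = "popmatch_validation_error")
})

test_that("PCA recovers known covariance structure", {
  # rank-1 data: one direction explains everything
  set.seed(1)
  u <- rnorm(40)
  m <- outer(u, c(1, 2, 3))
  s <- compute_pca(m, n_pcs = 2)
  sdev <- attr(s, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.999)

  # 2D points with known covariance: axes match analytic eigenvectors
  set.seed(2)
  n <- 4000
  a <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 0.5))
  theta <- pi / 6
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts <- a %*% t(rot)
  pc <- prcomp(pts)$rotation[, 1]
  analytic <- eigen(cov(pts))$vectors[, 1]
  expect_lt(min(sum((pc - analytic)^2), sum((pc + analytic)^2)), 1e-6)

  expect_error(compute_pca(m, n_pcs = 10),
               class = "popmatch_validation_error")
})

test_that("PCA embedding is deterministic including sign", {
  gen <- generate_counts(small_spec(seed = 31, n_cells = 120))
  logn <- log_transform(normalize_per_cell(gen$matrix))
  e1 <- compute_pca(logn, n_pcs = 10)
  e2 <- compute_pca(logn, n_pcs = 10)
  expect_identical(e1, e2)
})

test_that("dispersion feature selection finds planted markers", {
  gen <- generate_counts(small_spec(seed = 12, n_cells = 600))
  logn <- log_transform(normalize_per_cell(
    filter_genes_min_counts(gen$matrix, 1)))
  sel <- select_features(logn, 50)
  expect_true(all(sprintf("MK%d", 1:6) %in% sel))

  expect_setequal(select_features(logn, ncol(logn$values)),
                  logn$gene_symbols)
  # a constant gene has zero dispersion and is never selected
  v <- cbind(matrix(rpois(40 * 5, 5), 40, 5), 3L)
  em <- toy_matrix(v, genes = c(sprintf("V%d", 1:5), "CONST"))
  em$layer <- "lognorm"
  expect_false("CONST" %in% select_features(em, 5))
  expect_error(select_features(logn, ncol(logn$values) + 1),
               class = "popmatch_validation_error")
})

test_that("kNN graph is exact, self-free and metric-correct", {
  # 3 collinear points: middle point's single neighbour is the nearer end
  emb <- matrix(c(0, 0, 1, 0, 10, 0), 3, 2, byrow = TRUE)
  g <- build_knn_graph(emb, k = 1, metric = "euclidean")
  expect_equal(g$neighbors[2, 1], 1L)

  # cosine is scale-invariant
  set.seed(5)
  pts <- matrix(rnorm(30 * 4), 30, 4)
  g1 <- build_knn_graph(pts, k = 4, metric = "cosine")
  pts2 <- pts
  pts2[7, ] <- 5 * pts2[7, ]
  g2 <- build_knn_graph(pts2, k = 4, metric = "cosine")
  expect_identical(g1$neighbors, g2$neighbors)

  expect_error(build_knn_graph(pts, k = 30),
               class = "popmatch_validation_error")
  expect_false(any(g1$neighbors == row(g1$neighbors)))
})

test_that("kNN graph equals the brute-force all-pairs oracle", {
  set.seed(17)
  for (metric in c("euclidean", "cosine")) {
    emb <- matrix(rnorm(100 * 6), 100, 6)
    g <- build_knn_graph(emb, k = 7, metric = metric)
    expect_identical(g$neighbors, oracle_knn(emb, 7, metric))
  }
  # duplicated points: ties resolved by lower index, no error
  emb2 <- rbind(matrix(rnorm(20 * 3), 20, 3))
  emb2[5, ] <- emb2[9, ]
  g2 <- build_knn_graph(emb2, k = 3, metric = "euclidean")
  expect_identical(g2$neighbors, oracle_knn(emb2, 3, "euclidean"))
})

test_that("graph clustering separates planted blobs deterministically", {
  set.seed(8)
  blob1 <- matrix(rnorm(60 * 3), 60, 3)
  blob2 <- matrix(rnorm(50 * 3, mean = 20), 50, 3)
  emb <- rbind(blob1, blob2)
  g <- build_knn_graph(emb, k = 8, metric = "euclidean")
  # low resolution: communities are the two connected blobs, nothing finer
  cl <- cluster_graph(g, resolution = 0.1, seed = 4)
  expect_equal(cl$n_clusters, 2L)
  membership <- rep(c("a", "b"), c(60, 50))
  expect_equal(length(unique(cl$cluster[membership == "a"])), 1L)
  expect_equal(length(unique(cl$cluster[membership == "b"])), 1L)
  # size-ordered dense ids: the 60-cell blob is cluster "0"
  expect_identical(cl$cluster[1], "0")

  expect_identical(cluster_graph(g, 0.1, seed = 4)$cluster, cl$cluster)
  # on a connected graph the zero-resolution limit is a single community
  one <- build_knn_graph(matrix(rnorm(80 * 3), 80, 3), k = 10,
                         metric = "euclidean")
  expect_equal(cluster_graph(one, resolution = 1e-9, seed = 4)$n_clusters, 1L)
})

test_that("marker-absence flag implements the exclusion rule", {
  v <- matrix(rpois(50 * 3, 4), 50, 3)
  v[, 2] <- 0L
  em <- toy_matrix(v, genes = c("SFRP2", "ABSENT0", "OTHER"))
  expect_false(flag_sample_marker_absence(em, "SFRP2", 0.05))
  expect_true(flag_sample_marker_absence(em, "ABSENT0", 0.05))
  expect_false(flag_sample_marker_absence(em, "ABSENT0", 0))
  expect_warning(flag <- flag_sample_marker_absence(em, "NOTINDATA", 0.05),
                 "absent")
  expect_true(flag)
})

test_that("the full cycle recovers planted populations with high purity", {
  gen <- generate_counts(small_spec(seed = 19, n_cells = 800, n_genes = 200))
  pp <- preprocess_cycle(gen$matrix, pipeline_config(random_seed = 19))
  tab <- table(pp$clusters$cluster, gen$truth$population)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.95)
})
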