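#' Pipeline configuration
#'
#' The tunable parameters of the standard processing and matching pipeline,
#' with the package defaults: discard genes with fewer than 30 total
#' counts, 30 principal components, cosine kNN with k = 15, Leiden
#' resolution 1.0, percentile-70 cluster aggregation, intermediate-state
#' threshold 0.05, median per-cell normalization target.
#'
#' @param min_gene_counts gene-filter threshold.
#' @param n_pcs number of principal components.
#' @param knn_k neighbours per cell.
#' @param knn_metric `"cosine"` or `"euclidean"`.
#' @param clustering_resolution Leiden resolution.
#' @param percentile cluster-score aggregation percentile in (0, 100].
#' @param intermediate_threshold score gap for composite labels.
#' @param random_seed global seed; per-stage seeds are derived from it.
#' @param normalization_target `"median"` or a positive number.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_gene_counts = 30, n_pcs = 30, knn_k = 15,
                            knn_metric = "cosine",
                            clustering_resolution = 1.0, percentile = 70,
                            intermediate_threshold = 0.05, random_seed = 1L,
                            normalization_target = "median") {
  num <- c(min_gene_counts = min_gene_counts, n_pcs = n_pcs, knn_k = knn_k,
           clustering_resolution = clustering_resolution,
           percentile = percentile)
  if (any(num <= 0)) stop_validation("numeric config fields must be positive")
  if (percentile > 100) stop_validation("percentile must be in (0, 100]")
  if (intermediate_threshold < 0)
    stop_validation("intermediate_threshold must be >= 0")
  structure(list(min_gene_counts = min_gene_counts, n_pcs = n_pcs,
                 knn_k = knn_k, knn_metric = knn_metric,
                 clustering_resolution = clustering_resolution,
                 percentile = percentile,
                 intermediate_threshold = intermediate_threshold,
                 random_seed = as.integer(random_seed),
                 normalization_target = normalization_target),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys raise a schema error naming them; missing keys take the
#' package defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_integrity("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), c(known, "generator", "output_dir",
                                 "marker_file", "n_features"))
  if (length(extra))
    stop_validation("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' Run the full analysis end-to-end
#'
#' Composes the pipeline: synthetic data generation (or reading a count
#' directory), preprocessing and clustering, population matching against a
#' marker dictionary, stress and hypoxia cluster classification, state
#' correction with pre/post mixing scores, and report writing. All outputs
#' are TSV files with a provenance header (config hash, seed, package
#' version); re-running with the same config reproduces them.
#'
#' @param config a [pipeline_config()], or path to a YAML config file. When
#'   a YAML file provides a `generator:` block it overrides `spec`.
#' @param output_dir directory for outputs.
#' @param spec a [generator_spec()] used when no count `input_dir` is given.
#' @param input_dir optional directory with `matrix.mtx` sidecar trio to
#'   analyze instead of generated data.
#' @param markers a `marker_dict`, default the fibroblast subtypes.
#' @return Invisibly, a list with the in-memory results (`clusters`,
#'   `match`, `stress_report`, `hypoxia_report`, `correction`, paths).
#' @export
run_analysis <- function(config = pipeline_config(), output_dir,
                         spec = NULL, input_dir = NULL,
                         markers = fibroblast_subtype_markers()) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- read_pipeline_config(config)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(input_dir)) {
    mat <- read_expression_matrix(input_dir)
  } else {
    if (is.null(spec))
      spec <- generator_spec(random_seed = derive_seed(config$random_seed,
                                                       "generate"))
    gen <- generate_counts(spec)
    mat <- gen$matrix
    truth <- gen$truth
  }

  pp <- preprocess_cycle(mat, config)
  match <- match_populations(pp$normalized, pp$graph, markers, pp$clusters,
                             percentile = config$percentile,
                             intermediate_threshold =
                               config$intermediate_threshold)

  stress_rep <- classify_clusters(pp$normalized, pp$graph, pp$clusters,
                                  stress_signature(),
                                  percentile = config$percentile)
  hypoxia_rep <- classify_clusters(pp$normalized, pp$graph, pp$clusters,
                                   hypoxia_signature(),
                                   percentile = config$percentile)

  # stress takes precedence over hypoxia: signature scores are relative
  # ranks, so a stressed cluster can also carry a high hypoxia rank
  state_by_cluster <- setNames(ifelse(
    stress_rep$label == "Stress", "stress",
    ifelse(hypoxia_rep$label == "Hypoxia", "hypoxia", "normal")),
    stress_rep$cluster)
  cell_state <- unname(state_by_cluster[pp$clusters$cluster])

  correction <- NULL
  if (all(c("stress", "normal") %in% cell_state) ||
      all(c("hypoxia", "normal") %in% cell_state)) {
    correction <- list()
    if (all(c("stress", "normal") %in% cell_state))
      correction$stress <- correction_experiment(mat, cell_state,
                                                 stress_signature(), "stress",
                                                 config = config)
    if (all(c("hypoxia", "normal") %in% cell_state))
      correction$hypoxia <- correction_experiment(mat, cell_state,
                                                  hypoxia_signature(),
                                                  "hypoxia", config = config)
  }

  header <- sprintf("# popmatch %s | seed %d | config %s",
                    as.character(utils::packageVersion("popmatch")),
                    config$random_seed, cfg_hash)
  wtsv <- function(df, file) {
    path <- file.path(output_dir, file)
    con <- file(path, "w")
    writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }

  ann <- data.frame(cell_id = mat$cell_ids,
                    cluster = pp$clusters$cluster,
                    label = match$cell_labels,
                    state = cell_state,
                    stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    ann$true_population <- truth$population
    ann$true_state <- truth$state
  }
  paths <- c(
    annotations = wtsv(ann, "annotations.tsv"),
    cell_scores = wtsv(data.frame(cell_id = mat$cell_ids,
                                  match$cell_scores$scores,
                                  check.names = FALSE),
                       "cell_scores.tsv"),
    cluster_scores = wtsv(data.frame(cluster = match$cluster_scores$cluster_ids,
                                     match$cluster_scores$scores,
                                     check.names = FALSE),
                          "cluster_scores.tsv"),
    assignment = wtsv(data.frame(cluster = names(match$assignment),
                                 label = unname(match$assignment)),
                      "assignment.tsv"),
    classification = wtsv(rbind(cbind(signature = "Stress", stress_rep),
                                cbind(signature = "Hypoxia", hypoxia_rep)),
                          "classification.tsv"),
    correction = wtsv(
      if (is.null(correction)) {
        data.frame(state = character(), mixing_pre = numeric(),
                   mixing_post = numeric())
      } else {
        do.call(rbind, lapply(correction, function(r)
          data.frame(state = r$state_name, mixing_pre = r$mixing_pre,
                     mixing_post = r$mixing_post)))
      }, "correction.tsv"))

  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(c(header,
               paste0(names(unclass(config)), " = ",
                      vapply(unclass(config), function(v)
                        paste(format(v), collapse = ","), character(1)))),
             log_path)
  invisible(list(clusters = pp$clusters, match = match,
                 stress_report = stress_rep, hypoxia_report = hypoxia_rep,
                 correction = correction, cell_state = cell_state,
                 paths = c(paths, log = log_path)))
}
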