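#' Specification for the synthetic count generator
#'
#' Describes a multi-donor droplet scRNA-seq experiment with discrete
#' populations defined by marker-gene enrichment. Counts are drawn from a
#' negative-binomial model: the expected count of gene g in cell c is
#' `library_size(c) * donor_factor(c) * gene_rate(g) * fold(c, g)`, where
#' `fold(c, g)` is the population's `marker_fold_change` when g is a marker
#' of c's population and 1 otherwise, and `gene_rate` is the per-gene
#' relative rate (normalized to sum to 1).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param populations list of populations, each a list with `name`,
#'   `proportion`, `marker_genes` (character), `marker_fold_change` (>= 1).
#'   Defaults to the five dermal fibroblast subtypes with their packaged
#'   marker lists at fold change 8.
#' @param n_donors number of donors; cells are assigned to donors by
#'   round-robin within each population.
#' @param donor_effect_sd standard deviation (log scale) of the scalar
#'   per-donor library factor.
#' @param library_size_lognormal `c(mean_log, sd_log)` of per-cell library
#'   sizes.
#' @param baseline_mean optional per-gene positive relative rates (length
#'   `n_genes`); drawn from a gamma distribution when `NULL`. Marker and
#'   state-program genes are floored at the mean rate so planted structure is
#'   expressed at realistic levels.
#' @param dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param state_programs list of [state_program()] objects applied after
#'   base generation.
#' @param random_seed integer seed; the whole draw is deterministic given it.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n_cells = 2000, n_genes = 400,
                           populations = default_populations(),
                           n_donors = 3, donor_effect_sd = 0.1,
                           library_size_lognormal = c(log(2500), 0.3),
                           baseline_mean = NULL, dispersion = 0.4,
                           state_programs = list(), random_seed = 1L) {
  props <- vapply(populations, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop_validation("population proportions must sum to 1")
  for (p in populations) {
    stopifnot(is.character(p$marker_genes), length(p$marker_genes) >= 1)
    if (p$marker_fold_change < 1)
      stop_validation("marker_fold_change must be >= 1")
  }
  if (!is.null(baseline_mean)) {
    stopifnot(length(baseline_mean) == n_genes, all(baseline_mean > 0))
  }
  all_markers <- toupper(unlist(lapply(populations, `[[`, "marker_genes")))
  for (sp in state_programs) {
    stopifnot(inherits(sp, "state_program"))
    if (any(sp$signature_genes %in% all_markers))
      stop_validation("state program '", sp$name,
                      "' signature overlaps population markers")
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 populations = populations, n_donors = as.integer(n_donors),
                 donor_effect_sd = donor_effect_sd,
                 library_size_lognormal = library_size_lognormal,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 state_programs = state_programs,
                 random_seed = as.integer(random_seed)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_populations <- function(fold_change = 8) {
  mk <- fibroblast_subtype_markers()
  props <- c(A1 = 0.30, A2 = 0.25, B1 = 0.20, B2 = 0.15, C = 0.10)
  lapply(names(mk), function(nm) {
    list(name = nm, proportion = unname(props[nm]),
         marker_genes = mk[[nm]], marker_fold_change = fold_change)
  })
}

#' Overlay state program applied to a subset of cells
#'
#' A state program emulates a sample-processing artifact (dissociation
#' stress, hypoxia) that induces a gene signature in a fraction of cells of
#' every population. Two modes are provided:
#' \describe{
#'   \item{`additive_linear`}{adds negative-binomial counts with mean
#'     `magnitude` times the cell's baseline expected count to the signature
#'     genes only. The perturbation is a linear shift along the signature
#'     and is removable by regressing a signature score out of expression.}
#'   \item{`saturating_destructive`}{the same additive signature plus an
#'     identity-program collapse: each affected cell retains only a
#'     cell-specific fraction `u` of its baseline (non-signature) counts,
#'     drawn uniformly in `[1 - loss, 1 - loss + 0.1]`, with the counts
#'     rescaled by `u` and re-rounded, and the lost reads re-drawn from the
#'     population-agnostic baseline profile. Because the collapse direction
#'     is population-specific (each population loses *its own* marker
#'     elevation), the perturbation has rank equal to the number of
#'     populations, and regressing out a single per-cell score can remove
#'     at most one direction of it: the baseline structure is destroyed in
#'     a way no linear function of a score can restore.}
#' }
#'
#' @param name state label, e.g. `"stress"`.
#' @param target_fraction fraction of cells of each population affected,
#'   in (0, 1).
#' @param signature_genes character vector; must be disjoint from population
#'   marker lists.
#' @param mode `"additive_linear"` or `"saturating_destructive"`.
#' @param magnitude positive number: mean added signature expression as a
#'   multiple of baseline.
#' @param loss in [0, 1); fraction of baseline structure destroyed in
#'   destructive mode (retained fraction drawn in
#'   `[1 - loss, 1 - loss + 0.1]`).
#' @return A `state_program` object.
#' @export
state_program <- function(name, target_fraction = 0.4,
                          signature_genes = stress_signature_genes(),
                          mode = c("additive_linear", "saturating_destructive"),
                          magnitude = 10, loss = 0.85) {
  mode <- match.arg(mode)
  if (target_fraction <= 0 || target_fraction >= 1)
    stop_validation("target_fraction must be in (0, 1)")
  if (magnitude < 0) stop_validation("magnitude must be non-negative")
  if (loss < 0 || loss >= 1) stop_validation("loss must be in [0, 1)")
  structure(list(name = name, target_fraction = target_fraction,
                 signature_genes = toupper(signature_genes), mode = mode,
                 magnitude = magnitude, loss = loss),
            class = "state_program")
}

# Gene universe: population markers, program signatures, packaged artifact
# lists, then numbered filler genes.
generator_gene_universe <- function(spec) {
  named <- unique(c(unlist(lapply(spec$populations, `[[`, "marker_genes")),
                    unlist(lapply(spec$state_programs, `[[`, "signature_genes")),
                    stress_signature_genes(), hypoxia_signature_genes()))
  named <- toupper(named)
  if (length(named) > spec$n_genes)
    stop_validation("n_genes (", spec$n_genes,
                    ") smaller than the number of named genes (",
                    length(named), ")")
  filler <- sprintf("G%04d", seq_len(spec$n_genes - length(named)))
  c(named, filler)
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws negative-binomial counts under the model described in
#' [generator_spec()], allocates cells to populations by deterministic
#' largest-remainder quotas, and applies any state programs in the spec.
#'
#' @param spec a [generator_spec()].
#' @return A list with `matrix` (an [expression_matrix()], layer
#'   `raw_counts`) and `truth` (data.frame with per-cell `population`,
#'   `state`, `donor`).
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  genes <- generator_gene_universe(spec)
  for (p in spec$populations)
    if (!all(toupper(p$marker_genes) %in% genes))
      stop_validation("marker gene(s) of ", p$name, " not in gene universe")

  n <- spec$n_cells
  sizes <- quota_allocate(n, vapply(spec$populations, `[[`, numeric(1),
                                    "proportion"))
  pop_of <- rep(vapply(spec$populations, `[[`, character(1), "name"), sizes)
  donor_of <- unlist(lapply(sizes, function(s)
    rep_len(paste0("D", seq_len(spec$n_donors)), s)), use.names = FALSE)

  out <- with_seed(spec$random_seed, {
    rel <- spec$baseline_mean
    if (is.null(rel)) {
      rel <- rgamma(spec$n_genes, shape = 0.6, rate = 1)
      rel <- pmax(rel, 1e-3)
      # named (marker/signature) genes floored at the mean rate: planted
      # structure should not land on an unexpressed gene
      named_idx <- which(!grepl("^G[0-9]{4}$", genes))
      rel[named_idx] <- pmax(rel[named_idx], mean(rel))
    }
    rel <- rel / sum(rel)
    lib <- rlnorm(n, spec$library_size_lognormal[1],
                  spec$library_size_lognormal[2])
    donor_fac <- rlnorm(spec$n_donors, 0, spec$donor_effect_sd)
    names(donor_fac) <- paste0("D", seq_len(spec$n_donors))

    mu <- outer(lib * donor_fac[donor_of], rel)
    for (p in spec$populations) {
      gi <- match(toupper(p$marker_genes), genes)
      ci <- which(pop_of == p$name)
      mu[ci, gi] <- mu[ci, gi] * p$marker_fold_change
    }
    size <- 1 / spec$dispersion
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                     nrow = n)
    list(counts = counts, rel = rel)
  })

  cell_ids <- sprintf("cell_%05d", seq_len(n))
  truth <- data.frame(population = pop_of, state = "normal",
                      donor = donor_of, stringsAsFactors = FALSE,
                      row.names = cell_ids)
  em <- expression_matrix(out$counts, cell_ids, genes,
                          cell_meta = data.frame(donor = donor_of,
                                                 row.names = cell_ids),
                          layer = "raw_counts")
  attr(em, "gene_rel_rate") <- out$rel
  res <- list(matrix = em, truth = truth)
  for (i in seq_along(spec$state_programs))
    res <- apply_state_program(res$matrix, res$truth, spec$state_programs[[i]],
                               seed = derive_seed(spec$random_seed,
                                                  paste0("state", i)))
  res
}

#' Apply a state program to a generated dataset
#'
#' Selects `target_fraction` of the still-normal cells of every population
#' (deterministic quota, randomized membership given `seed`) and perturbs
#' their counts according to the program mode; see [state_program()].
#' Unaffected cells are left bit-identical.
#'
#' @param matrix an [expression_matrix()] on the `raw_counts` layer.
#' @param truth ground-truth data.frame from [generate_counts()].
#' @param program a [state_program()].
#' @param seed integer seed for cell selection and count draws.
#' @return A list with updated `matrix` and `truth`.
#' @export
apply_state_program <- function(matrix, truth, program, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(program, "state_program"))
  if (matrix$layer != "raw_counts")
    stop_validation("state programs apply to the raw_counts layer")
  if (program$name %in% truth$state)
    stop_validation("state '", program$name, "' already present")
  sig_idx <- match(program$signature_genes, matrix$gene_symbols)
  if (anyNA(sig_idx))
    stop_validation("signature gene(s) not in gene universe: ",
                    paste(program$signature_genes[is.na(sig_idx)],
                          collapse = ", "))

  rel <- attr(matrix, "gene_rel_rate")
  counts <- as.matrix(matrix$values)
  truth <- truth

  with_seed(seed, {
    affected <- integer(0)
    for (pop in unique(truth$population)) {
      pool <- which(truth$population == pop & truth$state == "normal")
      n_take <- round(length(pool) * program$target_fraction)
      if (n_take > 0)
        affected <- c(affected, sample(pool, n_take))
    }
    affected <- sort(affected)
    if (length(affected) && program$magnitude > 0) {
      base_mu <- rowSums(counts[affected, , drop = FALSE])
      if (is.null(rel)) {
        gene_tot <- colSums(counts)
        rel <- gene_tot / sum(gene_tot)
        rel <- pmax(rel, 1e-6)
      }
      mu_add <- outer(base_mu, rel[sig_idx]) * program$magnitude
      add <- matrix(rnbinom(length(mu_add), mu = as.vector(mu_add),
                            size = 2.5),
                    nrow = length(affected))
      counts[affected, sig_idx] <- counts[affected, sig_idx] + add
      if (program$mode == "saturating_destructive") {
        u <- runif(length(affected), 1 - program$loss,
                   min(1, 1 - program$loss + 0.1))
        non_sig <- setdiff(seq_len(ncol(counts)), sig_idx)
        kept <- round(counts[affected, non_sig, drop = FALSE] * u)
        mu_re <- outer(base_mu * (1 - u), rel[non_sig] / sum(rel[non_sig]))
        redraw <- matrix(rnbinom(length(mu_re), mu = as.vector(mu_re),
                                 size = 2.5),
                         nrow = length(affected))
        counts[affected, non_sig] <- kept + redraw
      }
    }
    truth$state[affected] <- program$name
  })

  em <- expression_matrix(counts, matrix$cell_ids, matrix$gene_symbols,
                          cell_meta = matrix$cell_meta, layer = "raw_counts")
  attr(em, "gene_rel_rate") <- attr(matrix, "gene_rel_rate")
  list(matrix = em, truth = truth)
}
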