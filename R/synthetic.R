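#' Cohort specification for synthetic donor-paired panels
#'
#' Describes a paired stimulation/blockade cohort: every donor is measured
#' under the same condition list, with a shared per-donor multiplicative
#' scale (the pairing structure) and multiplicative lognormal measurement
#' noise, matching the fold-change-oriented analysis of multiplex
#' supernatant panels.
#'
#' @param n_donors Number of donors (>= 2; default 28 as in the secretome
#'   panels).
#' @param conditions Named list of [condition()] objects shared by all
#'   donors.
#' @param noise_sd Lognormal sigma of measurement noise (default 0.3,
#'   a typical multiplex assay coefficient of variation).
#' @param donor_effect_sd Lognormal sigma of the per-donor scale factor
#'   (default 0.2).
#' @param seed Integer seed.
#' @param mode Simulation mode for the model endpoint (see
#'   [simulate_network()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 28, conditions, noise_sd = 0.3,
                        donor_effect_sd = 0.2, seed = NULL,
                        mode = c("timecourse", "steady_state")) {
  mode <- match.arg(mode)
  if (n_donors < 2) stop("n_donors must be at least 2")
  if (noise_sd < 0 || donor_effect_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (!length(conditions) || !all(vapply(conditions, inherits, logical(1), "culture_condition")))
    stop("'conditions' must be a non-empty list of condition objects")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("'conditions' must be named (condition ids)")
  structure(list(n_donors = as.integer(n_donors), conditions = conditions,
                 noise_sd = noise_sd, donor_effect_sd = donor_effect_sd,
                 seed = seed, mode = mode),
            class = "cohort_spec")
}

#' Simulate a donor-paired cytokine panel
#'
#' Endpoint concentrations per donor and condition are the deterministic
#' model simulation times a shared per-donor lognormal scale times
#' per-measurement lognormal noise.  With both sigmas zero every donor
#' reproduces the model output exactly; a fixed seed gives bit-identical
#' tables.
#'
#' @param net A [ground_truth_network()].
#' @param spec A [cohort_spec()]; its conditions may only reference nodes,
#'   exogenous inputs and receptors defined on `net`.
#' @param receptor_map See [default_receptor_map()].
#' @return A tidy panel `data.frame` with columns `donor_id`,
#'   `condition_id`, `analyte`, `concentration_pg_ml`.
#' @export
simulate_cohort_panel <- function(net, spec,
                                  receptor_map = default_receptor_map()) {
  stopifnot(inherits(net, "ground_truth_network"), inherits(spec, "cohort_spec"))
  config <- as_network_config(net)
  params <- as_model_params(net)
  base <- simulate_network(config, params, spec$conditions, mode = spec$mode)
  n <- nrow(base); nc <- ncol(base); nd <- spec$n_donors
  with_seed(spec$seed, {
    donor_scale <- if (spec$donor_effect_sd > 0)
      stats::rlnorm(nd, 0, spec$donor_effect_sd) else rep(1, nd)
    donor_ids <- sprintf("D%02d", seq_len(nd))
    out <- data.frame(
      donor_id = rep(donor_ids, each = n * nc),
      condition_id = rep(rep(colnames(base), each = n), nd),
      analyte = rep(rownames(base), nc * nd),
      concentration_pg_ml = as.vector(outer(as.vector(base), donor_scale)))
    if (spec$noise_sd > 0)
      out$concentration_pg_ml <- out$concentration_pg_ml *
        stats::rlnorm(nrow(out), 0, spec$noise_sd)
    out
  })
}

#' Tissue cohort specification
#'
#' Describes a synthetic bulk intestinal transcriptome cohort driven by
#' two independent latent module factors per sample -- an "inflammatory
#' cytokine" factor and a "lymphocyte differentiation" factor.  Module
#' member genes load on their factor; planted signature genes load on the
#' inflammatory factor, on both, or on the lymphoid factor; diagnosis and
#' anti-TNF non-response labels are drawn from a logistic link on the
#' inflammatory factor.  Expression noise is additive Gaussian on the
#' log2 scale.
#'
#' @param n_samples Number of biopsy samples (default 200).
#' @param module_sizes Named sizes of the two planted modules.
#' @param n_noise_genes Unstructured background genes (default 150).
#' @param n_signature Planted signature genes per class
#'   (inflammatory-only, both, lymphoid-only); default 10 each.
#' @param loading Factor loading of module genes and single-factor
#'   signature genes (default 1).
#' @param both_loading Loading of dual signature genes on each factor
#'   (default 0.7).
#' @param diagnosis_effect Log-odds of CD diagnosis per SD of the
#'   inflammatory factor (default 1.5).
#' @param response_effect Log-odds of anti-TNF *non*-response per SD of
#'   the inflammatory factor (default 1.5).
#' @param noise_sd Gaussian noise sigma on log2 expression (default 0.3).
#' @param seed Integer seed.
#' @return An object of class `tissue_cohort_spec`.
#' @export
tissue_cohort_spec <- function(n_samples = 200,
                               module_sizes = c(inflammatory = 60, lymphoid = 60),
                               n_noise_genes = 150,
                               n_signature = c(inflammatory_only = 10,
                                               both = 10,
                                               lymphoid_only = 10),
                               loading = 1, both_loading = 0.7,
                               diagnosis_effect = 1.5, response_effect = 1.5,
                               noise_sd = 0.3, seed = NULL) {
  if (n_samples < 4) stop("n_samples must be at least 4")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(all(module_sizes >= 2),
            all(c("inflammatory", "lymphoid") %in% names(module_sizes)),
            all(c("inflammatory_only", "both", "lymphoid_only") %in%
                  names(n_signature)))
  structure(list(n_samples = as.integer(n_samples),
                 module_sizes = module_sizes,
                 n_noise_genes = as.integer(n_noise_genes),
                 n_signature = n_signature, loading = loading,
                 both_loading = both_loading,
                 diagnosis_effect = diagnosis_effect,
                 response_effect = response_effect,
                 noise_sd = noise_sd, seed = seed),
            class = "tissue_cohort_spec")
}

#' Simulate a bulk tissue transcriptome cohort
#'
#' @param spec A [tissue_cohort_spec()].
#' @return An object of class `tissue_cohort`: list with `expr` (genes x
#'   samples log2 matrix), `metadata` (`sample_id`, `diagnosis`,
#'   `inflamed`, `responder`), `factors` (per-sample latent factors),
#'   `modules` (planted gene-to-module map) and `signature`
#'   (`data.frame` of planted signature genes and their true class).
#' @export
simulate_tissue_cohort <- function(spec) {
  stopifnot(inherits(spec, "tissue_cohort_spec"))
  ns <- spec$n_samples
  gene_names <- c(
    sprintf("INFL%03d", seq_len(spec$module_sizes[["inflammatory"]])),
    sprintf("LYMPH%03d", seq_len(spec$module_sizes[["lymphoid"]])),
    sprintf("SIGI%02d", seq_len(spec$n_signature[["inflammatory_only"]])),
    sprintf("SIGB%02d", seq_len(spec$n_signature[["both"]])),
    sprintf("SIGL%02d", seq_len(spec$n_signature[["lymphoid_only"]])),
    sprintf("NOISE%03d", seq_len(spec$n_noise_genes)))
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  with_seed(spec$seed, {
    f_infl <- stats::rnorm(ns); f_lymph <- stats::rnorm(ns)
    li <- c(rep(spec$loading, spec$module_sizes[["inflammatory"]]),
            rep(0, spec$module_sizes[["lymphoid"]]),
            rep(spec$loading, spec$n_signature[["inflammatory_only"]]),
            rep(spec$both_loading, spec$n_signature[["both"]]),
            rep(0, spec$n_signature[["lymphoid_only"]]),
            rep(0, spec$n_noise_genes))
    ll <- c(rep(0, spec$module_sizes[["inflammatory"]]),
            rep(spec$loading, spec$module_sizes[["lymphoid"]]),
            rep(0, spec$n_signature[["inflammatory_only"]]),
            rep(spec$both_loading, spec$n_signature[["both"]]),
            rep(spec$loading, spec$n_signature[["lymphoid_only"]]),
            rep(0, spec$n_noise_genes))
    base <- stats::runif(length(gene_names), 6, 10)   # log2 baseline abundance
    expr <- base + outer(li, f_infl) + outer(ll, f_lymph)
    if (spec$noise_sd > 0)
      expr <- expr + matrix(stats::rnorm(length(expr), 0, spec$noise_sd),
                            nrow(expr))
    dimnames(expr) <- list(gene_names, sprintf("S%03d", seq_len(ns)))
    diagnosis <- ifelse(
      stats::rbinom(ns, 1, stats::plogis(spec$diagnosis_effect * f_infl)) == 1,
      "CD", "control")
    nonresponse <- stats::rbinom(ns, 1, stats::plogis(-0.4 +
      spec$response_effect * f_infl)) == 1
    metadata <- data.frame(
      sample_id = colnames(expr),
      diagnosis = diagnosis,
      inflamed = diagnosis == "CD",
      responder = !nonresponse)
    modules <- stats::setNames(
      rep(c("inflammatory", "lymphoid", "signature", "signature", "signature",
            "noise"),
          times = c(spec$module_sizes[["inflammatory"]],
                    spec$module_sizes[["lymphoid"]],
                    spec$n_signature[["inflammatory_only"]],
                    spec$n_signature[["both"]],
                    spec$n_signature[["lymphoid_only"]],
                    spec$n_noise_genes)),
      gene_names)
    signature <- data.frame(
      gene = grep("^SIG", gene_names, value = TRUE),
      class = rep(c("inflammatory_only", "both", "lymphoid_only"),
                  times = spec$n_signature[c("inflammatory_only", "both",
                                             "lymphoid_only")]))
    structure(list(expr = expr, metadata = metadata,
                   factors = data.frame(sample_id = colnames(expr),
                                        inflammatory = f_infl,
                                        lymphoid = f_lymph),
                   modules = modules, signature = signature, spec = spec),
              class = "tissue_cohort")
  })
}

#' @export
print.tissue_cohort <- function(x, ...) {
  cat("Synthetic tissue cohort:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples;", sum(x$metadata$diagnosis == "CD"), "CD\n")
  invisible(x)
}

#' Single-cell cohort specification
#'
#' Describes condition-labelled monocyte single-cell counts with a planted
#' cluster structure: each condition is a mixture over clusters, each
#' cluster has a mean expression profile, and counts are negative
#' binomial (Poisson in the infinite-dispersion limit).  The default
#' emulates an eight-cluster design across unstimulated, LPS and
#' LPS + anti-IL-10R conditions, with 35 genes specific to the clusters
#' that only appear under LPS + anti-IL-10R.
#'
#' @param n_cells Named vector of cells per condition.
#' @param mixtures Named list (per condition) of named cluster weights,
#'   each summing to 1.
#' @param cluster_means Genes x clusters matrix of mean counts.
#' @param planted_genes Genes elevated only in the target condition's
#'   exclusive clusters (recorded as ground truth).
#' @param target_condition The condition whose exclusive clusters carry
#'   the planted genes.
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @param seed Integer seed.
#' @return An object of class `single_cell_spec`.
#' @export
single_cell_spec <- function(n_cells = c(unstim = 300, LPS = 300,
                                         `LPS+aIL10R` = 300),
                             mixtures = NULL, cluster_means = NULL,
                             planted_genes = NULL,
                             target_condition = "LPS+aIL10R",
                             dispersion = 10, seed = NULL) {
  if (is.null(mixtures)) mixtures <- default_sc_mixtures()
  if (is.null(cluster_means)) {
    prof <- default_sc_profiles()
    cluster_means <- prof$means
    planted_genes <- planted_genes %||% prof$planted
  }
  stopifnot(all(names(n_cells) %in% names(mixtures)))
  for (cn in names(mixtures)) {
    wsum <- sum(mixtures[[cn]])
    if (abs(wsum - 1) > 1e-8)
      stop("mixture weights for condition ", cn, " must sum to 1")
    if (!all(names(mixtures[[cn]]) %in% colnames(cluster_means)))
      stop("mixture references unknown cluster")
  }
  if (any(cluster_means < 0)) stop("cluster means must be non-negative")
  if (dispersion <= 0) stop("dispersion must be positive (Inf = Poisson)")
  structure(list(n_cells = n_cells, mixtures = mixtures,
                 cluster_means = cluster_means,
                 planted_genes = planted_genes %||% character(),
                 target_condition = target_condition,
                 dispersion = dispersion, seed = seed),
            class = "single_cell_spec")
}

# Default eight-cluster design.  Clusters c0/c7 dominate unstimulated
# cells, c1/c2/c5 the LPS response (and persist under IL-10R blockade),
# c3/c4/c6 appear only under LPS + anti-IL-10R and carry the 35 planted
# hyperinflammatory genes.
default_sc_mixtures <- function() {
  list(
    unstim = c(c0 = 0.85, c7 = 0.15),
    LPS = c(c0 = 0.15, c1 = 0.40, c2 = 0.35, c5 = 0.10),
    `LPS+aIL10R` = c(c1 = 0.12, c2 = 0.12, c3 = 0.25, c4 = 0.28,
                     c5 = 0.08, c6 = 0.15))
}

default_sc_profiles <- function(base_mean = 0.6, marker_mass = 100,
                                n_housekeeping = 95) {
  clusters <- paste0("c", 0:7)
  planted <- sprintf("HYPER%02d", 1:35)
  marker_sets <- list(
    c0 = sprintf("C0MARK%02d", 1:20), c7 = sprintf("C7MARK%02d", 1:10),
    c1 = sprintf("C1MARK%02d", 1:15), c2 = sprintf("C2MARK%02d", 1:15),
    c5 = sprintf("C5MARK%02d", 1:10),
    c3 = planted[1:12], c4 = planted[13:24], c6 = planted[25:35])
  hk <- sprintf("HK%03d", seq_len(n_housekeeping))
  genes <- c(planted, unlist(marker_sets[c("c0", "c7", "c1", "c2", "c5")],
                             use.names = FALSE), hk)
  means <- matrix(0.02, length(genes), length(clusters),
                  dimnames = list(genes, clusters))
  means[hk, ] <- base_mean
  # clusters differ in which programme they express, not in total output:
  # each cluster's markers share the same total mass, so per-cell depth is
  # balanced across conditions and depth normalisation stays neutral
  for (cl in names(marker_sets))
    means[marker_sets[[cl]], cl] <- marker_mass / length(marker_sets[[cl]])
  list(means = means, planted = planted)
}

#' Simulate condition-labelled single-cell counts
#'
#' @param spec A [single_cell_spec()].
#' @return List with `counts` (genes x cells integer matrix),
#'   `cell_metadata` (`cell_id`, `condition`, `cluster`) and
#'   `planted_genes`.
#' @export
simulate_single_cells <- function(spec) {
  stopifnot(inherits(spec, "single_cell_spec"))
  with_seed(spec$seed, {
    conds <- names(spec$n_cells)
    cells <- list(); meta <- list()
    for (cn in conds) {
      nc <- spec$n_cells[[cn]]
      wts <- spec$mixtures[[cn]]
      cl <- sample(names(wts), nc, replace = TRUE, prob = wts)
      mu <- spec$cluster_means[, cl, drop = FALSE]
      counts <- if (is.infinite(spec$dispersion)) {
        matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu))
      } else {
        matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                              size = spec$dispersion), nrow(mu))
      }
      rownames(counts) <- rownames(spec$cluster_means)
      cells[[cn]] <- counts
      meta[[cn]] <- data.frame(condition = cn, cluster = cl)
    }
    counts <- do.call(cbind, cells)
    meta <- do.call(rbind, meta)
    meta$cell_id <- sprintf("cell%04d", seq_len(nrow(meta)))
    colnames(counts) <- meta$cell_id
    rownames(meta) <- NULL
    list(counts = counts,
         cell_metadata = meta[, c("cell_id", "condition", "cluster")],
         planted_genes = spec$planted_genes)
  })
}
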