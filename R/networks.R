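#' Receptor-to-ligand map
#'
#' Receptor blockade neutralises every ligand signalling through that
#' receptor.  The default map covers the two receptors blocked in the
#' monocyte stimulation experiments: IL-1R1 (shared by IL-1a and IL-1b)
#' and the IL-10 receptor.
#'
#' @return Named list mapping receptor name to a character vector of ligands.
#' @export
default_receptor_map <- function() {
  list("IL-10R" = "IL-10", "IL-1R1" = c("IL-1a", "IL-1b"))
}

#' Define a network configuration
#'
#' A network configuration is a set of signed directed edges among modelled
#' cytokines -- one point in the model-selection space.  Edge sources may
#' additionally be exogenous inputs (cytokines that are added to cultures
#' but whose production is not modelled, e.g. IFN-g).
#'
#' @param nodes Character vector of modelled cytokine names.
#' @param edges `data.frame` with columns `source`, `target`, `sign`
#'   (+1 activating, -1 inhibiting).  May be `NULL` for an empty edge set.
#' @param exogenous Character vector of input-only sources.
#' @return An object of class `network_config`.
#' @export
network_config <- function(nodes, edges = NULL, exogenous = character()) {
  nodes <- as.character(nodes)
  exogenous <- as.character(exogenous)
  if (anyDuplicated(c(nodes, exogenous)))
    stop("node and exogenous names must be unique")
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  edges <- as.data.frame(edges)[, c("source", "target", "sign")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges)) {
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge signs must be +1 or -1")
    if (!all(edges$source %in% c(nodes, exogenous)))
      stop("unknown edge source: ",
           paste(setdiff(edges$source, c(nodes, exogenous)), collapse = ", "))
    if (!all(edges$target %in% nodes))
      stop("unknown edge target: ",
           paste(setdiff(edges$target, nodes), collapse = ", "))
    if (any(edges$source == edges$target))
      stop("self-edges are not allowed")
    if (anyDuplicated(paste(edges$source, edges$target)))
      stop("at most one edge per ordered node pair")
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, exogenous = exogenous, edges = edges),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("Network configuration:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (length(x$exogenous))
    cat("  exogenous inputs:", paste(x$exogenous, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    arrows <- ifelse(x$edges$sign > 0, "->", "-|")
    cat("  ", paste(x$edges$source, arrows, x$edges$target, collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

edge_labels <- function(edges) {
  if (!nrow(edges)) return(character())
  paste0(edges$source, ifelse(edges$sign > 0, "->", "-|"), edges$target)
}

#' Define an experimental condition
#'
#' A condition combines an innate stimulus with exogenous cytokine
#' additions and ligand or receptor blockades, mirroring the 16-hour
#' monocyte/PBMC stimulation design.
#'
#' @param stimulus One of `"none"`, `"LPS"`, `"bacteria"`.
#' @param additions Named numeric vector of added recombinant cytokine
#'   doses in pg/mL (e.g. `c("IL-10" = 1e4)`).
#' @param ligand_blockades Character vector of neutralised cytokines.
#' @param receptor_blockades Character vector of blocked receptors; each
#'   receptor neutralises all ligands in the receptor map.
#' @return An object of class `culture_condition`.
#' @export
condition <- function(stimulus = c("none", "LPS", "bacteria"),
                      additions = NULL,
                      ligand_blockades = character(),
                      receptor_blockades = character()) {
  stimulus <- match.arg(stimulus)
  additions <- additions %||% numeric()
  if (length(additions) && (is.null(names(additions)) || any(names(additions) == "")))
    stop("'additions' must be a named numeric vector of doses (pg/mL)")
  if (any(additions < 0)) stop("doses must be non-negative")
  if (length(intersect(names(additions), ligand_blockades)))
    stop("a cytokine cannot be both added and ligand-blocked: ",
         paste(intersect(names(additions), ligand_blockades), collapse = ", "))
  structure(list(stimulus = stimulus,
                 additions = additions,
                 ligand_blockades = as.character(ligand_blockades),
                 receptor_blockades = as.character(receptor_blockades)),
            class = "culture_condition")
}

#' @export
print.culture_condition <- function(x, ...) {
  bits <- x$stimulus
  if (length(x$additions))
    bits <- c(bits, paste0("+", names(x$additions)))
  if (length(x$ligand_blockades))
    bits <- c(bits, paste0("anti-", x$ligand_blockades))
  if (length(x$receptor_blockades))
    bits <- c(bits, paste0("anti-", x$receptor_blockades))
  cat("Condition:", paste(bits, collapse = " "), "\n")
  invisible(x)
}

# Full set of neutralised ligands for a condition under a receptor map.
blocked_ligands <- function(cond, receptor_map = default_receptor_map()) {
  unknown <- setdiff(cond$receptor_blockades, names(receptor_map))
  if (length(unknown))
    stop("blockade of unknown receptor: ", paste(unknown, collapse = ", "))
  sort(unique(c(cond$ligand_blockades,
                unlist(receptor_map[cond$receptor_blockades], use.names = FALSE))))
}

#' Ground-truth cytokine network for synthetic cohorts
#'
#' Holds the latent structure behind the synthetic-data generators: signed
#' weighted edges plus the kinetic parameters of the production model.
#'
#' @param nodes Modelled cytokines.
#' @param edges `data.frame` with columns `source`, `target`, `sign`,
#'   `strength` (dimensionless, >= 0).
#' @param basal_unstim Per-node basal production rate (pg/mL/h) without
#'   stimulus.
#' @param basal_stim Per-node stimulus-induced additional production rate
#'   (pg/mL/h).
#' @param degradation Per-node first-order decay rate (1/h), strictly
#'   positive.
#' @param half_saturation Global half-saturation constant K (pg/mL).
#' @param exogenous Input-only sources (dose-driven, not produced).
#' @return An object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(nodes, edges,
                                 basal_unstim, basal_stim, degradation,
                                 half_saturation = 100,
                                 exogenous = character()) {
  cfg <- network_config(nodes, edges[, c("source", "target", "sign")],
                        exogenous = exogenous)
  if (!"strength" %in% names(edges) && nrow(edges))
    stop("ground-truth edges need a 'strength' column")
  strength <- if (nrow(edges)) as.numeric(edges$strength) else numeric()
  if (any(strength < 0)) stop("edge strengths must be non-negative")
  check_rate <- function(x, nm, strict = FALSE) {
    if (is.null(names(x))) names(x) <- nodes
    x <- x[nodes]
    if (any(is.na(x)) || any(x < 0) || (strict && any(x <= 0)))
      stop(sprintf("'%s' must give a %s rate for every node", nm,
                   if (strict) "strictly positive" else "non-negative"))
    x
  }
  structure(list(nodes = cfg$nodes, exogenous = cfg$exogenous,
                 edges = cbind(cfg$edges, strength = strength),
                 basal_unstim = check_rate(basal_unstim, "basal_unstim"),
                 basal_stim = check_rate(basal_stim, "basal_stim"),
                 degradation = check_rate(degradation, "degradation", strict = TRUE),
                 half_saturation = as.numeric(half_saturation)),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("Ground-truth cytokine network (", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges, K = ", x$half_saturation, " pg/mL)\n", sep = "")
  if (nrow(x$edges))
    cat("  ", paste(edge_labels(x$edges), sprintf("(w=%g)", x$edges$strength),
                    collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @describeIn ground_truth_network Strip strengths/rates down to a
#'   `network_config` (the model-selection representation).
#' @param x A `ground_truth_network`.
#' @export
as_network_config <- function(x) {
  stopifnot(inherits(x, "ground_truth_network"))
  network_config(x$nodes, x$edges[, c("source", "target", "sign")],
                 exogenous = x$exogenous)
}

#' @describeIn ground_truth_network Model parameters implied by the ground
#'   truth (for [simulate_network()] / [network_rhs()]).
#' @export
as_model_params <- function(x) {
  stopifnot(inherits(x, "ground_truth_network"))
  model_params(
    s0 = x$basal_unstim / x$degradation,
    sL = (x$basal_unstim + x$basal_stim) / x$degradation,
    delta = x$degradation,
    w = stats::setNames(x$edges$strength, edge_labels(x$edges)),
    K = x$half_saturation)
}

#' Example ground-truth network
#'
#' A six-cytokine network with IFN-g as an exogenous input used throughout
#' the documentation and tests: IL-1b drives IL-23 strongly, IL-10 is a
#' strong negative feedback on IL-23 and a weaker brake on IL-1a, and
#' IL-1a supports IL-6 production.  Stimulated production levels are in
#' the hundreds-to-thousands pg/mL range typical of 16-hour LPS
#' supernatants; decay is 1/h so 16-hour endpoints sit effectively at
#' steady state.
#'
#' @return A [ground_truth_network()].
#' @export
example_ground_truth <- function() {
  nodes <- c("TNF", "IL-1a", "IL-1b", "IL-6", "IL-10", "IL-23")
  edges <- data.frame(
    source   = c("IL-1b", "IL-10", "IL-10", "IL-1a"),
    target   = c("IL-23", "IL-23", "IL-1a", "IL-6"),
    sign     = c(1L, -1L, -1L, 1L),
    strength = c(15, 30, 6, 4))
  ground_truth_network(
    nodes, edges,
    basal_unstim = c(TNF = 15, `IL-1a` = 8, `IL-1b` = 20, `IL-6` = 10,
                     `IL-10` = 20, `IL-23` = 0.5),
    basal_stim   = c(TNF = 1485, `IL-1a` = 792, `IL-1b` = 1980, `IL-6` = 990,
                     `IL-10` = 1980, `IL-23` = 49.5),
    degradation  = c(TNF = 1, `IL-1a` = 1, `IL-1b` = 1, `IL-6` = 1,
                     `IL-10` = 1, `IL-23` = 1),
    half_saturation = 100,
    exogenous = "IFN-g")
}

#' Standard perturbation condition panel
#'
#' Builds the condition set used for edge screening and network fitting:
#' unstimulated control, LPS, LPS with IL-10R blockade, and -- on the LPS
#' background -- one addition and one ligand-blockade condition per
#' modelled cytokine plus an addition condition per exogenous input.
#'
#' @param config A `network_config` or `ground_truth_network` (defines the
#'   node set).
#' @param dose Added recombinant cytokine dose in pg/mL (default 1e4,
#'   i.e. 10 ng/mL).
#' @return Named list of [condition()] objects.
#' @export
perturbation_conditions <- function(config, dose = 1e4) {
  nodes <- config$nodes
  conds <- list(
    "Ctrl" = condition("none"),
    "LPS" = condition("LPS"))
  if ("IL-10" %in% nodes)
    conds[["LPS+aIL10R"]] <- condition("LPS", receptor_blockades = "IL-10R")
  for (j in nodes) {
    conds[[paste0("LPS+", j)]] <-
      condition("LPS", additions = stats::setNames(dose, j))
    conds[[paste0("LPS+anti-", j)]] <-
      condition("LPS", ligand_blockades = j)
  }
  for (j in config$exogenous)
    conds[[paste0("LPS+", j)]] <-
      condition("LPS", additions = stats::setNames(dose, j))
  conds
}
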