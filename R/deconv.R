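#' Detect coexpression modules (reduced weighted correlation network
#' analysis)
#'
#' Builds a signed adjacency \eqn{a_{ij} = ((1 + cor_{ij})/2)^{power}}
#' over genes, converts it to topological-overlap dissimilarity,
#' clusters by average-linkage hierarchical clustering and cuts the tree
#' at a fixed height; clusters below the minimal size are collected into
#' `"unassigned"`.  This is the reduced form of weighted gene
#' correlation network analysis used for the tissue deconvolution:
#' signed adjacency, TOM and a fixed-height cut, with all parameters
#' exposed.
#'
#' @param expr Genes x samples matrix of log-scale expression.
#' @param soft_power Soft-threshold exponent (default 6).
#' @param min_module_size Minimal module size (default 30).
#' @param cut_height Tree cut height on TOM dissimilarity (default 0.5:
#'   genes merging while still sharing most of their topological
#'   neighbourhood stay together; unrelated genes join near height 1).
#' @param top_n_var Optional variance filter: keep only the `top_n_var`
#'   most variable genes.
#' @return An object of class `module_set`: list with `modules` (named
#'   gene-to-label vector, labels `"M1"`, `"M2"`, ... by decreasing size
#'   plus `"unassigned"`), `eigengenes` (samples x modules matrix),
#'   `sizes`, and the parameters used.
#' @export
detect_modules <- function(expr, soft_power = 6, min_module_size = 30,
                           cut_height = 0.5, top_n_var = NULL) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  if (ncol(expr) < 20) stop("need at least 20 samples")
  genes <- rownames(expr) %||% paste0("g", seq_len(nrow(expr)))
  rownames(expr) <- genes
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s)")
    expr <- expr[sds > 0, , drop = FALSE]
    genes <- rownames(expr)
  }
  if (!is.null(top_n_var) && top_n_var < nrow(expr)) {
    keep <- order(apply(expr, 1, stats::var), decreasing = TRUE)[seq_len(top_n_var)]
    expr <- expr[sort(keep), , drop = FALSE]
    genes <- rownames(expr)
  }
  adj <- ((1 + stats::cor(t(expr))) / 2)^soft_power
  diss <- 1 - tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # label modules M1, M2, ... by decreasing size; the rest are unassigned
  ord <- big[order(-sizes[big], as.numeric(big))]
  labels <- stats::setNames(rep("unassigned", length(cl)), genes)
  for (i in seq_along(ord))
    labels[cl == as.numeric(ord[i])] <- paste0("M", i)
  mods <- setdiff(unique(labels), "unassigned")
  eig <- vapply(mods, function(m) eigengene(expr, genes[labels == m]),
                numeric(ncol(expr)))
  if (length(mods)) {
    rownames(eig) <- colnames(expr)
  } else eig <- matrix(numeric(), ncol(expr), 0)
  structure(list(modules = labels, eigengenes = eig,
                 sizes = table(labels),
                 soft_power = soft_power, min_module_size = min_module_size,
                 cut_height = cut_height),
            class = "module_set")
}

# Unsigned topological overlap matrix from an adjacency matrix.
tom_similarity <- function(adj) {
  diag(adj) <- 0
  L <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

#' @export
print.module_set <- function(x, ...) {
  cat("Coexpression modules:",
      sum(names(x$sizes) != "unassigned"), "modules\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the standardised module submatrix: one
#' score per sample, unit norm, sign-oriented so that the mean
#' correlation with the module's genes is non-negative.
#'
#' @param expr Genes x samples matrix.
#' @param genes Module member genes (>= 2, rows of `expr`).
#' @return Named numeric vector (one value per sample, unit norm).
#' @export
eigengene <- function(expr, genes) {
  if (length(genes) < 2) stop("a module needs at least 2 genes")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes absent from expr: ", paste(missing, collapse = ", "))
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stop("module submatrix is constant; eigengene undefined")
  if (any(sds == 0)) sub <- sub[sds > 0, , drop = FALSE]
  z <- t(scale(t(sub)))                     # standardise each gene
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(stats::cor(e, t(sub))) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each (numerically
#' encoded) sample trait, BH-corrected across modules x traits.
#'
#' @param moduleset A [detect_modules()] result (or a samples x modules
#'   eigengene matrix).
#' @param metadata `data.frame` of per-sample traits; logical and
#'   two-level traits are encoded 0/1, non-numeric traits with more
#'   levels are skipped.
#' @param traits Optional subset of trait columns.
#' @return `data.frame` with `module`, `trait`, `r`, `p`, `p_adj`
#'   (constant traits give `NA` with a note in `note`).
#' @export
module_trait_correlation <- function(moduleset, metadata, traits = NULL) {
  eig <- if (inherits(moduleset, "module_set")) moduleset$eigengenes
         else as.matrix(moduleset)
  if (!ncol(eig)) stop("no modules")
  traits <- traits %||% setdiff(names(metadata), "sample_id")
  rows <- list()
  for (tr in traits) {
    v <- metadata[[tr]]
    if (is.logical(v)) v <- as.numeric(v)
    if (is.character(v) || is.factor(v)) {
      lv <- unique(as.character(v))
      if (length(lv) != 2) next
      v <- as.numeric(as.character(v) == sort(lv)[1])
    }
    for (m in colnames(eig)) {
      if (stats::sd(v) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = tr, r = NA_real_, p = NA_real_,
          note = "constant trait")
        next
      }
      ct <- stats::cor.test(eig[, m], v)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = unname(ct$estimate), p = ct$p.value,
        note = "")
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Partition a signature against two module eigengenes
#'
#' Correlates each signature gene with the inflammatory-cytokine and the
#' lymphocyte-differentiation eigengenes and classifies it as
#' `inflammatory_only`, `both`, `lymphoid_only` or `unassigned`.  A gene
#' "correlates" with an eigengene when r >= `r_min` and its BH-adjusted
#' p (corrected across signature genes x 2 eigengenes) is below `alpha`.
#'
#' @param signature_genes Character vector of signature genes.
#' @param expr Genes x samples expression matrix.
#' @param eigengene_infl,eigengene_lymph Per-sample eigengene scores.
#' @param alpha BH-adjusted level (default 0.05).
#' @param r_min Correlation threshold (default 0.3).
#' @return An object of class `signature_partition`: `data.frame` with
#'   per-gene correlations, adjusted p values and `class`; genes absent
#'   from `expr` are reported in attribute `missing` and skipped.
#' @export
partition_signature <- function(signature_genes, expr, eigengene_infl,
                                eigengene_lymph, alpha = 0.05, r_min = 0.3) {
  stop_if_not_scalar_prob(alpha, "alpha")
  missing <- setdiff(signature_genes, rownames(expr))
  if (length(missing))
    message("skipping ", length(missing), " signature gene(s) absent from expr")
  genes <- intersect(signature_genes, rownames(expr))
  if (!length(genes)) stop("no signature genes present in expr")
  corp <- function(g, e) {
    ct <- stats::cor.test(expr[g, ], e)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  ri <- t(vapply(genes, corp, numeric(2), e = eigengene_infl))
  rl <- t(vapply(genes, corp, numeric(2), e = eigengene_lymph))
  p_adj <- bh_adjust(c(ri[, "p"], rl[, "p"]))
  padj_i <- p_adj[seq_along(genes)]
  padj_l <- p_adj[length(genes) + seq_along(genes)]
  hit_i <- ri[, "r"] >= r_min & padj_i < alpha
  hit_l <- rl[, "r"] >= r_min & padj_l < alpha
  cls <- ifelse(hit_i & hit_l, "both",
         ifelse(hit_i, "inflammatory_only",
         ifelse(hit_l, "lymphoid_only", "unassigned")))
  out <- data.frame(gene = genes,
                    r_infl = ri[, "r"], p_infl = ri[, "p"], p_adj_infl = padj_i,
                    r_lymph = rl[, "r"], p_lymph = rl[, "p"], p_adj_lymph = padj_l,
                    class = cls, row.names = NULL)
  structure(out, class = c("signature_partition", "data.frame"),
            missing = missing, alpha = alpha, r_min = r_min)
}
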