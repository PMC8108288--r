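#' Derive condition-specific marker genes from labelled single cells
#'
#' Identifies genes specific to one stimulation condition (the
#' hyperinflammatory LPS + anti-IL-10R signature in the motivating
#' analysis).  Counts are depth-normalised per cell (counts per
#' `scale_factor`, log1p) and each gene is tested against *every* other
#' condition with a two-sided Wilcoxon rank-sum test.  A gene enters the
#' signature when, versus every other condition, its BH-adjusted p is
#' below `alpha` and its log2 fold change is at least
#' `log2(fc_threshold)`, and it is detected in at least
#' `min_detect_frac` of target-condition cells.  BH correction is applied
#' across genes x contrasts.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Per-cell condition labels (length `ncol(counts)`).
#' @param target Target condition label.
#' @param fc_threshold Minimal linear fold change versus each other
#'   condition (default 1.5).
#' @param alpha BH-adjusted level (default 0.05).
#' @param min_detect_frac Minimal detection fraction in target cells
#'   (default 0.1).
#' @param scale_factor Depth normalisation target (default 1e4, counts
#'   per 10k).
#' @return An object of class `condition_markers`: list with `signature`
#'   (character vector) and `table` (per-gene statistics per contrast).
#' @export
condition_marker_genes <- function(counts, labels, target,
                                   fc_threshold = 1.5, alpha = 0.05,
                                   min_detect_frac = 0.1,
                                   scale_factor = 1e4) {
  if (length(labels) != ncol(counts))
    stop("labels must have one entry per cell")
  labels <- as.character(labels)
  conds <- unique(labels)
  if (!target %in% conds) stop("target condition absent: ", target)
  if (length(conds) < 2) stop("need at least 2 conditions")
  genes <- rownames(counts) %||% paste0("g", seq_len(nrow(counts)))

  depth <- colSums(counts)
  depth[depth == 0] <- 1
  norm <- sweep(counts, 2, depth / scale_factor, "/")   # counts per 10k
  lognorm <- log1p(norm)

  ti <- which(labels == target)
  detect_frac <- rowMeans(counts[, ti, drop = FALSE] > 0)
  others <- setdiff(conds, target)
  res <- list()
  for (oc in others) {
    oi <- which(labels == oc)
    mt <- rowMeans(norm[, ti, drop = FALSE])
    mo <- rowMeans(norm[, oi, drop = FALSE])
    log2fc <- log2((mt + 1) / (mo + 1))
    p <- vapply(seq_len(nrow(counts)), function(g)
      suppressWarnings(stats::wilcox.test(lognorm[g, ti],
                                          lognorm[g, oi])$p.value),
      numeric(1))
    p[is.na(p)] <- 1   # all-constant gene
    res[[oc]] <- data.frame(gene = genes, contrast = oc,
                            log2fc = log2fc, p = p, row.names = NULL)
  }
  tab <- do.call(rbind, res)
  tab$p_adj <- bh_adjust(tab$p)
  thr <- log2(fc_threshold)
  pass <- tab$p_adj < alpha & tab$log2fc >= thr
  pass_all <- tapply(pass, factor(tab$gene, genes), all)
  sig <- genes[pass_all & detect_frac >= min_detect_frac]
  tab$detect_frac <- detect_frac[match(tab$gene, genes)]
  structure(list(signature = sig, table = tab, target = target,
                 fc_threshold = fc_threshold, alpha = alpha,
                 min_detect_frac = min_detect_frac),
            class = "condition_markers")
}

#' @export
print.condition_markers <- function(x, ...) {
  cat("Condition-specific signature for '", x$target, "': ",
      length(x$signature), " genes\n", sep = "")
  if (length(x$signature))
    cat("  ", paste(utils::head(x$signature, 10), collapse = ", "),
        if (length(x$signature) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}
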