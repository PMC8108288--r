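#' Area under the precision-recall curve for a single gene
#'
#' Average-precision formulation: items are ranked by decreasing score
#' and precision is accumulated at each positive.  Tied scores are
#' handled as blocks -- every positive in a tied block receives the
#' precision at the end of the block -- so constant scores yield the
#' positive-class prevalence, the random-classifier baseline.  Higher
#' scores predict the positive class.
#'
#' @param scores Numeric per-sample scores (e.g. expression of one gene).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return The AUPRC in `[0, 1]`.
#' @export
gene_auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(is.na(scores)) || any(is.na(labels))) stop("missing values")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  P <- sum(labels)
  if (P == 0 || P == length(labels))
    stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n <- length(s)
  # block ends of tied scores
  ends <- c(which(s[-n] != s[-1]), n)
  cum_tp <- cumsum(y)[ends]
  prec <- cum_tp / ends
  tp_gain <- diff(c(0, cum_tp))
  sum(tp_gain * prec) / P
}

#' Random-classifier baseline
#'
#' The AUPRC of a random classifier equals the positive-class prevalence.
#'
#' @param labels Binary labels.
#' @return `n_positives / n`.
#' @export
random_baseline <- function(labels) {
  labels <- as.numeric(labels)
  if (!length(labels)) stop("empty labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  mean(labels)
}

#' Compare per-gene AUPRC distributions between signature subsets
#'
#' Two-sided Mann-Whitney rank test on per-gene AUPRC values for every
#' pair of subsets, BH-corrected across pairs.  Subsets with fewer than
#' two genes are excluded with a warning.
#'
#' @param auprc_by_subset Named list of numeric AUPRC vectors.
#' @return `data.frame` with `subset_a`, `subset_b`, `p`, `p_adj`.
#' @export
compare_subsets <- function(auprc_by_subset) {
  keep <- vapply(auprc_by_subset, length, integer(1)) >= 2
  if (any(!keep))
    warning("excluding subset(s) with < 2 genes: ",
            paste(names(auprc_by_subset)[!keep], collapse = ", "))
  auprc_by_subset <- auprc_by_subset[keep]
  nms <- names(auprc_by_subset)
  if (length(nms) < 2) stop("need at least two subsets with >= 2 genes")
  pairs <- utils::combn(nms, 2)
  p <- apply(pairs, 2, function(ab)
    suppressWarnings(stats::wilcox.test(auprc_by_subset[[ab[1]]],
                                        auprc_by_subset[[ab[2]]])$p.value))
  data.frame(subset_a = pairs[1, ], subset_b = pairs[2, ],
             p = p, p_adj = bh_adjust(p), row.names = NULL)
}

#' Evaluate a signature partition as single-gene classifiers
#'
#' Computes the per-gene AUPRC of every partitioned signature gene for
#' predicting disease diagnosis and anti-TNF non-response, with the
#' prevalence baseline, and compares the AUPRC distributions across the
#' partition classes.
#'
#' @param expr Genes x samples expression matrix.
#' @param metadata Per-sample `data.frame` with columns `diagnosis`
#'   (positive class `"CD"`) and/or `responder` (logical; positive class
#'   is non-response).
#' @param partition A [partition_signature()] result (or a `data.frame`
#'   with columns `gene`, `class`).
#' @param tasks Subset of `c("diagnosis", "nonresponse")`.
#' @return An object of class `partition_evaluation`: list with `table`
#'   (`gene`, `class`, `task`, `auprc`, `baseline`), `comparisons`
#'   (per-task subset tests) and `medians`.
#' @export
evaluate_partition <- function(expr, metadata, partition,
                               tasks = c("diagnosis", "nonresponse")) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  part <- as.data.frame(partition)[, c("gene", "class")]
  genes <- intersect(part$gene, rownames(expr))
  part <- part[part$gene %in% genes, ]
  labels <- list()
  if ("diagnosis" %in% tasks) {
    if (is.null(metadata$diagnosis)) {
      message("no 'diagnosis' column; task skipped")
    } else labels$diagnosis <- as.numeric(metadata$diagnosis == "CD")
  }
  if ("nonresponse" %in% tasks) {
    if (is.null(metadata$responder)) {
      message("no 'responder' column; task skipped")
    } else labels$nonresponse <- as.numeric(!metadata$responder)
  }
  if (!length(labels)) stop("no task labels available")
  rows <- list()
  for (task in names(labels)) {
    y <- labels[[task]]
    base <- random_baseline(y)
    for (g in part$gene)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, class = part$class[part$gene == g], task = task,
        auprc = gene_auprc(expr[g, ], y), baseline = base)
  }
  tab <- do.call(rbind, rows)
  comparisons <- list(); medians <- list()
  for (task in names(labels)) {
    tt <- tab[tab$task == task, ]
    by_class <- split(tt$auprc, tt$class)
    medians[[task]] <- vapply(by_class, stats::median, numeric(1))
    cmp <- tryCatch(suppressWarnings(compare_subsets(by_class)),
                    error = function(e) NULL)
    if (!is.null(cmp)) {
      cmp$task <- task
      comparisons[[task]] <- cmp
    }
  }
  structure(list(table = tab,
                 comparisons = if (length(comparisons))
                   do.call(rbind, c(comparisons, make.row.names = FALSE))
                 else NULL,
                 medians = medians),
            class = "partition_evaluation")
}

#' @export
print.partition_evaluation <- function(x, ...) {
  cat("Single-gene AUPRC evaluation\n")
  for (task in names(x$medians)) {
    cat("  task", task, "- median AUPRC by class:\n")
    print(round(x$medians[[task]], 3))
  }
  invisible(x)
}
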