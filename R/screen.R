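#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving on input positions (wraps [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p values must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p value on within-donor differences.  Zero
#' differences are dropped first; with `n <= exact_max` untied differences
#' the exact distribution is used, otherwise the normal approximation with
#' tie and continuity correction.
#'
#' @param x,y Per-donor paired values (equal length).
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return The p value, with attribute `degenerate = TRUE` when all
#'   differences are zero (p = 1 by convention).
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- y - x
  d <- d[!is.na(d)]
  if (!length(d)) stop("no complete pairs")
  if (all(d == 0)) return(structure(1, degenerate = TRUE))
  dn <- d[d != 0]
  if (length(dn) < 3)
    stop("need at least 3 non-zero differences")
  ties <- anyDuplicated(abs(dn)) > 0
  use_exact <- !ties && length(dn) <= exact_max
  p <- suppressWarnings(stats::wilcox.test(
    dn, mu = 0, alternative = "two.sided", exact = use_exact,
    correct = TRUE)$p.value)
  structure(min(p, 1), degenerate = FALSE)
}

#' Per-donor paired fold changes
#'
#' Computes test/reference concentration ratios per donor and analyte and
#' their across-donor mean.  The reported summary is the mean of per-donor
#' ratios (not the ratio of condition means).  Reference concentrations
#' are floored at the detection limit before division.
#'
#' @param panel Panel `data.frame` (see [simulate_cohort_panel()]).
#' @param ref,test Condition ids (reference and test).
#' @param epsilon Detection floor (pg/mL) applied to the reference.
#' @return List with `ratios` (`data.frame`: `donor_id`, `analyte`,
#'   `ratio`) and `mean_fc` (named per-analyte mean of ratios).
#' @export
paired_fold_changes <- function(panel, ref, test, epsilon = 1) {
  assert_panel(panel)
  sub <- panel[panel$condition_id %in% c(ref, test), ]
  if (!any(sub$condition_id == ref)) stop("reference condition absent: ", ref)
  if (!any(sub$condition_id == test)) stop("test condition absent: ", test)
  rows <- list()
  for (a in unique(sub$analyte)) {
    sa <- sub[sub$analyte == a, ]
    r <- sa[sa$condition_id == ref, ]
    t <- sa[sa$condition_id == test, ]
    donors <- intersect(r$donor_id, t$donor_id)
    miss <- setdiff(union(r$donor_id, t$donor_id), donors)
    if (length(miss))
      warning("analyte ", a, ": dropping donors without both conditions: ",
              paste(miss, collapse = ", "))
    if (!length(donors))
      stop("analyte ", a, ": no donor has both conditions")
    ratio <- t$concentration_pg_ml[match(donors, t$donor_id)] /
      pmax(r$concentration_pg_ml[match(donors, r$donor_id)], epsilon)
    rows[[a]] <- data.frame(donor_id = donors, analyte = a, ratio = ratio)
  }
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  mean_fc <- vapply(split(ratios$ratio, ratios$analyte), mean, numeric(1))
  list(ratios = ratios, mean_fc = mean_fc)
}

#' Screen for induced analytes in a paired panel
#'
#' The secretome screening rule: an analyte passes when its mean
#' per-donor fold change meets `fc_threshold` and its paired Wilcoxon
#' signed-rank p value survives BH correction across all tested analytes
#' at level `alpha` (defaults 4-fold and 0.05).
#'
#' @inheritParams paired_fold_changes
#' @param fc_threshold Minimal mean fold change (default 4).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A `screen_result` `data.frame` with columns `analyte`,
#'   `mean_fc`, `p`, `p_adj`, `pass`.
#' @export
screen_induced <- function(panel, ref, test, fc_threshold = 4, alpha = 0.05,
                           epsilon = 1) {
  stop_if_not_scalar_prob(alpha, "alpha")
  fc <- paired_fold_changes(panel, ref, test, epsilon = epsilon)
  analytes <- names(fc$mean_fc)
  p <- vapply(analytes, function(a) {
    ra <- fc$ratios[fc$ratios$analyte == a, ]
    r <- panel[panel$condition_id == ref & panel$analyte == a, ]
    t <- panel[panel$condition_id == test & panel$analyte == a, ]
    donors <- ra$donor_id
    as.numeric(wilcoxon_paired(
      r$concentration_pg_ml[match(donors, r$donor_id)],
      t$concentration_pg_ml[match(donors, t$donor_id)]))
  }, numeric(1))
  p_adj <- bh_adjust(p)
  out <- data.frame(analyte = analytes, mean_fc = unname(fc$mean_fc),
                    p = unname(p), p_adj = p_adj,
                    pass = unname(fc$mean_fc) >= fc_threshold & p_adj < alpha)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Differential-expression screen on a log-scale expression matrix
#'
#' Applies the secretome screen logic gene-wise: fold change (on the
#' linear scale, from mean log2 difference) at least `fc_threshold` and a
#' BH-adjusted Wilcoxon p value below `alpha`.  Samples may be paired by
#' donor (signed-rank) or unpaired (rank-sum).
#'
#' @param expr Genes x samples matrix of log2 expression values.
#' @param groups Vector (length `ncol(expr)`) of sample condition labels.
#' @param ref,test Contrast levels of `groups`.
#' @param fc_threshold Minimal linear fold change (default 1.5).
#' @param alpha BH-adjusted level (default 0.05).
#' @param donors Optional vector of donor ids (length `ncol(expr)`)
#'   enabling the paired test.
#' @return List with `up`, `down` (gene names) and the full `table`.
#' @export
de_screen <- function(expr, groups, ref, test, fc_threshold = 1.5,
                      alpha = 0.05, donors = NULL) {
  if (!ref %in% groups) stop("contrast level absent: ", ref)
  if (!test %in% groups) stop("contrast level absent: ", test)
  ri <- which(groups == ref); ti <- which(groups == test)
  paired <- !is.null(donors)
  if (paired) {
    common <- intersect(donors[ri], donors[ti])
    ri <- ri[match(common, donors[ri])]
    ti <- ti[match(common, donors[ti])]
  }
  genes <- rownames(expr) %||% paste0("g", seq_len(nrow(expr)))
  log2fc <- rowMeans(expr[, ti, drop = FALSE]) - rowMeans(expr[, ri, drop = FALSE])
  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ri]; y <- expr[i, ti]
    if (paired) {
      if (all(y - x == 0)) return(1)
      as.numeric(wilcoxon_paired(x, y))
    } else {
      suppressWarnings(stats::wilcox.test(y, x)$p.value)
    }
  }, numeric(1))
  p_adj <- bh_adjust(p)
  tab <- data.frame(gene = genes, log2fc = log2fc, p = p, p_adj = p_adj,
                    row.names = NULL)
  thr <- log2(fc_threshold)
  list(up = genes[tab$log2fc >= thr & p_adj < alpha],
       down = genes[tab$log2fc <= -thr & p_adj < alpha],
       table = tab)
}
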