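# Independent brute-force oracles used to check the package implementations.

# Step-up Benjamini-Hochberg from the definition: adjusted p at rank i is
# min over j >= i of p_(j) * m / j, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (requires untied non-zero absolute differences).
signed_rank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Average precision by explicit threshold sweep: predict positive at
# score >= t for every distinct threshold, accumulate precision times
# recall increment.
auprc_sweep_oracle <- function(scores, labels) {
  labels <- as.numeric(labels)
  P <- sum(labels)
  ap <- 0; recall_prev <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    precision <- tp / sum(sel)
    recall <- tp / P
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

# Per-sample eigengene from the leading eigenvector of the module gene
# correlation matrix (loadings route, vs the package's SVD route).
eigengene_eigen_oracle <- function(expr, genes) {
  sub <- expr[genes, , drop = FALSE]
  z <- t(scale(t(sub)))
  u1 <- eigen(stats::cor(t(sub)), symmetric = TRUE)$vectors[, 1]
  e <- as.vector(t(z) %*% u1)
  e <- e / sqrt(sum(e^2))
  if (mean(stats::cor(e, t(sub))) < 0) e <- -e
  e
}
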