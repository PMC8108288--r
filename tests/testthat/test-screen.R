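test_that("bh_adjust matches the brute-force step-up definition on small grids", {
  set.seed(11)
  for (len in 1:8) {
    for (rep in 1:20) {
      p <- sample(seq(0.01, 1, by = 0.01), len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
  expect_equal(bh_adjust(0.2), 0.2)                       # single p unchanged
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))        # equal ps unchanged
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_true(all(bh_adjust(runif(20)) >= runif(0)))       # no-op guard
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bh adjustment never falls below the raw p values", {
  set.seed(12)
  for (rep in 1:10) {
    p <- runif(15)
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("exact paired Wilcoxon equals full sign enumeration for n <= 10", {
  set.seed(21)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:10) {
      x <- rnorm(n)
      d <- rnorm(n)
      d <- d + sign(d) * 0.01           # keep away from exact zeros
      while (anyDuplicated(abs(d))) d <- rnorm(n)
      y <- x + d
      expect_equal(as.numeric(wilcoxon_paired(x, y)),
                   signed_rank_enum_oracle(d), tolerance = 1e-12)
    }
  }
})

test_that("paired Wilcoxon handles degeneracy, symmetry and the all-positive case", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(as.numeric(wilcoxon_paired(x, x)), 1)
  expect_true(attr(wilcoxon_paired(x, x), "degenerate"))
  # n = 6 all-positive untied differences: p = 2 / 2^6
  y <- x + c(0.1, 0.25, 0.43, 0.6, 0.77, 0.95)
  expect_equal(as.numeric(wilcoxon_paired(x, y)), 2 / 64)
  # swapping the roles of x and y leaves the two-sided p unchanged
  expect_equal(as.numeric(wilcoxon_paired(x, y)),
               as.numeric(wilcoxon_paired(y, x)))
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
  expect_error(wilcoxon_paired(c(1, 2, 3), c(1, 2, 3.5)), "3 non-zero")
})

test_that("paired fold changes are means of per-donor ratios", {
  mk_panel <- function(ref_vals, test_vals, analyte = "IL-23") {
    nd <- length(ref_vals)
    data.frame(
      donor_id = rep(sprintf("D%d", 1:nd), 2),
      condition_id = rep(c("Ctrl", "LPS"), each = nd),
      analyte = analyte,
      concentration_pg_ml = c(ref_vals, test_vals))
  }
  p <- mk_panel(c(10, 20, 40), c(10, 20, 40))
  expect_equal(unname(paired_fold_changes(p, "Ctrl", "LPS")$mean_fc), 1)
  p2 <- mk_panel(c(10, 10), c(20, 80))
  expect_equal(unname(paired_fold_changes(p2, "Ctrl", "LPS")$mean_fc), 5)
  # 3-donor toy panel against hand arithmetic (reference floored at 1)
  p3 <- mk_panel(c(2, 0.5, 8), c(10, 3, 4))
  hand <- mean(c(10 / 2, 3 / 1, 4 / 8))
  expect_equal(unname(paired_fold_changes(p3, "Ctrl", "LPS")$mean_fc), hand)
  # missing pair drops the donor with a warning; all-missing errors
  p4 <- p3[-1, ]
  expect_warning(fc4 <- paired_fold_changes(p4, "Ctrl", "LPS"), "dropping")
  expect_equal(nrow(fc4$ratios), 2)
})

test_that("screen_induced finds exactly the planted inductions", {
  gt <- ground_truth_network(
    c("A", "B", "C", "D", "E"),
    data.frame(source = character(), target = character(), sign = integer()),
    basal_unstim = c(A = 50, B = 50, C = 50, D = 50, E = 50),
    basal_stim = c(A = 450, B = 0, C = 450, D = 0, E = 0),  # A, C induced 10x
    degradation = rep(1, 5))
  conds <- list(Ctrl = condition("none"), LPS = condition("LPS"))
  spec <- cohort_spec(n_donors = 20, conditions = conds, noise_sd = 0.1,
                      donor_effect_sd = 0, seed = 5)
  panel <- simulate_cohort_panel(gt, spec)
  res <- screen_induced(panel, "Ctrl", "LPS", fc_threshold = 4)
  expect_setequal(res$analyte[res$pass], c("A", "C"))
  # an infinite fold-change threshold empties the pass set
  res_inf <- screen_induced(panel, "Ctrl", "LPS", fc_threshold = Inf)
  expect_false(any(res_inf$pass))
  # pass sets are monotone in the fold-change threshold
  res_lo <- screen_induced(panel, "Ctrl", "LPS", fc_threshold = 2)
  expect_true(all(res$analyte[res$pass] %in% res_lo$analyte[res_lo$pass]))
})

test_that("screen_induced holds its type-I error under the null", {
  # two replicate cultures of the same condition: any pass is a false call
  conds <- list(LPS_a = condition("LPS"), LPS_b = condition("LPS"))
  hits <- 0; analytes <- 0
  for (r in 1:200) {
    spec <- cohort_spec(n_donors = 10, conditions = conds, noise_sd = 0.3,
                        donor_effect_sd = 0.2, seed = 3000 + r)
    panel <- simulate_cohort_panel(null_gt_fixture, spec)
    res <- screen_induced(panel, "LPS_a", "LPS_b", fc_threshold = 1)
    hits <- hits + sum(res$pass)
    analytes <- analytes + nrow(res)
  }
  # binomial upper bound at alpha = 0.05 over all analyte tests
  expect_lt(hits / analytes, 0.05 + 3 * sqrt(0.05 * 0.95 / analytes))
})

test_that("de_screen applies the expression screen gene-wise", {
  set.seed(31)
  n_genes <- 60; n_samp <- 12
  expr <- matrix(rnorm(n_genes * 2 * n_samp, 8, 0.2), n_genes,
                 dimnames = list(sprintf("G%02d", 1:n_genes), NULL))
  groups <- rep(c("ctrl", "stim"), each = n_samp)
  planted <- sprintf("G%02d", 1:10)
  expr[planted, groups == "stim"] <- expr[planted, groups == "stim"] + 1  # 2-fold
  res <- de_screen(expr, groups, "ctrl", "stim")
  expect_setequal(res$up, planted)
  expect_length(res$down, 0)
  # contrast of a group against itself yields nothing
  same <- de_screen(cbind(expr[, 1:6], expr[, 1:6]),
                    rep(c("a", "b"), each = 6), "a", "b")
  expect_length(same$up, 0)
  expect_length(same$down, 0)
  # lowering the threshold never shrinks the pass set
  res_lo <- de_screen(expr, groups, "ctrl", "stim", fc_threshold = 1.2)
  expect_true(all(res$up %in% res_lo$up))
  expect_error(de_screen(expr, groups, "ctrl", "missing"), "absent")
})
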